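# Synthetic multi-method ILA study generator. One latent bivariate
# VAR(1) affect process per person drives EMA, end-of-day, and
# day-reconstruction samples plus daily health outcomes.

BASE_DATE <- "2023-05-01"

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the design of a 7-day panel study in older adults:
#' 6 momentary prompts/day in a 12-h window on a 0-100 analog scale,
#' one end-of-day diary per evening, one day of self-selected episodes
#' rated 0-6, and daily health items. Population parameters are set so
#' that mean PA is near 66 and mean NA near 12 with right-skewed NA
#' set-points, and so that the between-person share of rating variance
#' (ICC) lands near 0.6 for PA. The latent process is a stationary
#' person-specific bivariate VAR(1) on an hourly grid.
#'
#' @param n_persons number of persons.
#' @param n_days study days.
#' @param prompts_per_day momentary prompts per day.
#' @param prompt_window clock-hour window for prompts, `c(start, end)`.
#' @param waking_window clock-hour window treated as awake; end-of-day
#'   summaries and episodes cover this window.
#' @param step_hours latent grid step in hours.
#' @param pa_setpoint_mean,pa_setpoint_sd Normal population of PA
#'   set-points (0-100 scale).
#' @param na_setpoint_meanlog,na_setpoint_sdlog log-Normal population of
#'   NA set-points (right-skewed, floor effects near 0).
#' @param ar_pa_mean,ar_pa_sd,ar_na_mean,ar_na_sd Normal populations of
#'   person autoregressive coefficients at the grid step (truncated to
#'   keep the VAR stationary).
#' @param cross_pa_na_mean,cross_pa_na_sd effect of lagged NA on PA.
#' @param cross_na_pa_mean,cross_na_pa_sd effect of lagged PA on NA.
#' @param innovation_sd_pa,innovation_sd_na,innovation_cor innovation
#'   scale and contemporaneous innovation correlation (negative values
#'   give within-person PA/NA anticorrelation, i.e. low dialecticism).
#' @param noise_sd_ema,noise_sd_eod measurement noise SD added at
#'   sampling; episode ratings get quantization error instead.
#' @param ema_completion probability a scheduled prompt is answered
#'   (missing completely at random).
#' @param eod_summary `"day_mean"` (default) or `"peak_end"` recall rule.
#' @param episode_lambda,episode_min,episode_max truncated-Poisson
#'   episode count per day.
#' @param episode_shape gamma shape for relative episode durations.
#' @param health_model per-outcome coefficient vectors
#'   `c(intercept, pa, na, na_innov, noise_sd)` applied to centred true
#'   person parameters; see [generate_health()].
#' @param seed integer seed.
#' @return a `GeneratorConfig` list, class `emodyn_config`.
#' @export
generator_config <- function(n_persons = 90, n_days = 7, prompts_per_day = 6,
                             prompt_window = c(8, 20), waking_window = c(8, 22),
                             step_hours = 1,
                             pa_setpoint_mean = 66, pa_setpoint_sd = 16,
                             na_setpoint_meanlog = 2.2, na_setpoint_sdlog = 0.8,
                             ar_pa_mean = 0.6, ar_pa_sd = 0.12,
                             ar_na_mean = 0.55, ar_na_sd = 0.12,
                             cross_pa_na_mean = -0.05, cross_pa_na_sd = 0.05,
                             cross_na_pa_mean = -0.03, cross_na_pa_sd = 0.05,
                             innovation_sd_pa = 9.6, innovation_sd_na = 7.5,
                             innovation_cor = -0.4,
                             noise_sd_ema = 4, noise_sd_eod = 4,
                             ema_completion = 1,
                             eod_summary = c("day_mean", "peak_end"),
                             episode_lambda = 12, episode_min = 5,
                             episode_max = 20, episode_shape = 2,
                             health_model = default_health_model(),
                             seed = 1L) {
  eod_summary <- match.arg(eod_summary)
  stopifnot(n_persons >= 1, n_days >= 1, prompts_per_day >= 1,
            prompt_window[2] > prompt_window[1],
            waking_window[2] > waking_window[1],
            step_hours > 0,
            pa_setpoint_sd >= 0, ar_pa_sd >= 0, ar_na_sd >= 0,
            innovation_sd_pa >= 0, innovation_sd_na >= 0,
            abs(innovation_cor) <= 1,
            noise_sd_ema >= 0, noise_sd_eod >= 0,
            ema_completion > 0, ema_completion <= 1,
            abs(ar_pa_mean) < 1, abs(ar_na_mean) < 1,
            episode_min >= 1, episode_max >= episode_min)
  cfg <- as.list(environment())
  structure(cfg, class = "emodyn_config")
}

#' @rdname generator_config
#' @export
default_health_model <- function() {
  list(
    general_health = c(intercept = 3.9, pa = 0.012, na = -0.045,
                       na_innov = 0, noise_sd = 0.6),
    pain = c(intercept = 25, pa = -0.15, na = 0.9, na_innov = 0, noise_sd = 12),
    fatigue = c(intercept = 30, pa = -0.25, na = 0.8, na_innov = 0, noise_sd = 12)
  )
}

#' Random prompt schedule within a daily window
#'
#' Prompts are placed sequentially: each spacing is drawn uniformly on
#' `[0.75 * W/n, 1.10 * W/n]` hours, where `W` is the window length, and
#' the first prompt falls one such spacing after the window opens.
#' Prompts past the end of the window are truncated.
#'
#' @param window_start,window_end clock hours bounding the window.
#' @param n nominal number of prompts.
#' @return numeric clock hours of the scheduled prompts (length <= n).
#' @export
generate_prompt_schedule <- function(window_start, window_end, n) {
  if (window_end <= window_start) stop("degenerate prompt window", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  w <- window_end - window_start
  spacing <- stats::runif(n, 0.75 * w / n, 1.10 * w / n)
  times <- window_start + cumsum(spacing)
  times[times <= window_end]
}

# stationary covariance of x_t = A x_{t-1} + eps, eps ~ N(0, Q)
var1_stationary_cov <- function(A, Q) {
  vec <- solve(diag(4) - kronecker(A, A), as.vector(Q))
  matrix(vec, 2, 2)
}

#' Draw one person's latent-process parameters
#'
#' Set-points, autoregressive and cross-lagged coefficients are drawn
#' from the configured populations; coefficient draws yielding a
#' non-stationary VAR (spectral radius >= 0.98) are redrawn, up to
#' `max_retries` times.
#'
#' @param config an `emodyn_config`.
#' @param max_retries redraw budget for stationarity.
#' @return list with `mu` (length-2 set-points), `A` (2x2 lag matrix,
#'   rows = PA/NA outcome), `Q` (innovation covariance).
#' @export
draw_person_params <- function(config, max_retries = 100) {
  mu <- c(pa = stats::rnorm(1, config$pa_setpoint_mean, config$pa_setpoint_sd),
          na = stats::rlnorm(1, config$na_setpoint_meanlog, config$na_setpoint_sdlog))
  for (i in seq_len(max_retries)) {
    A <- matrix(c(stats::rnorm(1, config$ar_pa_mean, config$ar_pa_sd),
                  stats::rnorm(1, config$cross_pa_na_mean, config$cross_pa_na_sd),
                  stats::rnorm(1, config$cross_na_pa_mean, config$cross_na_pa_sd),
                  stats::rnorm(1, config$ar_na_mean, config$ar_na_sd)),
                2, 2, byrow = TRUE)
    if (max(abs(eigen(A, only.values = TRUE)$values)) < 0.98) {
      Q <- diag(c(config$innovation_sd_pa, config$innovation_sd_na)) %*%
        matrix(c(1, config$innovation_cor, config$innovation_cor, 1), 2) %*%
        diag(c(config$innovation_sd_pa, config$innovation_sd_na))
      return(list(mu = mu, A = A, Q = Q))
    }
  }
  stop("could not draw stationary VAR coefficients", call. = FALSE)
}

#' Simulate one person's latent bivariate affect trace
#'
#' A stationary VAR(1) around the person's set-points, initialized from
#' its stationary distribution. The latent state is not clipped; clipping
#' to the 0-100 response scale happens only when observations are
#' sampled.
#'
#' @param params list from [draw_person_params()].
#' @param n_steps number of grid points.
#' @param step_hours grid step (hours).
#' @return list with `hours` (grid, starting at 0) and `x`
#'   (`n_steps` x 2 matrix, columns pa/na).
#' @export
simulate_latent_process <- function(params, n_steps, step_hours = 1) {
  A <- params$A; Q <- params$Q; mu <- params$mu
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("non-stationary VAR parameters", call. = FALSE)
  }
  S0 <- var1_stationary_cov(A, Q)
  L0 <- chol_psd(S0)
  Lq <- chol_psd(Q)
  x <- matrix(0, n_steps, 2, dimnames = list(NULL, c("pa", "na")))
  x[1, ] <- drop(L0 %*% stats::rnorm(2))
  if (n_steps > 1) {
    eps <- matrix(stats::rnorm(2 * (n_steps - 1)), 2) # 2 x (n-1)
    eps <- Lq %*% eps
    for (t in 2:n_steps) {
      x[t, ] <- A %*% x[t - 1, ] + eps[, t - 1]
    }
  }
  x <- sweep(x, 2, mu, "+")
  list(hours = (seq_len(n_steps) - 1) * step_hours, x = x)
}

chol_psd <- function(S) {
  out <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(S, symmetric = TRUE)
    out <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
  }
  out
}

clip01 <- function(x) pmin(100, pmax(0, x))

latent_at <- function(trace, hours) {
  idx <- pmin(length(trace$hours),
              pmax(1, round(hours / (trace$hours[2] - trace$hours[1])) + 1))
  trace$x[idx, , drop = FALSE]
}

#' Sample momentary (EMA) observations from a latent trace
#'
#' @param trace latent trace from [simulate_latent_process()].
#' @param schedule_hours absolute study hours of answered prompts.
#' @param day_index day of each prompt.
#' @param person_id person identifier.
#' @param noise_sd measurement noise SD.
#' @return observation table rows with `method = "EMA"`, scores clipped
#'   to 0-100.
#' @export
sample_ema <- function(trace, schedule_hours, day_index, person_id, noise_sd = 0) {
  v <- latent_at(trace, schedule_hours)
  v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), ncol = 2)
  data.frame(person_id = person_id, method = "EMA",
             timestamp = study_time(schedule_hours),
             day_index = as.integer(day_index),
             pa = clip01(v[, 1]), na = clip01(v[, 2]),
             stringsAsFactors = FALSE)
}

study_time <- function(hours) {
  # second precision so CSV round-trips are exact
  as.POSIXct(paste(BASE_DATE, "00:00:00"), tz = "UTC") + round(hours * 3600)
}

#' Sample one end-of-day diary observation
#'
#' `day_mean` summarizes the day as the mean latent value over the waking
#' window; `peak_end` uses the average of the day's maximum and final
#' waking value (a recall-bias variant).
#'
#' @param trace latent trace.
#' @param day day index (1-based).
#' @param config an `emodyn_config`.
#' @param person_id person identifier.
#' @return one observation row with `method = "EOD"`, timestamped 21:00.
#' @export
sample_eod <- function(trace, day, config, person_id) {
  h0 <- (day - 1) * 24 + config$waking_window[1]
  h1 <- (day - 1) * 24 + config$waking_window[2]
  sel <- trace$hours >= h0 & trace$hours <= h1
  vals <- trace$x[sel, , drop = FALSE]
  summ <- switch(config$eod_summary,
    day_mean = colMeans(vals),
    peak_end = (apply(vals, 2, max) + vals[nrow(vals), ]) / 2,
    stop("unknown eod_summary mode", call. = FALSE)
  )
  summ <- summ + stats::rnorm(2, 0, config$noise_sd_eod)
  data.frame(person_id = person_id, method = "EOD",
             timestamp = study_time((day - 1) * 24 + 21),
             day_index = as.integer(day),
             pa = clip01(summ[1]), na = clip01(summ[2]),
             stringsAsFactors = FALSE)
}

#' Sample one day of self-selected episodes
#'
#' The waking window is partitioned into K contiguous episodes (K from a
#' truncated Poisson, relative durations from a gamma renormalized to the
#' window). Each episode is rated with the mean latent value over its
#' span, mapped to the raw 0-6 scale by inverting the rescale formula.
#'
#' @param trace latent trace.
#' @param day day index the episodes reconstruct.
#' @param config an `emodyn_config`.
#' @param person_id person identifier.
#' @return episode table rows (`start`, `end`, `raw_pa`, `raw_na`).
#' @export
sample_drm <- function(trace, day, config, person_id) {
  k <- max(config$episode_min,
           min(config$episode_max, stats::rpois(1, config$episode_lambda)))
  if (k < 1) stop("episode count must be >= 1", call. = FALSE)
  w0 <- config$waking_window[1]; w1 <- config$waking_window[2]
  dur <- 0.25 + stats::rgamma(k, shape = config$episode_shape, rate = 1)
  dur <- dur / sum(dur) * (w1 - w0)
  bounds <- w0 + c(0, cumsum(dur))
  bounds[k + 1] <- w1            # exact partition
  bounds <- round(bounds * 60) / 60  # respondents enter clock times in minutes
  day0 <- (day - 1) * 24
  step <- trace$hours[2] - trace$hours[1]
  raw <- matrix(0L, k, 2)
  for (j in seq_len(k)) {
    sel <- trace$hours >= day0 + bounds[j] - step / 2 &
           trace$hours < day0 + bounds[j + 1] + step / 2
    m <- clip01(colMeans(trace$x[sel, , drop = FALSE]))
    raw[j, ] <- drm_quantize(m)
  }
  data.frame(person_id = person_id, day_index = as.integer(day),
             start = study_time(day0 + bounds[seq_len(k)]),
             end = study_time(day0 + bounds[-1]),
             raw_pa = raw[, 1], raw_na = raw[, 2],
             label = paste0("episode_", seq_len(k)),
             stringsAsFactors = FALSE)
}

#' Generate daily health records from true person parameters
#'
#' Each outcome is a linear function of the person's centred true
#' set-points (and optionally NA innovation SD) plus daily Gaussian
#' noise: general health is rounded and clipped to the 1-5 ordinal scale
#' (5 = excellent), pain and fatigue clipped to 0-100.
#'
#' @param truth per-person truth table with `mu_pa`, `mu_na`,
#'   `innovation_sd_na` columns.
#' @param config an `emodyn_config` (supplies `health_model`, `n_days`,
#'   and centring constants).
#' @return daily health table (one row per person-day).
#' @export
generate_health <- function(truth, config) {
  hm <- config$health_model
  mu_na_pop <- exp(config$na_setpoint_meanlog + config$na_setpoint_sdlog^2 / 2)
  pa_c <- truth$mu_pa - config$pa_setpoint_mean
  na_c <- truth$mu_na - mu_na_pop
  ni_c <- truth$innovation_sd_na - config$innovation_sd_na
  n <- nrow(truth)
  out <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
    lin <- function(co) co[["intercept"]] + co[["pa"]] * pa_c +
      co[["na"]] * na_c + co[["na_innov"]] * ni_c +
      stats::rnorm(n, 0, co[["noise_sd"]])
    data.frame(person_id = truth$person_id, day_index = d,
               general_health = pmin(5L, pmax(1L, as.integer(round(lin(hm$general_health))))),
               pain = clip01(lin(hm$pain)),
               fatigue = clip01(lin(hm$fatigue)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$person_id, out$day_index), ]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic multi-method study
#'
#' One latent VAR(1) process per person drives all three assessment
#' methods: momentary prompts every day, one end-of-day diary each
#' evening, and one day (uniformly chosen among days 2..n_days) of
#' reconstructed episodes. Daily health records are derived from the
#' true person parameters. Deterministic given `(config, seed)`.
#'
#' @param config an `emodyn_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with `study` (an `ila_study`) and `truth` (data frame of
#'   true person parameters plus a list column of latent traces in
#'   `attr(truth, "traces")`).
#' @export
generate_study <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "emodyn_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n_steps <- as.integer(config$n_days * 24 / config$step_hours) + 1L
  ids <- sprintf("p%03d", seq_len(config$n_persons))
  obs <- vector("list", config$n_persons)
  eps <- vector("list", config$n_persons)
  truth <- vector("list", config$n_persons)
  traces <- vector("list", config$n_persons)
  for (i in seq_along(ids)) {
    prm <- draw_person_params(config)
    trace <- simulate_latent_process(prm, n_steps, config$step_hours)
    traces[[i]] <- trace
    drm_day <- if (config$n_days >= 2) sample(2:config$n_days, 1) else 1L
    ema <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      sched <- generate_prompt_schedule(config$prompt_window[1],
                                        config$prompt_window[2],
                                        config$prompts_per_day)
      if (config$ema_completion < 1) {
        sched <- sched[stats::runif(length(sched)) <= config$ema_completion]
      }
      if (!length(sched)) return(NULL)
      sample_ema(trace, (d - 1) * 24 + sched, rep(d, length(sched)), ids[i],
                 config$noise_sd_ema)
    }))
    eod <- do.call(rbind, lapply(seq_len(config$n_days), function(d) {
      sample_eod(trace, d, config, ids[i])
    }))
    eps[[i]] <- sample_drm(trace, drm_day, config, ids[i])
    obs[[i]] <- rbind(ema, eod)
    truth[[i]] <- data.frame(
      person_id = ids[i], mu_pa = prm$mu[1], mu_na = prm$mu[2],
      ar_pa = prm$A[1, 1], cross_pa_na = prm$A[1, 2],
      cross_na_pa = prm$A[2, 1], ar_na = prm$A[2, 2],
      innovation_sd_pa = sqrt(prm$Q[1, 1]),
      innovation_sd_na = sqrt(prm$Q[2, 2]),
      true_density = sum(abs(prm$A)),
      drm_day = drm_day, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  health <- generate_health(truth, config)
  study <- ila_study(do.call(rbind, obs), episodes = do.call(rbind, eps),
                     health = health)
  attr(truth, "traces") <- traces
  list(study = study, truth = truth)
}

#' Population ICC implied by a generator configuration
#'
#' Between-person variance is the configured set-point variance; within
#' is the stationary VAR variance at the population-mean coefficients
#' plus measurement noise. Clipping to 0-100 is ignored, so this is an
#' approximation (close for PA, rougher for floor-affected NA).
#'
#' @param config an `emodyn_config`.
#' @param affect `"pa"` or `"na"`.
#' @return expected between/(between+within) variance ratio of momentary
#'   ratings.
#' @export
expected_icc <- function(config, affect = c("pa", "na")) {
  affect <- match.arg(affect)
  A <- matrix(c(config$ar_pa_mean, config$cross_pa_na_mean,
                config$cross_na_pa_mean, config$ar_na_mean), 2, 2, byrow = TRUE)
  Q <- diag(c(config$innovation_sd_pa, config$innovation_sd_na)) %*%
    matrix(c(1, config$innovation_cor, config$innovation_cor, 1), 2) %*%
    diag(c(config$innovation_sd_pa, config$innovation_sd_na))
  S <- var1_stationary_cov(A, Q)
  j <- if (affect == "pa") 1 else 2
  within <- S[j, j] + config$noise_sd_ema^2
  between <- if (affect == "pa") {
    config$pa_setpoint_sd^2
  } else {
    (exp(config$na_setpoint_sdlog^2) - 1) *
      exp(2 * config$na_setpoint_meanlog + config$na_setpoint_sdlog^2)
  }
  between / (between + within)
}
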