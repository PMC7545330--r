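# The per-person emotion-dynamics battery: mean level, variability
# (within-person SD), instability (RMSSD over gap-filtered successive
# pairs), inertia (EB autoregressive slope), network density (sum of
# absolute EB lagged parameters), mixed emotions (MIN index), and
# dialecticism (within-person PA-NA correlation).

#' Names of the 11 dynamics measures, in canonical order
#' @export
dynamics_measures <- function() {
  c("pa_mean", "na_mean", "pa_sd", "na_sd", "pa_rmssd", "na_rmssd",
    "pa_inertia", "na_inertia", "network_density", "mixed_emotions",
    "dialecticism")
}

#' Mean affect level
#' @param x numeric ratings for one person.
#' @return arithmetic mean.
#' @export
mean_level <- function(x) {
  if (!length(x)) stop("empty series", call. = FALSE)
  mean(x)
}

#' Affect variability: within-person standard deviation
#' @param x numeric ratings (sample SD, denominator n - 1).
#' @return SD, or `NA` when fewer than 2 ratings.
#' @export
variability <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

#' Affect instability: root mean square successive difference
#'
#' Computed over retained lag pairs only, i.e. after the method's gap
#' rules (overnight / >10 h gaps dropped) have been applied by
#' [lagged_pairs()].
#'
#' @param pairs lag-pair table from [lagged_pairs()].
#' @param affect `"pa"` or `"na"`.
#' @return RMSSD, or `NA` when no pair was retained.
#' @export
instability <- function(pairs, affect = c("pa", "na")) {
  affect <- match.arg(affect)
  if (nrow(pairs) == 0) return(NA_real_)
  d <- pairs[[paste0(affect, "_next")]] - pairs[[paste0(affect, "_prev")]]
  sqrt(mean(d^2))
}

#' Mixed emotions: the MIN index
#'
#' Per time point, total affect (PA + NA) minus polarity (|PA - NA|),
#' which equals `2 * min(PA, NA)`; averaged over the person's time
#' points. High only when PA and NA co-occur.
#'
#' @param pa,na aligned rating vectors.
#' @return mean MIN index (0-200 scale).
#' @export
mixed_emotions <- function(pa, na) {
  if (!length(pa) || length(pa) != length(na)) {
    stop("need aligned, non-empty PA and NA series", call. = FALSE)
  }
  mean((pa + na) - abs(pa - na))
}

#' Emotional dialecticism: within-person PA-NA correlation
#'
#' Product-moment by default; `method = "spearman"` gives the rank-based
#' variant. Values near -1 indicate bipolarity, values near 0 or above
#' indicate co-occurrence.
#'
#' @param pa,na aligned rating vectors (>= 3 points).
#' @param method correlation type.
#' @return correlation in \[-1, 1\], or `NA` when either affect has zero
#'   variance or fewer than 3 points.
#' @export
dialecticism <- function(pa, na, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(pa) < 3 || length(pa) != length(na)) return(NA_real_)
  if (stats::var(pa) < 1e-12 || stats::var(na) < 1e-12) return(NA_real_)
  stats::cor(pa, na, method = method)
}

# Stack one method's lag pairs into a regression table:
# one row per retained pair with outcome = next, predictors = prev.
lag_regression_rows <- function(study, method, max_gap_hours = 10) {
  pr <- study_lag_pairs(study, method, max_gap_hours)
  data.frame(person_id = pr$person_id,
             pa_next = pr$pa_next, na_next = pr$na_next,
             pa_prev = pr$pa_prev, na_prev = pr$na_prev,
             stringsAsFactors = FALSE)
}

#' Emotional inertia: empirical-Bayes autoregressive slopes
#'
#' For one method, regresses each affect rating on the same affect at the
#' previous retained time point in a random-intercept + random-slope
#' model over all persons jointly, and returns the EB person slopes. The
#' lag predictor is within-person centered by default so the slope reads
#' as autocorrelation rather than mean level.
#'
#' @param study filtered `ila_study`.
#' @param method assessment method.
#' @param affect `"pa"` or `"na"`.
#' @param center_lag center the lag predictor within person.
#' @param max_gap_hours hour cap for the method's gap rules.
#' @return data frame `person_id`, `inertia`.
#' @export
inertia <- function(study, method, affect = c("pa", "na"),
                    center_lag = TRUE, max_gap_hours = 10) {
  affect <- match.arg(affect)
  rows <- lag_regression_rows(study, method, max_gap_hours)
  y <- paste0(affect, "_next"); x <- paste0(affect, "_prev")
  fit <- fit_random_slope_model(rows, y, x, center_within = center_lag)
  eb <- empirical_bayes_coefficients(fit)
  data.frame(person_id = eb$person_id, inertia = eb[[x]],
             stringsAsFactors = FALSE)
}

#' Emotion network density: sum of absolute EB lagged parameters
#'
#' Two multilevel lagged models per method -- PA and NA each regressed on
#' both within-person-centered lagged affects with random slopes -- give
#' each person 2 autoregressive and 2 cross-lagged EB parameters; density
#' is the sum of their absolute values.
#'
#' @inheritParams inertia
#' @return data frame `person_id`, `density`, plus the four EB
#'   parameters (`a_pp`, `a_pn`, `a_np`, `a_nn`; outcome first).
#' @export
network_density <- function(study, method, center_lag = TRUE,
                            max_gap_hours = 10) {
  rows <- lag_regression_rows(study, method, max_gap_hours)
  fit_pa <- fit_random_slope_model(rows, "pa_next", c("pa_prev", "na_prev"),
                                   center_within = center_lag)
  fit_na <- fit_random_slope_model(rows, "na_next", c("pa_prev", "na_prev"),
                                   center_within = center_lag)
  eb_pa <- empirical_bayes_coefficients(fit_pa)
  eb_na <- empirical_bayes_coefficients(fit_na)
  m <- merge(eb_pa[, c("person_id", "pa_prev", "na_prev")],
             eb_na[, c("person_id", "pa_prev", "na_prev")],
             by = "person_id", suffixes = c("_pa", "_na"))
  data.frame(person_id = m$person_id,
             density = abs(m$pa_prev_pa) + abs(m$na_prev_pa) +
               abs(m$pa_prev_na) + abs(m$na_prev_na),
             a_pp = m$pa_prev_pa, a_pn = m$na_prev_pa,
             a_np = m$pa_prev_na, a_nn = m$na_prev_na,
             stringsAsFactors = FALSE)
}

#' Compute the full dynamics battery per person and method
#'
#' All 11 measures for every person under every requested method, each
#' computed the same way from that method's ratings: DRM episodes enter
#' as midpoint-timestamped rescaled ratings, and instability, inertia and
#' density use the method's gap rules. Inertia and density are estimated
#' jointly over persons (multilevel); all other measures are per-person.
#'
#' @param study an `ila_study` that has passed the inclusion filter.
#' @param methods methods to profile.
#' @param center_lag center lag predictors within person.
#' @param max_gap_hours hour cap for EMA/DRM gap rules.
#' @param cor_method correlation type for dialecticism.
#' @return data frame, one row per (person, method): the 11 measures plus
#'   `n_obs`, `n_pairs`, `mean_gap_hours`.
#' @export
compute_profiles <- function(study, methods = ILA_METHODS, center_lag = TRUE,
                             max_gap_hours = 10,
                             cor_method = c("pearson", "spearman")) {
  stopifnot(inherits(study, "ila_study"))
  cor_method <- match.arg(cor_method)
  out <- lapply(methods, function(m) {
    obs <- study$observations[study$observations$method == m, , drop = FALSE]
    if (nrow(obs) == 0) return(NULL)
    rules <- method_lag_rules(m, max_gap_hours)
    per <- lapply(split(obs, obs$person_id), function(s) {
      pr <- lagged_pairs(s, rules$max_gap_hours, rules$cross_day_rule)
      data.frame(
        person_id = s$person_id[1], method = m,
        pa_mean = mean_level(s$pa), na_mean = mean_level(s$na),
        pa_sd = variability(s$pa), na_sd = variability(s$na),
        pa_rmssd = instability(pr, "pa"), na_rmssd = instability(pr, "na"),
        mixed_emotions = mixed_emotions(s$pa, s$na),
        dialecticism = dialecticism(s$pa, s$na, cor_method),
        n_obs = nrow(s), n_pairs = nrow(pr),
        mean_gap_hours = if (nrow(pr)) mean(pr$gap_hours) else NA_real_,
        stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, per)
    in_pa <- inertia(study, m, "pa", center_lag, max_gap_hours)
    in_na <- inertia(study, m, "na", center_lag, max_gap_hours)
    dens <- network_density(study, m, center_lag, max_gap_hours)
    tab$pa_inertia <- in_pa$inertia[match(tab$person_id, in_pa$person_id)]
    tab$na_inertia <- in_na$inertia[match(tab$person_id, in_na$person_id)]
    tab$network_density <- dens$density[match(tab$person_id, dens$person_id)]
    tab
  })
  out <- do.call(rbind, out)
  cols <- c("person_id", "method", dynamics_measures(),
            "n_obs", "n_pairs", "mean_gap_hours")
  out <- out[order(out$person_id, match(out$method, ILA_METHODS)), cols]
  rownames(out) <- NULL
  out
}
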