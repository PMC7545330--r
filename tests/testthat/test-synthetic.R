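test_that("prompt spacings obey the scheduling rule", {
  set.seed(1)
  for (rep in 1:50) {
    sched <- generate_prompt_schedule(8, 20, 6)
    sp <- diff(c(8, sched))
    expect_true(all(sp >= 0.75 * 12 / 6 - 1e-12))
    expect_true(all(sp <= 1.10 * 12 / 6 + 1e-12))
    expect_true(all(sched <= 20))
  }
  # n = 1: single prompt one spacing after the window opens
  one <- replicate(200, generate_prompt_schedule(8, 20, 1))
  one <- unlist(one)
  expect_true(all(one >= 8 + 0.75 * 12 - 1e-12 & one <= 20))
  expect_error(generate_prompt_schedule(20, 8, 6), "degenerate")
})

test_that("Monte-Carlo mean spacing matches the uniform-bounds mean", {
  set.seed(2)
  sp <- stats::runif(10000, 0.75 * 2, 1.10 * 2)  # oracle: spacing distribution
  sched_sp <- unlist(replicate(2000, diff(c(8, generate_prompt_schedule(8, 20, 6))),
                               simplify = FALSE))
  expect_equal(mean(sched_sp), 0.925 * 2, tolerance = 0.01)
  expect_equal(mean(sched_sp), mean(sp), tolerance = 0.01)
})

test_that("latent process is a stationary VAR with the configured dynamics", {
  set.seed(3)
  mu <- c(pa = 70, na = 10)
  # zero innovation: trace constant at set-points
  prm0 <- list(mu = mu, A = diag(c(0.5, 0.5)), Q = diag(c(0, 0)))
  tr0 <- simulate_latent_process(prm0, 50)
  expect_true(all(tr0$x[, 1] == 70) && all(tr0$x[, 2] == 10))
  # white noise: lag-1 autocorrelation ~ 0
  prm_w <- list(mu = mu, A = matrix(0, 2, 2), Q = diag(c(4, 4)))
  tr_w <- simulate_latent_process(prm_w, 10000)
  ac <- stats::acf(tr_w$x[, 1], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.05)
  # AR(1) with phi = 0.6 recovered in the sample autocorrelation
  prm_a <- list(mu = mu, A = diag(c(0.6, 0)), Q = diag(c(4, 4)))
  tr_a <- simulate_latent_process(prm_a, 10000)
  ac_a <- stats::acf(tr_a$x[, 1], lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(ac_a, 0.6, tolerance = 0.05)
  expect_error(simulate_latent_process(list(mu = mu, A = diag(c(1.2, 0.5)),
                                            Q = diag(2)), 10),
               "non-stationary")
})

test_that("EMA sampling reads the trace, counts 42, and clips", {
  cfg <- generator_config(n_persons = 1, seed = 5)
  prm <- list(mu = c(pa = 70, na = 10), A = diag(c(0, 0)), Q = diag(c(0, 0)))
  tr <- simulate_latent_process(prm, 169)
  o <- sample_ema(tr, c(8, 10, 12), c(1, 1, 1), "p1", noise_sd = 0)
  expect_true(all(o$pa == 70) && all(o$na == 10))
  # clipping at the response bounds
  tr_hi <- tr; tr_hi$x[, 1] <- 104; tr_hi$x[, 2] <- -3
  o2 <- sample_ema(tr_hi, 8, 1, "p1", noise_sd = 0)
  expect_equal(c(o2$pa, o2$na), c(100, 0))
  # a full default study schedules 6 x 7 = 42 prompts per person
  gen <- generate_study(generator_config(n_persons = 3, seed = 5))
  ema <- gen$study$observations[gen$study$observations$method == "EMA", ]
  expect_equal(as.integer(table(ema$person_id)), rep(42L, 3))
  eod <- gen$study$observations[gen$study$observations$method == "EOD", ]
  expect_equal(as.integer(table(eod$person_id)), rep(7L, 3))
  drm <- gen$study$observations[gen$study$observations$method == "DRM", ]
  expect_true(all(table(drm$person_id) >= 4))
})

test_that("end-of-day summaries implement day_mean and peak_end", {
  cfg <- generator_config(n_persons = 1, noise_sd_eod = 0, seed = 1)
  prm <- list(mu = c(pa = 40, na = 20), A = diag(c(0, 0)), Q = diag(c(0, 0)))
  tr <- simulate_latent_process(prm, 169)
  expect_equal(sample_eod(tr, 2, cfg, "p1")$pa, 40)
  # linear ramp 0 -> 100 over the waking window averages to 50
  sel <- tr$hours >= 24 + 8 & tr$hours <= 24 + 22
  tr$x[sel, 1] <- seq(0, 100, length.out = sum(sel))
  expect_equal(sample_eod(tr, 2, cfg, "p1")$pa, 50)
  # peak_end: (max + last) / 2
  cfg_pe <- generator_config(n_persons = 1, noise_sd_eod = 0,
                             eod_summary = "peak_end", seed = 1)
  tr$x[sel, 1] <- 30
  tr$x[which(sel)[3], 1] <- 90
  tr$x[which(sel)[sum(sel)], 1] <- 50
  expect_equal(sample_eod(tr, 2, cfg_pe, "p1")$pa, 70)
})

test_that("episodes partition the waking window and quantize correctly", {
  set.seed(7)
  cfg <- generator_config(n_persons = 1, seed = 7)
  prm <- list(mu = c(pa = 50, na = 50), A = diag(c(0, 0)), Q = diag(c(0, 0)))
  tr <- simulate_latent_process(prm, 169)
  ep <- sample_drm(tr, 3, cfg, "p1")
  w_len <- diff(cfg$waking_window)
  dur <- as.numeric(difftime(ep$end, ep$start, units = "hours"))
  expect_equal(sum(dur), w_len)
  expect_true(all(dur > 0))
  expect_equal(as.numeric(ep$start[-1]), as.numeric(ep$end[-nrow(ep)]))
  expect_equal(format(ep$start[1], "%H:%M"),
               sprintf("%02d:00", cfg$waking_window[1]))
  # constant latent 50 -> raw = round(50 * 7/100 - 0.5) = 3 everywhere
  expect_true(all(ep$raw_pa == 3L))
  expect_true(nrow(ep) >= cfg$episode_min && nrow(ep) <= cfg$episode_max)
})

test_that("health outcomes follow the configured linear model", {
  set.seed(8)
  cfg <- generator_config(n_persons = 1, seed = 8)
  truth <- data.frame(person_id = sprintf("h%03d", 1:500),
                      mu_pa = stats::rnorm(500, 66, 16),
                      mu_na = stats::rlnorm(500, 2.2, 0.8),
                      innovation_sd_na = 7.5)
  # all coefficients zero, zero noise -> constant at the intercept
  cfg0 <- cfg
  cfg0$health_model <- lapply(default_health_model(), function(co) {
    co[c("pa", "na", "na_innov", "noise_sd")] <- 0; co
  })
  h0 <- generate_health(truth, cfg0)
  expect_true(all(h0$general_health == 4L))  # round(3.9)
  expect_true(all(h0$pain == 25) && all(h0$fatigue == 30))
  expect_true(all(h0$day_index %in% 1:7) &&
                all(table(h0$person_id) == 7))
  # positive pain loading on the NA set-point is recovered
  h <- generate_health(truth, cfg)
  pm <- tapply(h$pain, h$person_id, mean)[truth$person_id]
  expect_gt(stats::cor(pm, truth$mu_na), 0.3)
  expect_true(all(h$general_health %in% 1:5))
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- generator_config(n_persons = 5, seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  for (f in c("observations.csv", "episodes.csv", "health.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  run_simulate(cfg, d2, seed = 124)
  expect_false(identical(readLines(file.path(d1, "observations.csv")),
                         readLines(file.path(d2, "observations.csv"))))
})

test_that("cross-method mean-level correlation is high under the shared process", {
  gen <- generate_study(generator_config(n_persons = 60, seed = 31))
  obs <- gen$study$observations
  pm <- sapply(c("EMA", "EOD", "DRM"), function(m) {
    sub <- obs[obs$method == m, ]
    tapply(sub$pa, sub$person_id, mean)[sort(unique(obs$person_id))]
  })
  expect_gt(stats::cor(pm[, "EMA"], pm[, "EOD"]), 0.9)
  expect_gt(stats::cor(pm[, "EMA"], pm[, "DRM"]), 0.9)
})
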