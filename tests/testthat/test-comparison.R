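test_that("rm_anova has the textbook df and matches aov on a toy matrix", {
  m <- matrix(rep(c(3, 7, 5, 9), 3), ncol = 3)
  res0 <- rm_anova(m)
  expect_equal(res0$F, 0)
  expect_equal(c(res0$df_num, res0$df_den), c(2, 6))
  # df at n = 90, k = 3 is (2, 178)
  set.seed(41)
  m90 <- matrix(stats::rnorm(270), ncol = 3)
  r90 <- rm_anova(m90)
  expect_equal(c(r90$df_num, r90$df_den), c(2, 178))
  # oracle: stats::aov with a within-subject error stratum
  toy <- matrix(c(1, 4, 2, 7,   3, 6, 1, 9,   5, 8, 4, 12), ncol = 3)
  res <- rm_anova(toy)
  long <- data.frame(y = as.vector(toy),
                     subj = factor(rep(1:4, 3)),
                     meth = factor(rep(1:3, each = 4)))
  av <- summary(stats::aov(y ~ meth + Error(subj/meth), data = long))
  ftab <- av[["Error: subj:meth"]][[1]]
  expect_equal(res$F, ftab["meth", "F value"], tolerance = 1e-10)
  expect_equal(res$p, ftab["meth", "Pr(>F)"], tolerance = 1e-10)
  # incomplete rows are dropped and counted
  toy_na <- toy; toy_na[2, 3] <- NA
  expect_equal(rm_anova(toy_na)$n_dropped, 1)
})

test_that("Bonferroni pairwise tests flag the shifted method only", {
  set.seed(42)
  base <- stats::rnorm(40)
  m <- cbind(A = base + stats::rnorm(40, 0, 0.3),
             B = base + stats::rnorm(40, 0, 0.3),
             C = base + 10 * stats::sd(base))
  pw <- bonferroni_pairwise(m)
  sigAB <- pw$significant[pw$method_a == "A" & pw$method_b == "B"]
  expect_false(sigAB)
  expect_true(all(pw$significant[pw$method_b == "C"]))
  expect_equal(pw$p_bonferroni, pmin(1, pw$p * 3))
  same <- matrix(rep(stats::rnorm(10), 3), ncol = 3)
  expect_false(any(bonferroni_pairwise(same)$significant))
})

test_that("Fisher z and Cohen q identities hold", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-7)
  expect_equal(cohen_q(0.3, 0.3), 0)
  expect_equal(cohen_q(0.2, 0.7), -cohen_q(0.7, 0.2))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(r)), r)
  expect_error(fisher_z(1), "< 1")
})

test_that("critical_r matches the printed n=90 cutoff and a numeric oracle", {
  expect_equal(round(critical_r(90, 0.05), 2), 0.21)
  expect_lt(critical_r(90, 0.999), 0.01)  # alpha -> 1 limit
  # brute-force inversion of the t CDF over a grid of n
  p_of_r <- function(r, n) {
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  for (n in c(5, 10, 30, 90, 200)) {
    oracle <- stats::uniroot(function(r) p_of_r(r, n) - 0.05,
                             c(1e-6, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(critical_r(n, 0.05), oracle, tolerance = 1e-6)
  }
})

test_that("the Wald statistic vanishes under forced correlation equality", {
  set.seed(43)
  x <- make_exchangeable_sample(40)
  R <- stats::cor(x)
  expect_equal(R[1, 2], R[1, 3], tolerance = 1e-10)  # construction check
  expect_equal(R[1, 2], R[2, 3], tolerance = 1e-10)
  wd <- wald_dependent_correlations(x)
  expect_lt(wd$chisq, 1e-10)
  expect_gt(wd$p, 0.99)
  expect_equal(wd$method, "delta")
  expect_true(all(abs(wd$pairwise$z) < 1e-5))
})

test_that("the Wald test holds its size under the equicorrelated null", {
  set.seed(44)
  rho <- 0.5; n <- 90
  L <- chol(matrix(c(1, rho, rho, rho, 1, rho, rho, rho, 1), 3))
  rej <- 0; reps <- 1500
  for (b in seq_len(reps)) {
    x <- matrix(stats::rnorm(3 * n), n, 3) %*% L
    if (wald_dependent_correlations(x)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("correlation networks and node strength behave", {
  set.seed(45)
  n <- 200
  f <- stats::rnorm(n)
  prof <- data.frame(person_id = seq_len(n), method = "EMA")
  for (ms in dynamics_measures()) prof[[ms]] <- f + stats::rnorm(n, 0, 0.8)
  prof$dialecticism <- stats::rnorm(n)  # one node decoupled from the rest
  nw <- correlation_network(prof)
  expect_true(all(nw$strength <= 10))
  expect_true(isSymmetric(nw$matrix))
  expect_equal(unname(diag(nw$matrix)), rep(1, 11))
  expect_lt(nw$strength["dialecticism"], min(nw$strength[1:8]))
  # column-order invariance
  nw2 <- correlation_network(prof[, c(1:2, sample(3:13))])
  expect_equal(sort(nw2$strength), sort(nw$strength))
  # identical networks -> ordering correspondence 1; reversal -> negative
  expect_equal(compare_networks(nw, nw), 1)
  rev_nw <- nw
  rev_nw$strength <- stats::setNames(rev(nw$strength), names(nw$strength))
  expect_lt(compare_networks(nw, rev_nw), 0)
  # zero-variance measure is flagged and dropped from its row/column
  prof$pa_sd <- 5
  nw3 <- correlation_network(prof)
  expect_equal(nw3$dropped, "pa_sd")
  expect_true(all(is.na(nw3$matrix["pa_sd", -3])))
})

test_that("incremental regression matches the normal equations and flags collinearity", {
  set.seed(46)
  n <- 12
  d <- data.frame(ms = stats::rnorm(n), pa = stats::rnorm(n), na_ = stats::rnorm(n))
  y <- 2 + 0.8 * d$ms - 0.3 * d$pa + stats::rnorm(n, 0, 0.4)
  ir <- incremental_regression(y, d$ms, d$pa, d$na_)
  X <- cbind(1, d$ms, d$pa, d$na_)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # hand linear algebra oracle
  expect_equal(ir$coef, beta[2, 1], tolerance = 1e-10)
  expect_error(incremental_regression(y, d$pa, d$pa, d$na_), "collinear")
  # outcome generated purely from the controls: partial coefficient ~ 0
  set.seed(47)
  n2 <- 400
  pa <- stats::rnorm(n2); na_ <- stats::rnorm(n2); ms <- stats::rnorm(n2)
  y2 <- 1 - 0.5 * na_ + stats::rnorm(n2, 0, 0.3)
  ir2 <- incremental_regression(y2, ms, pa, na_)
  expect_lt(abs(ir2$coef), 0.1)
  # measure with unique signal is recovered with the right sign
  y3 <- 1 - 0.5 * na_ + 0.6 * ms + stats::rnorm(n2, 0, 0.3)
  expect_gt(incremental_regression(y3, ms, pa, na_)$coef, 0.4)
})

test_that("health associations count 33 Wald tests and recover loadings", {
  set.seed(48)
  gen <- generate_study(generator_config(n_persons = 40, seed = 48))
  st <- apply_inclusion_filter(gen$study)
  pf <- compute_profiles(st)
  ha <- health_associations(pf, st$health)
  expect_equal(nrow(ha$correlations), 33)
  expect_equal(nrow(ha$mean_abs_q), 9)
  # pain loads positively on the NA set-point, so the na_mean correlation
  # is positive and among the strongest for pain
  pain <- ha$correlations[ha$correlations$outcome == "pain", ]
  expect_gt(pain$r_EMA[pain$measure == "na_mean"], 0.2)
})

test_that("compare_methods assembles the full per-measure table", {
  set.seed(49)
  gen <- generate_study(generator_config(n_persons = 30, seed = 49))
  st <- apply_inclusion_filter(gen$study)
  pf <- compute_profiles(st)
  cmp <- compare_methods(pf)
  expect_equal(nrow(cmp$table), 11)
  expect_equal(cmp$table$df_num[1], 2)
  expect_equal(cmp$table$df_den[1], 2 * (cmp$table$n[1] - 1))
  expect_true(all(abs(cmp$table[, c("r_EMA_EOD", "r_EMA_DRM", "r_EOD_DRM")]) <= 1))
  expect_equal(cmp$table$q_EMA_EOD_vs_EMA_DRM,
               cohen_q(cmp$table$r_EMA_EOD, cmp$table$r_EMA_DRM))
  expect_named(cmp$detail, dynamics_measures())
})
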