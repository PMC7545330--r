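# Cross-method comparability statistics: repeated-measures ANOVA with
# Bonferroni pairwise follow-ups, Fisher-z / Cohen-q machinery,
# dependent-correlation Wald tests (Steiger-type delta method on the
# Olkin-Siotani covariance, with a percentile-bootstrap fallback),
# correlation networks with node strength, and health associations with
# incremental-validity regressions.

#' One-way repeated-measures ANOVA
#'
#' Within-person factor with k levels (the assessment methods), complete
#' cases only, sphericity assumed: `F = MS_method / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))`.
#'
#' @param values n x k numeric matrix, one row per person.
#' @return list: `F`, `df_num`, `df_den`, `p`, `n` (complete cases),
#'   `n_dropped`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  cc <- stats::complete.cases(values)
  dropped <- sum(!cc)
  values <- values[cc, , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("need >= 3 complete cases", call. = FALSE)
  grand <- mean(values)
  ss_method <- n * sum((colMeans(values) - grand)^2)
  ss_subject <- k * sum((rowMeans(values) - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_error <- ss_total - ss_method - ss_subject
  df_num <- k - 1
  df_den <- (k - 1) * (n - 1)
  ms_method <- ss_method / df_num
  ms_error <- ss_error / df_den
  f <- if (ms_error <= 0) 0 else ms_method / ms_error
  list(F = f, df_num = df_num, df_den = df_den,
       p = stats::pf(f, df_num, df_den, lower.tail = FALSE),
       n = n, n_dropped = dropped)
}

#' Bonferroni-adjusted pairwise paired t tests
#'
#' Paired t test for every column pair, significance judged at
#' `alpha / n_pairs` (Bonferroni); also reports the adjusted p values.
#'
#' @param values n x k matrix (complete cases used).
#' @param alpha family-wise level (default 0.05).
#' @return data frame: pair labels, mean difference, t, df, raw p,
#'   Bonferroni p, `significant`.
#' @export
bonferroni_pairwise <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  k <- ncol(values)
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("m", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- values[, a] - values[, b]
    if (stats::sd(d) < 1e-12) {
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(d)
    }
    data.frame(method_a = nm[a], method_b = nm[b],
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs),
               significant = tt$p.value < alpha / n_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher's z transform and Cohen's q effect size
#'
#' `fisher_z(r) = atanh(r)`; `cohen_q(r1, r2)` is the difference of the
#' transformed correlations (0.1 / 0.3 / 0.5 read as small / medium /
#' large).
#'
#' @param r,r1,r2 correlations with `|r| < 1`.
#' @param z a Fisher z value.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' @rdname fisher_z
#' @export
cohen_q <- function(r1, r2) fisher_z(r1) - fisher_z(r2)

#' Smallest correlation significant at a given level
#'
#' Inverts the t transform `t = r sqrt((n - 2) / (1 - r^2))` with
#' `df = n - 2` (two-sided by default).
#'
#' @param n sample size (>= 4).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return the critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05, tails = 2) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, tails %in% c(1, 2))
  tcrit <- stats::qt(1 - alpha / tails, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

# Olkin-Siotani covariance element of sqrt(n) * (r_jk, r_hm) at the
# correlation matrix R (Steiger 1980 form).
cor_cov_element <- function(R, j, k, h, m) {
  0.5 * R[j, k] * R[h, m] *
    (R[j, h]^2 + R[j, m]^2 + R[k, h]^2 + R[k, m]^2) +
    R[j, h] * R[k, m] + R[j, m] * R[k, h] -
    (R[j, k] * R[j, h] * R[j, m] + R[k, j] * R[k, h] * R[k, m] +
     R[h, j] * R[h, k] * R[h, m] + R[m, j] * R[m, k] * R[m, h])
}

fisher_z_cov <- function(R, pairs, n) {
  q <- length(pairs)
  S <- matrix(0, q, q)
  for (a in seq_len(q)) {
    for (b in a:q) {
      ra <- R[pairs[[a]][1], pairs[[a]][2]]
      rb <- R[pairs[[b]][1], pairs[[b]][2]]
      c_ab <- cor_cov_element(R, pairs[[a]][1], pairs[[a]][2],
                              pairs[[b]][1], pairs[[b]][2])
      S[a, b] <- S[b, a] <- c_ab / ((1 - ra^2) * (1 - rb^2)) / (n - 3)
    }
  }
  S
}

#' Wald test for equality of dependent correlations
#'
#' Tests H0: all selected correlations of one sample are equal, on the
#' Fisher-z scale, using the asymptotic covariance of correlations that
#' share variables (Olkin-Siotani elements; Steiger-type delta method).
#' The omnibus statistic is chi-squared with `q - 1` df for `q`
#' correlations; pairwise z tests follow up. If the contrast covariance
#' is numerically singular the p value is replaced by a percentile
#' bootstrap (flagged in the result).
#'
#' @param x n x p data matrix (complete cases used).
#' @param pairs list of column index pairs naming the correlations under
#'   test; default: all three pairs of a 3-column matrix.
#' @param boot_reps bootstrap replicates for the fallback.
#' @return list: `chisq`, `df`, `p`, `r` (the correlations), `pairwise`
#'   (z and p per correlation pair), `method` ("delta" or "bootstrap"),
#'   `n`.
#' @export
wald_dependent_correlations <- function(x, pairs = list(c(1, 2), c(1, 3), c(2, 3)),
                                        boot_reps = 2000) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 10) stop("need >= 10 complete cases", call. = FALSE)
  R <- stats::cor(x)
  r <- vapply(pairs, function(p) R[p[1], p[2]], 0)
  z <- fisher_z(pmin(0.9999, pmax(-0.9999, r)))
  S <- fisher_z_cov(R, pairs, n)
  q <- length(pairs)
  C <- diff(diag(q))  # (q-1) x q successive-difference contrasts
  d <- drop(C %*% z)
  V <- C %*% S %*% t(C)
  method <- "delta"
  stat <- tryCatch(drop(t(d) %*% solve(V, d)), error = function(e) NA_real_)
  if (!is.finite(stat) || min(eigen(V, only.values = TRUE)$values) < 1e-12) {
    method <- "bootstrap"
    bt <- bootstrap_wald(x, pairs, boot_reps)
    stat <- bt$stat; p <- bt$p
  } else {
    p <- stats::pchisq(stat, df = q - 1, lower.tail = FALSE)
  }
  combos <- utils::combn(q, 2)
  pw <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    se <- sqrt(max(S[a, a] + S[b, b] - 2 * S[a, b], 1e-12))
    zstat <- (z[a] - z[b]) / se
    data.frame(pair_a = a, pair_b = b, z = zstat,
               p = 2 * stats::pnorm(-abs(zstat)),
               q = cohen_q(r[a], r[b]))
  })
  list(chisq = stat, df = q - 1, p = p, r = r,
       pairwise = do.call(rbind, pw), method = method, n = n)
}

#' Percentile-bootstrap version of the dependent-correlation Wald test
#'
#' Resamples persons, re-centres the bootstrap contrast vectors at the
#' observed contrasts, and compares their Mahalanobis norms (under the
#' bootstrap covariance) with that of the observed contrast vector.
#'
#' @inheritParams wald_dependent_correlations
#' @param reps bootstrap replicates.
#' @return list: `stat`, `p`.
#' @export
bootstrap_wald <- function(x, pairs = list(c(1, 2), c(1, 3), c(2, 3)),
                           reps = 2000) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  q <- length(pairs)
  C <- diff(diag(q))
  zvec <- function(m) {
    R <- stats::cor(m)
    fisher_z(pmin(0.9999, pmax(-0.9999,
      vapply(pairs, function(p) R[p[1], p[2]], 0))))
  }
  d_obs <- drop(C %*% zvec(x))
  D <- matrix(0, reps, q - 1)
  for (b in seq_len(reps)) {
    D[b, ] <- drop(C %*% zvec(x[sample.int(n, n, replace = TRUE), , drop = FALSE]))
  }
  S <- stats::cov(D)
  Dc <- sweep(D, 2, colMeans(D))
  stat <- drop(t(d_obs) %*% solve(S, d_obs))
  norms <- rowSums((Dc %*% solve(S)) * Dc)
  list(stat = stat, p = mean(norms >= stat))
}

#' Correlation network of the dynamics measures for one method
#'
#' Pairwise-complete correlations among the 11 measures; node strength is
#' the sum of a measure's absolute correlations with all other measures.
#' The display threshold is the critical correlation at `alpha`.
#'
#' @param profiles profile table for one method (from
#'   [compute_profiles()]).
#' @param measures measure columns (default the canonical 11).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param alpha display-threshold level.
#' @return object of class `network_summary`: `matrix`, `strength`,
#'   `threshold`, `n`, `method` (assessment method), `dropped`
#'   (zero-variance measures).
#' @export
correlation_network <- function(profiles, measures = dynamics_measures(),
                                cor_method = c("pearson", "spearman"),
                                alpha = 0.05) {
  cor_method <- match.arg(cor_method)
  stopifnot(all(measures %in% names(profiles)))
  m <- as.matrix(profiles[, measures])
  n <- nrow(m)
  if (n < 4) stop("need >= 4 persons", call. = FALSE)
  vars <- apply(m, 2, stats::var, na.rm = TRUE)
  dropped <- measures[!is.finite(vars) | vars < 1e-12]
  R <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = cor_method))
  R[dropped, ] <- NA; R[, dropped] <- NA
  diag(R) <- 1
  absR <- abs(R); diag(absR) <- NA
  strength <- rowSums(absR, na.rm = TRUE)
  structure(list(matrix = R, strength = strength,
                 threshold = critical_r(n, alpha), n = n,
                 method = unique(profiles$method), dropped = dropped,
                 cor_method = cor_method),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network_summary (%s, n=%d, |r| threshold %.2f)\n",
              paste(x$method, collapse = "/"), x$n, x$threshold))
  print(round(sort(x$strength, decreasing = TRUE), 2))
  invisible(x)
}

#' Correspondence of node-strength orderings between two networks
#'
#' @param a,b `network_summary` objects over the same node set.
#' @param method correlation type for the strength vectors (default
#'   Spearman, an ordering comparison).
#' @return correlation of the two strength vectors.
#' @export
compare_networks <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(identical(names(a$strength), names(b$strength)))
  stats::cor(a$strength, b$strength, method = method)
}

#' Incremental-validity regression of a health outcome on one measure
#'
#' OLS of the outcome on the measure plus mean PA and mean NA as
#' controls; reports the measure's partial coefficient and p value.
#'
#' @param outcome,measure,mean_pa,mean_na aligned person-level vectors.
#' @return list: `coef`, `se`, `t`, `p`, `n`, plus the full coefficient
#'   table.
#' @export
incremental_regression <- function(outcome, measure, mean_pa, mean_na) {
  d <- data.frame(y = outcome, x = measure, pa = mean_pa, na_ = mean_na)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10) stop("need >= 10 complete cases", call. = FALSE)
  X <- cbind(1, d$x, d$pa, d$na_)
  if (qr(X)$rank < 4) {
    stop("measure is collinear with the mean-level controls", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + pa + na_, data = d)
  sm <- summary(fit)$coefficients
  list(coef = sm["x", 1], se = sm["x", 2], t = sm["x", 3], p = sm["x", 4],
       n = nrow(d), table = sm)
}

# profiles in long (person, method) form -> wide person x method matrix
# for one measure
measure_wide <- function(profiles, measure, methods = ILA_METHODS) {
  persons <- sort(unique(profiles$person_id))
  out <- sapply(methods, function(m) {
    sub <- profiles[profiles$method == m, ]
    sub[[measure]][match(persons, sub$person_id)]
  })
  rownames(out) <- persons
  out
}

#' Full cross-method comparison of the dynamics measures
#'
#' For every measure: per-method means and SDs, the repeated-measures
#' ANOVA of method differences with Bonferroni pairwise follow-ups, the
#' three cross-method correlations, the dependent-correlation Wald test
#' with pairwise follow-ups, and Cohen q per method pair.
#'
#' @param profiles long profile table from [compute_profiles()].
#' @param measures measures to compare.
#' @param methods assessment methods (columns of the wide matrices).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param alpha significance level.
#' @return list of class `method_comparison`: `table` (one row per
#'   measure) and `detail` (per-measure pairwise tables).
#' @export
compare_methods <- function(profiles, measures = dynamics_measures(),
                            methods = ILA_METHODS,
                            cor_method = c("pearson", "spearman"),
                            alpha = 0.05) {
  cor_method <- match.arg(cor_method)
  detail <- list()
  rows <- lapply(measures, function(ms) {
    w <- measure_wide(profiles, ms, methods)
    an <- rm_anova(w)
    pw <- bonferroni_pairwise(w, alpha)
    cc <- w[stats::complete.cases(w), , drop = FALSE]
    if (cor_method == "spearman") cc <- apply(cc, 2, rank)
    wd <- wald_dependent_correlations(cc)
    detail[[ms]] <<- list(pairwise_means = pw, pairwise_correlations = wd$pairwise)
    data.frame(
      measure = ms,
      mean_EMA = mean(w[, 1], na.rm = TRUE), sd_EMA = stats::sd(w[, 1], na.rm = TRUE),
      mean_EOD = mean(w[, 2], na.rm = TRUE), sd_EOD = stats::sd(w[, 2], na.rm = TRUE),
      mean_DRM = mean(w[, 3], na.rm = TRUE), sd_DRM = stats::sd(w[, 3], na.rm = TRUE),
      F = an$F, df_num = an$df_num, df_den = an$df_den, p_anova = an$p,
      r_EMA_EOD = wd$r[1], r_EMA_DRM = wd$r[2], r_EOD_DRM = wd$r[3],
      wald_chisq = wd$chisq, wald_df = wd$df, wald_p = wd$p,
      q_EMA_EOD_vs_EMA_DRM = cohen_q(wd$r[1], wd$r[2]),
      q_EMA_EOD_vs_EOD_DRM = cohen_q(wd$r[1], wd$r[3]),
      q_EMA_DRM_vs_EOD_DRM = cohen_q(wd$r[2], wd$r[3]),
      n = an$n, stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), detail = detail,
                 cor_method = cor_method, alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cols <- c("measure", "mean_EMA", "mean_EOD", "mean_DRM", "F", "p_anova",
            "r_EMA_EOD", "r_EMA_DRM", "r_EOD_DRM", "wald_chisq", "wald_p")
  tab <- x$table[, cols]
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Associations of the dynamics measures with health outcomes
#'
#' Averages each person's daily health items into summary scores, then
#' correlates every measure with every outcome under every method,
#' Wald-tests the equality of the three dependent correlations per
#' (measure, outcome), reports Cohen q per method pair, and runs the
#' incremental regression of each outcome on each measure controlling
#' for mean PA and mean NA within each method.
#'
#' @param profiles long profile table.
#' @param health daily health table (`person_id`, `day_index`,
#'   `general_health`, `pain`, `fatigue`).
#' @param outcomes outcome columns to analyze.
#' @param methods assessment methods.
#' @param measures measures to analyze.
#' @param cor_method correlation type.
#' @return list of class `health_associations`: `correlations` (long
#'   table with Wald tests and q values), `incremental` (regression
#'   table), `mean_abs_q` (per outcome and method pair), `person_health`.
#' @export
health_associations <- function(profiles, health,
                                outcomes = c("general_health", "pain", "fatigue"),
                                methods = ILA_METHODS,
                                measures = dynamics_measures(),
                                cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  ph <- stats::aggregate(health[, outcomes],
                         by = list(person_id = health$person_id),
                         FUN = mean, na.rm = TRUE)
  rows <- list(); inc <- list()
  for (oc in outcomes) {
    for (ms in measures) {
      w <- measure_wide(profiles, ms, methods)
      y <- ph[[oc]][match(rownames(w), ph$person_id)]
      dat <- cbind(w, outcome = y)
      if (cor_method == "spearman") {
        cc <- dat[stats::complete.cases(dat), , drop = FALSE]
        dat <- apply(cc, 2, rank)
      }
      wd <- wald_dependent_correlations(
        dat, pairs = list(c(1, 4), c(2, 4), c(3, 4)))
      rows[[paste(oc, ms)]] <- data.frame(
        outcome = oc, measure = ms,
        r_EMA = wd$r[1], r_EOD = wd$r[2], r_DRM = wd$r[3],
        wald_chisq = wd$chisq, wald_df = wd$df, wald_p = wd$p,
        q_EMA_EOD = cohen_q(wd$r[1], wd$r[2]),
        q_EMA_DRM = cohen_q(wd$r[1], wd$r[3]),
        q_EOD_DRM = cohen_q(wd$r[2], wd$r[3]),
        n = wd$n, stringsAsFactors = FALSE)
      for (m in methods) {
        sub <- profiles[profiles$method == m, ]
        yy <- ph[[oc]][match(sub$person_id, ph$person_id)]
        if (ms %in% c("pa_mean", "na_mean")) next  # collinear with controls
        ir <- incremental_regression(yy, sub[[ms]], sub$pa_mean, sub$na_mean)
        inc[[paste(oc, ms, m)]] <- data.frame(
          outcome = oc, measure = ms, method = m,
          coef = ir$coef, se = ir$se, p = ir$p, n = ir$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, rows)
  rownames(correlations) <- NULL
  qcols <- c("q_EMA_EOD", "q_EMA_DRM", "q_EOD_DRM")
  mean_abs_q <- do.call(rbind, lapply(outcomes, function(oc) {
    sub <- correlations[correlations$outcome == oc, qcols]
    data.frame(outcome = oc, pair = c("EMA_EOD", "EMA_DRM", "EOD_DRM"),
               mean_abs_q = colMeans(abs(sub)), row.names = NULL)
  }))
  structure(list(correlations = correlations,
                 incremental = do.call(rbind, c(inc, make.row.names = FALSE)),
                 mean_abs_q = mean_abs_q, person_health = ph,
                 cor_method = cor_method),
            class = "health_associations")
}

#' @export
print.health_associations <- function(x, ...) {
  tab <- x$correlations[, c("outcome", "measure", "r_EMA", "r_EOD", "r_DRM",
                            "wald_chisq", "wald_p")]
  tab[-(1:2)] <- lapply(tab[-(1:2)], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
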