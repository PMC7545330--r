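# Two-level random-slope models with empirical-Bayes person
# coefficients, and intraclass correlation via variance components.
# Estimation is delegated to lme4 (REML by default); this module owns
# the model-spec contract, centering, the diagonal-covariance fallback,
# and EB extraction.

#' Fit a random-intercept + random-slope model and return person coefficients
#'
#' Fits `y = (b0 + u0_i) + sum_j (bj + uj_i) x_j + e` with jointly normal
#' random effects, by REML (default) or ML. On non-convergence with the
#' full random-effects covariance, refits with a diagonal covariance and
#' flags the fallback. Empirical-Bayes person coefficients are the fixed
#' effects plus the conditional (posterior) means of the random effects.
#'
#' @param data data frame containing `person_id`, the outcome, and the
#'   predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of 0, 1 or 2 predictor columns.
#' @param center_within center each predictor at its person mean before
#'   fitting (default TRUE).
#' @param reml use REML (default) rather than ML.
#' @return object of class `mixed_model_fit`: `fixef`, `re_cov`, `sigma2`,
#'   `eb` (per-person coefficient table), `converged`, `diagonal_fallback`.
#' @export
fit_random_slope_model <- function(data, outcome, predictors = character(0),
                                   center_within = TRUE, reml = TRUE) {
  stopifnot(length(predictors) <= 2, outcome %in% names(data),
            all(predictors %in% names(data)), "person_id" %in% names(data))
  data <- data[stats::complete.cases(data[, c(outcome, predictors), drop = FALSE]), ,
               drop = FALSE]
  tab <- table(data$person_id)
  if (sum(tab >= 2) < 2) stop("need >= 2 persons with >= 2 usable rows", call. = FALSE)
  if (center_within && length(predictors)) {
    for (p in predictors) {
      data[[p]] <- data[[p]] - stats::ave(data[[p]], data$person_id)
    }
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  f_full <- stats::as.formula(
    sprintf("%s ~ %s + (%s | person_id)", outcome, rhs, rhs))
  f_diag <- stats::as.formula(
    sprintf("%s ~ %s + (%s || person_id)", outcome, rhs, rhs))
  fit_one <- function(f) {
    warned <- FALSE
    m <- withCallingHandlers(
      lme4::lmer(f, data = data, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(model = m, converged = !warned)
  }
  res <- fit_one(f_full)
  fallback <- FALSE
  if (!res$converged && length(predictors)) {
    res <- fit_one(f_diag)
    fallback <- TRUE
  }
  if (!res$converged) {
    stop("mixed model failed to converge (full and diagonal covariance)",
         call. = FALSE)
  }
  m <- res$model
  vc <- lme4::VarCorr(m)
  re_cov <- as.matrix(Matrix::bdiag(lapply(vc, function(v) v[, , drop = FALSE])))
  eb <- stats::coef(m)$person_id
  eb <- data.frame(person_id = rownames(eb), eb, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fixef = lme4::fixef(m), re_cov = re_cov,
                 sigma2 = stats::sigma(m)^2, eb = eb,
                 converged = res$converged, diagonal_fallback = fallback,
                 reml = reml, formula = if (fallback) f_diag else f_full,
                 n_persons = length(unique(data$person_id)),
                 model = m),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("mixed_model_fit:", deparse(x$formula), "\n")
  cat("  fixed effects:", paste(sprintf("%s=%.4f", names(x$fixef), x$fixef),
                                collapse = ", "), "\n")
  cat(sprintf("  residual var %.4f; %d persons%s\n", x$sigma2, x$n_persons,
              if (x$diagonal_fallback) " (diagonal-covariance fallback)" else ""))
  invisible(x)
}

#' Empirical-Bayes person-specific coefficients
#'
#' One coefficient vector per person: the fixed effects plus the
#' conditional means of that person's random effects (best linear
#' unbiased predictions), i.e. per-person estimates shrunk toward the
#' population values.
#'
#' @param fit a `mixed_model_fit`.
#' @return data frame: `person_id` plus one column per coefficient.
#' @export
empirical_bayes_coefficients <- function(fit) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  fit$eb
}

#' Intraclass correlation of repeated ratings
#'
#' Variance components from a random-intercept-only model: the ICC is
#' the between-person variance divided by the total (between + within)
#' variance.
#'
#' @param values numeric ratings.
#' @param person person identifier per rating.
#' @param reml use REML (default).
#' @return list: `icc`, `between`, `within`.
#' @export
icc <- function(values, person, reml = TRUE) {
  ok <- is.finite(values)
  values <- values[ok]; person <- as.character(person)[ok]
  if (length(unique(person)) < 2) stop("need >= 2 persons", call. = FALSE)
  if (stats::var(values) < 1e-12) stop("zero total variance", call. = FALSE)
  # degenerate case lme4 cannot fit: no within-person variance at all
  within_resid <- unlist(lapply(split(values, person),
                                function(v) v - mean(v)))
  if (stats::var(within_resid) < 1e-12) {
    return(list(icc = 1, between = stats::var(tapply(values, person, mean)),
                within = 0))
  }
  d <- data.frame(y = values, person_id = person)
  m <- suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | person_id), data = d, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")))
  between <- as.numeric(lme4::VarCorr(m)$person_id[1, 1])
  within <- stats::sigma(m)^2
  list(icc = between / (between + within), between = between, within = within)
}

#' Intraclass correlation from known variance components
#'
#' @param between,within non-negative variance components.
#' @return `between / (between + within)`.
#' @export
icc_from_components <- function(between, within) {
  stopifnot(between >= 0, within >= 0, between + within > 0)
  between / (between + within)
}
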