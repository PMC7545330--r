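# Shared fixture builders. All fixtures are constructed in code.

base_time <- function() as.POSIXct("2023-05-01 00:00:00", tz = "UTC")

# observation rows at absolute study hours (hour 0 = day-1 midnight)
make_obs <- function(person, method, hours, day, pa, na) {
  data.frame(person_id = person, method = method,
             timestamp = base_time() + hours * 3600,
             day_index = as.integer(day), pa = pa, na = na,
             stringsAsFactors = FALSE)
}

# n observations for one person/method spaced 2 h apart within day 1
make_block <- function(person, method, n, pa = 50, na = 10) {
  make_obs(person, method, 8 + 2 * (seq_len(n) - 1) %% 7 +
             24 * ((seq_len(n) - 1) %/% 7),
           1 + (seq_len(n) - 1) %/% 7,
           rep_len(pa, n), rep_len(na, n))
}

# a study where every person has n_each observations under each method
make_min_study <- function(n_persons, n_each = 5) {
  ids <- sprintf("q%03d", seq_len(n_persons))
  obs <- do.call(rbind, lapply(ids, function(id) {
    rbind(make_block(id, "EMA", n_each, pa = 50 + stats::runif(n_each, -5, 5),
                     na = 10 + stats::runif(n_each, 0, 5)),
          make_block(id, "EOD", n_each, pa = 55, na = 12),
          make_block(id, "DRM", n_each, pa = 45, na = 8))
  }))
  ila_study(obs)
}

# AR(1) series draw
sim_ar1 <- function(n, phi, sd_innov = 1, mu = 0) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, sd_innov)
  x + mu
}

# study whose observations follow person-specific bivariate VAR(1)
# dynamics on an hourly grid, labelled DRM so only the 10-h gap rule
# applies (all gaps are 1 h) — used for parameter-recovery checks
make_var_study <- function(n_persons, t_occasions, ar_pa = 0.4, ar_na = 0.3,
                           cross = 0.1, sd_person = c(0.1, 0.1, 0.05, 0.05),
                           innov_sd = 5, setpoint = 50) {
  ids <- sprintf("v%03d", seq_len(n_persons))
  truth <- data.frame(person_id = ids,
                      a_pp = stats::rnorm(n_persons, ar_pa, sd_person[1]),
                      a_nn = stats::rnorm(n_persons, ar_na, sd_person[2]),
                      a_pn = stats::rnorm(n_persons, cross, sd_person[3]),
                      a_np = stats::rnorm(n_persons, cross, sd_person[4]))
  # redraw non-stationary coefficient sets, as the generator contract does
  for (i in seq_len(n_persons)) {
    repeat {
      A <- matrix(c(truth$a_pp[i], truth$a_pn[i],
                    truth$a_np[i], truth$a_nn[i]), 2, 2, byrow = TRUE)
      if (max(abs(eigen(A, only.values = TRUE)$values)) < 0.98) break
      truth$a_pp[i] <- stats::rnorm(1, ar_pa, sd_person[1])
      truth$a_nn[i] <- stats::rnorm(1, ar_na, sd_person[2])
      truth$a_pn[i] <- stats::rnorm(1, cross, sd_person[3])
      truth$a_np[i] <- stats::rnorm(1, cross, sd_person[4])
    }
  }
  obs <- do.call(rbind, lapply(seq_len(n_persons), function(i) {
    A <- matrix(c(truth$a_pp[i], truth$a_pn[i],
                  truth$a_np[i], truth$a_nn[i]), 2, 2, byrow = TRUE)
    x <- matrix(0, t_occasions, 2)
    x[1, ] <- stats::rnorm(2, 0, innov_sd)
    for (t in 2:t_occasions) {
      x[t, ] <- A %*% x[t - 1, ] + stats::rnorm(2, 0, innov_sd)
    }
    make_obs(ids[i], "DRM", seq_len(t_occasions), 1,
             pmin(100, pmax(0, setpoint + x[, 1])),
             pmin(100, pmax(0, setpoint + x[, 2])))
  }))
  truth$true_density <- abs(truth$a_pp) + abs(truth$a_pn) +
    abs(truth$a_np) + abs(truth$a_nn)
  list(study = ila_study(obs), truth = truth)
}

# sample with exactly exchangeable correlation structure: all three
# pairwise correlations equal by construction, |r| < 1
make_exchangeable_sample <- function(n = 30, load = 1, resid = 0.8) {
  f <- scale(stats::rnorm(n))[, 1]
  M <- matrix(stats::rnorm(2 * n), n, 2)
  M <- qr.Q(qr(cbind(1, f, M)))[, 3:4]  # orthogonal to 1 and f
  e <- cbind(M[, 1],
             -0.5 * M[, 1] + sqrt(3) / 2 * M[, 2],
             -0.5 * M[, 1] - sqrt(3) / 2 * M[, 2])
  load * f + resid * e * sqrt(n)
}
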