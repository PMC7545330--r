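# End-to-end pipeline: simulate -> dynamics -> compare, with files as
# contracts so real study data can replace the simulator at the
# observations.csv boundary. Each stage writes a JSON metadata sidecar
# recording seed and flags.

write_sidecar <- function(dir, stage, meta) {
  meta$stage <- stage
  meta$package_version <- as.character(utils::packageVersion("emodyn"))
  jsonlite::write_json(meta, file.path(dir, paste0(stage, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Load a generator configuration from a JSON document
#'
#' Keys mirror the arguments of [generator_config()]; unknown keys raise
#' an error naming the key.
#'
#' @param path JSON file.
#' @return an `emodyn_config`.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(generator_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$health_model)) {
    raw$health_model <- lapply(raw$health_model, unlist)
  }
  do.call(generator_config, raw)
}

#' Simulate a study and write its dataset files
#'
#' Writes `observations.csv`, `episodes.csv`, `health.csv`, `truth.csv`
#' and a metadata sidecar to `out_dir`. Deterministic given
#' `(config, seed)`.
#'
#' @param config an `emodyn_config` or path to a JSON config.
#' @param out_dir output directory.
#' @param seed overrides the config seed when given.
#' @return the generated `list(study, truth)`, invisibly.
#' @export
run_simulate <- function(config = generator_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_generator_config(config)
  gen <- generate_study(config, seed = seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_study(gen$study, out_dir)
  utils::write.csv(gen$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_sidecar(out_dir, "simulate",
                list(seed = if (is.null(seed)) config$seed else seed,
                     n_persons = config$n_persons, n_days = config$n_days,
                     prompts_per_day = config$prompts_per_day,
                     eod_summary = config$eod_summary))
  invisible(gen)
}

#' Compute dynamics profiles from dataset files
#'
#' Reads a study directory, applies the inclusion filter, computes the
#' 11-measure battery per person and method, and writes `profiles.csv`,
#' `exclusions.csv` and a sidecar.
#'
#' @param in_dir directory with `observations.csv` (and optionally
#'   `episodes.csv`, `health.csv`).
#' @param out_dir output directory (default `in_dir`).
#' @param min_obs inclusion threshold per method.
#' @param center_lag,max_gap_hours,cor_method passed to
#'   [compute_profiles()].
#' @return the profile table, invisibly.
#' @export
run_dynamics <- function(in_dir, out_dir = in_dir, min_obs = 4,
                         center_lag = TRUE, max_gap_hours = 10,
                         cor_method = "pearson") {
  study <- read_study(in_dir)
  study <- apply_inclusion_filter(study, min_obs)
  profiles <- compute_profiles(study, center_lag = center_lag,
                               max_gap_hours = max_gap_hours,
                               cor_method = cor_method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  utils::write.csv(study$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  write_sidecar(out_dir, "dynamics",
                list(min_obs = min_obs, center_lag = center_lag,
                     max_gap_hours = max_gap_hours, cor_method = cor_method,
                     n_included = length(unique(profiles$person_id)),
                     n_excluded = length(unique(study$exclusions$person_id))))
  invisible(profiles)
}

#' Run the full cross-method comparison suite from profiles.csv
#'
#' Writes `comparison.csv` (mean/correlation comparisons per measure),
#' `network_<method>.csv` and `strengths.csv` (correlation networks and
#' node strengths), `health_correlations.csv`, `health_incremental.csv`,
#' `health_mean_abs_q.csv`, and a sidecar.
#'
#' @param in_dir directory with `profiles.csv` (and `health.csv` for the
#'   health analyses).
#' @param out_dir output directory (default `in_dir`).
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param alpha significance level.
#' @return list with the comparison, networks, and health results,
#'   invisibly.
#' @export
run_compare <- function(in_dir, out_dir = in_dir, cor_method = "pearson",
                        alpha = 0.05) {
  pf <- file.path(in_dir, "profiles.csv")
  if (!file.exists(pf)) stop("profiles.csv not found in ", in_dir, call. = FALSE)
  profiles <- utils::read.csv(pf, stringsAsFactors = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cmp <- compare_methods(profiles, cor_method = cor_method, alpha = alpha)
  utils::write.csv(cmp$table, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  nets <- lapply(intersect(ILA_METHODS, unique(profiles$method)), function(m) {
    nw <- correlation_network(profiles[profiles$method == m, ],
                              cor_method = cor_method, alpha = alpha)
    utils::write.csv(data.frame(measure = rownames(nw$matrix), nw$matrix,
                                check.names = FALSE),
                     file.path(out_dir, paste0("network_", m, ".csv")),
                     row.names = FALSE)
    nw
  })
  names(nets) <- intersect(ILA_METHODS, unique(profiles$method))
  strengths <- data.frame(measure = names(nets[[1]]$strength),
                          sapply(nets, function(n) n$strength),
                          check.names = FALSE)
  utils::write.csv(strengths, file.path(out_dir, "strengths.csv"),
                   row.names = FALSE)
  health <- NULL
  hf <- file.path(in_dir, "health.csv")
  if (file.exists(hf)) {
    hd <- read_ila_csv(hf, "health")
    health <- health_associations(profiles, hd, cor_method = cor_method)
    utils::write.csv(health$correlations,
                     file.path(out_dir, "health_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(health$incremental,
                     file.path(out_dir, "health_incremental.csv"),
                     row.names = FALSE)
    utils::write.csv(health$mean_abs_q,
                     file.path(out_dir, "health_mean_abs_q.csv"),
                     row.names = FALSE)
  }
  write_sidecar(out_dir, "compare",
                list(cor_method = cor_method, alpha = alpha,
                     n_persons = length(unique(profiles$person_id)),
                     health_included = !is.null(health)))
  invisible(list(comparison = cmp, networks = nets, strengths = strengths,
                 health = health))
}
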