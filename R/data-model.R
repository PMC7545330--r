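# Domain types, ingest/validation, rescaling, episode geometry,
# inclusion filtering, and lag-pair construction.

ILA_METHODS <- c("EMA", "EOD", "DRM")
TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Rescale a raw day-reconstruction rating to the 0-100 scale
#'
#' Day-reconstruction episodes are rated on a 7-point scale (0 = not at
#' all, 6 = very much) whereas momentary and end-of-day ratings use a
#' 0-100 visual analog scale. Raw episode ratings are mapped onto 0-100
#' with the affine transform `100 * (raw + 0.5) / 7`, which places each
#' scale point at the centre of its bin.
#'
#' @param raw integer rating(s) in 0..6.
#' @return numeric score(s) on the 0-100 scale.
#' @export
#' @examples
#' rescale_drm(0:6)
rescale_drm <- function(raw) {
  if (length(raw) == 0) return(numeric(0))
  if (any(!is.finite(raw)) || any(raw != round(raw)) || any(raw < 0 | raw > 6)) {
    stop("raw DRM ratings must be integers in [0, 6]", call. = FALSE)
  }
  100 * (raw + 0.5) / 7
}

#' Quantize a 0-100 affect score back to the raw 0-6 episode scale
#'
#' Inverts [rescale_drm()] and rounds half away from zero to the nearest
#' integer in 0..6. Used by the synthetic generator to emit episode
#' ratings on the scale respondents actually use.
#'
#' @param score numeric score(s) on 0-100.
#' @return integer rating(s) in 0..6.
#' @export
drm_quantize <- function(score) {
  x <- score * 7 / 100 - 0.5
  raw <- floor(x + 0.5)  # half away from zero; x >= -0.5 always here
  as.integer(pmin(6L, pmax(0L, raw)))
}

#' Midpoint of a day-reconstruction episode
#'
#' Lag construction for episode data measures gaps from the midpoint of
#' one episode to the midpoint of the next.
#'
#' @param start,end `POSIXct` vectors; `end > start` element-wise.
#' @return `POSIXct` midpoint(s).
#' @export
episode_midpoint <- function(start, end) {
  if (any(as.numeric(end) < as.numeric(start))) {
    stop("episode end precedes start", call. = FALSE)
  }
  if (any(as.numeric(end) == as.numeric(start))) {
    warning("zero-duration episode; midpoint set to start")
  }
  start + (as.numeric(end) - as.numeric(start)) / 2
}

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("timestamp '%s' (row %d) does not parse as ISO-8601", x[bad], bad),
         call. = FALSE)
  }
  out
}

format_ts <- function(x) format(x, TS_FORMAT, tz = "UTC")

#' Validate raw observation / episode tables
#'
#' Checks required columns, rating ranges, and strictly increasing
#' timestamps within (person, method); returns the typed, sorted table.
#' Called by [read_ila_csv()] and [ila_study()]; exported so external
#' ingest code can reuse the same contract.
#'
check_range <- function(x, lo, hi, name) {
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad)) {
    stop(sprintf("%s out of range [%s, %s] at row %d (value %s)",
                 name, lo, hi, bad[1], x[bad[1]]), call. = FALSE)
  }
}

#' Validate raw observation / episode tables
#'
#' Checks required columns, rating ranges, and strictly increasing
#' timestamps within (person, method); returns the typed, sorted table.
#' Called by [read_ila_csv()] and [ila_study()]; exported so external
#' ingest code can reuse the same contract.
#'
#' @param obs raw observation table.
#' @param ep raw episode table.
#' @return the validated, typed table.
#' @rdname validators
#' @export
validate_observations <- function(obs) {
  need <- c("person_id", "method", "timestamp", "day_index", "pa", "na")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(obs$method %in% ILA_METHODS)) {
    stop("method must be one of ", paste(ILA_METHODS, collapse = "/"), call. = FALSE)
  }
  check_range(obs$pa, 0, 100, "pa")
  check_range(obs$na, 0, 100, "na")
  obs$person_id <- as.character(obs$person_id)
  obs$day_index <- as.integer(obs$day_index)
  obs <- obs[order(obs$person_id, obs$method, obs$timestamp), , drop = FALSE]
  key <- split(as.numeric(obs$timestamp), interaction(obs$person_id, obs$method, drop = TRUE))
  for (k in names(key)) {
    if (any(diff(key[[k]]) <= 0)) {
      stop(sprintf("timestamps not strictly increasing within %s", k), call. = FALSE)
    }
  }
  rownames(obs) <- NULL
  obs
}

#' @rdname validators
#' @export
validate_episodes <- function(ep) {
  need <- c("person_id", "day_index", "start", "end", "raw_pa", "raw_na")
  miss <- setdiff(need, names(ep))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(as.numeric(ep$end) <= as.numeric(ep$start))) {
    bad <- which(as.numeric(ep$end) <= as.numeric(ep$start))[1]
    stop(sprintf("episode end <= start at row %d", bad), call. = FALSE)
  }
  check_range(ep$raw_pa, 0, 6, "raw_pa")
  check_range(ep$raw_na, 0, 6, "raw_na")
  if (is.null(ep$label)) ep$label <- ""
  ep$person_id <- as.character(ep$person_id)
  ep$day_index <- as.integer(ep$day_index)
  ep <- ep[order(ep$person_id, ep$start), , drop = FALSE]
  for (p in split(ep, ep$person_id)) {
    if (nrow(p) > 1 &&
        any(as.numeric(p$start[-1]) < as.numeric(p$end[-nrow(p)]) - 1e-6)) {
      stop(sprintf("overlapping episodes for person %s", p$person_id[1]), call. = FALSE)
    }
  }
  rownames(ep) <- NULL
  ep
}

validate_health <- function(h) {
  need <- c("person_id", "day_index", "general_health", "pain", "fatigue")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  check_range(h$general_health, 1, 5, "general_health")
  check_range(h$pain, 0, 100, "pain")
  check_range(h$fatigue, 0, 100, "fatigue")
  h$person_id <- as.character(h$person_id)
  h$day_index <- as.integer(h$day_index)
  h <- h[order(h$person_id, h$day_index), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Convert day-reconstruction episodes to 0-100 affect observations
#'
#' Each episode becomes one observation: the timestamp is the episode
#' midpoint and ratings are rescaled with [rescale_drm()].
#'
#' @param episodes validated episode table.
#' @return observation table with `method = "DRM"`.
#' @export
episodes_to_observations <- function(episodes) {
  if (nrow(episodes) == 0) {
    return(data.frame(person_id = character(0), method = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      day_index = integer(0), pa = numeric(0), na = numeric(0)))
  }
  data.frame(
    person_id = episodes$person_id,
    method = "DRM",
    timestamp = episode_midpoint(episodes$start, episodes$end),
    day_index = episodes$day_index,
    pa = rescale_drm(episodes$raw_pa),
    na = rescale_drm(episodes$raw_na),
    stringsAsFactors = FALSE
  )
}

#' Assemble a multi-method study dataset
#'
#' Bundles momentary/diary observations, raw day-reconstruction episodes
#' (converted to DRM observations at ingest), and daily health records
#' into one validated container.
#'
#' @param observations observation table (EMA/EOD rows; DRM rows allowed
#'   if already converted).
#' @param episodes optional raw episode table; converted and appended as
#'   DRM observations.
#' @param health optional daily health table.
#' @return an object of class `ila_study` with elements `observations`,
#'   `episodes`, `health`, `exclusions`.
#' @export
ila_study <- function(observations, episodes = NULL, health = NULL) {
  obs <- validate_observations(observations)
  ep <- if (!is.null(episodes) && nrow(episodes) > 0) validate_episodes(episodes) else NULL
  if (!is.null(ep)) {
    obs <- rbind(obs[, c("person_id", "method", "timestamp", "day_index", "pa", "na")],
                 episodes_to_observations(ep))
    obs <- validate_observations(obs)
  }
  h <- if (!is.null(health)) validate_health(health) else NULL
  structure(list(observations = obs, episodes = ep, health = h,
                 exclusions = NULL),
            class = "ila_study")
}

#' @export
print.ila_study <- function(x, ...) {
  np <- length(unique(x$observations$person_id))
  cat(sprintf("ila_study: %d persons, %d observations (%s)\n", np,
              nrow(x$observations),
              paste(sprintf("%s: %d", ILA_METHODS,
                            vapply(ILA_METHODS, function(m)
                              sum(x$observations$method == m), 0L)),
                    collapse = ", ")))
  if (!is.null(x$exclusions) && nrow(x$exclusions) > 0) {
    cat(sprintf("  %d persons excluded by inclusion filter\n",
                length(unique(x$exclusions$person_id))))
  }
  invisible(x)
}

#' Read one study CSV
#'
#' @param path file path.
#' @param schema one of `"observations"`, `"episodes"`, `"health"`.
#' @return validated typed table.
#' @export
read_ila_csv <- function(path, schema = c("observations", "episodes", "health")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(schema,
    observations = {
      if (!"timestamp" %in% names(raw)) stop("missing column(s): timestamp", call. = FALSE)
      raw$timestamp <- parse_ts(raw$timestamp)
      validate_observations(raw)
    },
    episodes = {
      for (cl in c("start", "end")) {
        if (!cl %in% names(raw)) stop("missing column(s): ", cl, call. = FALSE)
        raw[[cl]] <- parse_ts(raw[[cl]])
      }
      validate_episodes(raw)
    },
    health = validate_health(raw)
  )
}

#' Write a study dataset to a directory of CSV files
#'
#' Emits `observations.csv`, and `episodes.csv` / `health.csv` when
#' present, as RFC-4180 CSV with ISO-8601 timestamps at second precision
#' and floats at full precision.
#'
#' @param study an `ila_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ila_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly
  obs <- study$observations
  obs$timestamp <- format_ts(obs$timestamp)
  obs$pa <- fmt(obs$pa); obs$na <- fmt(obs$na)
  utils::write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  if (!is.null(study$episodes)) {
    ep <- study$episodes
    ep$start <- format_ts(ep$start)
    ep$end <- format_ts(ep$end)
    utils::write.csv(ep, file.path(dir, "episodes.csv"), row.names = FALSE)
  }
  if (!is.null(study$health)) {
    h <- study$health
    h$pain <- fmt(h$pain); h$fatigue <- fmt(h$fatigue)
    utils::write.csv(h, file.path(dir, "health.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study dataset written by [write_study()]
#' @param dir directory containing the CSV files.
#' @return an `ila_study`.
#' @export
read_study <- function(dir) {
  obs <- read_ila_csv(file.path(dir, "observations.csv"), "observations")
  epf <- file.path(dir, "episodes.csv")
  hf <- file.path(dir, "health.csv")
  ep <- if (file.exists(epf)) read_ila_csv(epf, "episodes") else NULL
  h <- if (file.exists(hf)) read_ila_csv(hf, "health") else NULL
  # observations.csv already contains the converted DRM rows, so pass
  # episodes through without re-converting
  st <- ila_study(obs, episodes = NULL, health = h)
  st$episodes <- ep
  st
}

#' Apply the minimum-observations inclusion filter
#'
#' Persons must provide at least `min_obs` observations under every
#' assessment method to enter the analysis; all others are dropped and
#' reported. Counts are taken after ingest validation, before any lag
#' filtering. The filter is idempotent.
#'
#' @param study an `ila_study`.
#' @param min_obs minimum observations per method (default 4).
#' @param methods methods a person must satisfy (default all three).
#' @return an `ila_study` with only retained persons; `$exclusions` lists
#'   each excluded person with the failing method(s) and counts.
#' @export
apply_inclusion_filter <- function(study, min_obs = 4, methods = ILA_METHODS) {
  stopifnot(inherits(study, "ila_study"))
  obs <- study$observations
  if (nrow(obs) == 0) stop("empty dataset", call. = FALSE)
  persons <- unique(obs$person_id)
  counts <- table(factor(obs$person_id, levels = persons),
                  factor(obs$method, levels = methods))
  fail <- counts < min_obs
  excluded <- persons[rowSums(fail) > 0]
  report <- do.call(rbind, lapply(excluded, function(p) {
    fm <- methods[fail[p, ]]
    data.frame(person_id = p, failing_method = fm,
               n_obs = as.integer(counts[p, fm]), stringsAsFactors = FALSE)
  }))
  if (is.null(report)) {
    report <- data.frame(person_id = character(0), failing_method = character(0),
                         n_obs = integer(0))
  }
  keep <- !(obs$person_id %in% excluded)
  out <- study
  out$observations <- obs[keep, , drop = FALSE]
  rownames(out$observations) <- NULL
  if (!is.null(study$episodes)) {
    out$episodes <- study$episodes[!(study$episodes$person_id %in% excluded), , drop = FALSE]
  }
  if (!is.null(study$health)) {
    out$health <- study$health[!(study$health$person_id %in% excluded), , drop = FALSE]
  }
  out$exclusions <- report
  out
}

#' Gap rules used for lag construction under each method
#'
#' EMA drops overnight pairs (timestamps on different calendar dates) and
#' pairs more than `max_gap_hours` apart; DRM applies only the hour cap
#' to episode-midpoint gaps; EOD keeps only pairs of consecutive calendar
#' days and has no hour cap.
#'
#' @param method `"EMA"`, `"EOD"` or `"DRM"`.
#' @param max_gap_hours hour cap for EMA/DRM (default 10).
#' @return list with `max_gap_hours` and `cross_day_rule`.
#' @export
method_lag_rules <- function(method, max_gap_hours = 10) {
  switch(method,
    EMA = list(max_gap_hours = max_gap_hours, cross_day_rule = "omit_cross_day"),
    DRM = list(max_gap_hours = max_gap_hours, cross_day_rule = "none"),
    EOD = list(max_gap_hours = Inf, cross_day_rule = "consecutive_days_only"),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Successive-observation lag pairs under the active gap rules
#'
#' Builds (previous, next) pairs of successive observations within one
#' person and method, then drops pairs violating the gap rules: pairs
#' whose gap exceeds `max_gap_hours`, pairs spanning two calendar dates
#' (`omit_cross_day`), or pairs of non-consecutive `day_index`
#' (`consecutive_days_only`).
#'
#' @param series observation table for one person and one method, ordered
#'   by timestamp.
#' @param max_gap_hours drop pairs with a larger gap (hours); `Inf` for
#'   no cap.
#' @param cross_day_rule `"omit_cross_day"`, `"consecutive_days_only"`,
#'   or `"none"`.
#' @return data frame of retained pairs: `person_id`, `pa_prev`,
#'   `pa_next`, `na_prev`, `na_next`, `gap_hours`, `day_prev`, `day_next`.
#' @export
lagged_pairs <- function(series, max_gap_hours = 10,
                         cross_day_rule = c("omit_cross_day",
                                            "consecutive_days_only", "none")) {
  cross_day_rule <- match.arg(cross_day_rule)
  empty <- data.frame(person_id = character(0), pa_prev = numeric(0),
                      pa_next = numeric(0), na_prev = numeric(0),
                      na_next = numeric(0), gap_hours = numeric(0),
                      day_prev = integer(0), day_next = integer(0))
  n <- nrow(series)
  if (n < 2) return(empty)
  i <- seq_len(n - 1)
  gap <- as.numeric(difftime(series$timestamp[i + 1], series$timestamp[i],
                             units = "hours"))
  keep <- gap <= max_gap_hours
  if (cross_day_rule == "omit_cross_day") {
    d <- as.Date(series$timestamp, tz = "UTC")
    keep <- keep & (d[i + 1] == d[i])
  } else if (cross_day_rule == "consecutive_days_only") {
    keep <- keep & (series$day_index[i + 1] - series$day_index[i] == 1L)
  }
  i <- i[keep]
  if (!length(i)) return(empty)
  data.frame(person_id = series$person_id[i],
             pa_prev = series$pa[i], pa_next = series$pa[i + 1],
             na_prev = series$na[i], na_next = series$na[i + 1],
             gap_hours = gap[keep],
             day_prev = series$day_index[i], day_next = series$day_index[i + 1],
             stringsAsFactors = FALSE)
}

#' Lag pairs for every person under a method's default rules
#'
#' @param study an `ila_study`.
#' @param method assessment method.
#' @param max_gap_hours hour cap passed to [method_lag_rules()].
#' @return stacked pair table across persons.
#' @export
study_lag_pairs <- function(study, method, max_gap_hours = 10) {
  rules <- method_lag_rules(method, max_gap_hours)
  obs <- study$observations[study$observations$method == method, , drop = FALSE]
  parts <- lapply(split(obs, obs$person_id), lagged_pairs,
                  max_gap_hours = rules$max_gap_hours,
                  cross_day_rule = rules$cross_day_rule)
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- lagged_pairs(obs[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}
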