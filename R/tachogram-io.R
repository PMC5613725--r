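#' RR-interval tachograms
#'
#' An `rr_tachogram` holds an ordered series of RR intervals (milliseconds),
#' a per-interval artifact mask (`TRUE` = flagged), and recording metadata
#' (patient id, months since transplant, source). Interval values are never
#' mutated by filtering; only the mask changes, so every decision remains
#' auditable.
#'
#' @param intervals Numeric vector of RR intervals in ms, all > 0.
#' @param patient_id Identifier string.
#' @param months_post_tx Follow-up months (optional, `NA` if unknown).
#' @param artifact_mask Logical vector, same length as `intervals`.
#' @param source File path or format tag.
#' @return An object of class `rr_tachogram`.
#' @export
rr_tachogram <- function(intervals, patient_id = NA_character_,
                         months_post_tx = NA_real_,
                         artifact_mask = logical(length(intervals)),
                         source = NA_character_) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L)
    stop("a tachogram needs at least one interval", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("RR intervals must be finite and > 0 ms", call. = FALSE)
  if (length(artifact_mask) != length(intervals))
    stop("`artifact_mask` must match `intervals` in length", call. = FALSE)
  structure(list(intervals = intervals,
                 artifact_mask = as.logical(artifact_mask),
                 patient_id = patient_id,
                 months_post_tx = months_post_tx,
                 source = source),
            class = "rr_tachogram")
}

#' @export
print.rr_tachogram <- function(x, ...) {
  cat(sprintf("<rr_tachogram: %d intervals, %d flagged (%.1f%% regular)>\n",
              length(x$intervals), sum(x$artifact_mask),
              100 * regular_fraction(x)))
  if (!is.na(x$patient_id))
    cat(sprintf("  patient %s, %s months post-transplant\n",
                x$patient_id, format(x$months_post_tx)))
  invisible(x)
}

#' Fraction of intervals not flagged as artifacts
#' @param t An `rr_tachogram`.
#' @return Proportion in \[0, 1\].
#' @export
regular_fraction <- function(t) {
  1 - sum(t$artifact_mask) / length(t$intervals)
}

#' Read an RR-interval series from disk
#'
#' Two dialects are supported: `plain` (UTF-8, one interval in ms per line,
#' blank lines and `#` comments ignored) and `hrm` (INI-style sections in
#' square brackets; only the `[HRData]` section, one RR per line, is
#' consumed). `auto` sniffs for an `[HRData]` header.
#'
#' @param path File path.
#' @param format `"plain"`, `"hrm"` or `"auto"`.
#' @param patient_id,months_post_tx Optional metadata attached to the result.
#' @return An `rr_tachogram` with a clear artifact mask.
#' @export
read_rr_series <- function(path, format = c("auto", "plain", "hrm"),
                           patient_id = NA_character_,
                           months_post_tx = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("RR file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(trimws(lines)) == 0L || all(trimws(lines) == ""))
    stop(sprintf("RR file is empty: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^\\s*\\[HRData\\]\\s*$", lines, ignore.case = TRUE)))
      "hrm" else "plain"
  if (format == "hrm") {
    start <- grep("^\\s*\\[HRData\\]\\s*$", lines, ignore.case = TRUE)
    if (length(start) == 0L)
      stop(sprintf("no [HRData] section in %s", path), call. = FALSE)
    body <- lines[-seq_len(start[1L])]
    nxt <- grep("^\\s*\\[", body)
    if (length(nxt)) body <- body[seq_len(nxt[1L] - 1L)]
    lines <- body
    offset <- start[1L]
  } else offset <- 0L
  keep <- !grepl("^\\s*(#|$)", lines)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]] + offset
    stop(sprintf("non-numeric RR value at line %d of %s", bad, path),
         call. = FALSE)
  }
  if (length(vals) == 0L)
    stop(sprintf("no RR intervals in %s", path), call. = FALSE)
  rr_tachogram(vals, patient_id = patient_id,
               months_post_tx = months_post_tx, source = path)
}

#' Write an RR series in the plain one-interval-per-line format
#'
#' @param t An `rr_tachogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(t, path) {
  writeLines(sprintf("%.15g", t$intervals), path)
  invisible(path)
}

#' Two-stage artifact filter
#'
#' Stage 1 is the automatic filter: an interval is flagged if it falls
#' outside the physiological band `band_ms` or differs from the previous
#' *accepted* interval by more than `jump_fraction` (relative). Stage 2
#' represents manual visual inspection as an explicit list of 1-based
#' indices to exclude. Values are never altered; only the mask is set.
#'
#' @param t An `rr_tachogram`.
#' @param band_ms Length-2 numeric, plausible RR band in ms
#'   (default 300--2000).
#' @param jump_fraction Maximum allowed relative change from the previous
#'   accepted interval (default 0.20).
#' @param manual_exclusions Integer vector of 1-based indices flagged by
#'   visual inspection.
#' @return A list with elements `tachogram` (mask updated) and `report`
#'   (an `artifact_report` with per-rule counts).
#' @export
filter_artifacts <- function(t, band_ms = c(300, 2000), jump_fraction = 0.20,
                             manual_exclusions = integer()) {
  stopifnot(inherits(t, "rr_tachogram"))
  if (length(band_ms) != 2L || band_ms[1L] >= band_ms[2L])
    stop("`band_ms` must be c(low, high) with low < high", call. = FALSE)
  if (jump_fraction <= 0 || jump_fraction >= 1)
    stop("`jump_fraction` must be in (0, 1)", call. = FALSE)
  x <- t$intervals
  n <- length(x)
  if (length(manual_exclusions) &&
      (any(manual_exclusions < 1) || any(manual_exclusions > n)))
    stop("manual exclusion index out of range", call. = FALSE)

  band_hit <- x < band_ms[1L] | x > band_ms[2L]
  jump_hit <- logical(n)
  flagged <- band_hit
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (flagged[i]) next
    if (!is.na(prev) && abs(x[i] - prev) / prev > jump_fraction) {
      jump_hit[i] <- TRUE
      flagged[i] <- TRUE
    } else prev <- x[i]
  }
  manual_hit <- logical(n)
  manual_hit[manual_exclusions] <- TRUE
  flagged <- flagged | manual_hit

  t$artifact_mask <- flagged
  report <- structure(list(
    n_total = n,
    n_flagged = sum(flagged),
    regular_fraction = (n - sum(flagged)) / n,
    rule_hits = c(band = sum(band_hit), jump = sum(jump_hit),
                  manual = sum(manual_hit))),
    class = "artifact_report")
  list(tachogram = t, report = report)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report: %d/%d flagged, %.1f%% regular (band %d, jump %d, manual %d)>\n",
              x$n_flagged, x$n_total, 100 * x$regular_fraction,
              x$rule_hits[["band"]], x$rule_hits[["jump"]],
              x$rule_hits[["manual"]]))
  invisible(x)
}

#' Regularity acceptance rule
#'
#' A series is accepted only if strictly more than `min_regular` of its
#' beats are regular (unflagged); at exactly the threshold it is rejected.
#'
#' @param t An `rr_tachogram` (already filtered).
#' @param min_regular Minimum regular fraction, exclusive (default 0.95).
#' @return `t` unchanged if accepted; otherwise an error of class
#'   `hrvrqa_rejection` carrying the regular fraction.
#' @export
accept_series <- function(t, min_regular = 0.95) {
  stopifnot(inherits(t, "rr_tachogram"))
  rf <- regular_fraction(t)
  if (rf > min_regular) return(t)
  stop(errorCondition(
    sprintf("series rejected: %.1f%% regular beats (need > %.0f%%)",
            100 * rf, 100 * min_regular),
    class = c("hrvrqa_rejection", "hrvrqa_error"),
    regular_fraction = rf))
}

#' Truncate to the analysis length
#'
#' Keeps the first `n` unflagged intervals in order (the standard analysis
#' window is 1000 beats).
#'
#' @param t An `rr_tachogram`.
#' @param n Target length (default 1000).
#' @return An `rr_tachogram` of exactly `n` clean intervals.
#' @export
trim_to_length <- function(t, n = 1000) {
  stopifnot(inherits(t, "rr_tachogram"))
  clean <- t$intervals[!t$artifact_mask]
  if (length(clean) < n)
    stop(errorCondition(
      sprintf("insufficient data: %d clean intervals, need %d",
              length(clean), n),
      class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  rr_tachogram(clean[seq_len(n)], patient_id = t$patient_id,
               months_post_tx = t$months_post_tx, source = t$source)
}

#' Read a sidecar manual-exclusion file
#'
#' One 0-based index per line (`#` comments allowed); returned 1-based for
#' use with [filter_artifacts()].
#'
#' @param path File path.
#' @return Integer vector of 1-based indices.
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path))
    stop(sprintf("exclusion file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(integer())
  idx <- suppressWarnings(as.integer(trimws(lines)))
  if (anyNA(idx)) stop("non-integer exclusion index", call. = FALSE)
  idx + 1L
}
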