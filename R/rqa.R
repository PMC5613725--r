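#' Line-length histograms of a recurrence matrix
#'
#' The substrate of all RQA measures: counts of maximal runs of consecutive
#' recurrent cells, by exact length, along diagonals (parallel trajectory
#' evolution) or verticals (trapped states).
#'
#' For diagonals the matrix symmetry is exploited: only offsets above the
#' main diagonal are scanned, so each symmetric pair of lines is counted
#' once. The line of identity (the trivially recurrent main diagonal) is
#' excluded by default. Vertical runs are counted per column over the full
#' matrix, with identity cells treated as ordinary cells.
#'
#' @param r A `recurrence_matrix`.
#' @param exclude_loi Drop the main diagonal from the count (default TRUE).
#' @return A `line_histogram`: list with `counts` (element `l` = number of
#'   maximal runs of exact length `l`), `orientation`, `exclude_loi`, `n`.
#' @export
diagonal_histogram <- function(r, exclude_loi = TRUE) {
  stopifnot(inherits(r, "recurrence_matrix"))
  R <- r$r
  n <- r$n
  counts <- integer(n)
  offsets <- if (exclude_loi) seq_len(n - 1L) else c(0L, seq_len(n - 1L))
  for (k in offsets) {
    len <- n - k
    v <- R[cbind(seq_len(len), seq_len(len) + k)]
    counts <- add_runs(counts, v)
  }
  structure(list(counts = counts, orientation = "diagonal",
                 exclude_loi = exclude_loi, n = n),
            class = "line_histogram")
}

#' @rdname diagonal_histogram
#' @export
vertical_histogram <- function(r) {
  stopifnot(inherits(r, "recurrence_matrix"))
  R <- r$r
  n <- r$n
  counts <- integer(n)
  for (j in seq_len(n)) counts <- add_runs(counts, R[, j])
  structure(list(counts = counts, orientation = "vertical",
                 exclude_loi = FALSE, n = n),
            class = "line_histogram")
}

# accumulate run lengths of TRUE in `v` into `counts`
add_runs <- function(counts, v) {
  rl <- rle(v)
  lens <- rl$lengths[rl$values]
  if (length(lens)) {
    tab <- tabulate(lens, nbins = length(counts))
    counts <- counts + tab
  }
  counts
}

#' @export
print.line_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<line_histogram: %s%s, %d line(s), lengths %s>\n",
              x$orientation, if (x$exclude_loi) " (LOI excluded)" else "",
              sum(x$counts),
              if (length(nz)) paste0(min(nz), "..", max(nz)) else "none"))
  invisible(x)
}

#' The seven recurrence-quantification measures
#'
#' From the recurrence matrix and its line histograms:
#' * `rec_pct` — percentage of recurrent cells over all `n^2` cells
#'   (line of identity included);
#' * `det_pct` — percentage of off-identity recurrent points lying on
#'   diagonals of length >= `lmin`;
#' * `lmean` — mean length of qualifying diagonals (beats);
#' * `lmax` — longest qualifying diagonal;
#' * `entr` — Shannon entropy (bits by default) of the qualifying
#'   diagonal-length distribution;
#' * `lam_pct` — percentage of recurrent points on verticals of length
#'   >= `vmin`;
#' * `tt` — trapping time, the mean qualifying vertical length.
#'
#' If no recurrent point exists off the line of identity the diagonal
#' measures are reported as 0 with a warning (keeping cohort tables
#' rectangular), and likewise for degenerate vertical structure.
#'
#' @param r A `recurrence_matrix`.
#' @param lmin Minimum diagonal line length (default 2).
#' @param vmin Minimum vertical line length (default 2).
#' @param entropy_base `2` for bits (default) or `exp(1)` for nats.
#' @return An `rqa_result`: list with the seven measures plus `n` and the
#'   thresholds used.
#' @export
compute_rqa <- function(r, lmin = 2, vmin = 2, entropy_base = 2) {
  stopifnot(inherits(r, "recurrence_matrix"))
  n <- r$n
  rec_pct <- 100 * sum(r$r) / n^2

  dh <- diagonal_histogram(r, exclude_loi = TRUE)$counts
  lens <- seq_along(dh)
  mass <- lens * dh                      # recurrent points per length
  qual <- lens >= lmin & dh > 0
  if (!any(dh > 0)) {
    warning("no recurrent point off the line of identity; diagonal measures set to 0")
    det_pct <- lmean <- lmax <- entr <- 0
  } else if (!any(qual)) {
    warning(sprintf("no diagonal of length >= %d; diagonal measures set to 0", lmin))
    det_pct <- lmean <- lmax <- entr <- 0
  } else {
    det_pct <- 100 * sum(mass[qual]) / sum(mass)
    lmean <- sum(mass[qual]) / sum(dh[qual])
    lmax <- max(lens[qual])
    p <- dh[qual] / sum(dh[qual])
    entr <- -sum(p * log(p, base = entropy_base))
  }

  vh <- vertical_histogram(r)$counts
  vmass <- seq_along(vh) * vh
  vqual <- seq_along(vh) >= vmin & vh > 0
  if (!any(vqual)) {
    warning(sprintf("no vertical of length >= %d; lam_pct and tt set to 0", vmin))
    lam_pct <- tt <- 0
  } else {
    lam_pct <- 100 * sum(vmass[vqual]) / sum(vmass)
    tt <- sum(vmass[vqual]) / sum(vh[vqual])
  }

  structure(list(rec_pct = rec_pct, det_pct = det_pct, lmean = lmean,
                 lmax = lmax, entr = entr, lam_pct = lam_pct, tt = tt,
                 n = n, lmin = lmin, vmin = vmin,
                 entropy_base = entropy_base),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf(paste0("<rqa_result (n = %d)>\n",
                     "  %%REC %.1f  %%DET %.1f  Lmean %.3f  Lmax %d\n",
                     "  ENTR %.3f  %%LAM %.1f  TT %.3f\n"),
              x$n, x$rec_pct, x$det_pct, x$lmean, x$lmax,
              x$entr, x$lam_pct, x$tt))
  invisible(x)
}

#' @export
as.data.frame.rqa_result <- function(x, ...) {
  data.frame(n = x$n, rec_pct = x$rec_pct, det_pct = x$det_pct,
             lmean = x$lmean, lmax = x$lmax, entr = x$entr,
             lam_pct = x$lam_pct, tt = x$tt)
}

#' RQA of a raw series in one call
#'
#' Embeds, thresholds and quantifies with the standard tachogram settings
#' (m = 10, tau = 1, radius = 70% of mean distance, minimum line 2).
#'
#' @inheritParams recurrence_from_series
#' @inheritParams compute_rqa
#' @return An `rqa_result`.
#' @examples
#' rqa_series(gen_logistic_series(521))
#' @export
rqa_series <- function(series, m = 10, tau = 1, radius = 70,
                       radius_type = c("meanpct", "absolute"),
                       norm = c("euclidean", "maximum"),
                       lmin = 2, vmin = 2, entropy_base = 2) {
  compute_rqa(recurrence_from_series(series, m = m, tau = tau,
                                     radius = radius,
                                     radius_type = match.arg(radius_type),
                                     norm = match.arg(norm)),
              lmin = lmin, vmin = vmin, entropy_base = entropy_base)
}
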