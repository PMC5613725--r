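#' Sample entropy (SampEn)
#'
#' SampEn(m, r) = -ln(A / B), where B is the number of pairs of distinct
#' length-`m` templates whose Chebyshev distance is <= `r`, and A is the
#' same count for length `m + 1`. Self-matches are excluded, and both counts
#' run over the same `n - m` template start points (the Richman--Moorman
#' convention). The tolerance is `r_frac` times the sample standard
#' deviation of the series, which makes the measure invariant under affine
#' rescaling. Lower values indicate a more regular signal.
#'
#' Degenerate inputs: a constant series (zero tolerance) returns 0 with a
#' warning — a perfectly regular signal; if no template pair matches at
#' length `m + 1` (or none at length `m`), `Inf` is returned with a warning.
#'
#' @param series Numeric vector (or `model_series` / `rr_tachogram`).
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @return A single number: SampEn in nats.
#' @examples
#' sample_entropy(sin(1:200))            # regular, low
#' sample_entropy(gen_logistic_series(200)$values)
#' @export
sample_entropy <- function(series, m = 2, r_frac = 0.2) {
  x <- series_values(series)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (r_frac <= 0) stop("`r_frac` must be > 0", call. = FALSE)
  n <- length(x)
  if (n <= m + 1)
    stop(errorCondition(
      sprintf("series too short for SampEn: length %d, need > m + 1 = %d",
              n, m + 1),
      class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  sdev <- stats::sd(x)
  if (sdev == 0) {
    warning("constant series: SampEn reported as 0 (perfectly regular)")
    return(0)
  }
  r <- r_frac * sdev
  nt <- n - m                       # template start points for both lengths
  templ_m  <- vapply(0:(m - 1L), function(k) x[seq_len(nt) + k], numeric(nt))
  templ_m1 <- vapply(0:m,        function(k) x[seq_len(nt) + k], numeric(nt))
  B <- sum(stats::dist(matrix(templ_m,  nrow = nt), method = "maximum") <= r)
  A <- sum(stats::dist(matrix(templ_m1, nrow = nt), method = "maximum") <= r)
  if (B == 0 || A == 0) {
    warning("no matching template pairs: SampEn reported as Inf")
    return(Inf)
  }
  -log(A / B)
}
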