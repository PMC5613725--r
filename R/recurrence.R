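#' Time-delay embedding
#'
#' Reconstructs state-space vectors from a scalar series:
#' vector `i` is `(x[i], x[i + tau], ..., x[i + (m-1) tau])`, giving
#' `L - (m - 1) * tau` vectors from a series of length `L`.
#'
#' @param series Numeric vector (or a `model_series` / `rr_tachogram`,
#'   whose values are extracted).
#' @param m Embedding dimension (>= 1).
#' @param tau Time delay in samples (>= 1).
#' @return An `embedded_series`: list with `vectors` (an
#'   `n_vectors x m` matrix), `n_vectors` and `source_length`.
#' @export
embed_series <- function(series, m = 10, tau = 1) {
  x <- series_values(series)
  if (m < 1 || tau < 1) stop("need m >= 1 and tau >= 1", call. = FALSE)
  m <- as.integer(m); tau <- as.integer(tau)
  L <- length(x)
  nv <- L - (m - 1L) * tau
  if (nv < 2L)
    stop(errorCondition(
      sprintf("series too short to embed: length %d gives %d vector(s) at m=%d, tau=%d (need >= 2)",
              L, nv, m, tau),
      class = c("hrvrqa_insufficient_data", "hrvrqa_error")))
  vectors <- vapply(seq_len(m) - 1L,
                    function(k) x[seq_len(nv) + k * tau],
                    numeric(nv))
  structure(list(vectors = matrix(vectors, nrow = nv),
                 n_vectors = nv, source_length = L, m = m, tau = tau),
            class = "embedded_series")
}

series_values <- function(series) {
  if (inherits(series, "model_series")) return(as.numeric(series$values))
  if (inherits(series, "rr_tachogram")) return(series$intervals)
  as.numeric(series)
}

#' Pairwise distance matrix of embedded vectors
#'
#' @param emb An `embedded_series`.
#' @param norm `"euclidean"` or `"maximum"` (Chebyshev).
#' @return A `distance_matrix`: list with the symmetric zero-diagonal
#'   matrix `d` and `n`.
#' @export
distance_matrix <- function(emb, norm = c("euclidean", "maximum")) {
  stopifnot(inherits(emb, "embedded_series"))
  norm <- match.arg(norm)
  d <- as.matrix(stats::dist(emb$vectors, method = norm))
  dimnames(d) <- NULL
  structure(list(d = d, n = emb$n_vectors, norm = norm),
            class = "distance_matrix")
}

#' Thresholded recurrence matrix
#'
#' Cell (i, j) is recurrent when `d[i, j] <= eps`, where the effective
#' threshold `eps` depends on `radius_type`:
#' * `"meanpct"` (default): `radius` is a percentage of the mean pairwise
#'   distance, `eps = radius / 100 * mean(d)` — the convention of classic
#'   visual-recurrence software, which makes the analysis invariant to the
#'   scale of the series;
#' * `"absolute"`: `radius` is a distance in series units.
#'
#' The comparison is inclusive, so the line of identity (zero distance) is
#' always recurrent.
#'
#' @param d A `distance_matrix`.
#' @param radius Threshold (percent of mean distance, or absolute).
#' @param radius_type `"meanpct"` or `"absolute"`.
#' @return A `recurrence_matrix`: list with logical matrix `r`, `n`,
#'   `eps` (the resolved absolute threshold) and the settings used.
#' @export
recurrence_matrix <- function(d, radius = 70,
                              radius_type = c("meanpct", "absolute")) {
  stopifnot(inherits(d, "distance_matrix"))
  radius_type <- match.arg(radius_type)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  eps <- if (radius_type == "meanpct") radius / 100 * mean(d$d) else radius
  structure(list(r = d$d <= eps, n = d$n, eps = eps, radius = radius,
                 radius_type = radius_type, norm = d$norm),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix: %d x %d, %.1f%% recurrent (radius %g %s, eps %.3f)>\n",
              x$n, x$n, 100 * mean(x$r), x$radius,
              if (x$radius_type == "meanpct") "% of mean distance" else "abs",
              x$eps))
  invisible(x)
}

#' One-call recurrence matrix from a raw series
#'
#' Convenience wrapper: embed, compute distances, threshold.
#'
#' @inheritParams embed_series
#' @inheritParams distance_matrix
#' @inheritParams recurrence_matrix
#' @return A `recurrence_matrix`.
#' @export
recurrence_from_series <- function(series, m = 10, tau = 1, radius = 70,
                                   radius_type = c("meanpct", "absolute"),
                                   norm = c("euclidean", "maximum")) {
  recurrence_matrix(
    distance_matrix(embed_series(series, m = m, tau = tau),
                    norm = match.arg(norm)),
    radius = radius, radius_type = match.arg(radius_type))
}

#' Quantize distances into color bands
#'
#' Maps each distance to `floor(n_bands * min(d, max_distance) /
#' max_distance)`, clipped to `n_bands - 1`, so that cells at equal distance
#' share a band; the zero-distance diagonal always lands in band 0.
#'
#' @param d A `distance_matrix`.
#' @param n_bands Number of bands (>= 2).
#' @param max_distance Saturation distance (default: the matrix maximum).
#' @return Integer matrix of band indices 0 .. `n_bands - 1`.
#' @export
band_quantize <- function(d, n_bands = 8, max_distance = max(d$d)) {
  stopifnot(inherits(d, "distance_matrix"))
  if (n_bands < 2) stop("`n_bands` must be >= 2", call. = FALSE)
  if (max_distance <= 0) stop("`max_distance` must be > 0", call. = FALSE)
  b <- floor(n_bands * pmin(d$d, max_distance) / max_distance)
  b[b > n_bands - 1] <- n_bands - 1
  storage.mode(b) <- "integer"
  b
}

#' Render a recurrence plot to PNG
#'
#' Writes a square raster with axis i horizontal, axis j vertical, origin at
#' the lower left, one pixel per matrix cell. Boolean recurrence matrices are
#' drawn black-on-white; band matrices use a dark-to-warm color ramp
#' (near-black violet through red and orange to pale yellow) in which band 0
#' — the recurrent core including the line of identity — is darkest.
#' Output is deterministic: the same matrix yields byte-identical files.
#'
#' @param x A `recurrence_matrix`, or an integer band matrix from
#'   [band_quantize()].
#' @param out Output PNG path.
#' @param colormap Only `"lava"` (the built-in ramp) is provided.
#' @return `out`, invisibly.
#' @export
render_rp <- function(x, out, colormap = "lava") {
  if (inherits(x, "recurrence_matrix")) {
    n <- x$n
    # recurrent = ink (0), non-recurrent = white (1)
    img <- array(as.numeric(!x$r), dim = c(n, n))
    rgb <- array(rep(img, 3L), dim = c(n, n, 3L))
  } else {
    if (!is.matrix(x)) stop("`x` must be a recurrence or band matrix", call. = FALSE)
    n <- nrow(x)
    nb <- max(x) + 1L
    ramp <- lava_ramp(max(nb, 2L))
    idx <- x + 1L
    rgb <- array(0, dim = c(n, n, 3L))
    for (ch in 1:3) rgb[, , ch] <- matrix(ramp[idx, ch], n, n)
  }
  if (n == 0L) stop("empty matrix", call. = FALSE)
  # writePNG's row 1 is the top scanline; flip so j increases upward
  rgb <- rgb[n:1, , , drop = FALSE]
  png::writePNG(rgb, target = out)
  invisible(out)
}

# dark violet -> red -> orange -> pale yellow, as an n x 3 matrix in [0,1]
lava_ramp <- function(n) {
  anchors <- matrix(c(0.05, 0.00, 0.10,
                      0.45, 0.05, 0.25,
                      0.80, 0.15, 0.10,
                      0.95, 0.55, 0.10,
                      1.00, 0.95, 0.70),
                    ncol = 3, byrow = TRUE)
  s <- seq(0, 1, length.out = n)
  sa <- seq(0, 1, length.out = nrow(anchors))
  vapply(1:3, function(ch) stats::approx(sa, anchors[, ch], xout = s)$y,
         numeric(n))
}
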