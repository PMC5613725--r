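#' Benchmark model series
#'
#' Generators for the four formula-defined benchmark series used to anchor
#' the recurrence-plot measures: a truncated-uniform random series, the
#' logistic map in its chaotic regime, a periodic ramp over 0--50, and the
#' ascending prime numbers as a (near-)linear trend. All four live on the
#' same dimensionless 0--100-ish integer scale so that their recurrence
#' plots are directly comparable.
#'
#' @name model_series
#' @keywords internal
NULL

new_model_series <- function(values, label, params) {
  structure(list(values = values, label = label, params = params),
            class = "model_series")
}

#' @export
print.model_series <- function(x, ...) {
  cat(sprintf("<model_series: %s, n = %d>\n", x$label, length(x$values)))
  cat("  head:", paste(utils::head(x$values, 8), collapse = " "), "...\n")
  invisible(x)
}

#' Random model series
#'
#' `n` independent draws of `floor(100 * U)`, `U ~ Uniform[0, 1)`: integers
#' 0--99, the spreadsheet idiom `RAND() * 100` with the decimals discarded.
#'
#' @param n Series length (>= 1).
#' @param seed Integer seed; the generator is bit-reproducible for a fixed
#'   seed and does not disturb the caller's RNG state.
#' @return A `model_series` with integer `values` in 0--99.
#' @examples
#' s <- gen_random_series(10, seed = 1)
#' range(s$values)
#' @export
gen_random_series <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  n <- as.integer(n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  values <- as.integer(floor(stats::runif(n) * 100))
  new_model_series(values, "random", list(seed = seed, count = n))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Chaotic model series (logistic map)
#'
#' Iterates `x[t+1] = x[t] * (1 - x[t]) * r` from `x0` and records
#' `floor(100 * x[t])` for `t = 1..n`. The defaults `x0 = 0.2`, `r = 3.7`
#' put the map in a well-known chaotic regime; the scaled maximum is
#' `floor(100 * r / 4) = 92` for `r = 3.7`.
#'
#' @param n Series length (>= 1).
#' @param x0 Initial state, strictly inside (0, 1) so the orbit stays in
#'   the unit interval.
#' @param r Map parameter (0 < r <= 4).
#' @param truncate How to drop decimals after scaling by 100: `"floor"`
#'   (the default, "excluding the decimal place") or `"round"` for
#'   sensitivity checks.
#' @return A `model_series` with integer `values`.
#' @examples
#' gen_logistic_series(5)$values  # 59 89 ...
#' @export
gen_logistic_series <- function(n, x0 = 0.2, r = 3.7,
                                truncate = c("floor", "round")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  if (!is.numeric(x0) || x0 <= 0 || x0 >= 1)
    stop("`x0` must lie strictly inside (0, 1); the map leaves [0, 1] otherwise",
         call. = FALSE)
  truncate <- match.arg(truncate)
  n <- as.integer(n)
  x <- numeric(n)
  cur <- x0
  for (t in seq_len(n)) {
    cur <- cur * (1 - cur) * r
    x[t] <- cur
  }
  f <- if (truncate == "floor") floor else round
  new_model_series(as.integer(f(100 * x)), "chaotic",
                   list(x0 = x0, r = r, count = n, truncate = truncate))
}

#' Periodic model series
#'
#' Repeats the numbers 0--50. Two readings of "repeating" are supported:
#' `"triangle"` (default) oscillates 0,1,...,50,49,...,1,0,... (period 100),
#' `"sawtooth"` ramps 0,1,...,50,0,1,... (period 51). The triangle is the
#' default because its recurrence structure matches the published benchmark
#' table (maximal diagonal 511 at the calibrated radius); the sawtooth's
#' wrap-around jump of 50 breaks the first off-diagonal into period-51
#' segments.
#'
#' @param n Series length (default 521).
#' @param style `"triangle"` or `"sawtooth"`.
#' @return A `model_series` with integer `values` in 0--50.
#' @examples
#' gen_periodic_series(6)$values
#' gen_periodic_series(60, style = "sawtooth")$values[52]  # back to 0
#' @export
gen_periodic_series <- function(n = 521, style = c("triangle", "sawtooth")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  style <- match.arg(style)
  n <- as.integer(n)
  values <- if (style == "sawtooth") {
    (seq_len(n) - 1L) %% 51L
  } else {
    pattern <- c(0:50, 49:1)
    pattern[(seq_len(n) - 1L) %% 100L + 1L]
  }
  new_model_series(as.integer(values), "periodic",
                   list(count = n, style = style,
                        period = if (style == "sawtooth") 51L else 100L))
}

#' Linear model series (ascending primes)
#'
#' The first `count` prime numbers in ascending order (default 521, ending
#' at 3739), a strictly increasing, nearly linear trend.
#'
#' @param count Number of primes (default 521).
#' @return A `model_series` with strictly increasing integer `values`.
#' @examples
#' gen_prime_series(5)$values  # 2 3 5 7 11
#' @export
gen_prime_series <- function(count = 521) {
  if (!is.numeric(count) || length(count) != 1L || count < 1)
    stop("`count` must be a single count >= 1", call. = FALSE)
  count <- as.integer(count)
  # upper bound p_n < n (log n + log log n) for n >= 6; sieve once
  limit <- if (count < 6) 13L else {
    as.integer(ceiling(count * (log(count) + log(log(count)))) + 10L)
  }
  values <- sieve_primes(limit)
  while (length(values) < count) {   # bound is proven but belt-and-braces
    limit <- limit * 2L
    values <- sieve_primes(limit)
  }
  new_model_series(values[seq_len(count)], "linear", list(count = count))
}

sieve_primes <- function(limit) {
  is_p <- rep(TRUE, limit)
  is_p[1L] <- FALSE
  p <- 2L
  while (p * p <= limit) {
    if (is_p[p]) is_p[seq.int(p * p, limit, by = p)] <- FALSE
    p <- p + 1L
  }
  which(is_p)
}
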