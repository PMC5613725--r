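# Independent brute-force oracles, written as plain double loops so they
# share no code path with the package implementations they check.

# Pairwise distances of a delay embedding, cell by cell.
bf_distance <- function(series, m, tau, norm = "euclidean") {
  nv <- length(series) - (m - 1) * tau
  d <- matrix(0, nv, nv)
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      diffs <- numeric(m)
      for (k in 0:(m - 1))
        diffs[k + 1] <- series[i + k * tau] - series[j + k * tau]
      d[i, j] <- if (norm == "euclidean") sqrt(sum(diffs^2)) else max(abs(diffs))
    }
  }
  d
}

# All seven RQA measures from a logical matrix, runs counted cell by cell.
bf_rqa <- function(R, lmin = 2, vmin = 2) {
  n <- nrow(R)
  rec_pct <- 100 * sum(R) / n^2

  dcounts <- integer(n)
  for (k in 1:(n - 1)) {        # upper-triangle offsets only
    run <- 0
    for (i in 1:(n - k)) {
      if (R[i, i + k]) run <- run + 1
      else {
        if (run > 0) dcounts[run] <- dcounts[run] + 1L
        run <- 0
      }
    }
    if (run > 0) dcounts[run] <- dcounts[run] + 1L
  }
  lens <- seq_len(n)
  tot <- sum(lens * dcounts)
  qual <- lens >= lmin & dcounts > 0
  if (tot == 0 || !any(qual)) {
    det_pct <- lmean <- lmax <- entr <- 0
  } else {
    det_pct <- 100 * sum((lens * dcounts)[qual]) / tot
    lmean <- sum((lens * dcounts)[qual]) / sum(dcounts[qual])
    lmax <- max(lens[qual])
    p <- dcounts[qual] / sum(dcounts[qual])
    entr <- -sum(p * log2(p))
  }

  vcounts <- integer(n)
  for (j in 1:n) {
    run <- 0
    for (i in 1:n) {
      if (R[i, j]) run <- run + 1
      else {
        if (run > 0) vcounts[run] <- vcounts[run] + 1L
        run <- 0
      }
    }
    if (run > 0) vcounts[run] <- vcounts[run] + 1L
  }
  vqual <- lens >= vmin & vcounts > 0
  if (!any(vqual)) {
    lam_pct <- tt <- 0
  } else {
    lam_pct <- 100 * sum((lens * vcounts)[vqual]) / sum(lens * vcounts)
    tt <- sum((lens * vcounts)[vqual]) / sum(vcounts[vqual])
  }

  list(rec_pct = rec_pct, det_pct = det_pct, lmean = lmean, lmax = lmax,
       entr = entr, lam_pct = lam_pct, tt = tt,
       dcounts = dcounts, vcounts = vcounts)
}

# Naive O(n^2) SampEn with explicit template comparison.
bf_sampen <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sd(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      match_m <- TRUE
      for (k in 0:(m - 1)) {
        if (abs(x[i + k] - x[j + k]) > r) { match_m <- FALSE; break }
      }
      if (match_m) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# Random symmetric recurrence mask with a full line of identity, wrapped
# in the class the package operates on.
random_recurrence <- function(n, p = 0.3) {
  mask <- matrix(stats::runif(n * n) < p, n, n)
  mask <- mask | t(mask)
  diag(mask) <- TRUE
  structure(list(r = mask, n = n, eps = NA_real_, radius = NA_real_,
                 radius_type = "absolute", norm = "euclidean"),
            class = "recurrence_matrix")
}

# A clean synthetic tachogram with optional artifacts spliced in.
make_tachogram <- function(n = 1200, base = 800, seed = 1) {
  set.seed(seed)
  rr_tachogram(base + rnorm(n, sd = 10), patient_id = "T01")
}
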