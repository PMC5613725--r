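all_true_rm <- function(n) {
  structure(list(r = matrix(TRUE, n, n), n = n, eps = Inf, radius = Inf,
                 radius_type = "absolute", norm = "euclidean"),
            class = "recurrence_matrix")
}

test_that("diagonal histogram of a saturated matrix counts one line per offset", {
  h <- diagonal_histogram(all_true_rm(5))
  expect_identical(h$counts[1:4], rep(1L, 4))   # lengths 4, 3, 2, 1 once each
  expect_identical(sum(h$counts), 4L)

  # identity-only matrix: no off-diagonal structure at all
  id <- all_true_rm(5)
  id$r <- diag(5) == 1
  expect_identical(sum(diagonal_histogram(id)$counts), 0L)
  # ... unless the line of identity is kept
  expect_identical(diagonal_histogram(id, exclude_loi = FALSE)$counts[5], 1L)
})

test_that("vertical histogram counts column runs with identity cells included", {
  h <- vertical_histogram(all_true_rm(4))
  expect_identical(h$counts[4], 4L)             # four runs of length 4

  cb <- all_true_rm(6)
  cb$r <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  hv <- vertical_histogram(cb)
  expect_identical(hv$counts[1], sum(cb$r))     # checkerboard: all runs length 1
  expect_identical(sum(hv$counts[-1]), 0L)
})

test_that("line histograms match the brute-force run counter on random masks", {
  set.seed(99)
  for (i in 1:25) {
    rmx <- random_recurrence(sample(5:25, 1), p = runif(1, 0.1, 0.6))
    bf <- bf_rqa(rmx$r)
    expect_identical(diagonal_histogram(rmx)$counts, bf$dcounts)
    expect_identical(vertical_histogram(rmx)$counts, bf$vcounts)
  }
})

test_that("saturated matrix yields the degenerate RQA limits", {
  n <- 8
  res <- compute_rqa(all_true_rm(n))
  expect_equal(res$rec_pct, 100)
  expect_equal(res$lmax, n - 1)                # longest off-identity diagonal
  expect_equal(res$lam_pct, 100)
  expect_equal(res$tt, n)
  # one full diagonal per offset: lengths 1 .. n-1 once each, so only the
  # single length-1 corner diagonal fails lmin = 2
  mass <- n * (n - 1) / 2
  expect_equal(res$det_pct, 100 * (mass - 1) / mass)
  expect_equal(res$entr, log2(n - 2))          # lengths 2..n-1, equally frequent
})

test_that("identity-only matrix reports zeros with a degenerate warning", {
  id <- all_true_rm(6)
  id$r <- diag(6) == 1
  expect_warning(expect_warning(res <- compute_rqa(id), "no recurrent point"),
                 "no vertical")
  expect_equal(res$det_pct, 0)
  expect_equal(res$lmax, 0)
  expect_equal(res$entr, 0)
  expect_equal(res$rec_pct, 100 * 6 / 36)
})

test_that("entropy is zero for a point-mass length distribution and bounded above", {
  set.seed(4)
  for (i in 1:20) {
    rmx <- random_recurrence(sample(8:30, 1), p = runif(1, 0.15, 0.5))
    res <- suppressWarnings(compute_rqa(rmx))
    dh <- diagonal_histogram(rmx)$counts
    k <- sum(dh[2:length(dh)] > 0)
    if (k >= 1) expect_lte(res$entr, log2(max(k, 1)) + 1e-12)
    if (k == 1) expect_equal(res$entr, 0)
    expect_lte(res$det_pct, 100)
    expect_gte(res$det_pct, 0)
    if (res$lmax > 0) expect_lte(res$lmean, res$lmax)
  }
})

test_that("masking recurrences never increases the recurrence rate", {
  set.seed(12)
  rmx <- random_recurrence(20, p = 0.4)
  res <- suppressWarnings(compute_rqa(rmx))
  drop <- rmx
  off <- which(drop$r & row(drop$r) < col(drop$r))
  kill <- sample(off, 10)
  drop$r[kill] <- FALSE
  drop$r <- drop$r & t(drop$r)
  res2 <- suppressWarnings(compute_rqa(drop))
  expect_lte(res2$rec_pct, res$rec_pct)
})

test_that("all seven measures equal the brute-force oracle on random matrices", {
  set.seed(2024)
  for (i in 1:40) {
    rmx <- random_recurrence(sample(6:30, 1), p = runif(1, 0.1, 0.7))
    got <- suppressWarnings(compute_rqa(rmx))
    want <- bf_rqa(rmx$r)
    for (f in c("rec_pct", "det_pct", "lmean", "lmax", "entr", "lam_pct", "tt"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("the four benchmark series are ordered by recurrence rate", {
  rnd <- rqa_series(gen_random_series(521, seed = 5))
  cha <- rqa_series(gen_logistic_series(521))
  per <- rqa_series(gen_periodic_series(521))
  lin <- rqa_series(gen_prime_series(521))
  expect_lt(rnd$rec_pct, cha$rec_pct)
  expect_lt(cha$rec_pct, per$rec_pct)
  expect_lte(per$rec_pct, lin$rec_pct)
})
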