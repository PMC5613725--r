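test_that("delay embedding has the right shape and content", {
  e <- embed_series(gen_periodic_series(521), m = 10, tau = 1)
  expect_equal(e$n_vectors, 512)          # 521 - 9
  expect_equal(dim(e$vectors), c(512, 10))

  x <- c(1, 4, 9, 16, 25, 36)
  e2 <- embed_series(x, m = 3, tau = 2)
  expect_equal(e2$n_vectors, 2)
  expect_equal(e2$vectors[1, ], c(1, 9, 25))
  expect_equal(e2$vectors[2, ], c(4, 16, 36))

  e1 <- embed_series(x, m = 1, tau = 1)   # identity embedding
  expect_equal(as.numeric(e1$vectors), x)

  expect_error(embed_series(1:10, m = 10, tau = 1),
               class = "hrvrqa_insufficient_data")
})

test_that("distance matrices honor the norm and are symmetric with zero diagonal", {
  e <- embed_series(c(0, 3, 0, 3), m = 2, tau = 1)  # vectors (0,3),(3,0),(0,3)
  d <- distance_matrix(e)
  expect_equal(d$d[1, 3], 0)
  expect_equal(d$d[1, 2], sqrt(18))
  dm <- distance_matrix(e, norm = "maximum")
  expect_equal(dm$d[1, 2], 3)

  set.seed(5)
  er <- embed_series(rnorm(40), m = 4, tau = 2)
  dr <- distance_matrix(er)$d
  expect_equal(dr, t(dr))
  expect_true(all(diag(dr) == 0))
  expect_true(all(dr >= 0))
})

test_that("euclidean and maximum norms match the textbook 3-4-5 example", {
  # embed so that two 2-d vectors are exactly (0,0) and (3,4)
  e <- embed_series(c(0, 3, 0, 4), m = 2, tau = 2)  # (0,0), (3,4)
  expect_equal(distance_matrix(e, "euclidean")$d[1, 2], 5)
  expect_equal(distance_matrix(e, "maximum")$d[1, 2], 4)
})

test_that("recurrence matrices are symmetric, reflexive, and monotone in radius", {
  set.seed(11)
  d <- distance_matrix(embed_series(rnorm(60, sd = 10), m = 3, tau = 1))
  r1 <- recurrence_matrix(d, radius = 5, radius_type = "absolute")
  r2 <- recurrence_matrix(d, radius = 15, radius_type = "absolute")
  expect_true(all(diag(r1$r)))
  expect_equal(r1$r, t(r1$r))
  # growing the radius never removes a recurrence
  expect_true(all(r2$r[r1$r]))

  # below the smallest off-diagonal distance only the identity line remains
  eps0 <- min(d$d[d$d > 0]) * 0.5
  r0 <- recurrence_matrix(d, radius = eps0, radius_type = "absolute")
  expect_equal(sum(r0$r), r0$n)

  # constant series: all distances zero, all cells recurrent
  rc <- recurrence_from_series(rep(5, 30), m = 2, tau = 1, radius = 1,
                               radius_type = "absolute")
  expect_true(all(rc$r))
})

test_that("meanpct radius resolves to a fraction of the mean distance", {
  set.seed(3)
  s <- runif(50, 0, 100)
  d <- distance_matrix(embed_series(s, m = 2, tau = 1))
  r <- recurrence_matrix(d, radius = 70, radius_type = "meanpct")
  expect_equal(r$eps, 0.70 * mean(d$d))
  # scale invariance: multiplying the series by 10 changes nothing
  ra <- recurrence_matrix(distance_matrix(embed_series(s, 2, 1)), 70, "meanpct")
  rb <- recurrence_matrix(distance_matrix(embed_series(10 * s, 2, 1)), 70, "meanpct")
  expect_identical(ra$r, rb$r)
})

test_that("thresholded matrix matches a brute-force double loop on short series", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- runif(25, 0, 100)
    m <- sample(1:4, 1); tau <- sample(1:2, 1)
    d_pkg <- distance_matrix(embed_series(s, m, tau))$d
    d_bf <- bf_distance(s, m, tau)
    expect_equal(d_pkg, d_bf, tolerance = 1e-12)
    eps <- stats::median(d_bf)
    r_pkg <- recurrence_matrix(
      structure(list(d = d_pkg, n = nrow(d_pkg), norm = "euclidean"),
                class = "distance_matrix"),
      radius = eps, radius_type = "absolute")
    expect_identical(r_pkg$r, d_bf <= eps)
  }
})

test_that("band quantization maps distances to the documented bands", {
  d <- structure(list(d = matrix(c(0, 55, 55, 0), 2), n = 2L,
                      norm = "euclidean"), class = "distance_matrix")
  b <- band_quantize(d, n_bands = 4, max_distance = 100)
  expect_identical(b[1, 1], 0L)            # diagonal in band 0
  expect_identical(b[1, 2], 2L)            # floor(4 * 0.55)
  d2 <- structure(list(d = matrix(c(0, 100, 100, 0), 2), n = 2L,
                       norm = "euclidean"), class = "distance_matrix")
  expect_identical(band_quantize(d2, 4, 100)[1, 2], 3L)  # clipped at top
  expect_error(band_quantize(d, 4, max_distance = 0), "max_distance")
})

test_that("recurrence plots render deterministically with one pixel per cell", {
  rmx <- recurrence_from_series(gen_periodic_series(120), m = 2, tau = 1)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_rp(rmx, f1)
  render_rp(rmx, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  expect_equal(dim(img)[1:2], c(rmx$n, rmx$n))

  # banded rendering too
  d <- distance_matrix(embed_series(gen_periodic_series(60), 2, 1))
  f3 <- withr::local_tempfile(fileext = ".png")
  render_rp(band_quantize(d, 8), f3)
  expect_equal(dim(png::readPNG(f3))[3], 3)
})

test_that("a triangle-wave series gives fully recurrent period-spaced diagonals", {
  rmx <- recurrence_from_series(gen_periodic_series(521), m = 10, tau = 1)
  n <- rmx$n
  # vectors one full period (100 samples) apart are identical
  k <- 100
  expect_true(all(rmx$r[cbind(1:(n - k), (1 + k):n)]))
})
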