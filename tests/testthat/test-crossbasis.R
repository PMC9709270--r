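test_that("constant exposure series gives B(c) x colsums of the lag basis", {
  n <- 40L
  cval <- 8.5
  x <- rep(cval, n)
  # a constant series has no spread for knot placement: supply the spec
  espec <- complete_spec(basis_spec(3), c(0, 5, 10, 15, 20))
  lspec <- lag_knots(4, 3)
  cb <- crossbasis(x, max_lag = 4, exposure_spec = espec, lag_spec = lspec)
  B <- templag:::eval_basis(espec, cval)
  Csum <- colSums(templag:::eval_basis(lspec, 0:4))
  expected <- as.vector(kronecker(as.vector(B), Csum))
  for (t in 5:40)
    expect_equal(unname(cb$matrix[t, ]), expected, tolerance = 1e-12)
  expect_equal(cb$incomplete_rows, 1:4)
})

test_that("max_lag 0 degenerates to the exposure basis", {
  set.seed(2)
  x <- rnorm(60, 10, 6)
  cb <- crossbasis(x, max_lag = 0, exposure_df = 4)
  b <- natural_spline_basis(x, basis_spec(4))
  attr(b, "spec") <- NULL
  expect_equal(unname(cb$matrix), unname(b), tolerance = 1e-12)
  expect_length(cb$incomplete_rows, 0L)
})

test_that("cross-basis matrix matches the brute-force quadruple loop", {
  set.seed(30)
  x <- rnorm(30, 12, 8)
  espec <- complete_spec(basis_spec(3), x)
  lspec <- lag_knots(3, 2)
  cb <- crossbasis(x, max_lag = 3, exposure_spec = espec, lag_spec = lspec)
  oracle <- brute_crossbasis(x, 3L, espec, lspec)
  expect_equal(unname(cb$matrix[-(1:3), ]), unname(oracle[-(1:3), ]),
               tolerance = 1e-10)
  expect_equal(ncol(cb$matrix), 3L * 2L)
})

test_that("series shorter than the lag window is rejected", {
  expect_error(crossbasis(rnorm(10), max_lag = 14), "must exceed")
})

test_that("missing exposures inside the lag window flag the row", {
  set.seed(4)
  x <- rnorm(50, 10, 6)
  x[20L] <- NA
  cb <- crossbasis(x, max_lag = 3, exposure_df = 3, lag_df = 2)
  expect_true(all(20:23 %in% cb$incomplete_rows))
  expect_false(24L %in% cb$incomplete_rows)
})

test_that("contrast vectors: identity, additivity, brute force", {
  set.seed(5)
  x <- rnorm(80, 10, 7)
  cb <- crossbasis(x, max_lag = 5, exposure_df = 4, lag_df = 3)
  expect_equal(contrast_vector(cb, 3, 3, 2), rep(0, 12))
  c10 <- contrast_vector(cb, 18, 3, 4)
  c1m <- contrast_vector(cb, 18, 11, 4)
  cm0 <- contrast_vector(cb, 11, 3, 4)
  expect_equal(c10, c1m + cm0, tolerance = 1e-12)
  # brute force at a random point
  B <- function(v) templag:::eval_basis(cb$exposure_spec, v)
  Cl <- templag:::eval_basis(cb$lag_spec, 3)
  expect_equal(contrast_vector(cb, 15, 8, 3),
               as.vector(kronecker(as.vector(B(15) - B(8)), as.vector(Cl))),
               tolerance = 1e-12)
  expect_error(contrast_vector(cb, 15, 8, 6), "lag")
  expect_error(contrast_vector(cb, 15, 8, -1), "lag")
})

test_that("cumulative contrasts sum the single-lag contrasts", {
  set.seed(6)
  x <- rnorm(70, 12, 9)
  cb <- crossbasis(x, max_lag = 5, exposure_df = 3, lag_df = 3)
  expect_equal(cumulative_contrast(cb, 20, 10, c(2, 2)),
               contrast_vector(cb, 20, 10, 2), tolerance = 1e-12)
  expect_equal(cumulative_contrast(cb, 12, 12, c(0, 5)), rep(0, 9))
  direct <- Reduce(`+`, lapply(0:3, function(l)
    contrast_vector(cb, 20, 10, l)))
  expect_equal(cumulative_contrast(cb, 20, 10, c(0, 3)), direct,
               tolerance = 1e-12)
  expect_error(cumulative_contrast(cb, 20, 10, c(3, 1)), "window")
})

test_that("separable coefficient surfaces factorize over the contrast", {
  set.seed(8)
  x <- rnorm(90, 10, 8)
  cb <- crossbasis(x, max_lag = 6, exposure_df = 4, lag_df = 3)
  u <- rnorm(4)
  v <- rnorm(3)
  beta <- kronecker(u, v)
  B <- function(t) as.vector(templag:::eval_basis(cb$exposure_spec, t))
  for (l in c(0L, 3L, 6L)) {
    lhs <- sum(contrast_vector(cb, 19, 4, l) * beta)
    rhs <- sum((B(19) - B(4)) * u) * sum(cb$lag_basis[l + 1L, ] * v)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("predictions are invariant to a consistent column permutation", {
  set.seed(9)
  x <- rnorm(60, 10, 8)
  cb <- crossbasis(x, max_lag = 4, exposure_df = 3, lag_df = 2)
  beta <- rnorm(6)
  perm <- sample.int(6L)
  cc <- contrast_vector(cb, 16, 2, 3)
  expect_equal(sum(cc * beta), sum(cc[perm] * beta[perm]))
})

test_that("out-of-range prediction warns but extrapolates", {
  set.seed(10)
  x <- runif(50, 0, 20)
  cb <- crossbasis(x, max_lag = 3, exposure_df = 3, lag_df = 2)
  expect_warning(v <- contrast_vector(cb, 25, 10, 1), "outside")
  expect_true(all(is.finite(v)))
})
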