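make_spectra <- function(values, wl = NULL, dt = NULL) {
  if (is.null(wl)) wl <- seq_len(nrow(values))
  if (is.null(dt)) dt <- seq_len(ncol(values))
  spectra_matrix(wl, dt, values)
}

test_that("spectra_matrix validates its grids", {
  expect_error(spectra_matrix(c(2, 1), 1:3, matrix(0, 2, 3)), "increasing")
  expect_error(spectra_matrix(1:2, 1:3, matrix(0, 3, 2)), "matrix")
  expect_error(spectra_matrix(1:2, 1:2, matrix(c(1, NA, 1, 1), 2)),
               "finite")
  expect_silent(spectra_matrix(1:3, 5, matrix(0, 3, 1)))  # single delay
})

test_that("rank-1 outer product has exactly one nonzero singular value", {
  u <- sin(seq(0, pi, length.out = 12))
  v <- exp(-seq(0, 3, length.out = 7))
  r <- svd_decompose(make_spectra(outer(u, v)))
  expect_gt(r$d[1], 0)
  expect_lt(r$d[2] / r$d[1], 1e-12)
})

test_that("diagonal matrices have their diagonal magnitudes as singular values", {
  m <- diag(c(3, -5, 1, 2))
  r <- svd_decompose(make_spectra(m))
  expect_equal(r$d, c(5, 3, 2, 1))
})

test_that("full reconstruction is exact and components orthonormal", {
  set.seed(5)
  m <- make_spectra(matrix(rnorm(15 * 9), 15, 9))
  r <- svd_decompose(m)
  rec <- reconstruct(r, length(r$d))
  expect_lt(norm(rec$values - m$values, "F") / norm(m$values, "F"), 1e-9)
  expect_equal(crossprod(r$spectral), diag(ncol(r$spectral)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(crossprod(r$amplitude), diag(ncol(r$amplitude)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(r$d) <= 0) && all(r$d >= 0))
})

test_that("rank-k reconstruction error equals the discarded singular values", {
  set.seed(6)
  m <- make_spectra(matrix(rnorm(20 * 8), 20, 8))
  r <- svd_decompose(m)
  for (k in c(1, 3, 7)) {
    err <- norm(reconstruct(r, k)$values - m$values, "F")
    expect_equal(err, sqrt(sum(r$d[-seq_len(k)]^2)), tolerance = 1e-9)
  }
  expect_error(reconstruct(r, 0), "k must be")
  expect_error(reconstruct(r, 9), "k must be")
})

test_that("rank-1 truncation of a known rank-2 matrix follows Eckart-Young", {
  # singular values (2, 1) by construction
  m <- make_spectra(diag(c(2, 1, 0)))
  r <- svd_decompose(m)
  expect_equal(norm(reconstruct(r, 1)$values - m$values, "F"), 1,
               tolerance = 1e-12)
  # rank-1 input: zero error
  m1 <- make_spectra(outer(c(1, 2, 3), c(4, 5)))
  r1 <- svd_decompose(m1)
  expect_lt(norm(reconstruct(r1, 1)$values - m1$values, "F"), 1e-12)
})

test_that("truncated SVD beats random rank-1 candidates on 3x3 instances", {
  # brute-force check of Eckart-Young optimality
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(rnorm(9), 3, 3)
    r <- svd_decompose(make_spectra(m))
    best_svd <- norm(reconstruct(r, 1)$values - m, "F")
    for (i in 1:200) {
      u <- rnorm(3); v <- rnorm(3)
      cand <- outer(u, v)
      # optimal scaling of the candidate direction
      s <- sum(m * cand) / sum(cand^2)
      expect_gte(norm(s * cand - m, "F"), best_svd - 1e-9)
    }
  }
})

test_that("transposing swaps spectral and amplitude roles", {
  set.seed(9)
  vals <- matrix(rnorm(12 * 6), 12, 6)
  r <- svd_decompose(make_spectra(vals))
  rt <- svd_decompose(make_spectra(t(vals)))
  expect_equal(r$d, rt$d, tolerance = 1e-12)
  for (i in 1:3) {
    expect_equal(abs(r$spectral[, i]), abs(rt$amplitude[, i]),
                 tolerance = 1e-9)
  }
})

test_that("white-noise components are rejected by the smoothness criterion", {
  set.seed(10)
  rejected <- vapply(1:10, function(i) {
    m <- make_spectra(matrix(rnorm(30 * 20), 30, 20))
    r <- svd_decompose(m)
    length(select_components(r, autocorr_min = 0.8)) == 0
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("a dominant flat component is selected", {
  # constant vectors have lag-1 autocorrelation (n-1)/n
  expect_equal(pgbkinetics:::lag1_autocorrelation(rep(2, 10)), 9 / 10)
  smooth_u <- rep(1, 20); smooth_v <- rep(1, 10)
  m <- make_spectra(outer(smooth_u, smooth_v))
  r <- svd_decompose(m)
  expect_equal(select_components(r), 1L)
})

test_that("two smooth components plus small noise select exactly {1, 2}", {
  set.seed(12)
  wl <- seq(400, 460, by = 1)
  dt <- 10^seq(-8, 0, length.out = 40)
  b1 <- gaussian_band(wl, 436, 8) - gaussian_band(wl, 419, 8)
  b2 <- gaussian_band(wl, 427, 6, 0.4)
  c1 <- exp(-dt / 1e-4)
  c2 <- exp(-dt / 1e-6) - exp(-dt / 1e-5)
  vals <- outer(b1, c1) + outer(b2, c2) +
    matrix(rnorm(length(wl) * length(dt), 0, 1e-4), length(wl))
  r <- svd_decompose(spectra_matrix(wl, dt, vals))
  expect_identical(select_components(r), 1:2)
})

test_that("threshold arguments are validated", {
  r <- svd_decompose(make_spectra(diag(3)))
  expect_error(select_components(r, sv_ratio_min = 0), "0, 1")
  expect_error(select_components(r, autocorr_min = 1.2), "0, 1")
})
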