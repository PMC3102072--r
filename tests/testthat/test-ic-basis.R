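# ICA basis learning, orientation clustering, amplitude vectors.

test_that("orientation estimation recovers grating angles within 3 degrees", {
  mk <- function(theta_deg, scale = 48L, f = 0.12) {
    th <- theta_deg * pi / 180
    xs <- matrix(seq_len(scale), scale, scale, byrow = TRUE)
    ys <- matrix(seq_len(scale), scale, scale)
    cos(2 * pi * f * (xs * sin(th) + ys * cos(th)))
  }
  circ_d <- function(a, b) abs(((a - b + 90) %% 180) - 90)
  for (ang in c(0, 45, 90, 135)) {
    est <- estimate_ic_orientation(mk(ang), 48L)
    expect_lte(circ_d(as.numeric(est), ang), 3)
    expect_false(attr(est, "low_anisotropy"))
  }
})

test_that("low-anisotropy filters are flagged and assigned 0 degrees", {
  xs <- matrix(1:48, 48, 48, byrow = TRUE)
  grating <- cos(2 * pi * 0.12 * xs)
  # a radially symmetric blob is far less anisotropic than a grating
  r2 <- outer((1:48 - 24.5)^2, (1:48 - 24.5)^2, `+`)
  blob <- exp(-r2 / (2 * 6^2))
  expect_lt(attr(estimate_ic_orientation(blob, 48L), "anisotropy"),
            attr(estimate_ic_orientation(grating, 48L), "anisotropy"))
  # below the anisotropy cutoff the filter is flagged and assigned 0 degrees
  est <- estimate_ic_orientation(grating, 48L, aniso_min = 1e9)
  expect_true(attr(est, "low_anisotropy"))
  expect_identical(as.numeric(est), 0)
  expect_error(estimate_ic_orientation(matrix(0, 16, 16)),
               class = "rapidscene_data_error")
})

test_that("orientation binning uses circular distance; midpoints go low", {
  expect_identical(orientation_bin(10), 0)
  expect_identical(orientation_bin(30), 45)
  expect_identical(orientation_bin(170), 0)     # wraps around 180
  expect_identical(orientation_bin(100), 90)
  expect_identical(orientation_bin(22.5), 0)    # exact midpoint -> lower bin
  expect_identical(orientation_bin(157.5), 0)   # midway 135/180; 0 is lower
})

test_that("a learned basis has exactly four clusters and unit-norm rotations", {
  basis <- fx_fine_basis()
  expect_s3_class(basis, "ic_basis")
  expect_identical(basis$n_retained, 12L)
  expect_true(all(basis$clusters %in% c(0, 45, 90, 135)))
  # W is orthonormal
  expect_equal(basis$unmixing_w %*% t(basis$unmixing_w), diag(12L),
               tolerance = 1e-8)
  # whitening rows are orthogonal to the constant patch (DC-free filters)
  expect_lt(max(abs(basis$whitening %*% rep(1, 256))), 1e-8)
})

test_that("basis learning is bit-reproducible for a fixed seed", {
  P <- fx_oriented_patches(16L, 120L, seed = 77L)
  b1 <- learn_ic_basis(P, n_components = 6L, seed = 3L)
  b2 <- learn_ic_basis(P, n_components = 6L, seed = 3L)
  expect_identical(b1$filters, b2$filters)
  expect_identical(b1$clusters, b2$clusters)
})

test_that("ICA recovers orthogonal grating sources from mixtures", {
  scale <- 16L
  mk <- function(theta_deg, f) {
    th <- theta_deg * pi / 180
    xs <- matrix(seq_len(scale), scale, scale, byrow = TRUE)
    ys <- matrix(seq_len(scale), scale, scale)
    g <- cos(2 * pi * f * (xs * sin(th) + ys * cos(th)))
    as.numeric(g / sqrt(sum(g^2)))
  }
  S <- cbind(mk(0, 0.125), mk(90, 0.125), mk(45, 0.176))
  X <- rapidscene:::with_seed(11L, {
    A <- matrix(stats::rnorm(900 * 3, 0, 1), 900, 3)
    # heavy-tailed activations so ICA has contrast to work with
    A <- A^3
    A %*% t(S) + matrix(stats::rnorm(900 * scale^2, 0, 1e-3), 900)
  })
  b <- learn_ic_basis(X, n_components = 3L, seed = 4L)
  cors <- abs(stats::cor(b$features, S))
  # every source matched by some component
  expect_true(all(apply(cors, 2L, max) > 0.95))
})

test_that("amplitude vectors are linear in the patch", {
  basis <- fx_fine_basis()
  patch <- fx_oriented_patches(16L, 1L, seed = 12L)[1L, ]
  a1 <- amplitude_vector(patch, basis)
  expect_named(a1, c("0", "45", "90", "135"))
  expect_true(all(a1 >= 0))
  expect_equal(amplitude_vector(3 * patch, basis), 3 * a1, tolerance = 1e-12)
  expect_equal(unname(amplitude_vector(rep(0, 256), basis)), rep(0, 4))
  # constant patches have zero amplitude (DC is removed)
  expect_equal(unname(amplitude_vector(rep(5, 256), basis)), rep(0, 4),
               tolerance = 1e-9)
})

test_that("a scaled mixing column has amplitude = scale in its own cluster", {
  basis <- fx_fine_basis()
  j <- 1L
  mix <- basis$features[, j]
  a <- amplitude_vector(3 * mix, basis)
  cl <- as.character(basis$clusters[j])
  expect_equal(unname(a[cl]), 3, tolerance = 1e-6)
  others <- setdiff(names(a), cl)
  # other clusters see (numerically) nothing of this component
  expect_lt(max(a[others]), 1e-6 * 3)
})

test_that("batched amplitudes match the exact projection oracle", {
  basis <- fx_fine_basis()
  P <- fx_oriented_patches(16L, 120L, seed = 13L)
  A <- rapidscene:::amplitude_matrix(P, basis)
  for (i in seq_len(nrow(P))) {
    x <- P[i, ]
    s <- as.numeric(basis$unmixing_w %*% basis$whitening %*% (x - mean(x)))
    oracle <- vapply(c(0, 45, 90, 135), function(b)
      sqrt(sum(s[basis$clusters == b]^2)), numeric(1))
    expect_equal(unname(A[i, ]), oracle, tolerance = 1e-9)
  }
})

test_that("an ic basis roundtrips through save/load", {
  basis <- fx_fine_basis()
  dir <- withr::local_tempdir()
  save_ic_basis(basis, dir)
  b2 <- load_ic_basis(dir)
  expect_equal(b2$filters, basis$filters, tolerance = 1e-12)
  expect_equal(b2$clusters, basis$clusters)   # JSON may integerize the bins
  expect_equal(b2$scale, basis$scale)
  P <- fx_oriented_patches(16L, 10L, seed = 14L)
  expect_equal(rapidscene:::amplitude_matrix(P, b2),
               rapidscene:::amplitude_matrix(P, basis), tolerance = 1e-9)
})

test_that("default component counts are 160 (48 px) and 100 (16 px)", {
  # requesting the default from too few patches must error, proving the
  # default is what we expect without paying for a full fit
  expect_error(learn_ic_basis(matrix(stats::rnorm(99 * 256), 99), seed = 1L),
               class = "rapidscene_data_error")
  expect_error(learn_ic_basis(matrix(stats::rnorm(159 * 2304), 159), seed = 1L),
               class = "rapidscene_data_error")
})
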