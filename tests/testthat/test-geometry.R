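# Ellipse fitting, the geometry Gaussian, candidate sampling.

test_that("fit_ellipse inverts rasterize_ellipses", {
  truth <- data.frame(cx = 60, cy = 45, a = 24, b = 11, theta = 30)
  m <- rasterize_ellipses(truth, 100L, 120L)
  fit <- fit_ellipse(m)
  expect_equal(fit$cx, truth$cx, tolerance = 0.3)
  expect_equal(fit$cy, truth$cy, tolerance = 0.3)
  expect_equal(fit$a, truth$a, tolerance = 0.05 * truth$a)
  expect_equal(fit$b, truth$b, tolerance = 0.05 * truth$b)
  expect_lt(abs(((fit$theta - truth$theta + 90) %% 180) - 90), 2)
  # fitted ellipse area matches the region's pixel count exactly
  expect_equal(pi * fit$a * fit$b, sum(m), tolerance = 1e-9)
  expect_gte(fit$a, fit$b)
  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), class = "rapidscene_data_error")
})

test_that("theta follows the screen convention (CCW, y down)", {
  # ellipse rotated +30 deg CCW on screen: long axis runs up-right, so pixels
  # to the right of center sit at SMALLER row indices
  m <- rasterize_ellipses(data.frame(cx = 50, cy = 50, a = 20, b = 6, theta = 30),
                          100L, 100L)
  idx <- which(m, arr.ind = TRUE)
  right <- idx[idx[, 2] > 60, , drop = FALSE]
  expect_true(all(right[, 1] < 50))
  # axis-aligned cases: theta 0 is wider than tall, theta 90 taller than wide
  m0 <- rasterize_ellipses(data.frame(cx = 50, cy = 50, a = 20, b = 6, theta = 0),
                           100L, 100L)
  expect_gt(diff(range(which(m0, arr.ind = TRUE)[, 2])),
            diff(range(which(m0, arr.ind = TRUE)[, 1])))
  m90 <- rasterize_ellipses(data.frame(cx = 50, cy = 50, a = 20, b = 6, theta = 90),
                            100L, 100L)
  expect_gt(diff(range(which(m90, arr.ind = TRUE)[, 1])),
            diff(range(which(m90, arr.ind = TRUE)[, 2])))
})

test_that("round-tripping 100 random ellipses recovers parameters", {
  shp <- rapidscene:::with_seed(71L, data.frame(
    cx = stats::runif(100, 40, 90), cy = stats::runif(100, 40, 90),
    a = stats::runif(100, 15, 25), b = stats::runif(100, 6, 9),
    theta = stats::runif(100, 0, 180)))
  for (i in seq_len(100)) {
    m <- rasterize_ellipses(shp[i, ], 128L, 128L)
    fit <- fit_ellipse(m)
    expect_equal(fit$a, shp$a[i], tolerance = 0.08 * shp$a[i])
    expect_equal(fit$b, shp$b[i], tolerance = 0.08 * shp$b[i])
    expect_lt(abs(((fit$theta - shp$theta[i] + 90) %% 180) - 90), 4)
  }
})

test_that("geometry model reproduces mean/covariance and the peak angles", {
  ann <- rapidscene:::with_seed(72L, {
    do.call(rbind, lapply(1:40, function(id) {
      th_b <- stats::rnorm(1, 20, 4); th_h <- stats::rnorm(1, 70, 4)
      tibble::tibble(
        object_id = id, part = c("head", "body"),
        cx = c(60 + stats::rnorm(1, 18, 2), 60), cy = c(50 + stats::rnorm(1, -6, 2), 50),
        a = c(stats::rnorm(1, 8, 0.5), stats::rnorm(1, 20, 1)),
        b = c(stats::rnorm(1, 6, 0.4), stats::rnorm(1, 10, 0.8)),
        theta = c(th_h, th_b))
    }))
  })
  gm <- fit_geometry_model(ann, n_parts = 2L)
  expect_length(gm$mean, 10L)
  # embedded mean matches a direct computation
  V <- t(vapply(1:40, function(id)
    rapidscene:::embed_annotation(ann[ann$object_id == id, ], 2L), numeric(10L)))
  expect_equal(gm$mean, colMeans(V), tolerance = 1e-12)
  expect_equal(unname(gm$covariance),
               unname(rapidscene:::regularize_cov(
                 crossprod(sweep(V, 2L, colMeans(V))) / 40)), tolerance = 1e-12)
  # the modal orientations decode back near the generating angles
  expect_equal(unname(gm$peak$theta[gm$peak$part == "body"]), 20, tolerance = 3)
  expect_equal(unname(gm$peak$theta[gm$peak$part == "head"]), 70, tolerance = 3)
  expect_error(fit_geometry_model(ann[ann$object_id <= 2, ], 2L),
               class = "rapidscene_data_error")
})

test_that("geometry_log_density matches a hand-written Gaussian density", {
  ann <- rapidscene:::with_seed(73L, tibble::tibble(
    object_id = rep(1:20, each = 1L), part = "whole",
    cx = 50, cy = 50,
    a = stats::rnorm(20, 18, 1.5), b = stats::rnorm(20, 9, 1),
    theta = stats::rnorm(20, 45, 6)))
  gm <- fit_geometry_model(ann, n_parts = 1L)
  pm <- structure(matrix(0.9, 64, 64), class = "probability_map")
  cand <- sample_candidates(gm, pm, n = 5L, p_threshold = 0.6, seed = 74L)[[3L]]
  got <- geometry_log_density(gm, cand)
  x <- cand$shape
  oracle <- mvtnorm::dmvnorm(matrix(x, 1L), gm$mean, gm$covariance, log = TRUE)
  expect_equal(got, as.numeric(oracle), tolerance = 1e-9)
  # log_peak is the density at the mode, an upper bound
  expect_lte(got, gm$log_peak)
  cand$shape <- NULL
  expect_error(geometry_log_density(gm, cand), class = "rapidscene_data_error")
})

test_that("candidates land on above-threshold pixels, clamped and a >= b", {
  ann <- rapidscene:::with_seed(75L, tibble::tibble(
    object_id = 1:20, part = "whole", cx = 50, cy = 50,
    a = stats::rnorm(20, 14, 1), b = stats::rnorm(20, 7, 0.8),
    theta = stats::rnorm(20, 100, 5)))
  gm <- fit_geometry_model(ann, n_parts = 1L)
  pm <- matrix(0, 90, 80)
  pm[30:40, 55:65] <- 0.95
  class(pm) <- "probability_map"
  cands <- sample_candidates(gm, pm, n = 50L, p_threshold = 0.6, seed = 76L)
  expect_length(cands, 50L)
  for (cd in cands) {
    e <- cd$ellipses
    expect_identical(e$part, "body")
    expect_true(e$cx >= 55 && e$cx <= 65 && e$cy >= 30 && e$cy <= 40)
    expect_gte(e$a, e$b)
  }
  # sampling is deterministic given the seed
  c2 <- sample_candidates(gm, pm, n = 50L, p_threshold = 0.6, seed = 76L)
  expect_identical(lapply(cands, `[[`, "ellipses"), lapply(c2, `[[`, "ellipses"))
  # empty above-threshold set falls back to the map maximum
  pm0 <- matrix(0, 90, 80); pm0[12, 70] <- 0.3; class(pm0) <- "probability_map"
  c3 <- sample_candidates(gm, pm0, n = 4L, p_threshold = 0.6, seed = 77L)
  for (cd in c3) expect_identical(c(cd$ellipses$cy, cd$ellipses$cx), c(12, 70))
})

test_that("two-part candidates place the head at the sampled offset", {
  ann <- rapidscene:::with_seed(78L, do.call(rbind, lapply(1:25, function(id)
    tibble::tibble(
      object_id = id, part = c("head", "body"),
      cx = c(60 + stats::rnorm(1, 15, 1.5), 60),
      cy = c(50 + stats::rnorm(1, -5, 1.5), 50),
      a = c(stats::rnorm(1, 7, 0.4), stats::rnorm(1, 18, 1)),
      b = c(stats::rnorm(1, 5, 0.3), stats::rnorm(1, 9, 0.6)),
      theta = c(stats::rnorm(1, 80, 4), stats::rnorm(1, 10, 4))))))
  gm <- fit_geometry_model(ann, n_parts = 2L)
  # above-threshold region kept interior so head centers never hit the clamp
  pm <- matrix(0, 100, 100); pm[40:60, 30:60] <- 0.7
  class(pm) <- "probability_map"
  cands <- sample_candidates(gm, pm, n = 20L, p_threshold = 0.5, seed = 79L)
  for (cd in cands) {
    e <- cd$ellipses
    expect_setequal(e$part, c("head", "body"))
    hd <- e[e$part == "head", ]; bd <- e[e$part == "body", ]
    expect_equal(hd$cx - bd$cx, unname(cd$shape["dx"]), tolerance = 1e-9)
    expect_equal(hd$cy - bd$cy, unname(cd$shape["dy"]), tolerance = 1e-9)
    expect_true(all(e$a >= e$b))
  }
})

test_that("tidy.geometry_model lists every parameter with its sd", {
  ann <- rapidscene:::with_seed(80L, tibble::tibble(
    object_id = 1:10, part = "whole", cx = 50, cy = 50,
    a = stats::rnorm(10, 15, 1), b = stats::rnorm(10, 8, 1),
    theta = stats::rnorm(10, 60, 5)))
  gm <- fit_geometry_model(ann, n_parts = 1L)
  td <- tidy(gm)
  expect_identical(td$parameter, names(gm$mean))
  expect_equal(td$sd, sqrt(diag(gm$covariance)), ignore_attr = TRUE)
})

test_that("annotations roundtrip through CSV", {
  ann <- tibble::tibble(object_id = c(1L, 1L), part = c("head", "body"),
                        cx = c(70.5, 55), cy = c(40, 48.25),
                        a = c(8, 20), b = c(6, 10), theta = c(75, 12.5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, p)
  back <- read_annotations(p)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  writeLines("object_id,part\n1,head", p)
  expect_error(read_annotations(p), class = "rapidscene_data_error")
})
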