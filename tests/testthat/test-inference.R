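# Probability maps, candidate scoring, scene decisions and manipulations.

test_that("default configuration exposes the standard constants", {
  cfg <- rs_config()
  expect_identical(c(cfg$r_center, cfg$r_surround), c(2, 4))
  expect_identical(rs_config(scene_class = "far_body")$r_center, 1)
  expect_identical(cfg$n_structures, 70L)
  expect_identical(rs_config(n_structures = 134L)$n_structures, 134L)
  expect_identical(cfg$n_context, 200L)
  expect_identical(cfg$n_candidates, 300L)
  expect_identical(cfg$share_threshold, 0.7)
  expect_identical(cfg$min_inside, 0.6)
  expect_identical(cfg$placement_threshold, 0.6)
  expect_identical(cfg$decision_threshold, 0.5)
  expect_identical(cfg$localization_threshold, 0.55)
  expect_identical(cfg$prior_object, 0.5)
  expect_identical(cfg$n_renders, 50L)
  expect_identical(cfg$n_splits, 20L)
  expect_identical(cfg$n_components_coarse, 160L)
  expect_identical(cfg$n_components_fine, 100L)
})

test_that("probability maps are in [0, 1], zero at the borders, deterministic", {
  bundle <- fx_bundle()
  ds <- fx_train_ds()
  pm <- probability_map(ds$scenes[[1L]], bundle)
  expect_s3_class(pm, "probability_map")
  expect_identical(dim(pm), c(128L, 128L))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(pm[1:23, ] == 0) && all(pm[, 1:23] == 0))
  expect_true(all(pm[106:128, ] == 0) && all(pm[, 106:128] == 0))
  pm2 <- probability_map(ds$scenes[[1L]], bundle)
  expect_identical(unclass(pm), unclass(pm2))
  expect_error(probability_map(matrix(100, 40, 40), bundle),
               class = "rapidscene_data_error")
})

test_that("the map is higher on the object than on the background", {
  bundle <- fx_bundle()
  ds <- fx_train_ds()
  # use the largest object so its eroded patch support is nonempty
  areas <- vapply(seq_along(ds$scenes), function(k)
    if (isTRUE(ds$labels[k])) as.numeric(sum(ds$masks[[k]])) else 0, numeric(1))
  i <- which.max(areas)
  pm <- probability_map(ds$scenes[[i]], bundle)
  sup <- rapidscene:::patch_support(ds$masks[[i]], bundle$config$min_inside)
  expect_gt(sum(sup), 0L)
  outside <- !ds$masks[[i]] & unclass(pm) > 0 & !sup
  expect_gt(mean(pm[sup]), mean(pm[outside]))
  j <- which(!ds$labels)[1L]
  pmn <- probability_map(ds$scenes[[j]], bundle)
  expect_lt(mean(pmn[unclass(pmn) > 0]), mean(pm[sup]))
})

test_that("patch_support matches a brute-force eroded-support oracle", {
  mask <- matrix(FALSE, 80, 90)
  mask[20:65, 25:80] <- TRUE
  mask[30:38, 40:48] <- FALSE
  sup <- rapidscene:::patch_support(mask, 0.6)
  oracle <- matrix(FALSE, 80, 90)
  for (y in 24:(80 - 24)) for (x in 24:(90 - 24)) {
    oracle[y, x] <- mean(mask[(y - 23):(y + 24), (x - 23):(x + 24)]) >= 0.6
  }
  expect_identical(sup, oracle)
  # empty and too-small masks give empty support
  expect_false(any(rapidscene:::patch_support(matrix(FALSE, 80, 90), 0.6)))
  expect_false(any(rapidscene:::patch_support(matrix(TRUE, 30, 30), 0.6)))
})

test_that("batched scoring agrees with single-candidate scoring", {
  bundle <- fx_bundle()
  ds <- fx_train_ds()
  i <- which(ds$labels)[2L]
  cm <- michelson_contrast(ds$scenes[[i]], bundle$config$r_center,
                           bundle$config$r_surround)
  pmap <- probability_map(cm, bundle)
  cands <- sample_candidates(bundle$geometry, pmap, n = 8L,
                             p_threshold = bundle$config$placement_threshold,
                             seed = 101L)
  sc <- rapidscene:::score_candidates(cands, cm, bundle, seed = 5L,
                                      prob_map = pmap)
  for (k in seq_along(cands)) {
    expect_equal(sc$posterior[k], score_candidate(cands[[k]], cm, bundle, seed = 5L),
                 tolerance = 1e-9)
  }
  expect_equal(sc$posterior, stats::plogis(sc$log_odds), tolerance = 1e-9)
  # map term equals the clamped Bernoulli log-odds summed over the support
  k <- 1L
  msk <- rasterize_ellipses(cands[[k]]$ellipses, 128L, 128L)
  sup <- rapidscene:::patch_support(msk, bundle$config$min_inside)
  p <- pmin(pmax(unclass(pmap), 1e-3), 1 - 1e-3)
  expect_equal(sc$map_ll[k], sum((log(p) - log1p(-p))[sup]), tolerance = 1e-9)
  expect_identical(sc$support_size[k], sum(sup))
})

test_that("col_maxs equals apply(..., 2, max)", {
  M <- rapidscene:::with_seed(111L, matrix(stats::rnorm(600), 30L, 20L))
  expect_identical(rapidscene:::col_maxs(M), apply(M, 2L, max))
  expect_identical(rapidscene:::col_maxs(M[1L, , drop = FALSE]), M[1L, ])
})

test_that("categorize_scene is seed-deterministic and self-consistent", {
  bundle <- fx_bundle()
  ds <- fx_train_ds()
  i <- which(ds$labels)[1L]
  d1 <- categorize_scene(ds$scenes[[i]], bundle, n_candidates = 40L, seed = 7L,
                         keep_map = TRUE)
  d2 <- categorize_scene(ds$scenes[[i]], bundle, n_candidates = 40L, seed = 7L)
  expect_s3_class(d1, "scene_decision")
  expect_identical(d1$posterior, d2$posterior)
  expect_identical(d1$best_candidate$ellipses, d2$best_candidate$ellipses)
  expect_true(d1$posterior >= 0 && d1$posterior <= 1)
  expect_identical(d1$label,
                   if (d1$posterior > bundle$config$decision_threshold)
                     "positive" else "negative")
  expect_s3_class(d1$prob_map, "probability_map")
  expect_null(d2$prob_map)
  expect_identical(d1$best_candidate$posterior, d1$posterior)
})

test_that("localization fraction is the covered share of object pixels", {
  truth <- rasterize_ellipses(data.frame(cx = 60, cy = 60, a = 20, b = 10,
                                         theta = 0), 120L, 120L)
  dec <- structure(list(best_candidate = structure(list(
    ellipses = data.frame(part = "body", cx = 65, cy = 60, a = 20, b = 10,
                          theta = 0)), class = "object_candidate")),
    class = "scene_decision")
  lc <- localization_correct(dec, truth, threshold = 0.55)
  cand_mask <- rasterize_ellipses(dec$best_candidate$ellipses, 120L, 120L)
  expect_equal(attr(lc, "fraction"), sum(truth & cand_mask) / sum(truth),
               tolerance = 1e-12)
  expect_identical(as.logical(lc), attr(lc, "fraction") > 0.55)
  # exact overlap localizes, a far-away candidate does not
  dec$best_candidate$ellipses$cx <- 60
  expect_true(localization_correct(dec, truth))
  dec$best_candidate$ellipses$cx <- 20; dec$best_candidate$ellipses$cy <- 20
  expect_false(localization_correct(dec, truth))
  expect_error(localization_correct(dec, matrix(FALSE, 5, 5)),
               class = "rapidscene_data_error")
})

test_that("noise replacement only touches pixels inside the mask", {
  ds <- fx_train_ds()
  i <- which(ds$labels)[1L]
  scene <- ds$scenes[[i]]; mask <- ds$masks[[i]]
  out <- replace_object_with_noise(scene, mask, seed = 99L)
  expect_identical(out[!mask], scene[!mask])
  expect_gt(mean(out[mask] != scene[mask]), 0.99)   # bound clipping may tie a few
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, replace_object_with_noise(scene, mask, seed = 99L))
  expect_false(identical(out, replace_object_with_noise(scene, mask, seed = 100L)))
  expect_error(replace_object_with_noise(scene, matrix(FALSE, 128, 128)),
               class = "rapidscene_data_error")
})

test_that("insert_object copies the object and returns its new mask", {
  ds <- fx_train_ds()
  i <- which(ds$labels)[1L]; j <- which(!ds$labels)[1L]
  res <- insert_object(ds$scenes[[j]], ds$scenes[[i]], ds$masks[[i]],
                       seed = 17L)
  expect_identical(sum(res$mask), sum(ds$masks[[i]]))
  expect_identical(sort(res$image[res$mask]),
                   sort(ds$scenes[[i]][ds$masks[[i]]]))
  expect_identical(res$image[!res$mask], ds$scenes[[j]][!res$mask])
  # explicit feasible placement is honored: mask centroid lands near it
  res2 <- insert_object(ds$scenes[[j]], ds$scenes[[i]], ds$masks[[i]],
                        placement = c(64, 64))
  idx <- which(res2$mask, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2]) - 64), 1)
  expect_lt(abs(mean(idx[, 1]) - 64), 1)
  # an object larger than the distractor cannot be placed
  expect_error(insert_object(matrix(0, 40, 40), ds$scenes[[i]], ds$masks[[i]]),
               class = "rapidscene_data_error")
  expect_error(insert_object(ds$scenes[[j]], ds$scenes[[i]],
                             matrix(FALSE, 128, 128)),
               class = "rapidscene_data_error")
})

test_that("evaluate_scenes reports one row per scene with localization", {
  fixd <- fx_acc1()
  ev <- fixd$ev
  te <- fixd$test
  expect_identical(nrow(ev), 100L)
  expect_identical(ev$id, 1:100)
  expect_identical(ev$truth, te$labels)
  expect_true(all(ev$decision %in% c("positive", "negative")))
  expect_true(all(ev$posterior >= 0 & ev$posterior <= 1))
  # localization fields only for positives
  expect_true(all(is.na(ev$localized[!ev$truth])))
  expect_true(all(!is.na(ev$localized[ev$truth])))
  expect_true(all(ev$loc_fraction[ev$truth] >= 0 &
                    ev$loc_fraction[ev$truth] <= 1))
  expect_identical(ev$localized[ev$truth],
                   ev$loc_fraction[ev$truth] > 0.55)
})

test_that("interp_grid reproduces bilinear functions exactly", {
  ys <- c(1, 5, 9, 13); xs <- c(2, 6, 10)
  f <- function(y, x) 2 * y - 3 * x + 0.5
  Z <- outer(ys, xs, f)
  got <- rapidscene:::interp_grid(ys, xs, Z, 1:13, 2:10)
  expect_equal(got, outer(1:13, 2:10, f), tolerance = 1e-12)
})
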