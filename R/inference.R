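# End-to-end localization and categorization: probability maps, candidate
# scoring, scene decisions, manipulations, and the split experiment protocol.

#' Per-pixel posterior probability map of a scene
#'
#' At each evaluation pixel, the posterior that the 48x48 patch centered there
#' belongs to the object class, taken as the maximum of [patch_posterior()]
#' over the selected structures. Evaluated on a `map_stride`-spaced grid and
#' bilinearly upsampled to full resolution; pixels where the full patch does
#' not fit are 0.
#'
#' @param scene a luminance matrix or a `contrast_image` (at least 48x48).
#' @param bundle a trained `model_bundle`.
#' @param stride evaluation stride in pixels (default from the bundle config).
#' @return matrix of class `probability_map`, same extent as the scene, all
#'   values in `[0, 1]`.
#' @export
probability_map <- function(scene, bundle, stride = NULL) {
  cm <- as_contrast(scene, bundle$config)
  map_from_parts(cm, bundle$coarse_basis, bundle$fine_basis,
                 bundle$structures, bundle$context, bundle$config,
                 stride %||% bundle$config$map_stride)
}

# probability_map from its ingredients (used during training, before a full
# bundle exists).
map_from_parts <- function(cm, coarse, fine, structures, context, config,
                           stride) {
  h <- nrow(cm); w <- ncol(cm)
  if (h < PATCH_SIDE || w < PATCH_SIDE)
    abort_data("scene smaller than the 48x48 patch")
  half <- PATCH_SIDE %/% 2L                      # 24
  ys <- unique(c(seq(half, h - half, by = stride), h - half))
  xs <- unique(c(seq(half, w - half, by = stride), w - half))
  tops <- as.matrix(expand.grid(row = ys - (half - 1L), col = xs - (half - 1L)))
  P <- extract_patches(unclass(cm), tops, PATCH_SIDE)
  sigs <- label_patches(P, coarse, fine)$signatures
  pm <- posterior_matrix(sigs, structures, context, config$prior_object)
  vals <- matrix(apply(pm, 1L, max), length(ys), length(xs))
  out <- matrix(0, h, w)
  out[half:(h - half), half:(w - half)] <-
    interp_grid(ys, xs, vals, half:(h - half), half:(w - half))
  structure(pmin(pmax(out, 0), 1), class = c("probability_map", "matrix", "array"))
}

# Pixel centers whose 48x48 patch has at least `min_inside` of its pixels
# inside the mask — the support on which the probability map can be high for
# an object occupying the mask.
patch_support <- function(mask, min_inside = 0.6) {
  h <- nrow(mask); w <- ncol(mask); s <- PATCH_SIDE
  out <- matrix(FALSE, h, w)
  if (h < s || w < s) return(out)
  ii <- apply(apply(matrix(as.numeric(mask), h, w), 2L, cumsum), 1L, cumsum)
  ii <- rbind(0, cbind(0, t(ii)))
  frac <- (ii[(s + 1L):(h + 1L), (s + 1L):(w + 1L)] -
           ii[1:(h - s + 1L), (s + 1L):(w + 1L)] -
           ii[(s + 1L):(h + 1L), 1:(w - s + 1L)] +
           ii[1:(h - s + 1L), 1:(w - s + 1L)]) / (s * s)
  half <- s %/% 2L
  out[half:(h - half), half:(w - half)] <- frac >= min_inside
  out
}

# Bilinear interpolation of values on the grid (ys, xs) to (yout, xout).
interp_grid <- function(ys, xs, Z, yout, xout) {
  tmp <- apply(Z, 2L, function(col)
    stats::approx(ys, col, xout = yout, rule = 2)$y)
  tmp <- matrix(tmp, length(yout), ncol(Z))
  t(apply(tmp, 1L, function(row)
    stats::approx(xs, row, xout = xout, rule = 2)$y))
}

as_contrast <- function(scene, config) {
  if (inherits(scene, "contrast_image")) scene
  else michelson_contrast(scene, config$r_center, config$r_surround)
}

# Patch top-left positions inside a candidate's ellipse union. Patch count
# scales with candidate area (area / patch_area_per_sample, at least
# min_candidate_patches); centers are clamped so the patch fits. NULL if the
# candidate has zero pixel area.
candidate_tops <- function(candidate, h, w, config, seed = NULL,
                           mask = NULL) {
  half <- PATCH_SIDE %/% 2L
  if (is.null(mask)) mask <- rasterize_ellipses(candidate$ellipses, h, w)
  area <- sum(mask)
  inner <- mask[half:(h - half), half:(w - half), drop = FALSE]
  pix <- which(inner)
  if (!length(pix)) {
    # candidate (almost) fully outside the patch-feasible region: clamp center
    cy <- min(max(round(mean(candidate$ellipses$cy)), half), h - half)
    cx <- min(max(round(mean(candidate$ellipses$cx)), half), w - half)
    pix <- (cx - half) * (h - 2L * half + 1L) + (cy - half + 1L)
    if (area == 0) return(NULL)
  }
  n_p <- max(config$min_candidate_patches,
             round(area / config$patch_area_per_sample))
  ih <- nrow(inner)
  picked <- with_seed(seed, {
    if (length(pix) == 1L) rep(pix, n_p)
    else sample(pix, n_p, replace = n_p > length(pix))
  })
  cy <- ((picked - 1L) %% ih) + half
  cx <- ((picked - 1L) %/% ih) + half
  cbind(row = cy - (half - 1L), col = cx - (half - 1L))
}

# Signatures of the patches sampled inside a candidate's ellipse union.
candidate_signatures <- function(candidate, contrast, coarse, fine, config,
                                 seed = NULL) {
  tops <- candidate_tops(candidate, nrow(contrast), ncol(contrast), config, seed)
  if (is.null(tops)) return(NULL)
  P <- extract_patches(unclass(contrast), tops, PATCH_SIDE)
  label_patches(P, coarse, fine)$signatures
}

# Deterministic per-candidate seed derived from its geometry, so identical
# candidates always receive identical patch samples.
candidate_seed <- function(seed, candidate) {
  e <- candidate$ellipses
  s <- sum(abs(c(e$cx, e$cy, e$a, e$b, e$theta)))
  child_seed(seed, floor(s * 97) %% 1000003L)
}

#' Posterior probability of one object candidate
#'
#' Samples patches inside the candidate's ellipse union, builds the evidence
#' vector (scene-level evidence of every selected structure over those
#' patches) and returns [candidate_posterior()] under the object and context
#' joint models. A candidate fully outside the image scores 0.
#'
#' @param candidate an `object_candidate`.
#' @param scene luminance matrix or `contrast_image`.
#' @param bundle a trained `model_bundle`.
#' @param seed integer seed for the patch sampling (deterministic per
#'   candidate geometry).
#' @export
score_candidate <- function(candidate, scene, bundle, seed = 1L) {
  cm <- as_contrast(scene, bundle$config)
  sigs <- candidate_signatures(candidate, cm, bundle$coarse_basis,
                               bundle$fine_basis, bundle$config,
                               seed = candidate_seed(seed, candidate))
  if (is.null(sigs)) return(0)
  pm <- posterior_matrix(sigs, bundle$structures, bundle$context,
                         bundle$config$prior_object)
  v <- apply(pm, 2L, max)
  as.numeric(candidate_posterior(matrix(v, 1L), bundle$joint_obj,
                                 bundle$joint_ctx, bundle$config$prior_object))
}

# Batched candidate scoring: candidates share patch positions heavily, so
# patches are extracted, labelled and scored once per distinct position; each
# candidate's evidence vector is the per-structure maximum over its positions.
# Returns posterior and (unsaturated) log posterior odds per candidate, plus
# (when a probability map is supplied) the pixel-wise Bernoulli log-likelihood
# of the map given the candidate's ellipse union, up to a candidate-free
# constant.
score_candidates <- function(candidates, cm, bundle, seed = 1L,
                             prob_map = NULL) {
  h <- nrow(cm); w <- ncol(cm)
  D <- if (!is.null(prob_map)) {
    p <- pmin(pmax(unclass(prob_map), 1e-3), 1 - 1e-3)
    log(p) - log1p(-p)
  }
  map_ll <- numeric(length(candidates))
  support_size <- integer(length(candidates))
  tops_list <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    mask <- rasterize_ellipses(cand$ellipses, h, w)
    # the map is high where a 48x48 patch is mostly inside the object, so a
    # candidate predicts high map values on its eroded support, not on the
    # whole union
    if (!is.null(D) && any(mask)) {
      # restrict the support computation to the candidate's bounding box
      # (padded by a patch) — outside it the support is empty
      rr <- range(which(rowSums(mask) > 0L)); cc <- range(which(colSums(mask) > 0L))
      r0 <- max(1L, rr[1L] - PATCH_SIDE); r1 <- min(h, rr[2L] + PATCH_SIDE)
      c0 <- max(1L, cc[1L] - PATCH_SIDE); c1 <- min(w, cc[2L] + PATCH_SIDE)
      sup <- patch_support(mask[r0:r1, c0:c1, drop = FALSE],
                           bundle$config$min_inside)
      support_size[i] <<- sum(sup)
      map_ll[i] <<- sum(D[r0:r1, c0:c1][sup])
    }
    candidate_tops(cand, h, w, bundle$config,
                   seed = candidate_seed(seed, cand), mask = mask)
  })
  keep <- !vapply(tops_list, is.null, logical(1))
  posterior <- numeric(length(candidates))
  log_odds <- rep(-Inf, length(candidates))
  if (any(keep)) {
    all_tops <- do.call(rbind, tops_list[keep])
    key <- (all_tops[, 1L] - 1L) * w + all_tops[, 2L]
    ukey <- unique(key)
    uidx <- match(key, ukey)
    utops <- all_tops[match(ukey, key), , drop = FALSE]
    P <- extract_patches(unclass(cm), utops, PATCH_SIDE)
    sigs <- label_patches(P, bundle$coarse_basis, bundle$fine_basis)$signatures
    pm <- posterior_matrix(sigs, bundle$structures, bundle$context,
                           bundle$config$prior_object)
    sizes <- vapply(tops_list[keep], nrow, integer(1))
    grp <- split(uidx, rep(seq_along(sizes), sizes))
    V <- do.call(rbind, lapply(grp, function(rows) {
      rows <- unique(rows)
      if (length(rows) == 1L) pm[rows, ]
      else col_maxs(pm[rows, , drop = FALSE])
    }))
    pr <- bundle$config$prior_object
    la <- log(pr) + joint_log_density(V, bundle$joint_obj)
    lb <- log(1 - pr) + joint_log_density(V, bundle$joint_ctx)
    posterior[keep] <- logistic2(la, lb)
    log_odds[keep] <- la - lb
  }
  list(posterior = posterior, log_odds = log_odds, map_ll = map_ll,
       support_size = support_size)
}

# Column maxima of a matrix without apply() overhead.
col_maxs <- function(M) {
  out <- M[1L, ]
  for (i in seq_len(nrow(M))[-1L]) {
    r <- M[i, ]
    gt <- r > out
    if (any(gt)) out[gt] <- r[gt]
  }
  out
}

#' Localize and categorize one scene
#'
#' Runs the three-step inference: posterior probability map; `n_candidates`
#' ellipse candidates sampled from the geometry model over pixels above the
#' placement threshold; Bayes scoring of every candidate (structure-evidence
#' log-odds + geometry prior + map likelihood on the candidate's support)
#' against the no-object hypothesis. The scene is labelled positive iff the
#' best candidate's posterior strictly exceeds the decision threshold
#' (default 0.5, i.e. a positive Bayes score).
#'
#' @param scene luminance matrix or `contrast_image`.
#' @param bundle a trained `model_bundle`.
#' @param n_candidates number of candidates (default from config, 300).
#' @param seed integer seed; the decision is seed-deterministic.
#' @param keep_map attach the probability map to the decision.
#' @return object of class `scene_decision` with `label` (`"positive"` /
#'   `"negative"`), `posterior` (logistic of the best candidate's Bayes
#'   score), `evidence_posterior` (the structure-evidence-only posterior of
#'   that candidate), `best_candidate`, and optionally `prob_map`.
#' @export
categorize_scene <- function(scene, bundle, n_candidates = NULL, seed = 1L,
                             keep_map = FALSE) {
  cfg <- bundle$config
  n_candidates <- n_candidates %||% cfg$n_candidates
  cm <- as_contrast(scene, cfg)
  pmap <- probability_map(cm, bundle)
  cands <- sample_candidates(bundle$geometry, pmap, n = n_candidates,
                             p_threshold = cfg$placement_threshold,
                             seed = child_seed(seed, 1L))
  sc <- score_candidates(cands, cm, bundle, seed = child_seed(seed, 2L),
                         prob_map = pmap)
  # Per-candidate Bayes score of "object with this shape/position" against
  # "no object": evidence log-odds, plus the geometry prior log-density of the
  # candidate's shape (normalized to 0 at the mode), plus the Bernoulli
  # log-likelihood ratio of the probability map on the candidate's support
  # (under H0 the map is low everywhere). Candidates whose ellipse union
  # cannot contain a single mostly-inside 48x48 patch are outside the model
  # class and infeasible.
  geom_ll <- vapply(cands, function(cn)
    geometry_log_density(bundle$geometry, cn), numeric(1))
  score <- sc$log_odds + geom_ll - bundle$geometry$log_peak + sc$map_ll
  score[sc$support_size == 0L] <- -Inf
  best <- which.max(score)
  posterior <- stats::plogis(score[best])
  cand <- cands[[best]]
  cand$posterior <- posterior
  structure(list(
    label = if (posterior > cfg$decision_threshold) "positive" else "negative",
    posterior = posterior,
    evidence_posterior = sc$posterior[best],
    best_candidate = cand,
    prob_map = if (keep_map) pmap
  ), class = "scene_decision")
}

#' @export
print.scene_decision <- function(x, ...) {
  cat(sprintf("<scene_decision> %s (posterior %.3f)\n", x$label, x$posterior))
  invisible(x)
}

#' Was the object localized correctly?
#'
#' The localization fraction is the share of ground-truth object pixels
#' covered by the selected candidate's ellipse union; localization is correct
#' iff the fraction strictly exceeds the threshold (default 0.55).
#'
#' @param decision a `scene_decision`.
#' @param truth_mask logical matrix of ground-truth object pixels (nonempty).
#' @param threshold coverage threshold.
#' @return logical, with attribute `fraction`.
#' @export
localization_correct <- function(decision, truth_mask, threshold = 0.55) {
  if (is.null(truth_mask) || !any(truth_mask)) abort_data("empty truth mask")
  union <- rasterize_ellipses(decision$best_candidate$ellipses,
                              nrow(truth_mask), ncol(truth_mask))
  fraction <- sum(truth_mask & union) / sum(truth_mask)
  structure(fraction > threshold, fraction = fraction)
}

#' Replace the object region with luminance-matched white noise
#'
#' Pixels inside the mask are replaced by Gaussian white noise with the
#' scene's mean and standard deviation (clipped to `[0, 255]`); pixels
#' outside the mask are bit-identical to the input. Seed-deterministic.
#'
#' @param scene luminance matrix.
#' @param mask logical matrix (nonempty).
#' @param seed integer seed.
#' @export
replace_object_with_noise <- function(scene, mask, seed = 1L) {
  if (is.null(mask) || !any(mask)) abort_data("empty mask")
  out <- scene
  n <- sum(mask)
  out[mask] <- with_seed(seed, pmin(pmax(
    stats::rnorm(n, mean(scene), stats::sd(scene)), 0), 255))
  out
}

#' Insert an object into a distractor scene
#'
#' Copies the masked object pixels into the distractor at a placement (target
#' center for the mask centroid). Where no placement is given (or the given
#' one is out of bounds), a random placement is drawn uniformly from the
#' feasible center range; an error is raised only when the object cannot fit
#' at all.
#'
#' @param distractor luminance matrix without an object.
#' @param object_pixels luminance matrix the object is copied from.
#' @param object_mask logical matrix marking the object in `object_pixels`.
#' @param placement optional `c(cx, cy)` target center.
#' @param seed integer seed.
#' @return list with `image` (altered scene) and `mask` (new ground truth).
#' @export
insert_object <- function(distractor, object_pixels, object_mask,
                          placement = NULL, seed = 1L) {
  if (is.null(object_mask) || !any(object_mask)) abort_data("empty object mask")
  idx <- which(object_mask, arr.ind = TRUE)
  cy0 <- mean(idx[, 1L]); cx0 <- mean(idx[, 2L])
  hh <- nrow(distractor); ww <- ncol(distractor)
  try_place <- function(cx, cy) {
    dy <- round(cy - cy0); dx <- round(cx - cx0)
    r2 <- idx[, 1L] + dy; c2 <- idx[, 2L] + dx
    if (min(r2) < 1L || max(r2) > hh || min(c2) < 1L || max(c2) > ww) return(NULL)
    img <- distractor
    img[cbind(r2, c2)] <- object_pixels[idx]
    msk <- matrix(FALSE, hh, ww)
    msk[cbind(r2, c2)] <- TRUE
    list(image = img, mask = msk)
  }
  if (!is.null(placement)) {
    res <- try_place(placement[1L], placement[2L])
    if (!is.null(res)) return(res)
  }
  # feasible center range from the mask extents
  cx_lo <- cx0 - (min(idx[, 2L]) - 1L); cx_hi <- cx0 + (ww - max(idx[, 2L]))
  cy_lo <- cy0 - (min(idx[, 1L]) - 1L); cy_hi <- cy0 + (hh - max(idx[, 1L]))
  if (cx_hi < cx_lo || cy_hi < cy_lo)
    abort_data("object could not be placed inside the distractor")
  res <- with_seed(seed, try_place(stats::runif(1, cx_lo, cx_hi),
                                   stats::runif(1, cy_lo, cy_hi)))
  if (is.null(res)) abort_data("object could not be placed inside the distractor")
  res
}

#' Evaluate a trained bundle on labelled scenes
#'
#' @param bundle a `model_bundle`.
#' @param dataset an `rs_dataset` (or compatible list).
#' @param idx indices of the scenes to evaluate (default all).
#' @param seed integer seed.
#' @return tibble with one row per scene: `id`, `truth`, `decision`,
#'   `posterior`, `localized`, `loc_fraction`.
#' @export
evaluate_scenes <- function(bundle, dataset, idx = NULL, seed = 1L) {
  idx <- idx %||% seq_along(dataset$scenes)
  rows <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    dec <- categorize_scene(dataset$scenes[[i]], bundle,
                            seed = child_seed(seed, i))
    loc <- NA; frac <- NA_real_
    if (isTRUE(dataset$labels[i]) && !is.null(dataset$masks[[i]])) {
      lc <- localization_correct(dec, dataset$masks[[i]],
                                 bundle$config$localization_threshold)
      loc <- as.logical(lc); frac <- attr(lc, "fraction")
    }
    tibble::tibble(id = i, truth = dataset$labels[i], decision = dec$label,
                   posterior = dec$posterior, localized = loc,
                   loc_fraction = frac)
  })
  dplyr::bind_rows(rows)
}

#' Run the repeated train/test split experiment
#'
#' For each split: a stratified 50/50 train/test partition, full bundle
#' training on the training half (with the configured number of augmentation
#' renders per scene), and evaluation on the test half. Reports per-split and
#' mean categorization rates on positives and negatives, balanced accuracy,
#' and the localization rate among true positives.
#'
#' @param dataset an `rs_dataset` with positives (masks + annotations) and
#'   negatives.
#' @param config an [rs_config()]; `config$n_splits` splits are run.
#' @param seed master seed; the whole report is seed-deterministic.
#' @return list of class `experiment_report` with `per_split` (tibble) and
#'   `mean` (named list of mean rates).
#' @export
run_experiment <- function(dataset, config = rs_config(), seed = 1L) {
  pos <- which(dataset$labels); neg <- which(!dataset$labels)
  if (!length(pos) || !length(neg))
    abort_data("dataset needs both positive and negative scenes")
  splits <- lapply(seq_len(config$n_splits), function(s) {
    with_seed(child_seed(seed, 100L + s), list(
      train = c(sample(pos, ceiling(length(pos) / 2)),
                sample(neg, ceiling(length(neg) / 2)))))
  })
  rows <- lapply(seq_len(config$n_splits), function(s) {
    tr <- splits[[s]]$train
    te <- setdiff(seq_along(dataset$scenes), tr)
    sub <- function(ix) list(
      scenes = dataset$scenes[ix], masks = dataset$masks[ix],
      labels = dataset$labels[ix],
      annotations = {
        a <- dataset$annotations[dataset$annotations$object_id %in% ix, , drop = FALSE]
        a$object_id <- match(a$object_id, ix); a
      })
    bundle <- train_bundle(sub(tr), config, seed = child_seed(seed, 200L + s))
    ev <- evaluate_scenes(bundle, dataset, idx = te,
                          seed = child_seed(seed, 300L + s))
    pos_rate <- mean(ev$decision[ev$truth] == "positive")
    neg_rate <- mean(ev$decision[!ev$truth] == "negative")
    tp <- ev$truth & ev$decision == "positive"
    tibble::tibble(
      split = s, n_train = length(tr), n_test = length(te),
      pos_rate = pos_rate, neg_rate = neg_rate,
      balanced_accuracy = (pos_rate + neg_rate) / 2,
      localization_rate = if (any(tp)) mean(ev$localized[tp]) else NA_real_)
  })
  per_split <- dplyr::bind_rows(rows)
  structure(list(
    per_split = per_split,
    mean = as.list(colMeans(per_split[, c("pos_rate", "neg_rate",
                                          "balanced_accuracy",
                                          "localization_rate")],
                            na.rm = TRUE)),
    seed = as.integer(seed)
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d splits; mean balanced accuracy %.3f, localization %.3f\n",
              nrow(x$per_split), x$mean$balanced_accuracy,
              x$mean$localization_rate))
  invisible(x)
}

#' Per-split rates of an experiment report
#' @param x an `experiment_report`.
#' @param ... unused.
#' @export
tidy.experiment_report <- function(x, ...) x$per_split

#' Mean rates of an experiment report
#' @param x an `experiment_report`.
#' @param ... unused.
#' @export
glance.experiment_report <- function(x, ...) tibble::as_tibble(x$mean)
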