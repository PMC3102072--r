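# Pipeline configuration and end-to-end training of a model bundle.

#' Pipeline configuration
#'
#' All tunable constants of the pipeline in one flat list. Defaults follow the
#' method's standard settings: contrast radii (2, 4) for standard scenes,
#' 48x48 patches with 3x3 16x16 blocks, 4 orientation clusters, sharing
#' threshold 0.7, 70 selected structures, 300 object candidates placed where
#' the posterior map exceeds 0.6, decision threshold 0.5, 50 augmentation
#' renders per training scene and 20 train/test splits. Desk-scale runs
#' typically reduce `n_renders`, `n_basis_patches` and the component counts.
#'
#' @param scene_class `"standard"` (radii 2, 4) or `"far_body"` (radii 1, 2).
#' @param map_stride stride (px) of the posterior probability map evaluation;
#'   the map is bilinearly upsampled to full resolution.
#' @param sample_stride stride (px) of patch sampling inside masks.
#' @param min_inside minimum fraction of patch pixels inside the mask.
#' @param share_threshold sharing threshold for candidate structures.
#' @param n_structures number of selected structures (70 animal / 134 car).
#' @param n_context number of context structures modelled.
#' @param n_candidates object candidates per scene.
#' @param placement_threshold probability-map threshold for candidate centers.
#' @param decision_threshold posterior threshold for a positive decision
#'   (strict inequality).
#' @param localization_threshold fraction of object pixels that must be
#'   covered for a correct localization (strict inequality).
#' @param prior_object class prior used in all Bayes posteriors.
#' @param n_renders augmentation renders per training scene.
#' @param n_basis_patches patches per scale for ICA basis learning.
#' @param n_components_coarse,n_components_fine retained ICs per scale.
#' @param n_splits train/test splits in [run_experiment()].
#' @param min_candidate_patches,patch_area_per_sample patch budget inside a
#'   candidate: `max(min, area / per_sample)` patches.
#' @param context_stride stride for context patch sampling.
#' @param max_unit_patches cap on patches per evaluation unit.
#' @param n_context_candidates map-guided candidates per negative render used
#'   to build the context evidence vectors.
#' @export
rs_config <- function(scene_class = "standard", map_stride = 4L,
                      sample_stride = 8L, min_inside = 0.6,
                      share_threshold = 0.7, n_structures = 70L,
                      n_context = 200L, n_candidates = 300L,
                      placement_threshold = 0.6, decision_threshold = 0.5,
                      localization_threshold = 0.55, prior_object = 0.5,
                      n_renders = 50L, n_basis_patches = 20000L,
                      n_components_coarse = 160L, n_components_fine = 100L,
                      n_splits = 20L, min_candidate_patches = 20L,
                      patch_area_per_sample = 256, context_stride = 16L,
                      max_unit_patches = 60L, n_context_candidates = 5L) {
  radii <- select_contrast_params(scene_class)
  structure(list(
    scene_class = scene_class,
    r_center = unname(radii[1L]), r_surround = unname(radii[2L]),
    map_stride = as.integer(map_stride),
    sample_stride = as.integer(sample_stride), min_inside = min_inside,
    share_threshold = share_threshold, n_structures = as.integer(n_structures),
    n_context = as.integer(n_context), n_candidates = as.integer(n_candidates),
    placement_threshold = placement_threshold,
    decision_threshold = decision_threshold,
    localization_threshold = localization_threshold,
    prior_object = prior_object, n_renders = as.integer(n_renders),
    n_basis_patches = as.integer(n_basis_patches),
    n_components_coarse = as.integer(n_components_coarse),
    n_components_fine = as.integer(n_components_fine),
    n_splits = as.integer(n_splits),
    min_candidate_patches = as.integer(min_candidate_patches),
    patch_area_per_sample = patch_area_per_sample,
    context_stride = as.integer(context_stride),
    max_unit_patches = as.integer(max_unit_patches),
    n_context_candidates = as.integer(n_context_candidates)
  ), class = "rs_config")
}

# Affine render of a scene (and its mask) about the image center: uniform
# random scale, rotation and translation, plus additive white Gaussian noise.
# Inverse-mapped bilinear interpolation for the image, nearest for the mask.
render_scene <- function(image, mask = NULL, seed = NULL,
                         scale_range = c(0.9, 1.1), rot_range = c(-10, 10),
                         trans_range = c(-8, 8), noise_sd = 0.05 * 255) {
  with_seed(seed, {
    sc <- stats::runif(1, scale_range[1L], scale_range[2L])
    rot <- stats::runif(1, rot_range[1L], rot_range[2L]) * pi / 180
    tx <- stats::runif(1, trans_range[1L], trans_range[2L])
    ty <- stats::runif(1, trans_range[1L], trans_range[2L])
    img <- warp_affine(image, sc, rot, tx, ty, fill = mean(image))
    img <- pmin(pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                  nrow(img)), 0), 255)
    msk <- if (!is.null(mask))
      warp_affine(mask * 1, sc, rot, tx, ty, nearest = TRUE, fill = 0) > 0.5
    list(image = img, mask = msk)
  })
}

# Inverse-mapped affine warp about the image center.
warp_affine <- function(img, sc, rot, tx, ty, nearest = FALSE, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - tx
  Y <- matrix(seq_len(h), h, w) - cy - ty
  # inverse of scale+rotation
  cr <- cos(-rot) / sc; sr <- sin(-rot) / sc
  Xs <- cr * X - sr * Y + cx
  Ys <- sr * X + cr * Y + cy
  if (nearest) {
    xi <- round(Xs); yi <- round(Ys)
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    out <- matrix(fill, h, w)
    out[ok] <- img[cbind(as.vector(yi)[ok], as.vector(xi)[ok])]
    out
  } else {
    x0 <- floor(Xs); y0 <- floor(Ys)
    fx <- Xs - x0; fy <- Ys - y0
    cl <- function(v, n) pmin(pmax(v, 1), n)
    g <- function(yy, xx)
      matrix(img[cbind(as.vector(cl(yy, h)), as.vector(cl(xx, w)))], h, w)
    vals <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x0 + 1) +
      (1 - fx) * fy * g(y0 + 1, x0) + fx * fy * g(y0 + 1, x0 + 1)
    ok <- Xs >= 1 & Xs <= w & Ys >= 1 & Ys <= h
    out <- matrix(fill, h, w)
    out[ok] <- vals[ok]
    out
  }
}

# Signatures of the grid patches of one render (inside or outside its mask).
render_signatures <- function(contrast, mask, coarse, fine, stride, min_inside,
                              invert = FALSE, max_patches = Inf, seed = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(contrast), ncol(contrast))
  tops <- mask_patch_tops(mask, stride, min_inside, invert = invert)
  if (!nrow(tops)) return(NULL)
  if (nrow(tops) > max_patches)
    tops <- with_seed(seed, tops[sample.int(nrow(tops), max_patches), , drop = FALSE])
  P <- extract_patches(unclass(contrast), tops, PATCH_SIDE)
  label_patches(P, coarse, fine)$signatures
}

#' Train a full model bundle on a dataset
#'
#' Runs the complete training pipeline: augmentation renders of every training
#' scene (affine transform + white noise), contrast preprocessing, two-scale
#' ICA basis learning from object patches, structure compilation and sharing
#' filtering, 10-D Gaussian structure distributions, the context model,
#' separation-based structure selection, the geometry Gaussian from the part
#' annotations, and the object and context joint models of evidence vectors.
#'
#' @param dataset an `rs_dataset` (or any list with `scenes`, `masks`,
#'   `annotations`, `labels`).
#' @param config an [rs_config()].
#' @param seed master seed; the bundle is a deterministic function of dataset,
#'   config and seed.
#' @return object of class `model_bundle`.
#' @export
train_bundle <- function(dataset, config = rs_config(), seed = 1L) {
  pos_idx <- which(dataset$labels)
  neg_idx <- which(!dataset$labels)
  if (!length(pos_idx) || !length(neg_idx))
    abort_data("training data needs both positive and negative scenes")

  # --- augmentation renders + contrast maps ------------------------------
  mk_renders <- function(idx, stream) {
    out <- list()
    for (i in seq_along(idx)) {
      sc <- dataset$scenes[[idx[i]]]
      mk <- dataset$masks[[idx[i]]]
      for (r in seq_len(config$n_renders)) {
        rn <- render_scene(sc, mk, seed = child_seed(seed, stream + i * 1000L + r))
        out[[length(out) + 1L]] <- list(
          contrast = michelson_contrast(rn$image, config$r_center,
                                        config$r_surround),
          mask = rn$mask)
      }
    }
    out
  }
  renders_pos <- mk_renders(pos_idx, 1L)
  renders_neg <- mk_renders(neg_idx, 2L)

  # --- IC bases from object patches --------------------------------------
  pool <- list()
  for (rn in renders_pos) {
    tops <- mask_patch_tops(rn$mask, config$sample_stride, config$min_inside)
    if (nrow(tops))
      pool[[length(pool) + 1L]] <- extract_patches(unclass(rn$contrast), tops,
                                                   PATCH_SIDE)
  }
  Pc <- do.call(rbind, pool)
  if (is.null(Pc) || nrow(Pc) < 10L) abort_data("too few object patches for basis learning")
  if (nrow(Pc) > config$n_basis_patches)
    Pc <- with_seed(child_seed(seed, 11L),
                    Pc[sample.int(nrow(Pc), config$n_basis_patches), , drop = FALSE])
  nc <- min(config$n_components_coarse, nrow(Pc) - 1L)
  coarse <- learn_ic_basis(Pc, n_components = nc, seed = child_seed(seed, 12L))

  Pf <- do.call(rbind, lapply(.block_idx, function(ix) Pc[, ix, drop = FALSE]))
  if (nrow(Pf) > config$n_basis_patches)
    Pf <- with_seed(child_seed(seed, 13L),
                    Pf[sample.int(nrow(Pf), config$n_basis_patches), , drop = FALSE])
  nf <- min(config$n_components_fine, nrow(Pf) - 1L)
  fine <- learn_ic_basis(Pf, n_components = nf, seed = child_seed(seed, 14L))

  # --- structure inventory + distributions -------------------------------
  # Renders of one training object are pooled so sharing counts objects.
  grp <- rep(seq_along(pos_idx), each = config$n_renders)
  objects_pos <- lapply(seq_along(pos_idx), function(i)
    list(renders = renders_pos[grp == i]))
  records <- compile_structures(objects_pos, coarse, fine,
                                stride = config$sample_stride,
                                min_inside = config$min_inside,
                                keep_patches = FALSE)
  shared <- filter_shared(records, config$share_threshold)
  if (!nrow(shared))
    abort_data("no structure is shared above the sharing threshold")
  shared_pds <- lapply(seq_len(nrow(shared)),
                       function(i) fit_structure_pd(shared[i, ]))

  ctx_records <- compile_structures(c(renders_pos, renders_neg), coarse, fine,
                                    stride = config$context_stride,
                                    min_inside = config$min_inside,
                                    invert = TRUE, keep_patches = FALSE)
  context <- build_context_model(ctx_records, keep = config$n_context)

  # --- structure selection ------------------------------------------------
  sig_pos <- lapply(seq_along(renders_pos), function(i)
    render_signatures(renders_pos[[i]]$contrast, renders_pos[[i]]$mask,
                      coarse, fine, config$sample_stride, config$min_inside))
  sig_neg <- lapply(seq_along(renders_neg), function(i)
    render_signatures(renders_neg[[i]]$contrast, NULL, coarse, fine,
                      config$context_stride, config$min_inside, invert = TRUE,
                      max_patches = config$max_unit_patches,
                      seed = child_seed(seed, 20L + i)))
  units <- c(
    lapply(sig_pos[!vapply(sig_pos, is.null, logical(1))],
           function(s) list(signatures = s, positive = TRUE)),
    lapply(sig_neg[!vapply(sig_neg, is.null, logical(1))],
           function(s) list(signatures = s, positive = FALSE)))
  sel <- select_structures(shared_pds, units, context,
                           m = config$n_structures,
                           prior_object = config$prior_object)

  # --- geometry model -----------------------------------------------------
  ann <- dataset$annotations
  ann_train <- ann[ann$object_id %in% pos_idx, , drop = FALSE]
  n_parts <- if (any(ann_train$part == "head")) 2L else 1L
  geometry <- fit_geometry_model(ann_train, n_parts)

  # --- evidence vectors + joint models ------------------------------------
  evidence_of <- function(sigs) {
    pm <- posterior_matrix(sigs, sel$pds, context, config$prior_object)
    apply(pm, 2L, max)
  }
  obj_vectors <- do.call(rbind, lapply(sig_pos[!vapply(sig_pos, is.null, logical(1))],
                                       evidence_of))
  # Context evidence must come from the same candidate process used at test
  # time (map-guided placement), otherwise the context model never sees the
  # moderately object-like evidence that the best context candidates produce.
  ctx_vectors <- do.call(rbind, lapply(seq_along(renders_neg), function(i) {
    rn <- renders_neg[[i]]
    s_i <- child_seed(seed, 40L + i)
    pmap <- map_from_parts(rn$contrast, coarse, fine, sel$pds, context,
                           config, config$map_stride)
    cands <- sample_candidates(geometry, pmap,
                               n = config$n_context_candidates,
                               p_threshold = config$placement_threshold,
                               seed = child_seed(s_i, 1L))
    vs <- lapply(seq_along(cands), function(k) {
      sigs <- candidate_signatures(cands[[k]], rn$contrast, coarse, fine,
                                   config, seed = child_seed(s_i, 1L + k))
      if (is.null(sigs)) NULL else evidence_of(sigs)
    })
    do.call(rbind, vs)
  }))
  joint_obj <- suppressWarnings(
    fit_joint_model(obj_vectors, "object", seed = child_seed(seed, 50L)))
  joint_ctx <- suppressWarnings(
    fit_joint_model(ctx_vectors, "context", seed = child_seed(seed, 51L)))

  structure(list(
    coarse_basis = coarse, fine_basis = fine,
    structures = sel$pds, selection_report = sel$report,
    context = context, geometry = geometry,
    joint_obj = joint_obj, joint_ctx = joint_ctx,
    sharing = sharing_histogram(records),
    config = config, seed = as.integer(seed)
  ), class = "model_bundle")
}

# Build an object_candidate from a sampled shape row at a given body center.
shapes_to_candidate <- function(sh, n_parts, cx, cy, h, w) {
  if (n_parts == 2L) {
    body <- shape_row_to_ellipse(sh["a_body"], sh["b_body"],
                                 sh["c2_body"], sh["s2_body"], cx, cy)
    head_ <- shape_row_to_ellipse(sh["a_head"], sh["b_head"],
                                  sh["c2_head"], sh["s2_head"],
                                  min(max(cx + sh["dx"], 1), w),
                                  min(max(cy + sh["dy"], 1), h))
    ell <- data.frame(part = c("head", "body"),
                      cx = c(head_["cx"], body["cx"]),
                      cy = c(head_["cy"], body["cy"]),
                      a = c(head_["a"], body["a"]),
                      b = c(head_["b"], body["b"]),
                      theta = c(head_["theta"], body["theta"]),
                      row.names = NULL)
  } else {
    e <- shape_row_to_ellipse(sh["a"], sh["b"], sh["c2"], sh["s2"], cx, cy)
    ell <- data.frame(part = "body", cx = e[["cx"]], cy = e[["cy"]],
                      a = e[["a"]], b = e[["b"]], theta = e[["theta"]],
                      row.names = NULL)
  }
  structure(list(ellipses = ell, shape = sh, posterior = NA_real_),
            class = "object_candidate")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(paste0("<model_bundle> %d selected structures, %d context structures, ",
                     "%d-part geometry, bases %d/%d ICs (seed %d)\n"),
              length(x$structures), length(x$context$pds),
              x$geometry$n_parts, x$coarse_basis$n_retained,
              x$fine_basis$n_retained, x$seed))
  invisible(x)
}
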