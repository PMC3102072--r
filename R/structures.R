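# Two-scale structural labels of 48x48 contrast patches and the structure
# inventory compiled from training objects.

PATCH_SIDE <- 48L
BLOCK_SIDE <- 16L

# Column-major indices of the nine 16x16 blocks of a flattened 48x48 patch,
# in row-major block order (slot 2 = top-left block, slot 3 = top-middle, ...).
block_indices <- function() {
  lapply(seq_len(9L), function(k) {
    bi <- (k - 1L) %/% 3L   # block row 0..2
    bj <- (k - 1L) %% 3L    # block col 0..2
    rows <- bi * BLOCK_SIDE + seq_len(BLOCK_SIDE)
    cols <- bj * BLOCK_SIDE + seq_len(BLOCK_SIDE)
    as.vector(outer(rows, (cols - 1L) * PATCH_SIDE, "+"))
  })
}
.block_idx <- block_indices()

# Extract flattened (column-major) side x side patches at the given top-left
# (row, col) positions of an image matrix. Returns an n x side^2 matrix.
extract_patches <- function(image, tops, side) {
  if (!nrow(tops)) return(matrix(numeric(0), 0L, side * side))
  h <- nrow(image)
  base <- (tops[, 2L] - 1L) * h + tops[, 1L]
  offs <- as.vector(outer(0:(side - 1L), (0:(side - 1L)) * h, "+"))
  matrix(image[outer(base, offs, "+")], nrow(tops), side * side)
}

#' Two-scale structural label of a 48x48 contrast patch
#'
#' Slot 1 is the dominant orientation cluster (the one with the greatest
#' root-total-square amplitude) of the whole 48x48 patch under the coarse
#' basis; slots 2-10 are the dominant clusters of the nine 16x16 blocks
#' (row-major order) under the fine basis. Exact amplitude ties break to the
#' lowest angle. Because amplitudes are linear in patch contrast, the label is
#' invariant to rescaling the patch by any k > 0.
#'
#' @param patch a 48x48 matrix or length-2304 vector of contrast values.
#' @param coarse_basis an `ic_basis` at scale 48.
#' @param fine_basis an `ic_basis` at scale 16.
#' @return integer vector of 10 orientation bins, each in `{0, 45, 90, 135}`.
#' @export
structural_label <- function(patch, coarse_basis, fine_basis) {
  x <- as.numeric(patch)
  if (length(x) != PATCH_SIDE^2) abort_data("patch must be 48x48")
  drop(label_patches(matrix(x, 1L), coarse_basis, fine_basis)$labels)
}

# Batched labeling: patches as rows (n x 2304). Returns labels (n x 10 bins)
# and signatures (n x 10 dominant amplitudes) in the slot order of the label.
label_patches <- function(patches, coarse_basis, fine_basis) {
  if (coarse_basis$scale != PATCH_SIDE || fine_basis$scale != BLOCK_SIDE)
    abort_data("bases must be at scales 48 and 16")
  n <- nrow(patches)
  bins <- c(0L, 45L, 90L, 135L)

  amp_c <- amplitude_matrix(patches, coarse_basis)          # n x 4
  labels <- matrix(0L, n, 10L)
  sigs <- matrix(0, n, 10L)
  labels[, 1L] <- bins[max.col(amp_c, ties.method = "first")]
  sigs[, 1L] <- amp_c[cbind(seq_len(n), max.col(amp_c, ties.method = "first"))]

  # stack the 9 blocks of all patches (block-major) and run the fine basis once
  blocks <- do.call(rbind, lapply(.block_idx, function(ix)
    patches[, ix, drop = FALSE]))
  amp_f <- amplitude_matrix(blocks, fine_basis)             # 9n x 4
  which_f <- max.col(amp_f, ties.method = "first")
  lab_f <- bins[which_f]
  sig_f <- amp_f[cbind(seq_len(n * 9L), which_f)]
  for (k in seq_len(9L)) {
    rows <- ((k - 1L) * n + 1L):(k * n)
    labels[, k + 1L] <- lab_f[rows]
    sigs[, k + 1L] <- sig_f[rows]
  }
  list(labels = labels, signatures = sigs)
}

label_key <- function(labels) apply(labels, 1L, paste, collapse = "-")

# Grid of admissible patch top-lefts inside a mask: stride-spaced positions in
# the mask bounding box whose 48x48 patch lies in the image and has at least
# `min_inside` of its pixels inside the mask.
mask_patch_tops <- function(mask, stride = 8L, min_inside = 0.6,
                            invert = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < PATCH_SIDE || w < PATCH_SIDE) return(matrix(integer(0), 0L, 2L))
  if (invert) {
    rs <- seq(1L, h - PATCH_SIDE + 1L, by = stride)
    cs <- seq(1L, w - PATCH_SIDE + 1L, by = stride)
  } else {
    idx <- which(mask, arr.ind = TRUE)
    if (!nrow(idx)) return(matrix(integer(0), 0L, 2L))
    r0 <- max(1L, min(idx[, 1L]) - PATCH_SIDE %/% 2L)
    r1 <- min(h - PATCH_SIDE + 1L, max(idx[, 1L]) - PATCH_SIDE %/% 2L)
    c0 <- max(1L, min(idx[, 2L]) - PATCH_SIDE %/% 2L)
    c1 <- min(w - PATCH_SIDE + 1L, max(idx[, 2L]) - PATCH_SIDE %/% 2L)
    if (r1 < r0 || c1 < c0) return(matrix(integer(0), 0L, 2L))
    rs <- seq(r0, r1, by = stride)
    cs <- seq(c0, c1, by = stride)
  }
  tops <- as.matrix(expand.grid(row = rs, col = cs))
  # cumulative-sum integral image for fast in-mask fractions
  ii <- apply(apply(matrix(as.numeric(mask), h, w), 2L, cumsum), 1L, cumsum)
  ii <- rbind(0, cbind(0, t(ii)))  # (h+1) x (w+1), ii[r+1, c+1] = sum mask[1:r, 1:c]
  s <- PATCH_SIDE
  frac <- (ii[cbind(tops[, 1L] + s, tops[, 2L] + s)] -
           ii[cbind(tops[, 1L], tops[, 2L] + s)] -
           ii[cbind(tops[, 1L] + s, tops[, 2L])] +
           ii[cbind(tops[, 1L], tops[, 2L])]) / (s * s)
  keep <- if (invert) frac <= 1 - min_inside else frac >= min_inside
  tops[keep, , drop = FALSE]
}

#' Compile the structure inventory from training objects
#'
#' Samples 48x48 patches on a stride grid inside each object's mask (keeping
#' patches with at least `min_inside` of their pixels inside the mask), labels
#' each patch with [structural_label()], and aggregates patches by label into
#' structure records with occurrence counts, sharing fractions and the
#' amplitude signatures used later for distribution fitting.
#'
#' @param objects list of objects, each a list with elements `contrast` (a
#'   contrast matrix) and `mask` (logical matrix of the same size; for context
#'   compilation pass `invert = TRUE` to sample outside the mask, or a
#'   full-`TRUE` mask for whole-scene sampling). An object may instead carry a
#'   `renders` element (a list of such contrast/mask pairs, e.g. augmentation
#'   renders of one training object); its patches are pooled, so sharing is
#'   counted per object, not per render.
#' @param coarse_basis,fine_basis bases at scales 48 and 16.
#' @param stride grid stride in pixels for patch sampling (default 8).
#' @param min_inside minimum fraction of patch pixels inside the mask.
#' @param invert sample outside rather than inside the masks.
#' @param keep_patches store the raw patches' mean per record (`mean_patch`,
#'   display only); disable to save memory on large compilations.
#' @return a tibble with one row per distinct label: `key`, `label`
#'   (list-column of 10 bins), `count`, `n_objects`, `sharing`, `samples`
#'   (list-column, one signature per row), `mean_patch` (list-column, for
#'   display only), sorted by descending `count`.
#' @export
compile_structures <- function(objects, coarse_basis, fine_basis,
                               stride = 8L, min_inside = 0.6, invert = FALSE,
                               keep_patches = TRUE) {
  if (!length(objects)) abort_data("no objects to compile from")
  all_keys <- character(0)
  per_obj <- vector("list", length(objects))
  for (i in seq_along(objects)) {
    ob <- objects[[i]]
    views <- if (!is.null(ob$renders)) ob$renders else list(ob)
    Ps <- list()
    for (vw in views) {
      mask <- vw$mask
      if (!invert && (is.null(mask) || !any(mask))) next
      if (is.null(mask)) mask <- matrix(FALSE, nrow(vw$contrast), ncol(vw$contrast))
      tops <- mask_patch_tops(mask, stride, min_inside, invert = invert)
      if (!nrow(tops)) next
      Ps[[length(Ps) + 1L]] <- extract_patches(unclass(vw$contrast), tops,
                                               PATCH_SIDE)
    }
    if (!length(Ps)) {
      if (!invert) warning(sprintf("object %d yielded no patches; skipped", i))
      next
    }
    P <- do.call(rbind, Ps)
    ls <- label_patches(P, coarse_basis, fine_basis)
    per_obj[[i]] <- list(keys = label_key(ls$labels), labels = ls$labels,
                         sigs = ls$signatures,
                         patches = if (keep_patches) P else NULL)
  }
  per_obj <- per_obj[!vapply(per_obj, is.null, logical(1))]
  if (!length(per_obj)) abort_data("no patches could be sampled")
  n_obj <- length(per_obj)

  keys <- unlist(lapply(per_obj, `[[`, "keys"))
  sigs <- do.call(rbind, lapply(per_obj, `[[`, "sigs"))
  pats <- if (keep_patches) do.call(rbind, lapply(per_obj, `[[`, "patches"))
  labs <- do.call(rbind, lapply(per_obj, `[[`, "labels"))
  obj_of <- rep(seq_len(n_obj), vapply(per_obj, function(o) length(o$keys), integer(1)))

  uk <- unique(keys)
  rows <- lapply(uk, function(k) {
    sel <- which(keys == k)
    tibble::tibble(
      key = k,
      label = list(labs[sel[1L], ]),
      count = length(sel),
      n_objects = length(unique(obj_of[sel])),
      sharing = length(unique(obj_of[sel])) / n_obj,
      samples = list(sigs[sel, , drop = FALSE]),
      mean_patch = list(if (keep_patches) colMeans(pats[sel, , drop = FALSE]))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$count), , drop = FALSE]
  class(out) <- c("structure_records", class(out))
  out
}

#' Keep structures shared by more than a threshold fraction of objects
#'
#' @param records a tibble from [compile_structures()].
#' @param threshold sharing fraction in `[0, 1]`; records with
#'   `sharing > threshold` (strict) are kept, ordered by descending count.
#'   The default mirrors the selection of structures shared by more than 70%
#'   of training objects.
#' @export
filter_shared <- function(records, threshold = 0.7) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    abort_param("`threshold` must be in [0, 1]")
  kept <- records[records$sharing > threshold, , drop = FALSE]
  kept[order(-kept$count), , drop = FALSE]
}

#' Cumulative histogram of structure sharing
#'
#' Counts how many distinct structures are shared by at least 10%, 20%, ...,
#' 100% of the training objects (a cumulative, hence monotone non-increasing,
#' tabulation).
#'
#' @param records a tibble from [compile_structures()].
#' @return tibble with columns `min_sharing` (0.1 ... 1.0) and `n_structures`.
#' @export
sharing_histogram <- function(records) {
  if (!nrow(records)) abort_data("no structure records")
  bins <- seq(0.1, 1, by = 0.1)
  tibble::tibble(
    min_sharing = bins,
    n_structures = vapply(bins, function(b)
      sum(records$sharing >= b - 1e-12), integer(1))
  )
}
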