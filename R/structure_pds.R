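# 10-dimensional Gaussian distributions of structure amplitude signatures,
# the context model, patch posteriors and structure selection.

#' Fit the 10-D Gaussian amplitude distribution of a structure
#'
#' The distribution is over amplitude signatures: the dominant-cluster
#' root-total-square amplitude of the whole 48x48 patch (slot 1) and of each
#' of its nine 16x16 blocks (slots 2-10). Mean and covariance are maximum
#' likelihood; with fewer than 30 samples the covariance is restricted to its
#' diagonal, and a ridge of `1e-6 * trace / 10` is always added to the
#' diagonal so the density is well defined even for a single sample.
#'
#' @param record one row of the tibble from [compile_structures()] (or any
#'   list with elements `label` and `samples`).
#' @return an object of class `structure_pd` with fields `label`, `mean`,
#'   `covariance`, `n_fit` and `differential_entropy` (nats,
#'   `0.5 * log((2*pi*e)^10 * det(Sigma))`).
#' @export
fit_structure_pd <- function(record) {
  samples <- if (is.data.frame(record)) record$samples[[1L]] else record$samples
  if (is.list(samples) && !is.matrix(samples)) samples <- samples[[1L]]
  label <- if (is.data.frame(record)) record$label[[1L]] else record$label
  if (is.null(samples) || !nrow(samples)) abort_data("no samples to fit")
  new_structure_pd(label, samples)
}

new_structure_pd <- function(label, samples) {
  n <- nrow(samples); d <- ncol(samples)
  mu <- colMeans(samples)
  S <- if (n > 1L) crossprod(sweep(samples, 2L, mu)) / n else matrix(0, d, d)
  if (n < 30L) S <- diag(diag(S), d)
  ridge <- 1e-6 * max(sum(diag(S)) / d, 1e-12)
  S <- (S + t(S)) / 2 + diag(ridge, d)
  ch <- chol(S)
  logdet <- 2 * sum(log(diag(ch)))
  structure(list(
    label = label, mean = mu, covariance = S, chol = ch, n_fit = n,
    logdet = logdet,
    differential_entropy = 0.5 * (d * log(2 * pi * exp(1)) + logdet)
  ), class = "structure_pd")
}

# log-density of N(pd$mean, pd$covariance) at the rows of `signatures`.
structure_logdens <- function(signatures, pd) {
  mvn_logdens(signatures, pd$mean, pd$chol)
}

#' Build the context model from context structure records
#'
#' Context structures are compiled exactly like object structures but from
#' patches sampled outside object masks (and from distractor scenes). The
#' model keeps the `keep` most frequent context structures, each with its own
#' 10-D Gaussian, plus one broad fallback Gaussian (mean and covariance of all
#' context signatures with the covariance inflated 4x) for patches matching no
#' context structure. The context density of a signature is the maximum
#' density over these components.
#'
#' @param records tibble from [compile_structures()] run on context patches.
#' @param keep number of most frequent context structures to model.
#' @return an object of class `context_model`.
#' @export
build_context_model <- function(records, keep = 200L) {
  if (!nrow(records)) abort_data("no context records")
  records <- records[order(-records$count), , drop = FALSE]
  top <- utils::head(records, keep)
  pds <- lapply(seq_len(nrow(top)), function(i) fit_structure_pd(top[i, ]))
  all_sigs <- do.call(rbind, records$samples)
  fb <- new_structure_pd(label = NULL, samples = all_sigs)
  fb$covariance <- fb$covariance * 4
  fb$chol <- chol(fb$covariance)
  fb$logdet <- 2 * sum(log(diag(fb$chol)))
  fb$differential_entropy <-
    0.5 * (ncol(all_sigs) * log(2 * pi * exp(1)) + fb$logdet)
  structure(list(pds = pds, fallback = fb), class = "context_model")
}

# Max log-density over the context components, for rows of `signatures`.
context_logdens <- function(signatures, context) {
  best <- structure_logdens(signatures, context$fallback)
  for (pd in context$pds) best <- pmax(best, structure_logdens(signatures, pd))
  best
}

#' Posterior probability that a patch belongs to the object class
#'
#' Two-class Bayes: `p = pi * f_o / (pi * f_o + (1 - pi) * f_c)` where `f_o`
#' is the density of the signature under the structure's Gaussian, `f_c` the
#' best (maximum) density under the context model, and `pi = prior_object`.
#' Computed in log space.
#'
#' @param signature amplitude signature (length 10) or an `n x 10` matrix.
#' @param pd a `structure_pd`.
#' @param context a `context_model`.
#' @param prior_object prior probability of the object class, in (0, 1).
#' @return posterior probability (vector of length `n`).
#' @export
patch_posterior <- function(signature, pd, context, prior_object = 0.5) {
  if (!is.numeric(prior_object) || prior_object <= 0 || prior_object >= 1)
    abort_param("`prior_object` must be in (0, 1)")
  X <- if (is.matrix(signature)) signature else matrix(signature, nrow = 1L)
  lo <- structure_logdens(X, pd)
  lc <- context_logdens(X, context)
  if (any(!is.finite(lo) & !is.finite(lc))) abort_data("non-finite densities")
  logistic2(log(prior_object) + lo, log(1 - prior_object) + lc)
}

#' Scene-level evidence of one structure: max posterior over patches
#'
#' A structure "fires" where it matches best, so its evidence for a scene or
#' candidate region is the maximum of [patch_posterior()] over the sampled
#' patches.
#'
#' @param scene_signatures `n x 10` matrix of patch amplitude signatures.
#' @inheritParams patch_posterior
#' @export
scene_structure_evidence <- function(scene_signatures, pd, context,
                                     prior_object = 0.5) {
  if (!is.matrix(scene_signatures) || !nrow(scene_signatures))
    abort_data("need at least one patch signature")
  max(patch_posterior(scene_signatures, pd, context, prior_object))
}

# Posterior matrix for many signatures against many structures: n x m.
# Context log-density is shared across structures.
posterior_matrix <- function(signatures, pds, context, prior_object = 0.5) {
  lc <- context_logdens(signatures, context) + log(1 - prior_object)
  lp <- log(prior_object)
  out <- matrix(0, nrow(signatures), length(pds))
  for (k in seq_along(pds))
    out[, k] <- logistic2(lp + structure_logdens(signatures, pds[[k]]), lc)
  out
}

#' Select the structures most diagnostic of the object class
#'
#' Each candidate structure is scored by its posterior separation: the mean of
#' its scene-level evidence over positive evaluation units (segmented objects)
#' minus the mean over negative units (context patch groups). The top `m`
#' structures by separation are kept, ranked descending.
#'
#' @param pds list of `structure_pd` for the candidate (shared) structures.
#' @param eval_units list of evaluation units, each a list with elements
#'   `signatures` (`n x 10` matrix) and `positive` (logical).
#' @param context a `context_model`.
#' @param m number of structures to keep (70 for the animal task, 134 for the
#'   car task by default elsewhere); if `m` exceeds the number of candidates
#'   all are kept with a warning.
#' @param prior_object prior for the patch posteriors.
#' @return list with `pds` (the selected structures, ranked) and `report`
#'   (tibble: rank, key, separation, entropy, n_fit).
#' @export
select_structures <- function(pds, eval_units, context, m = 70L,
                              prior_object = 0.5) {
  if (!length(pds)) abort_data("no candidate structures")
  pos <- vapply(eval_units, function(u) isTRUE(u$positive), logical(1))
  if (!any(pos) || all(pos))
    abort_data("evaluation set needs both positive and negative units")
  ev <- vapply(eval_units, function(u) {
    pm <- posterior_matrix(u$signatures, pds, context, prior_object)
    apply(pm, 2L, max)
  }, numeric(length(pds)))
  ev <- matrix(ev, nrow = length(pds))
  separation <- rowMeans(ev[, pos, drop = FALSE]) -
    rowMeans(ev[, !pos, drop = FALSE])
  if (m > length(pds)) {
    warning("m exceeds the number of candidate structures; keeping all")
    m <- length(pds)
  }
  ord <- order(-separation)
  keep <- ord[seq_len(m)]
  report <- tibble::tibble(
    rank = seq_along(keep),
    key = vapply(pds[keep], function(p) paste(p$label, collapse = "-"),
                 character(1)),
    separation = separation[keep],
    entropy = vapply(pds[keep], `[[`, numeric(1), "differential_entropy"),
    n_fit = vapply(pds[keep], `[[`, integer(1), "n_fit")
  )
  list(pds = pds[keep], report = report)
}

#' @export
print.structure_pd <- function(x, ...) {
  cat(sprintf("<structure_pd> label %s, n_fit %d, entropy %.2f nats\n",
              paste(x$label, collapse = "-"), x$n_fit,
              x$differential_entropy))
  invisible(x)
}
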