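# Joint density of the selected structures' evidence vector: ICA rotation plus
# generalized Gaussian marginals, and the candidate-level Bayes posterior.

#' Fit a generalized Gaussian density to a sample
#'
#' Density `f(x) = q / (2 * alpha * gamma(1/q)) * exp(-(|x - mu| / alpha)^q)`,
#' i.e. proportional to `exp(-a |x - mu|^q)` with `a = alpha^(-q)`; `q = 2` is
#' Gaussian, `q = 1` Laplacian. `mu` is the sample mean; for each candidate
#' exponent the scale has the closed-form maximum-likelihood value
#' `alpha = (q * mean(|x - mu|^q))^(1/q)`, and the exponent is found by
#' kurtosis-based moment matching followed by golden-section refinement of the
#' profile likelihood on `q` in `[0.2, 4]`.
#'
#' @param x numeric sample.
#' @param q_bounds search interval for the exponent.
#' @return object of class `gengauss_pd` with fields `mu`, `alpha`, `q`,
#'   `a_const` and `log_norm`.
#' @export
fit_gengauss <- function(x, q_bounds = c(0.2, 4)) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) abort_data("need at least 3 observations")
  mu <- mean(x)
  ax <- abs(x - mu)
  if (max(ax) < 1e-12) ax <- ax + 1e-12
  profile_nll <- function(q) {
    alpha <- (q * mean(ax^q))^(1 / q)
    -(log(q) - log(2) - log(alpha) - lgamma(1 / q) - 1 / q)
  }
  # moment-matching start: kurtosis of a generalized Gaussian is
  # gamma(5/q) gamma(1/q) / gamma(3/q)^2; invert numerically
  kur <- mean(ax^4) / max(mean(ax^2)^2, 1e-300)
  gg_kurt <- function(q) exp(lgamma(5 / q) + lgamma(1 / q) - 2 * lgamma(3 / q))
  q0 <- tryCatch(
    stats::uniroot(function(q) gg_kurt(q) - kur, q_bounds, extendInt = "no")$root,
    error = function(e) 2)
  lo <- max(q_bounds[1L], q0 / 2)
  hi <- min(q_bounds[2L], q0 * 2)
  if (hi <= lo) { lo <- q_bounds[1L]; hi <- q_bounds[2L] }
  opt <- stats::optimize(profile_nll, c(lo, hi))
  # guard against a bad moment-matching bracket
  opt_full <- stats::optimize(profile_nll, q_bounds)
  if (opt_full$objective < opt$objective - 1e-10) opt <- opt_full
  q <- opt$minimum
  alpha <- (q * mean(ax^q))^(1 / q)
  structure(list(mu = mu, alpha = alpha, q = q, a_const = alpha^(-q),
                 log_norm = log(q) - log(2) - log(alpha) - lgamma(1 / q)),
            class = "gengauss_pd")
}

#' Generalized Gaussian log-density
#' @param x numeric vector of evaluation points.
#' @param pd a `gengauss_pd`.
#' @export
dgengauss_log <- function(x, pd) {
  pd$log_norm - (abs(x - pd$mu) / pd$alpha)^pd$q
}

#' Fit the joint model of structure-evidence vectors
#'
#' Centers the evidence vectors, reduces to `r` principal dimensions
#' (`r = min(m, floor(n / 10))` by default, discarding the remaining
#' variance), whitens, runs fixed-point ICA, and fits each independent
#' component's amplitude histogram to a generalized Gaussian. The joint
#' log-density of a vector is the sum of the marginal log-densities of its
#' IC amplitudes plus a constant log-Jacobian term of the (possibly
#' rectangular) transform.
#'
#' @param vectors `n x m` matrix of evidence vectors (entries in `[0, 1]`,
#'   one row per scene or candidate).
#' @param class_tag `"object"` or `"context"`.
#' @param seed integer seed for the ICA initialization.
#' @param r number of independent components; default `min(m, floor(n/10))`,
#'   always capped at the data rank.
#' @return object of class `joint_structure_model`.
#' @export
fit_joint_model <- function(vectors, class_tag = "object", seed = 1L, r = NULL) {
  if (!is.matrix(vectors) || nrow(vectors) < 3L)
    abort_data("`vectors` must be a matrix with at least 3 rows")
  n <- nrow(vectors); m <- ncol(vectors)
  if (n < 10 * m)
    warning(sprintf("only %d vectors for %d dimensions; ICA dimension reduced", n, m))
  if (is.null(r)) r <- min(m, max(1L, n %/% 10L))
  center <- colMeans(vectors)
  Xc <- sweep(vectors, 2L, center)
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values, 1e-300) * 1e-9)
  r <- min(r, length(keep))
  if (r < 1L) abort_data("evidence vectors are constant; cannot fit")
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  # evidence entries are posteriors in [0, 1]; variation below ~0.01 is
  # noise, so floor the variance at 0.01^2 to bound the whitening gain
  lam <- pmax(eg$values[seq_len(r)], 1e-4)
  K <- t(E) / sqrt(lam)
  Z <- K %*% t(Xc)
  W <- with_seed(seed, fastica_symmetric(Z))
  unmixing <- W %*% K                          # r x m
  # constant log-Jacobian of the rectangular transform
  log_det_term <- 0.5 * determinant(unmixing %*% t(unmixing),
                                    logarithm = TRUE)$modulus
  S <- t(W %*% Z)                              # n x r source amplitudes
  # the same 0.01 evidence-resolution floor, mapped through each component's
  # unmixing row, bounds the fitted marginal scales
  marginals <- lapply(seq_len(r), function(j) {
    pd <- fit_gengauss(S[, j])
    sd_floor <- 0.01 * sqrt(sum(unmixing[j, ]^2))
    alpha_min <- sd_floor * sqrt(exp(lgamma(1 / pd$q) - lgamma(3 / pd$q)))
    if (pd$alpha < alpha_min) {
      pd$alpha <- alpha_min
      pd$a_const <- alpha_min^(-pd$q)
      pd$log_norm <- log(pd$q) - log(2) - log(alpha_min) - lgamma(1 / pd$q)
    }
    pd
  })
  structure(list(class = class_tag, m = m, r = r, center = center,
                 unmixing = unmixing,
                 log_det_term = as.numeric(log_det_term),
                 marginals = marginals, seed = as.integer(seed)),
            class = "joint_structure_model")
}

#' Joint log-density of an evidence vector
#'
#' @param v evidence vector of length `m`, or an `n x m` matrix.
#' @param model a `joint_structure_model`.
#' @return log-density (vector of length `n`), finite for all finite inputs.
#' @export
joint_log_density <- function(v, model) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(V) != model$m) abort_data("evidence vector length mismatch")
  Z <- model$unmixing %*% (t(V) - model$center)   # r x n
  ll <- rep(model$log_det_term, ncol(Z))
  for (j in seq_len(model$r))
    ll <- ll + dgengauss_log(Z[j, ], model$marginals[[j]])
  ll
}

#' Candidate posterior from the object and context joint models
#'
#' `p = pi exp(L_o) / (pi exp(L_o) + (1 - pi) exp(L_c))` evaluated stably in
#' log space, where `L_o` and `L_c` are the joint log-densities of the
#' evidence vector under the object and context models.
#'
#' @param v evidence vector (length `m`) or `n x m` matrix.
#' @param obj_model,ctx_model `joint_structure_model`s fitted on the same
#'   structure set.
#' @param prior_object prior probability of the object class.
#' @export
candidate_posterior <- function(v, obj_model, ctx_model, prior_object = 0.5) {
  if (obj_model$m != ctx_model$m)
    abort_data("object and context models use different structure sets")
  if (prior_object <= 0 || prior_object >= 1)
    abort_param("`prior_object` must be in (0, 1)")
  lo <- joint_log_density(v, obj_model)
  lc <- joint_log_density(v, ctx_model)
  if (any(!is.finite(lo)) || any(!is.finite(lc)))
    abort_data("non-finite joint log-densities")
  logistic2(log(prior_object) + lo, log(1 - prior_object) + lc)
}

#' @export
print.joint_structure_model <- function(x, ...) {
  qs <- vapply(x$marginals, `[[`, numeric(1), "q")
  cat(sprintf("<joint_structure_model> class %s, m = %d, r = %d, exponents [%.2f, %.2f]\n",
              x$class, x$m, x$r, min(qs), max(qs)))
  invisible(x)
}

#' Tidy the joint model: one row per independent component marginal
#' @param x a `joint_structure_model`.
#' @param ... unused.
#' @export
tidy.joint_structure_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$r),
    mu = vapply(x$marginals, `[[`, numeric(1), "mu"),
    alpha = vapply(x$marginals, `[[`, numeric(1), "alpha"),
    q = vapply(x$marginals, `[[`, numeric(1), "q")
  )
}

#' Range of fitted generalized-Gaussian exponents of a joint model
#' @param x a `joint_structure_model`.
#' @param ... unused.
#' @export
glance.joint_structure_model <- function(x, ...) {
  qs <- vapply(x$marginals, `[[`, numeric(1), "q")
  tibble::tibble(class = x$class, m = x$m, r = x$r,
                 q_min = min(qs), q_max = max(qs))
}

#' @importFrom generics glance
#' @export
generics::glance
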