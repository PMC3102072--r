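# Internal helpers: validation, seeded RNG scoping, small numeric utilities.

abort_param <- function(msg) stop(structure(
  class = c("rapidscene_param_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_data <- function(msg) stop(structure(
  class = c("rapidscene_data_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

#' @keywords internal
stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    abort_param(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Run `expr` under a local RNG state seeded by `seed`, restoring the caller's
# RNG afterwards so package functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed (kept below 2^31).
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483587)
}

# log-density of N(mu, Sigma) evaluated at the rows of X, via Cholesky.
mvn_logdens <- function(X, mu, chol_sigma) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  d <- length(mu)
  z <- forwardsolve(t(chol_sigma), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) - 0.5 * d * log(2 * pi)
}

# Symmetrize + ridge so a sample covariance is safely positive definite.
regularize_cov <- function(S, rel = 1e-6) {
  S <- (S + t(S)) / 2
  d <- nrow(S)
  ridge <- rel * max(sum(diag(S)) / d, .Machine$double.eps)
  S + diag(ridge, d)
}

logistic2 <- function(log_a, log_b) {
  # a / (a + b) computed stably from log a, log b
  m <- pmax(log_a, log_b)
  ea <- exp(log_a - m); eb <- exp(log_b - m)
  ea / (ea + eb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
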