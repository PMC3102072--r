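#' Learn an independent-component basis of contrast patches at one scale
#'
#' Performs PCA whitening followed by symmetric fixed-point ICA (tanh contrast)
#' on flattened contrast patches of a single scale (16x16 or 48x48 pixels).
#' Each retained component is an oriented feature; components are subsequently
#' assigned an orientation and binned into the four orientation clusters
#' (0, 45, 90, 135 degrees) by [cluster_ics()].
#'
#' Patches are mean-subtracted per patch (DC removed) and the dataset is
#' column-centered before whitening. The learned basis stores:
#' * `whitening` — the `r x p` PCA whitening matrix `K` (rows span the
#'   zero-DC patch subspace, so `K %*% rep(1, p) = 0`),
#' * `unmixing_w` — the orthonormal `r x r` ICA rotation `W` in whitened space
#'   (the unit-norm filters),
#' * `filters` — `W %*% K`, the input-space projection operators,
#' * `features` — the `p x r` mixing matrix (the oriented IC basis images used
#'   for orientation estimation and display).
#'
#' Component activations of a patch `x` are `s = W K (x - mean(x))`; they are
#' linear in the patch, so activations and amplitude vectors scale with patch
#' contrast and vanish for constant patches.
#'
#' @param patches numeric matrix, one flattened patch per row (column-major
#'   pixels of a `scale x scale` patch); at least `n_components` rows.
#' @param n_components number of independent components to extract; defaults to
#'   160 for 48x48 patches and 100 for 16x16 patches, capped at the data rank.
#' @param seed integer seed; fixing it makes the basis bit-reproducible.
#' @param scale patch side in pixels (16 or 48); inferred from `ncol(patches)`
#'   when omitted.
#' @param maxit,tol fixed-point iteration controls.
#' @return an object of class `ic_basis`.
#' @export
learn_ic_basis <- function(patches, n_components = NULL, seed = 1L,
                           scale = NULL, maxit = 200L, tol = 1e-6) {
  if (!is.matrix(patches) || nrow(patches) < 2L)
    abort_data("`patches` must be a matrix with at least 2 rows")
  p <- ncol(patches)
  s <- as.integer(round(sqrt(p)))
  if (s * s != p) abort_data("patch length is not a perfect square")
  if (is.null(scale)) scale <- s
  if (scale != s) abort_data("mixed or mismatched patch sizes")
  if (!scale %in% c(16L, 48L))
    abort_data("patch side must be 16 or 48 pixels")
  if (is.null(n_components)) n_components <- if (scale == 48L) 160L else 100L
  n_components <- stopifnot_scalar_count(n_components, "n_components", min = 1L)
  if (nrow(patches) < n_components)
    abort_data("fewer patches than requested components")

  X <- patches - rowMeans(patches)            # per-patch DC removal
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)

  C <- crossprod(Xc) / nrow(Xc)
  eg <- eigen(C, symmetric = TRUE)
  lam <- eg$values
  keep <- which(lam > max(lam) * 1e-10)
  r <- min(n_components, length(keep))
  if (r < n_components)
    warning(sprintf("data rank %d < n_components %d; reducing", r, n_components))
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  lam <- lam[seq_len(r)]
  K <- t(E) / sqrt(lam)                        # r x p whitening
  Z <- K %*% t(Xc)                             # r x n whitened data

  W <- with_seed(seed, fastica_symmetric(Z, maxit = maxit, tol = tol))

  mixing <- E * rep(sqrt(lam), each = nrow(E)) # p x r, = E diag(sqrt(lam))
  features <- mixing %*% t(W)                  # p x r IC basis images

  basis <- structure(list(
    scale = as.integer(scale),
    n_retained = r,
    whitening = K,
    unmixing_w = W,
    filters = W %*% K,
    features = features,
    orientations = rep(NA_real_, r),
    clusters = rep(NA_real_, r),
    low_anisotropy = rep(NA, r),
    seed = as.integer(seed)
  ), class = "ic_basis")
  cluster_ics(basis)
}

# Symmetric fixed-point ICA with tanh contrast on whitened data Z (r x n).
fastica_symmetric <- function(Z, maxit = 200L, tol = 1e-6) {
  r <- nrow(Z); n <- ncol(Z)
  sym_decorrelate <- function(W) {
    eg <- eigen(W %*% t(W), symmetric = TRUE)
    v <- pmax(eg$values, 1e-12)
    (eg$vectors %*% (t(eg$vectors) / sqrt(v))) %*% W
  }
  W <- sym_decorrelate(matrix(stats::rnorm(r * r), r, r))
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / n - rowMeans(1 - G^2) * W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) break
  }
  W
}

#' Estimate the dominant orientation of an IC basis image
#'
#' The orientation is the angle (degrees in `[0, 180)`, 0 = horizontal
#' stripes/edges, increasing counter-clockwise on screen) of the peak of the
#' orientation-marginalized 2-D Fourier power spectrum, scanned in 1-degree
#' bins with the DC term removed. A lightly smoothed profile is used for the
#' peak; ties resolve to the lowest angle. Filters whose orientation-energy
#' profile is nearly flat (max/mean ratio below `aniso_min`) are flagged
#' low-anisotropy and assigned 0 degrees.
#'
#' @param filter numeric vector of length `scale^2` (column-major image) or a
#'   `scale x scale` matrix.
#' @param scale patch side in pixels.
#' @param aniso_min anisotropy ratio below which a filter counts as isotropic.
#' @return orientation in degrees, with attributes `anisotropy` and
#'   `low_anisotropy`.
#' @export
estimate_ic_orientation <- function(filter, scale = NULL, aniso_min = 1.2) {
  img <- if (is.matrix(filter)) filter else {
    if (is.null(scale)) scale <- as.integer(round(sqrt(length(filter))))
    if (length(filter) != scale^2) abort_data("filter length != scale^2")
    matrix(filter, scale, scale)
  }
  if (all(img == 0)) abort_data("degenerate all-zero filter")
  prof <- orientation_energy_profile(img)
  # circular boxcar smoothing over +/- 2 degrees
  k <- 2L
  sm <- vapply(seq_along(prof), function(i) {
    idx <- ((i - 1 + (-k:k)) %% 180L) + 1L
    mean(prof[idx])
  }, numeric(1))
  aniso <- max(sm) / max(mean(sm), .Machine$double.eps)
  low <- aniso < aniso_min
  ang <- if (low) 0 else (which.max(sm) - 1)   # ties: which.max takes lowest
  structure(as.numeric(ang), anisotropy = aniso, low_anisotropy = low)
}

# Power of the 2-D spectrum accumulated into 180 one-degree orientation bins.
# For the frequency vector (u, v) (u = cycles along x/columns, v = along
# y/rows, y pointing down), the stripe orientation on screen is
# atan2(u, v) mod 180 (0 = horizontal stripes varying vertically).
orientation_energy_profile <- function(img) {
  h <- nrow(img); w <- ncol(img)
  P <- Mod(stats::fft(img - mean(img)))^2
  v <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h)
  u <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w)
  V <- matrix(v, h, w); U <- matrix(u, h, w, byrow = TRUE)
  theta <- (atan2(U, V) * 180 / pi) %% 180
  sel <- !(U == 0 & V == 0)
  bins <- (round(theta[sel]) %% 180L)
  prof <- numeric(180)
  agg <- tapply(P[sel], bins, sum)
  prof[as.integer(names(agg)) + 1L] <- agg
  prof
}

#' Assign every component of a basis to one of four orientation clusters
#'
#' Each component's estimated orientation is binned into the nearest of
#' 0, 45, 90, 135 degrees under the circular distance on `[0, 180)`; exact
#' midpoints (e.g. 22.5) break to the numerically lower bin, and
#' low-anisotropy components go to the 0-degree bin.
#'
#' @param basis an `ic_basis`.
#' @return the basis with `orientations`, `clusters` and `low_anisotropy`
#'   filled in.
#' @export
cluster_ics <- function(basis) {
  if (!inherits(basis, "ic_basis")) abort_param("`basis` must be an ic_basis")
  r <- basis$n_retained
  ors <- numeric(r); low <- logical(r)
  for (i in seq_len(r)) {
    o <- estimate_ic_orientation(basis$features[, i], basis$scale)
    ors[i] <- as.numeric(o)
    low[i] <- attr(o, "low_anisotropy")
  }
  basis$orientations <- ors
  basis$low_anisotropy <- low
  basis$clusters <- vapply(seq_len(r), function(i) {
    if (low[i]) return(0)
    orientation_bin(ors[i])
  }, numeric(1))
  basis
}

#' @rdname cluster_ics
#' @param theta orientation in degrees.
#' @export
orientation_bin <- function(theta) {
  bins <- c(0, 45, 90, 135)
  d <- abs(((theta - bins + 90) %% 180) - 90)
  bins[which.min(d)]   # ties break to the lower bin value
}

#' Root-total-square amplitude of a patch in the four orientation clusters
#'
#' Projects a contrast patch onto the basis (activations
#' `s = W K (x - mean(x))`) and returns, for each orientation cluster `c`,
#' `a_c = sqrt(sum of s_i^2 over components i in cluster c)`. The map is
#' linear in the patch, so `amplitude_vector(k * patch) = k *
#' amplitude_vector(patch)` for `k >= 0` and a zero patch gives the zero
#' vector.
#'
#' @param patch numeric vector of length `scale^2` or a `scale x scale` matrix.
#' @param basis an `ic_basis` of matching scale.
#' @return named numeric vector of 4 nonnegative amplitudes
#'   (`"0"`, `"45"`, `"90"`, `"135"`).
#' @export
amplitude_vector <- function(patch, basis) {
  x <- as.numeric(patch)
  if (length(x) != basis$scale^2)
    abort_data("patch size does not match basis scale")
  drop(amplitude_matrix(matrix(x, nrow = 1L), basis))
}

# Batched amplitudes: patches as rows (n x p) -> n x 4 matrix of cluster
# amplitudes. The workhorse behind labeling, signatures and probability maps.
amplitude_matrix <- function(patches, basis) {
  if (ncol(patches) != basis$scale^2) abort_data("patch size mismatch")
  Xpp <- patches - rowMeans(patches)
  S <- tcrossprod(Xpp, basis$filters)          # n x r activations
  out <- matrix(0, nrow(patches), 4L,
                dimnames = list(NULL, c("0", "45", "90", "135")))
  for (j in seq_len(4L)) {
    idx <- which(basis$clusters == c(0, 45, 90, 135)[j])
    if (length(idx))
      out[, j] <- sqrt(rowSums(S[, idx, drop = FALSE]^2))
  }
  out
}

#' @export
print.ic_basis <- function(x, ...) {
  cat(sprintf("<ic_basis> scale %d px, %d components, clusters: %s (seed %d)\n",
              x$scale, x$n_retained,
              paste(table(factor(x$clusters, levels = c(0, 45, 90, 135))),
                    collapse = "/"), x$seed))
  invisible(x)
}

#' Persist / restore an IC basis as a directory (flat binary + JSON metadata)
#'
#' @param basis an `ic_basis`.
#' @param dir directory to create.
#' @export
save_ic_basis <- function(basis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, name) {
    con <- file(file.path(dir, name), "wb"); on.exit(close(con))
    writeBin(as.numeric(m), con, size = 8L)
  }
  write_mat(basis$whitening, "whitening.bin")
  write_mat(basis$unmixing_w, "unmixing_w.bin")
  jsonlite::write_json(list(
    scale = basis$scale, n_retained = basis$n_retained, seed = basis$seed,
    p = ncol(basis$whitening),
    orientations = basis$orientations, clusters = basis$clusters,
    low_anisotropy = basis$low_anisotropy
  ), file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ic_basis
#' @param dir directory written by [save_ic_basis()].
#' @export
load_ic_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  read_mat <- function(name, nr, nc) {
    con <- file(file.path(dir, name), "rb"); on.exit(close(con))
    matrix(readBin(con, "numeric", n = nr * nc, size = 8L), nr, nc)
  }
  K <- read_mat("whitening.bin", meta$n_retained, meta$p)
  W <- read_mat("unmixing_w.bin", meta$n_retained, meta$n_retained)
  # features: K is not square-invertible in general; reconstruct via pseudo-
  # inverse of the whitening (K has orthogonal rows scaled by 1/sqrt(lambda)).
  Kp <- t(K) %*% solve(K %*% t(K))
  structure(list(
    scale = meta$scale, n_retained = meta$n_retained,
    whitening = K, unmixing_w = W, filters = W %*% K,
    features = Kp %*% t(W),
    orientations = meta$orientations, clusters = meta$clusters,
    low_anisotropy = meta$low_anisotropy, seed = meta$seed
  ), class = "ic_basis")
}
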