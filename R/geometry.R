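# Coarse object geometry: moment-based ellipse fits, the multivariate Gaussian
# geometry model (shape + part configuration), and candidate sampling.

#' Fit an ellipse to a binary mask region by image moments
#'
#' Center = centroid; axis directions from the eigenvectors of the second
#' central moment matrix; semi-axes from the eigenvalues, rescaled so the
#' ellipse has exactly the region's pixel area. Orientation `theta` is the
#' major-axis angle in degrees `[0, 180)`, 0 = horizontal, increasing
#' counter-clockwise on screen (image y axis points down).
#'
#' @param mask_region logical or 0/1 matrix.
#' @return tibble with columns `cx, cy, a, b, theta` (`a >= b`, pixels).
#' @export
fit_ellipse <- function(mask_region) {
  idx <- which(mask_region != 0, arr.ind = TRUE)
  if (!nrow(idx)) abort_data("empty mask region")
  y <- idx[, 1L]; x <- idx[, 2L]
  cx <- mean(x); cy <- mean(y)
  n <- length(x)
  # second central moments in screen coordinates (y up) so theta is CCW
  u <- x - cx; v <- -(y - cy)
  M <- matrix(c(mean(u * u), mean(u * v), mean(u * v), mean(v * v)), 2L)
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  a0 <- 2 * sqrt(lam[1L]); b0 <- 2 * sqrt(lam[2L])
  if (b0 < 1e-9) { b0 <- 1 }                       # collinear region: clamp
  scl <- sqrt(n / (pi * a0 * b0))
  a <- a0 * scl; b <- b0 * scl
  theta <- (atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]) * 180 / pi) %% 180
  tibble::tibble(cx = cx, cy = cy, a = a, b = max(b, 1), theta = theta)
}

#' Rasterize ellipses into a logical mask
#'
#' A pixel (x, y) is inside when the canonical ellipse equation holds under
#' the same screen-angle convention as [fit_ellipse()].
#'
#' @param ellipses data frame with columns `cx, cy, a, b, theta` (one row per
#'   ellipse; the union is returned).
#' @param h,w mask dimensions (rows, columns).
#' @export
rasterize_ellipses <- function(ellipses, h, w) {
  out <- matrix(FALSE, h, w)
  ecx <- ellipses$cx; ecy <- ellipses$cy
  ea <- ellipses$a; eb <- ellipses$b; eth <- ellipses$theta
  for (i in seq_along(ecx)) {
    r <- ceiling(max(ea[i], eb[i])) + 1L
    rows <- max(1L, floor(ecy[i] - r)):min(h, ceiling(ecy[i] + r))
    cols <- max(1L, floor(ecx[i] - r)):min(w, ceiling(ecx[i] + r))
    if (!length(rows) || !length(cols)) next
    th <- eth[i] * pi / 180
    dx <- outer(rep(1, length(rows)), cols - ecx[i])
    dy <- outer(-(rows - ecy[i]), rep(1, length(cols)))   # screen y up
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    out[rows, cols] <- out[rows, cols] | ((xr / ea[i])^2 + (yr / eb[i])^2 <= 1)
  }
  out
}

# Parameter vector embedding: angles enter as (cos 2*theta, sin 2*theta) so the
# Gaussian lives on a space without the 0/180 wrap.
embed_annotation <- function(ann, n_parts) {
  if (n_parts == 2L) {
    hd <- ann[ann$part == "head", ]; bd <- ann[ann$part == "body", ]
    if (nrow(hd) != 1L || nrow(bd) != 1L) abort_data("inconsistent part counts")
    c(a_head = hd$a, b_head = hd$b,
      c2_head = cos(2 * hd$theta * pi / 180), s2_head = sin(2 * hd$theta * pi / 180),
      a_body = bd$a, b_body = bd$b,
      c2_body = cos(2 * bd$theta * pi / 180), s2_body = sin(2 * bd$theta * pi / 180),
      dx = hd$cx - bd$cx, dy = hd$cy - bd$cy)
  } else {
    wh <- ann[ann$part %in% c("whole", "body"), ]
    if (nrow(wh) != 1L) abort_data("inconsistent part counts")
    c(a = wh$a, b = wh$b,
      c2 = cos(2 * wh$theta * pi / 180), s2 = sin(2 * wh$theta * pi / 180))
  }
}

#' Fit the multivariate Gaussian geometry model
#'
#' Models object shape and part configuration: for two-part objects (animal
#' head + body) the parameter vector is (head semi-axes and doubled-angle
#' orientation, body semi-axes and doubled-angle orientation, head-center
#' offset from the body center); for one-part objects (cars, heads, far
#' bodies) it is the single ellipse's shape. Absolute position is not
#' modelled; at test time candidates take their position from the posterior
#' probability map.
#'
#' @param annotations tibble with columns `object_id, part, cx, cy, a, b,
#'   theta` (parts `"head"`/`"body"` for 2-part objects, `"whole"` or
#'   `"body"` for 1-part).
#' @param n_parts 1 or 2.
#' @return object of class `geometry_model` with `mean`, `covariance` and a
#'   diagnostic `peak` tibble (modal shape per part, angles converted back to
#'   degrees).
#' @export
fit_geometry_model <- function(annotations, n_parts = 2L) {
  if (!n_parts %in% c(1L, 2L)) abort_param("`n_parts` must be 1 or 2")
  ids <- unique(annotations$object_id)
  if (length(ids) < 3L) abort_data("need at least 3 annotated objects")
  V <- t(vapply(ids, function(id)
    embed_annotation(annotations[annotations$object_id == id, ], n_parts),
    numeric(if (n_parts == 2L) 10L else 4L)))
  mu <- colMeans(V)
  S <- regularize_cov(crossprod(sweep(V, 2L, mu)) / nrow(V))
  peak <- if (n_parts == 2L) {
    tibble::tibble(
      part = c("head", "body"),
      a = c(mu["a_head"], mu["a_body"]),
      b = c(mu["b_head"], mu["b_body"]),
      theta = c((atan2(mu["s2_head"], mu["c2_head"]) * 90 / pi) %% 180,
                (atan2(mu["s2_body"], mu["c2_body"]) * 90 / pi) %% 180))
  } else {
    tibble::tibble(part = "whole", a = mu["a"], b = mu["b"],
                   theta = (atan2(mu["s2"], mu["c2"]) * 90 / pi) %% 180)
  }
  ch <- chol(S)
  structure(list(n_parts = as.integer(n_parts), mean = mu, covariance = S,
                 chol = ch,
                 log_peak = mvn_logdens(matrix(mu, 1L), mu, ch),
                 n_fit = nrow(V), peak = peak),
            class = "geometry_model")
}

# Draw n shape vectors from the geometry Gaussian; sizes truncated positive
# (resampled, then clamped), a >= b enforced by axis swap + 90 deg rotation.
sample_geometry_shapes <- function(model, n, seed = NULL) {
  with_seed(seed, {
    d <- length(model$mean)
    draw <- function(k) MASS::mvrnorm(k, model$mean, model$covariance)
    V <- matrix(draw(n), ncol = d)
    size_cols <- grep("^(a|b)", names(model$mean))
    for (tries in 1:50) {
      bad <- which(apply(V[, size_cols, drop = FALSE] <= 1, 1L, any))
      if (!length(bad)) break
      V[bad, ] <- matrix(draw(length(bad)), ncol = d)
    }
    V[, size_cols][V[, size_cols] <= 1] <- 1
    colnames(V) <- names(model$mean)
    V
  })
}

# Plain numeric c(cx, cy, a, b, theta); a >= b enforced by swap + 90 deg.
shape_row_to_ellipse <- function(a, b, c2, s2, cx, cy) {
  theta <- (atan2(s2, c2) * 90 / pi) %% 180
  if (a < b) { tmp <- a; a <- b; b <- tmp; theta <- (theta + 90) %% 180 }
  c(cx = unname(cx), cy = unname(cy), a = unname(a), b = unname(b),
    theta = unname(theta))
}

#' Sample object candidates from the geometry model over a probability map
#'
#' Candidate shapes are drawn from the geometry Gaussian; body centers are
#' placed on pixels of the posterior probability map whose value exceeds
#' `p_threshold`, sampled proportionally to their probability (without
#' replacement while pixels last), so the candidates cover most
#' above-threshold pixels. If no pixel exceeds the threshold all candidates
#' are centered on the map maximum. Centers are clamped to the image bounds.
#'
#' @param model a `geometry_model`.
#' @param prob_map matrix of posteriors in `[0, 1]` (class `probability_map`).
#' @param n number of candidates (default 300).
#' @param p_threshold placement threshold on the map (default 0.6).
#' @param seed integer seed; sampling is seed-deterministic.
#' @return list of `object_candidate`s, each with an `ellipses` data frame
#'   (columns `part, cx, cy, a, b, theta`; parts `head`+`body` or `body`).
#' @export
sample_candidates <- function(model, prob_map, n = 300L, p_threshold = 0.6,
                              seed = NULL) {
  n <- stopifnot_scalar_count(n, "n")
  if (p_threshold < 0 || p_threshold > 1)
    abort_param("`p_threshold` must be in [0, 1]")
  h <- nrow(prob_map); w <- ncol(prob_map)
  with_seed(seed, {
    shapes <- sample_geometry_shapes(model, n)
    above <- which(unclass(prob_map) > p_threshold)
    centers <- if (length(above) == 1L) {
      rep(above, n)
    } else if (length(above)) {
      wts <- prob_map[above]
      k <- min(n, length(above))
      picked <- sample(above, k, replace = FALSE, prob = wts)
      if (k < n) picked <- c(picked, sample(above, n - k, replace = TRUE, prob = wts))
      picked
    } else rep(which.max(prob_map), n)
    cy <- ((centers - 1L) %% h) + 1L
    cx <- ((centers - 1L) %/% h) + 1L
    lapply(seq_len(n), function(i)
      shapes_to_candidate(shapes[i, ], model$n_parts, cx[i], cy[i], h, w))
  })
}

#' Geometry log-density of a candidate's sampled shape
#'
#' Evaluates the geometry Gaussian at the candidate's latent shape vector (the
#' one it was sampled with). Used for maximum-a-posteriori candidate
#' selection; subtract `model$log_peak` for the density normalized to 0 at the
#' mode.
#'
#' @param model a `geometry_model`.
#' @param candidate an `object_candidate` carrying a `shape` vector.
#' @export
geometry_log_density <- function(model, candidate) {
  sh <- candidate$shape
  if (is.null(sh) || length(sh) != length(model$mean))
    abort_data("candidate carries no compatible shape vector")
  as.numeric(mvn_logdens(matrix(sh, 1L), model$mean, model$chol))
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf("<geometry_model> %d part(s), fitted on %d objects\n",
              x$n_parts, x$n_fit))
  print(x$peak)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy the geometry model: one row per parameter with mean and sd
#' @param x a `geometry_model`.
#' @param ... unused.
#' @export
tidy.geometry_model <- function(x, ...) {
  tibble::tibble(parameter = names(x$mean), mean = unname(x$mean),
                 sd = sqrt(diag(x$covariance)))
}

#' Read / write part-ellipse annotations as CSV
#'
#' Columns: `object_id, part, cx, cy, a, b, theta` with `part` one of
#' `"head"`, `"body"`, `"whole"`.
#' @param path CSV path.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("object_id", "part", "cx", "cy", "a", "b", "theta")
  if (!all(need %in% names(ann))) abort_data("missing annotation columns")
  tibble::as_tibble(ann)
}

#' @rdname read_annotations
#' @param annotations tibble of annotations.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
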