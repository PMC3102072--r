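# Seeded generator of synthetic scene datasets: textured elliptical objects
# (optionally head+body pairs) on textured backgrounds, with exact masks and
# ellipse annotations, emulating grayscale object-in-context photographs.

#' Generator configuration for synthetic scene datasets
#'
#' Positives contain exactly one object — a body ellipse plus, for
#' `n_parts = 2`, an attached head ellipse — drawn from `geometry_truth` and
#' filled with an oriented texture; negatives (distractors) are background
#' texture only. The `separation` knob rotates the object texture band away
#' from the background band: the object orientation is
#' `bg_orientation + separation * 90` degrees, so `separation = 0` makes
#' object and background statistically exchangeable and `separation = 1`
#' makes their orientation bands fully disjoint.
#'
#' @param image_size image side in pixels (default 256).
#' @param n_positive,n_negative scene counts.
#' @param n_parts 1 (single ellipse) or 2 (head + body).
#' @param separation scalar in `[0, 1]`.
#' @param bg_orientation background band center in degrees.
#' @param texture_type `"bandnoise"` (orientation-band-filtered white noise)
#'   or `"grating"`.
#' @param bandwidth angular band width (Gaussian sd, degrees).
#' @param freq_band radial passband in cycles/pixel.
#' @param mean_luminance,contrast_amplitude texture luminance mean and spread.
#' @param noise_sigma sd of the additive white Gaussian pixel noise.
#' @param geometry_truth list describing the generating geometry Gaussian; see
#'   [default_geometry_truth()]. Defaults scale with `image_size`.
#' @param seed master seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(image_size = 256L, n_positive = 30L,
                             n_negative = 30L, n_parts = 2L, separation = 1,
                             bg_orientation = 0, texture_type = "bandnoise",
                             bandwidth = 12, freq_band = c(0.06, 0.22),
                             mean_luminance = 128, contrast_amplitude = 60,
                             noise_sigma = 5, geometry_truth = NULL,
                             seed = 1L) {
  if (separation < 0 || separation > 1) abort_param("`separation` must be in [0, 1]")
  if (n_positive < 0 || n_negative < 0) abort_param("counts must be >= 0")
  if (!n_parts %in% c(1L, 2L)) abort_param("`n_parts` must be 1 or 2")
  if (is.null(geometry_truth))
    geometry_truth <- default_geometry_truth(image_size, n_parts)
  structure(list(
    image_size = as.integer(image_size), n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative), n_parts = as.integer(n_parts),
    separation = separation, bg_orientation = bg_orientation,
    texture_type = texture_type, bandwidth = bandwidth, freq_band = freq_band,
    mean_luminance = mean_luminance, contrast_amplitude = contrast_amplitude,
    noise_sigma = noise_sigma, geometry_truth = geometry_truth,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default generating geometry, scaled to the image size
#'
#' Two-part objects mimic an animal's head attached to its body at an offset
#' along the body axis; one-part objects mimic a car-like single ellipse. The
#' body is roughly horizontal; sizes and offsets scale linearly with
#' `image_size` (reference scale 256) but never below 75% of the reference:
#' the structure patch is a fixed 48 pixels, so objects must stay large
#' enough to contain it regardless of the image size.
#'
#' @param image_size image side in pixels.
#' @param n_parts 1 or 2.
#' @export
default_geometry_truth <- function(image_size = 256L, n_parts = 2L) {
  s <- max(image_size / 256, 0.75)
  body <- list(a = 40 * s, b = 26 * s, theta = 0,
               sd_a = 5 * s, sd_b = 3.5 * s, sd_theta = 10)
  if (n_parts == 1L)
    return(list(n_parts = 1L, body = body))
  list(
    n_parts = 2L,
    body = body,
    head = list(a = 18 * s, b = 13 * s, theta = 90,
                sd_a = 2.5 * s, sd_b = 2 * s, sd_theta = 15),
    offset = list(dx = 48 * s, dy = -10 * s, sd_dx = 5 * s, sd_dy = 4 * s)
  )
}

#' Generate an oriented texture
#'
#' Either a sinusoidal grating (random phase, the given orientation and the
#' low edge of `freq_band` as its frequency) or white noise filtered in the
#' Fourier domain by a radial passband and a Gaussian angular band around the
#' requested orientation, then normalized to the target mean and spread.
#'
#' @param spec list with `type` (`"grating"` or `"bandnoise"`), `orientation`
#'   (degrees), `freq_band` (cycles/pixel, `0 < lo < hi <= 0.5`), `bandwidth`
#'   (degrees), `mean`, `amplitude` (0 gives a constant image).
#' @param size image side in pixels.
#' @param seed integer seed.
#' @return `size x size` luminance matrix.
#' @export
generate_texture <- function(spec, size, seed = 1L) {
  type <- spec$type %||% "bandnoise"
  if (!type %in% c("grating", "bandnoise")) abort_param("unknown texture type")
  fb <- spec$freq_band %||% c(0.06, 0.22)
  if (length(fb) != 2L || fb[1L] <= 0 || fb[2L] <= fb[1L] || fb[2L] > 0.5)
    abort_param("invalid frequency band")
  m <- spec$mean %||% 128
  amp <- spec$amplitude %||% 60
  if (amp == 0) return(matrix(m, size, size))
  theta <- (spec$orientation %||% 0) * pi / 180
  with_seed(seed, {
    if (type == "grating") {
      f <- fb[1L]
      phase <- stats::runif(1, 0, 2 * pi)
      xs <- matrix(seq_len(size), size, size, byrow = TRUE)
      ys <- matrix(seq_len(size), size, size)
      # stripes at `orientation` on screen: luminance varies along the
      # perpendicular direction (x sin(theta) + y cos(theta) in y-down coords)
      m + amp * cos(2 * pi * f * (xs * sin(theta) + ys * cos(theta)) + phase)
    } else {
      bw <- spec$bandwidth %||% 12
      noise <- matrix(stats::rnorm(size * size), size, size)
      Fn <- stats::fft(noise)
      v <- ifelse(seq_len(size) - 1 <= size / 2, seq_len(size) - 1,
                  seq_len(size) - 1 - size)
      V <- matrix(v, size, size); U <- matrix(v, size, size, byrow = TRUE)
      fr <- sqrt((U / size)^2 + (V / size)^2)
      ang <- (atan2(U, V) * 180 / pi) %% 180
      d <- abs(((ang - (spec$orientation %||% 0) + 90) %% 180) - 90)
      mask <- exp(-0.5 * (d / bw)^2) * (fr >= fb[1L] & fr <= fb[2L])
      mask[1L, 1L] <- 0
      tex <- Re(stats::fft(Fn * mask, inverse = TRUE)) / (size * size)
      sdv <- stats::sd(tex)
      if (sdv < 1e-12) abort_param("frequency band contains no energy")
      m + (tex - mean(tex)) / sdv * (amp / 2)
    }
  })
}

# Draw the true geometry of one object (natural parameterization, independent
# truncated normals), as an annotations tibble placed at body center (cx, cy).
sample_true_object <- function(truth, cx, cy) {
  tn <- function(mu, sd, lo = 2) max(lo, stats::rnorm(1, mu, sd))
  bt <- truth$body
  body <- tibble::tibble(part = "body", cx = cx, cy = cy,
                         a = tn(bt$a, bt$sd_a), b = tn(bt$b, bt$sd_b),
                         theta = (stats::rnorm(1, bt$theta, bt$sd_theta)) %% 180)
  if (body$b > body$a) { tmp <- body$a; body$a <- body$b; body$b <- tmp
                         body$theta <- (body$theta + 90) %% 180 }
  if (truth$n_parts == 1L) return(body)
  ht <- truth$head; ot <- truth$offset
  head_ <- tibble::tibble(part = "head",
                          cx = cx + stats::rnorm(1, ot$dx, ot$sd_dx),
                          cy = cy + stats::rnorm(1, ot$dy, ot$sd_dy),
                          a = tn(ht$a, ht$sd_a), b = tn(ht$b, ht$sd_b),
                          theta = (stats::rnorm(1, ht$theta, ht$sd_theta)) %% 180)
  if (head_$b > head_$a) { tmp <- head_$a; head_$a <- head_$b; head_$b <- tmp
                           head_$theta <- (head_$theta + 90) %% 180 }
  dplyr::bind_rows(head_, body)
}

#' Generate a synthetic scene dataset
#'
#' Fully seed-deterministic: the same configuration (including seed) always
#' produces byte-identical scenes, masks and annotations. Objects whose
#' sampled geometry cannot be placed inside the image after 20 attempts are
#' skipped with a warning.
#'
#' @param config a [generator_config()].
#' @return list of class `rs_dataset` with elements `scenes` (list of
#'   luminance matrices), `masks` (list of logical matrices, `NULL` for
#'   negatives), `annotations` (tibble of true part ellipses for positives),
#'   `labels` (logical vector, `TRUE` = positive), `ids`, `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) abort_param("need a generator_config")
  sz <- config$image_size
  obj_orientation <- (config$bg_orientation + config$separation * 90) %% 180
  bg_spec <- list(type = config$texture_type, orientation = config$bg_orientation,
                  freq_band = config$freq_band, bandwidth = config$bandwidth,
                  mean = config$mean_luminance, amplitude = config$contrast_amplitude)
  obj_spec <- bg_spec; obj_spec$orientation <- obj_orientation

  n_total <- config$n_positive + config$n_negative
  scenes <- vector("list", n_total); masks <- vector("list", n_total)
  labels <- c(rep(TRUE, config$n_positive), rep(FALSE, config$n_negative))
  anns <- list()
  for (i in seq_len(n_total)) {
    s_i <- child_seed(config$seed, i)
    bg <- generate_texture(bg_spec, sz, seed = child_seed(s_i, 1L))
    if (labels[i]) {
      obj <- generate_texture(obj_spec, sz, seed = child_seed(s_i, 2L))
      placed <- with_seed(child_seed(s_i, 3L), {
        res <- NULL
        for (try in 1:20) {
          # sample the shape about a zero center, then draw a center for
          # which the whole object fits in the image
          ann <- sample_true_object(config$geometry_truth, 0, 0)
          ext <- pmax(ann$a, ann$b)
          lo_x <- 2 - min(ann$cx - ext); hi_x <- (sz - 1) - max(ann$cx + ext)
          lo_y <- 2 - min(ann$cy - ext); hi_y <- (sz - 1) - max(ann$cy + ext)
          if (lo_x > hi_x || lo_y > hi_y) next
          cx <- stats::runif(1, lo_x, hi_x)
          cy <- stats::runif(1, lo_y, hi_y)
          ann$cx <- ann$cx + cx; ann$cy <- ann$cy + cy
          res <- ann
          break
        }
        res
      })
      if (is.null(placed)) {
        warning(sprintf("scene %d: object could not be placed; left empty", i))
        labels[i] <- FALSE
        scene <- bg
      } else {
        mask <- rasterize_ellipses(placed, sz, sz)
        scene <- bg; scene[mask] <- obj[mask]
        masks[[i]] <- mask
        placed$object_id <- i
        anns[[length(anns) + 1L]] <- placed
      }
    } else scene <- bg
    noise <- with_seed(child_seed(s_i, 4L),
                       matrix(stats::rnorm(sz * sz, 0, config$noise_sigma), sz, sz))
    scenes[[i]] <- pmin(pmax(scene + noise, 0), 255)
  }
  structure(list(
    scenes = scenes, masks = masks,
    annotations = if (length(anns)) dplyr::bind_rows(anns) else
      tibble::tibble(object_id = integer(), part = character(), cx = numeric(),
                     cy = numeric(), a = numeric(), b = numeric(),
                     theta = numeric()),
    labels = labels, ids = seq_len(n_total), config = config
  ), class = "rs_dataset")
}

#' @export
print.rs_dataset <- function(x, ...) {
  cat(sprintf("<rs_dataset> %d positives + %d negatives, %dx%d px, separation %.2f (seed %d)\n",
              sum(x$labels), sum(!x$labels), x$config$image_size,
              x$config$image_size, x$config$separation, x$config$seed))
  invisible(x)
}

#' Write / read a dataset directory (`images/*.png`, `masks/*.png`,
#' `annotations.csv`, `manifest.json`)
#'
#' @param dataset an `rs_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("scene_%04d.png", dataset$ids)
  for (i in seq_along(dataset$scenes)) {
    write_scene(dataset$scenes[[i]], file.path(dir, "images", files[i]))
    if (!is.null(dataset$masks[[i]]))
      write_scene(dataset$masks[[i]] * 255, file.path(dir, "masks", files[i]))
  }
  write_annotations(dataset$annotations, file.path(dir, "annotations.csv"))
  jsonlite::write_json(list(
    files = files, labels = dataset$labels, ids = dataset$ids,
    image_size = dataset$config$image_size,
    separation = dataset$config$separation,
    n_parts = dataset$config$n_parts, seed = dataset$config$seed
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  scenes <- lapply(man$files, function(f) read_scene(file.path(dir, "images", f)))
  masks <- lapply(seq_along(man$files), function(i) {
    p <- file.path(dir, "masks", man$files[i])
    if (file.exists(p)) read_scene(p) > 127 else NULL
  })
  structure(list(
    scenes = scenes, masks = masks,
    annotations = read_annotations(file.path(dir, "annotations.csv")),
    labels = man$labels, ids = man$ids,
    config = generator_config(image_size = man$image_size,
                              n_positive = sum(man$labels),
                              n_negative = sum(!man$labels),
                              n_parts = man$n_parts,
                              separation = man$separation, seed = man$seed)
  ), class = "rs_dataset")
}
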