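#' Local Michelson contrast with a circular center-surround configuration
#'
#' Converts a grayscale luminance image into a map of local Michelson contrast,
#' the input representation of the whole pipeline. At each pixel the contrast is
#' \deqn{c = (\mu_c - \mu_s) / (\mu_c + \mu_s + \epsilon)}
#' where \eqn{\mu_c} is the mean luminance in the disk of radius `r_center`
#' centered at the pixel and \eqn{\mu_s} the mean luminance in the annulus
#' `(r_center, r_surround]`. Borders are handled by reflective padding, so the
#' map has the same extent as the input. The stabilizer
#' \eqn{\epsilon = 10^{-6} \max(I)} keeps all-black neighborhoods finite; with
#' it, a constant image maps to exactly zero contrast and all values lie in
#' \eqn{[-1, 1]}.
#'
#' @param image numeric matrix of luminances (rows = y, columns = x), e.g. 8-bit
#'   values in `[0, 255]`. Values must be nonnegative.
#' @param r_center radius in pixels of the center disk (`>= 1`).
#' @param r_surround radius in pixels of the surround (`> r_center`). A pixel at
#'   Euclidean distance `d` from the center belongs to the center iff
#'   `d <= r_center` and to the surround iff `r_center < d <= r_surround`.
#' @return a `contrast_image`: a numeric matrix of contrasts in `[-1, 1]` with
#'   the same dimensions as `image` and attribute `params = c(r_center,
#'   r_surround)`.
#' @seealso [select_contrast_params()] for the per-scene-class radii.
#' @examples
#' img <- matrix(128, 32, 32)
#' img[10:20, 10:20] <- 200
#' cm <- michelson_contrast(img, 2, 4)
#' range(cm)
#' @export
michelson_contrast <- function(image, r_center = 2, r_surround = 4) {
  if (!is.matrix(image) || length(image) == 0L)
    abort_param("`image` must be a non-empty numeric matrix")
  if (!is.numeric(r_center) || !is.numeric(r_surround) ||
      r_center < 1 || r_surround <= r_center)
    abort_param("radii must satisfy r_surround > r_center >= 1")
  storage.mode(image) <- "double"

  r <- as.integer(ceiling(r_surround))
  padded <- pad_reflect(image, r)
  h <- nrow(image); w <- ncol(image)

  off <- expand.grid(dy = -r:r, dx = -r:r)
  d <- sqrt(off$dy^2 + off$dx^2)
  in_center <- d <= r_center
  in_surround <- d > r_center & d <= r_surround

  sum_c <- matrix(0, h, w); sum_s <- matrix(0, h, w)
  for (k in seq_len(nrow(off))) {
    if (!in_center[k] && !in_surround[k]) next
    block <- padded[(1 + r + off$dy[k]):(h + r + off$dy[k]),
                    (1 + r + off$dx[k]):(w + r + off$dx[k])]
    if (in_center[k]) sum_c <- sum_c + block else sum_s <- sum_s + block
  }
  mu_c <- sum_c / sum(in_center)
  mu_s <- sum_s / sum(in_surround)
  eps <- 1e-6 * max(image)
  if (eps <= 0) eps <- .Machine$double.eps
  values <- (mu_c - mu_s) / (mu_c + mu_s + eps)

  structure(values,
            params = c(r_center = r_center, r_surround = r_surround),
            class = c("contrast_image", "matrix", "array"))
}

#' Contrast radii for a scene class
#'
#' Standard scenes use a center radius of 2 px and a surround radius of 4 px;
#' far-body scenes (where objects occupy few pixels) use 1 px and 2 px.
#'
#' @param scene_class `"standard"` or `"far_body"`.
#' @return named numeric vector `c(r_center, r_surround)`.
#' @export
select_contrast_params <- function(scene_class = c("standard", "far_body")) {
  if (length(scene_class) != 1L || !scene_class %in% c("standard", "far_body"))
    abort_param("`scene_class` must be \"standard\" or \"far_body\"")
  if (scene_class == "standard") c(r_center = 2, r_surround = 4)
  else c(r_center = 1, r_surround = 2)
}

# Reflective (mirror, edge not repeated) padding by `r` pixels on every side.
pad_reflect <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  if (r >= h || r >= w) abort_param("padding radius exceeds image size")
  ri <- c((r + 1):2, 1:h, (h - 1):(h - r))
  ci <- c((r + 1):2, 1:w, (w - 1):(w - r))
  x[ri, ci]
}

#' @export
print.contrast_image <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<contrast_image> %d x %d, r_center = %g, r_surround = %g, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), p[1], p[2], min(x), max(x)))
  invisible(x)
}

#' Read an 8-bit grayscale image (PNG or PGM) as a luminance matrix
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @return numeric matrix with values in `[0, 255]` (rows = y, columns = x).
#' @export
read_scene <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a * 255
  } else if (ext == "pgm") {
    read_pgm(path)
  } else abort_param(paste0("unsupported image format: ", ext))
}

#' Write a luminance matrix as an 8-bit grayscale PNG
#'
#' @param image numeric matrix; values are clipped to `[0, 255]`.
#' @param path output path.
#' @export
write_scene <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

# Plain (P2) or binary (P5, 8-bit) PGM reader.
read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) abort_data("not an 8-bit PGM file")
  tokens <- integer(0)
  # header: width, height, maxval, with '#' comments allowed
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (ch == "#") { while (readChar(con, 1L) != "\n") NULL; ch <- " " }
    if (grepl("[0-9]", ch)) buf <- c(buf, ch)
    else if (length(buf)) { tokens <- c(tokens, as.integer(paste(buf, collapse = ""))); buf <- character(0) }
  }
  w <- tokens[1]; h <- tokens[2]
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Save a contrast map as a flat 32-bit float binary plus JSON header
#'
#' The binary holds the values in column-major order; `<path>.json` records the
#' dimensions and radii so the map can be reloaded with [load_contrast()].
#'
#' @param cm a `contrast_image`.
#' @param path output path for the binary; a sidecar `<path>.json` is written.
#' @param preview optional path for a rescaled 8-bit PNG preview.
#' @export
save_contrast <- function(cm, path, preview = NULL) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(cm), con, size = 4L)
  p <- attr(cm, "params")
  jsonlite::write_json(
    list(height = nrow(cm), width = ncol(cm),
         r_center = unname(p[1]), r_surround = unname(p[2])),
    paste0(path, ".json"), auto_unbox = TRUE)
  if (!is.null(preview))
    write_scene((cm - min(cm)) / max(max(cm) - min(cm), 1e-12) * 255, preview)
  invisible(path)
}

#' @rdname save_contrast
#' @export
load_contrast <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "numeric", n = meta$height * meta$width, size = 4L)
  structure(matrix(vals, meta$height, meta$width),
            params = c(r_center = meta$r_center, r_surround = meta$r_surround),
            class = c("contrast_image", "matrix", "array"))
}
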