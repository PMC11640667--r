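# Shared pixel utilities. Frames are numeric matrices (grayscale, rows = y)
# or h x w x 3 arrays (RGB), with intensities on the 8-bit [0, 255] scale.

clip8 <- function(x) pmin(pmax(x, 0), 255)

is_frame <- function(x) {
  (is.matrix(x) && is.numeric(x)) ||
    (is.array(x) && is.numeric(x) && length(dim(x)) == 3L)
}

assert_frame <- function(x, what = "image") {
  if (!is_frame(x) || any(dim(x) == 0L)) {
    stop("invalid-image: ", what, " must be a non-empty numeric matrix or array",
         call. = FALSE)
  }
  invisible(x)
}

#' Convert an RGB frame to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114).
#' Grayscale input is returned unchanged.
#'
#' @param img Numeric matrix (grayscale) or h x w x 3 array (RGB),
#'   intensities in `[0, 255]`.
#' @return Numeric matrix of the same height and width.
#' @export
to_grayscale <- function(img) {
  assert_frame(img)
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Bilinear image resize
#'
#' Resamples a frame to a new size by bilinear interpolation. Output pixel
#' centres are mapped to input coordinates via
#' `src = (i + 0.5) * in/out - 0.5` (no corner alignment), clamped at the
#' image border; aspect ratio is not preserved. When the output size equals
#' the input size the image is returned pixel-identically.
#'
#' @param img Frame (matrix or 3-channel array).
#' @param out_h,out_w Output height and width in pixels.
#' @return Resized frame of the same kind as the input.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  assert_frame(img)
  stopifnot(out_h >= 1, out_w >= 1)
  if (is.array(img) && length(dim(img)) == 3L) {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (k in seq_len(dim(img)[3])) out[, , k] <- bilinear_resize(img[, , k], out_h, out_w)
    return(out)
  }
  in_h <- nrow(img); in_w <- ncol(img)
  sy <- (seq_len(out_h) - 0.5) * in_h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * in_w / out_w - 0.5
  sy <- pmin(pmax(sy, 0), in_h - 1)
  sx <- pmin(pmax(sx, 0), in_w - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- matrix(sy - y0, out_h, out_w)
  wx <- matrix(sx - x0, out_h, out_w, byrow = TRUE)
  A <- img[y0 + 1, x0 + 1, drop = FALSE]
  B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]
  D <- img[y1 + 1, x1 + 1, drop = FALSE]
  (A * (1 - wy) + C * wy) * (1 - wx) + (B * (1 - wy) + D * wy) * wx
}

#' Write a frame to a PNG file
#'
#' Intensities are rounded to 8-bit levels on write, so integer-valued
#' frames round-trip exactly through [read_frame_png()].
#'
#' @param img Frame with intensities in `[0, 255]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  assert_frame(img)
  png::writePNG(clip8(img) / 255, target = path)
  invisible(path)
}

#' Read a frame from a PNG file
#'
#' @param path PNG file path.
#' @param grayscale Collapse colour channels to BT.601 luminance
#'   (default `TRUE`).
#' @return Frame with intensities in `[0, 255]`.
#' @export
read_frame_png <- function(path, grayscale = TRUE) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
    if (grayscale) x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else if (length(dim(x)) == 3L) {
    x <- x[, , 1]
  }
  x * 255
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stable sub-seed from a base seed and a string key
#'
#' Hashes `key` into a 31-bit integer seed deterministically, so that
#' independent pipeline stages (or views, classes, episodes) draw from
#' decorrelated RNG streams while the whole run stays reproducible from a
#' single master seed.
#'
#' @param seed Base integer seed.
#' @param key Character key naming the stream.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
seed_from <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}
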