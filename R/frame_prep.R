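# Frame extraction, near-duplicate removal and ROI standardisation.
#
# Video stills arrive as bursts of almost identical frames. Two filters
# thin them: a 64-bit difference hash (drop when the Hamming distance to
# the last retained frame is below a threshold, default 5) and the
# structural similarity index (drop when SSIM against the last retained
# frame is at or above a threshold, default 0.7). Both scan sequentially
# and always keep the first frame, comparing each candidate to the most
# recently *retained* frame so a slow drift cannot chain-delete the whole
# sequence.

#' Subsample an ordered frame sequence at a fixed interval
#'
#' Keeps frames at positions 0, `interval`, `2*interval`, ... (0-based),
#' preserving order. The default interval of 30 corresponds to one still
#' every half second of 60 fps video.
#'
#' @param frames List (or vector) of frames in source order.
#' @param interval Positive integer sampling interval.
#' @return Subsequence of `frames`; empty input yields empty output.
#' @export
extract_frames <- function(frames, interval = 30L) {
  stopifnot(interval >= 1)
  n <- length(frames)
  if (n == 0L) return(frames[0])
  frames[seq(1L, n, by = as.integer(interval))]
}

#' 64-bit difference hash of a frame
#'
#' Canonical dHash: convert to grayscale, resize to 9 columns by 8 rows
#' (bilinear), then set bit `(r, c)` to 1 iff `pixel(r, c) > pixel(r, c+1)`,
#' packed row-major into 64 bits. A constant image hashes to all zeros
#' (the strict inequality never fires).
#'
#' @param image Frame (grayscale matrix or RGB array).
#' @return Integer vector of 64 bits (0/1) with class `perceptual_hash`.
#' @export
compute_dhash <- function(image) {
  assert_frame(image)
  g <- bilinear_resize(to_grayscale(image), 8L, 9L)
  bits <- t(g[, 1:8] > g[, 2:9]) # transpose -> row-major packing
  structure(as.integer(bits), class = "perceptual_hash")
}

#' Hamming distance between two 64-bit perceptual hashes
#'
#' @param a,b Objects returned by [compute_dhash()] (or any 64-element
#'   0/1 vectors).
#' @return Integer in `[0, 64]`: the number of differing bit positions.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != 64L || length(b) != 64L)
    stop("invalid-hash: perceptual hashes must have exactly 64 bits", call. = FALSE)
  sum(as.integer(a) != as.integer(b))
}

#' Remove near-duplicate frames by difference hash
#'
#' Sequential scan: a frame is dropped iff the Hamming distance between its
#' dHash and that of the most recently retained frame is strictly below
#' `threshold`. The first frame is always retained. `threshold = 0` retains
#' everything (a distance below 0 is impossible).
#'
#' @param frames List of frames in source order.
#' @param threshold Integer in `[0, 64]`; default 5.
#' @return List with `frames` (retained frames, original order) and `keep`
#'   (logical vector over the input).
#' @export
dedup_by_dhash <- function(frames, threshold = 5L) {
  stopifnot(threshold >= 0, threshold <= 64)
  n <- length(frames)
  keep <- logical(n)
  if (n > 0L) {
    keep[1] <- TRUE
    anchor <- compute_dhash(frames[[1]])
    for (i in seq_len(n)[-1]) {
      h <- compute_dhash(frames[[i]])
      if (hamming_distance(h, anchor) < threshold) next
      keep[i] <- TRUE
      anchor <- h
    }
  }
  list(frames = frames[keep], keep = keep)
}

# Valid-mode separable 2-D weighted windowing used by compute_ssim: returns
# the per-window weighted mean of M under the 1-D kernel k (applied to
# columns then rows; k sums to 1).
conv_valid <- function(M, k) {
  w <- length(k)
  Tn <- function(n) {
    # n_out x n banded operator applying k
    n_out <- n - w + 1L
    Tm <- matrix(0, n_out, n)
    for (i in seq_len(n_out)) Tm[i, i:(i + w - 1L)] <- k
    Tm
  }
  Tn(nrow(M)) %*% M %*% t(Tn(ncol(M)))
}

#' Structural similarity index between two frames
#'
#' Windowed SSIM (Wang et al.): by default an 11x11 Gaussian window with
#' sigma 1.5, stability constants `K1 = 0.01`, `K2 = 0.03` and dynamic
#' range `L = 255`, averaged over all fully interior windows. Window
#' statistics use the normalised window weights (population moments).
#' Symmetric in its arguments; identical frames score exactly 1. RGB input
#' is converted to luminance first.
#'
#' @param a,b Frames of equal dimensions.
#' @param window Odd window side length; may equal the image side, in which
#'   case a single global window is used.
#' @param sigma Gaussian window standard deviation (pixels); ignored when
#'   `gaussian = FALSE`.
#' @param gaussian Use Gaussian window weights (default) or uniform ones.
#' @param K1,K2,L Stability constants and dynamic range.
#' @return Scalar in `[-1, 1]`.
#' @export
compute_ssim <- function(a, b, window = 11L, sigma = 1.5, gaussian = TRUE,
                         K1 = 0.01, K2 = 0.03, L = 255) {
  assert_frame(a); assert_frame(b)
  a <- to_grayscale(a); b <- to_grayscale(b)
  if (!all(dim(a) == dim(b)))
    stop("invalid-pair: frames must have identical dimensions", call. = FALSE)
  if (window > min(dim(a)))
    stop("invalid-pair: window larger than the frames", call. = FALSE)
  k <- if (gaussian) {
    x <- seq_len(window) - (window + 1) / 2
    kk <- exp(-x^2 / (2 * sigma^2)); kk / sum(kk)
  } else rep(1 / window, window)

  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- conv_valid(a, k);      mu2 <- conv_valid(b, k)
  s11 <- conv_valid(a * a, k) - mu1^2
  s22 <- conv_valid(b * b, k) - mu2^2
  s12 <- conv_valid(a * b, k) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map)
}

#' Remove near-duplicate frames by structural similarity
#'
#' Sequential scan: a frame is dropped iff its SSIM against the most
#' recently retained frame is at or above `threshold` (high similarity =
#' delete). The first frame is always retained.
#'
#' @param frames List of frames in source order.
#' @param threshold SSIM deletion threshold in `[-1, 1]`; default 0.7.
#' @param ... Passed to [compute_ssim()].
#' @return List with `frames` (retained) and `keep` (logical vector).
#' @export
dedup_by_ssim <- function(frames, threshold = 0.7, ...) {
  stopifnot(threshold >= -1, threshold <= 1)
  n <- length(frames)
  keep <- logical(n)
  if (n > 0L) {
    keep[1] <- TRUE
    anchor <- frames[[1]]
    for (i in seq_len(n)[-1]) {
      if (compute_ssim(frames[[i]], anchor, ...) >= threshold) next
      keep[i] <- TRUE
      anchor <- frames[[i]]
    }
  }
  list(frames = frames[keep], keep = keep)
}

#' Crop a region of interest and resize it to a fixed size
#'
#' The box is given in pixel units, 0-based and half-open
#' (`x_min <= x < x_max`, `y_min <= y < y_max`, x = column). The crop is
#' resized by bilinear interpolation to exactly `size`; aspect ratio is not
#' preserved. A full-image box at the target size returns the input
#' pixel-identically.
#'
#' @param image Frame.
#' @param box Numeric `c(x_min, y_min, x_max, y_max)`.
#' @param size Output `c(height, width)`; default `c(224, 224)`.
#' @return Frame of dimensions `size`.
#' @export
crop_resize_roi <- function(image, box, size = c(224L, 224L)) {
  assert_frame(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  box <- as.numeric(box)
  if (length(box) != 4L || box[1] < 0 || box[2] < 0 ||
      box[3] > w || box[4] > h || box[3] <= box[1] || box[4] <= box[2])
    stop("invalid-box: box must be within bounds with positive area", call. = FALSE)
  rows <- (box[2] + 1):box[4]
  cols <- (box[1] + 1):box[3]
  crop <- if (is.matrix(image)) image[rows, cols, drop = FALSE]
          else image[rows, cols, , drop = FALSE]
  bilinear_resize(crop, size[1], size[2])
}

#' Variance-of-Laplacian sharpness score
#'
#' Optional stand-in for manual curation of blurred frames: the variance of
#' the 4-neighbour Laplacian response. Blurred images score low; frames can
#' be discarded below a user-chosen cutoff. Disabled by default in the
#' pipeline.
#'
#' @param image Frame.
#' @return Non-negative scalar sharpness score.
#' @export
sharpness_score <- function(image) {
  g <- to_grayscale(image)
  h <- nrow(g); w <- ncol(g)
  if (h < 3 || w < 3) return(0)
  core <- g[2:(h - 1), 2:(w - 1)]
  lap <- g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
    g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] - 4 * core
  mean((lap - mean(lap))^2)
}
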