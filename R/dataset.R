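# Balanced dataset construction. Works at two levels: pixel-level
# augmentation of individual frames (augment_image) and manifest-level
# planning (make_test_split / balance_manifest / make_train_val_split),
# which records *what* to augment without materialising pixels -- augmented
# frames are rendered lazily by load_frame() when a classifier asks for
# them. Test extraction precedes balancing, and augmented descendants never
# enter the test split.

AUG_OPS <- c("horizontal_mirror", "random_rotation", "translation",
             "brighten", "darken")

#' Configure per-class augmentation and balancing
#'
#' @param target_per_class Per-class image count after balancing
#'   (default 450).
#' @param ops Augmentation operations to sample from; subset of
#'   `horizontal_mirror`, `random_rotation`, `translation`, `brighten`,
#'   `darken`.
#' @param rotation_range Maximum absolute rotation in degrees (default 15).
#' @param translation_range Maximum translation as a fraction of each
#'   dimension (default 0.1), with edge reflection.
#' @param brightness_factors Length-2 multipliers for brighten/darken
#'   (default `c(1.25, 0.75)`), clipped to `[0, 255]`.
#' @param seed RNG seed for all sampling decisions.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(target_per_class = 450L, ops = AUG_OPS,
                                rotation_range = 15, translation_range = 0.1,
                                brightness_factors = c(1.25, 0.75),
                                seed = 0L) {
  stopifnot(target_per_class >= 1, rotation_range > 0, translation_range > 0,
            length(brightness_factors) == 2, all(brightness_factors > 0))
  if (!all(ops %in% AUG_OPS))
    stop("invalid-augmentation: unknown op(s) ",
         paste(setdiff(ops, AUG_OPS), collapse = ", "), call. = FALSE)
  structure(list(target_per_class = as.integer(target_per_class), ops = ops,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 brightness_factors = brightness_factors, seed = seed),
            class = "augmentation_config")
}

# index with edge reflection, 1-based
reflect_index <- function(i, n) {
  i <- abs(i - 1) %% (2 * n - 2)
  ifelse(i >= n, 2 * n - 2 - i, i) + 1
}

# sample a frame at fractional coordinates with bilinear interpolation and
# edge clamping (exact at integer coordinates)
sample_bilinear <- function(img, ys, xs) {
  h <- nrow(img); w <- ncol(img)
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  wy <- ys - y0; wx <- xs - x0
  img[cbind(y0, x0)] * (1 - wy) * (1 - wx) +
    img[cbind(y0, x1)] * (1 - wy) * wx +
    img[cbind(y1, x0)] * wy * (1 - wx) +
    img[cbind(y1, x1)] * wy * wx
}

#' Apply one augmentation operation to a frame
#'
#' Operations preserve the image dimensions and are deterministic for a
#' fixed `seed`. `horizontal_mirror` is an involution; `random_rotation`
#' rotates about the image centre by a uniformly drawn angle (bilinear
#' resampling, edge clamping; an explicit `params$angle = 0` returns the
#' input exactly); `translation` shifts by a uniformly drawn offset with
#' edge reflection; `brighten`/`darken` multiply intensities and clip to
#' `[0, 255]`.
#'
#' @param image Grayscale frame (matrix).
#' @param op Operation name (see [augmentation_config()]).
#' @param cfg An [augmentation_config()] supplying magnitude ranges.
#' @param seed Seed for the sampled magnitudes.
#' @param params Optional list overriding sampled magnitudes: `angle`
#'   (degrees), `dx`/`dy` (pixels), `factor`.
#' @return Augmented frame, same dimensions.
#' @export
augment_image <- function(image, op, cfg = augmentation_config(), seed = 0L,
                          params = list()) {
  assert_frame(image)
  if (!(op %in% AUG_OPS))
    stop("invalid-augmentation: unknown op ", op, call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  draw <- function(expr) with_seed(seed_from(seed, op), expr)
  switch(op,
    horizontal_mirror = image[, w:1, drop = FALSE],
    random_rotation = {
      ang <- if (!is.null(params$angle)) params$angle
             else draw(runif(1, -cfg$rotation_range, cfg$rotation_range))
      if (ang == 0) return(image)
      th <- ang * pi / 180
      cy <- (h + 1) / 2; cx <- (w + 1) / 2
      Y <- matrix(seq_len(h), h, w) - cy
      X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
      # inverse rotation of the output grid into the source image
      ys <- cy + (-sin(-th)) * X + cos(-th) * Y
      xs <- cx + cos(-th) * X + sin(-th) * Y
      matrix(sample_bilinear(image, as.vector(ys), as.vector(xs)), h, w)
    },
    translation = {
      if (!is.null(params$dx)) { dx <- params$dx; dy <- params$dy }
      else {
        sh <- draw(runif(2, -cfg$translation_range, cfg$translation_range))
        dx <- round(sh[1] * w); dy <- round(sh[2] * h)
      }
      image[reflect_index(seq_len(h) - dy, h),
            reflect_index(seq_len(w) - dx, w), drop = FALSE]
    },
    brighten = clip8(image * (params$factor %||% cfg$brightness_factors[1])),
    darken = clip8(image * (params$factor %||% cfg$brightness_factors[2]))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mark a per-class test split on a manifest
#'
#' Randomly selects `per_class` pre-augmentation images from every
#' (identity, view) class and marks them `"test"`; the rest stay
#' `"unassigned"` until balancing. Test images are never augmented nor used
#' as augmentation sources. Fails if any class does not exceed `per_class`
#' images.
#'
#' @param manifest Manifest `data.frame` (see [simulate_herd_manifest()]).
#' @param per_class Test images per class (default 20).
#' @param seed RNG seed; a fixed seed reproduces the exact membership.
#' @return Manifest with the `split` column updated.
#' @export
make_test_split <- function(manifest, per_class = 20L, seed = 0L) {
  stopifnot(is.data.frame(manifest), per_class >= 0)
  if (any(manifest$is_augmented))
    stop("split-infeasible: test split must precede augmentation", call. = FALSE)
  if (per_class == 0L) return(manifest)
  cls <- interaction(manifest$identity, manifest$view, drop = TRUE)
  for (g in levels(cls)) {
    idx <- which(cls == g)
    if (length(idx) <= per_class)
      stop("split-infeasible: class ", g, " has only ", length(idx),
           " images (need more than ", per_class, ")", call. = FALSE)
    pick <- with_seed(seed_from(seed, paste0("test-", g)),
                      sample(idx, per_class))
    manifest$split[pick] <- "test"
  }
  manifest
}

#' Balance every class to a fixed image count via planned augmentation
#'
#' For each (identity, view) class, non-test originals are kept and the
#' deficit up to `cfg$target_per_class` is filled with augmentation records
#' (a uniformly sampled source original plus a uniformly sampled operation
#' and magnitude seed); a surplus is reduced by seeded subsampling without
#' replacement. The returned records carry `is_augmented`, `source_path`,
#' `op` and `aug_seed` so pixels can be produced on demand by
#' [load_frame()].
#'
#' @param manifest Manifest after [make_test_split()].
#' @param cfg An [augmentation_config()].
#' @return Manifest whose non-test portion has exactly
#'   `cfg$target_per_class` rows per class, each marked `split = "balanced"`
#'   pending [make_train_val_split()]; test rows pass through unchanged.
#' @export
balance_manifest <- function(manifest, cfg = augmentation_config()) {
  stopifnot(is.data.frame(manifest))
  if (!"aug_seed" %in% names(manifest))
    manifest$aug_seed <- rep(NA_integer_, nrow(manifest))
  test_rows <- manifest[manifest$split == "test", , drop = FALSE]
  pool <- manifest[manifest$split != "test", , drop = FALSE]
  if (nrow(pool) == 0L) stop("empty-class: nothing to balance", call. = FALSE)
  target <- cfg$target_per_class
  cls <- interaction(pool$identity, pool$view, drop = TRUE)
  out <- vector("list", nlevels(cls))
  for (k in seq_len(nlevels(cls))) {
    g <- levels(cls)[k]
    rows <- pool[cls == g, , drop = FALSE]
    n <- nrow(rows)
    if (n >= target) {
      keep <- with_seed(seed_from(cfg$seed, paste0("sub-", g)), {
        if (n > target) sort(sample.int(n, target)) else seq_len(n)
      })
      res <- rows[keep, , drop = FALSE]
    } else {
      deficit <- target - n
      plan <- with_seed(seed_from(cfg$seed, paste0("aug-", g)), {
        list(src = sample.int(n, deficit, replace = TRUE),
             op = sample(cfg$ops, deficit, replace = TRUE),
             sd = sample.int(2147483646L, deficit))
      })
      aug <- rows[plan$src, , drop = FALSE]
      aug$source_path <- aug$path
      aug$path <- sprintf("%s#aug%03d", aug$path, seq_len(deficit))
      aug$is_augmented <- TRUE
      aug$op <- plan$op
      aug$aug_seed <- plan$sd
      res <- rbind(rows, aug)
    }
    res$split <- "balanced"
    out[[k]] <- res
  }
  res <- do.call(rbind, c(list(test_rows), out))
  rownames(res) <- NULL
  res
}

#' Stratified train/validation split of the balanced records
#'
#' Splits the balanced (non-test) records of every class into training and
#' validation sets; `round(val_fraction * n)` images per class go to
#' validation. Test rows are untouched and remain disjoint by path.
#'
#' @param manifest Manifest after [balance_manifest()].
#' @param val_fraction Validation fraction (default 0.2, i.e. an 8:2
#'   train/validation split).
#' @param seed RNG seed.
#' @return Manifest with `split` in `train`/`val`/`test`.
#' @export
make_train_val_split <- function(manifest, val_fraction = 0.2, seed = 0L) {
  stopifnot(is.data.frame(manifest), val_fraction >= 0, val_fraction < 1)
  pool <- which(manifest$split %in% c("balanced", "unassigned"))
  cls <- interaction(manifest$identity[pool], manifest$view[pool], drop = TRUE)
  manifest$split[pool] <- "train"
  for (g in levels(cls)) {
    idx <- pool[cls == g]
    n_val <- round(val_fraction * length(idx))
    if (n_val > 0) {
      pick <- with_seed(seed_from(seed, paste0("val-", g)), sample(idx, n_val))
      manifest$split[pick] <- "val"
    }
  }
  manifest
}

#' Balance one class's images in memory
#'
#' Pixel-level counterpart of [balance_manifest()] for a single
#' (identity, view) class: returns exactly `cfg$target_per_class` frames,
#' originals first (subsampled when in surplus), the deficit filled with
#' augmented copies.
#'
#' @param images List of frames belonging to one class.
#' @param cfg An [augmentation_config()].
#' @return List of `cfg$target_per_class` frames; augmented entries carry
#'   attributes `source` (index) and `op`.
#' @export
balance_class <- function(images, cfg = augmentation_config()) {
  n <- length(images)
  if (n == 0L) stop("empty-class: no source images", call. = FALSE)
  target <- cfg$target_per_class
  if (n >= target) {
    keep <- with_seed(seed_from(cfg$seed, "sub-class"), {
      if (n > target) sort(sample.int(n, target)) else seq_len(n)
    })
    return(images[keep])
  }
  deficit <- target - n
  plan <- with_seed(seed_from(cfg$seed, "aug-class"), {
    list(src = sample.int(n, deficit, replace = TRUE),
         op = sample(cfg$ops, deficit, replace = TRUE),
         sd = sample.int(2147483646L, deficit))
  })
  aug <- lapply(seq_len(deficit), function(i) {
    img <- augment_image(images[[plan$src[i]]], plan$op[i], cfg,
                         seed = plan$sd[i])
    attr(img, "source") <- plan$src[i]
    attr(img, "op") <- plan$op[i]
    img
  })
  c(images, aug)
}

#' Load the pixels for one manifest record
#'
#' Resolves a manifest row to a frame: plain rows are read from disk (or an
#' in-memory store), augmented rows load their source frame and re-apply
#' the recorded operation with the recorded seed.
#'
#' @param record One-row slice of a manifest.
#' @param images Optional named list mapping paths to in-memory frames
#'   (used by the synthetic pipeline to avoid disk I/O).
#' @param root Directory prepended to relative paths when reading PNGs.
#' @param cfg Augmentation config governing magnitudes of re-applied ops.
#' @return Grayscale frame.
#' @export
load_frame <- function(record, images = NULL, root = ".",
                       cfg = augmentation_config()) {
  fetch <- function(p) {
    if (!is.null(images) && p %in% names(images)) return(images[[p]])
    read_frame_png(file.path(root, p))
  }
  if (isTRUE(record$is_augmented)) {
    src <- fetch(record$source_path)
    augment_image(src, record$op, cfg, seed = record$aug_seed)
  } else {
    fetch(record$path)
  }
}
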