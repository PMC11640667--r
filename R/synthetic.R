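# Synthetic multi-view herd generator.
#
# Each individual carries a "signature": a band-limited sinusoidal texture
# (4 components with per-identity amplitude, frequency and phase) plus 3
# shape parameters describing an elliptical body blob. A camera view renders
# a fraction of that signature (its "informativeness") together with
# view-specific nuisance: global lighting jitter, pose jitter (texture
# translation), a smooth per-frame random field, per-pixel noise and --
# for the top-down back view -- a bright exposure artifact. The default view
# profile makes the side body (S) the most informative view and the two
# side faces (L, R) the least, so downstream classifiers reproduce the
# qualitative per-view accuracy ordering S >= B >= F >= {L, R}.

#' Create a bank of synthetic individual identities
#'
#' Draws one signature per individual: 4 texture components (amplitude,
#' x-frequency, y-frequency, phase) and 3 shape parameters (ellipse centre
#' and radius). Signatures are pairwise distinct and a fixed `(n, seed)`
#' pair always reproduces the same bank.
#'
#' @param n Number of individuals (herd size), at least 2.
#' @param seed RNG seed.
#' @return An object of class `identity_bank` with fields `n_identities`,
#'   `seed` and `signatures` (an `n x 19` matrix, one row per individual).
#' @export
make_identity_bank <- function(n, seed = 0L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("invalid-herd-size: need at least 2 identities", call. = FALSE)
  n <- as.integer(n)
  sig <- with_seed(seed_from(seed, "identity-bank"), {
    cbind(
      matrix(runif(n * 4L, 0.5, 1.0), n, 4L),   # component amplitudes
      matrix(runif(n * 4L, 2.0, 6.0), n, 4L),   # x frequencies (cycles)
      matrix(runif(n * 4L, 2.0, 6.0), n, 4L),   # y frequencies
      matrix(runif(n * 4L, 0, 2 * pi), n, 4L),  # phases
      matrix(runif(n * 2L, 0.40, 0.60), n, 2L), # ellipse centre
      matrix(runif(n, 0.18, 0.30), n, 1L)       # ellipse radius
    )
  })
  colnames(sig) <- c(paste0("amp", 1:4), paste0("fx", 1:4), paste0("fy", 1:4),
                     paste0("ph", 1:4), "cx", "cy", "r")
  rownames(sig) <- identity_labels(n)
  structure(list(n_identities = n, seed = seed, signatures = sig),
            class = "identity_bank")
}

#' Zero-padded identity labels
#'
#' @param n Herd size.
#' @return Character vector `"0001" ... sprintf("%04d", n)`.
#' @export
identity_labels <- function(n) sprintf("%04d", seq_len(n))

#' @export
print.identity_bank <- function(x, ...) {
  cat("identity_bank:", x$n_identities, "individuals, seed", x$seed, "\n")
  invisible(x)
}

VIEW_LABELS <- c("L", "F", "R", "B", "S")

#' Describe a synthetic camera view
#'
#' @param view View label, one of `"L"`, `"F"`, `"R"`, `"B"`, `"S"`.
#' @param informativeness Fraction in `[0, 1]` of the identity signature
#'   rendered into this view; higher means more identity signal.
#' @param lighting_sd Standard deviation of the per-frame global lighting
#'   offset (intensity levels).
#' @param pose_jitter Per-frame texture translation amplitude as a fraction
#'   of the image dimension.
#' @param field_sd Amplitude of a smooth per-frame random field (levels);
#'   this is what makes distinct frames of the same animal look different.
#' @param noise_sd Per-pixel Gaussian noise standard deviation (levels).
#' @param exposure_artifact Add a bright per-frame exposure blob (used for
#'   the top-down back view, which suffers from uneven natural lighting).
#' @return An object of class `view_spec`.
#' @export
view_spec <- function(view, informativeness = 1, lighting_sd = 5,
                      pose_jitter = 0.02, field_sd = 8, noise_sd = 6,
                      exposure_artifact = FALSE) {
  if (!is.character(view) || length(view) != 1L || !(view %in% VIEW_LABELS))
    stop("invalid-view: view must be one of ", paste(VIEW_LABELS, collapse = ", "),
         call. = FALSE)
  stopifnot(informativeness >= 0, informativeness <= 1,
            lighting_sd >= 0, pose_jitter >= 0, field_sd >= 0, noise_sd >= 0)
  structure(list(view = view, informativeness = informativeness,
                 lighting_sd = lighting_sd, pose_jitter = pose_jitter,
                 field_sd = field_sd, noise_sd = noise_sd,
                 exposure_artifact = isTRUE(exposure_artifact)),
            class = "view_spec")
}

#' Default five-view nuisance profile
#'
#' The side body (S) view is the most stable and informative; the back body
#' (B) is close behind but carries an exposure artifact; the front face (F)
#' is weaker; the two side faces (L, R) are weakest and noisiest. The
#' informativeness ordering S >= B >= F >= L = R is an invariant of this
#' profile.
#'
#' @return Named list of [view_spec()] objects, one per view label.
#' @export
default_view_profile <- function() {
  list(
    S = view_spec("S", informativeness = 1.00, lighting_sd = 4,
                  pose_jitter = 0.02, field_sd = 6, noise_sd = 6),
    B = view_spec("B", informativeness = 0.85, lighting_sd = 8,
                  pose_jitter = 0.03, field_sd = 7, noise_sd = 6,
                  exposure_artifact = TRUE),
    F = view_spec("F", informativeness = 0.72, lighting_sd = 9,
                  pose_jitter = 0.04, field_sd = 8, noise_sd = 7),
    L = view_spec("L", informativeness = 0.55, lighting_sd = 9,
                  pose_jitter = 0.045, field_sd = 8, noise_sd = 7),
    R = view_spec("R", informativeness = 0.55, lighting_sd = 9,
                  pose_jitter = 0.045, field_sd = 8, noise_sd = 7)
  )
}

# Smooth random field: coarse Gaussian grid upsampled bilinearly.
random_field <- function(size, coarse = 6L) {
  bilinear_resize(matrix(rnorm(coarse * coarse), coarse, coarse), size, size)
}

#' Render one synthetic appearance image
#'
#' Produces an 8-bit grayscale frame embedding the individual's signature
#' scaled by the view's informativeness, plus the view's nuisance terms.
#' The nuisance draw depends only on `(view, frame_seed)`, never on the
#' identity, so at informativeness 0 two individuals render pixel-identical
#' frames under the same jitter seed. The whole render is a pure function
#' of its arguments.
#'
#' @param bank An [make_identity_bank()] object.
#' @param identity Individual index in `1..n_identities`.
#' @param view A [view_spec()].
#' @param frame_seed Per-frame jitter seed.
#' @param size Image side length in pixels (square output; default 64,
#'   use 224 to match typical classifier input).
#' @return `size x size` numeric matrix with integer intensities in
#'   `[0, 255]`.
#' @export
render_view_image <- function(bank, identity, view, frame_seed = 0L, size = 64L) {
  stopifnot(inherits(bank, "identity_bank"))
  if (!inherits(view, "view_spec"))
    stop("invalid-view: expected a view_spec object", call. = FALSE)
  if (identity < 1 || identity > bank$n_identities)
    stop("identity index out of range", call. = FALSE)
  s <- bank$signatures[identity, ]

  # identity-independent nuisance stream
  nuis <- with_seed(seed_from(frame_seed, paste0("frame-", view$view)), {
    list(dx = runif(1, -view$pose_jitter, view$pose_jitter),
         dy = runif(1, -view$pose_jitter, view$pose_jitter),
         light = rnorm(1, 0, view$lighting_sd),
         field = if (view$field_sd > 0) view$field_sd * random_field(size) else 0,
         noise = if (view$noise_sd > 0)
           matrix(rnorm(size * size, 0, view$noise_sd), size, size) else 0,
         exp_cx = runif(1, 0.2, 0.8), exp_cy = runif(1, 0.2, 0.8),
         exp_amp = runif(1, 30, 55))
  })

  xs <- (seq_len(size) - 0.5) / size
  X <- matrix(xs, size, size, byrow = TRUE) + nuis$dx
  Y <- matrix(xs, size, size) + nuis$dy

  tex <- 0
  for (j in 1:4) {
    tex <- tex + s[paste0("amp", j)] *
      sin(2 * pi * (s[paste0("fx", j)] * X + s[paste0("fy", j)] * Y) +
            s[paste0("ph", j)])
  }
  tex <- tex / sqrt(sum(s[paste0("amp", 1:4)]^2) / 2)  # ~unit variance
  body <- ((X - s["cx"])^2 + (Y - s["cy"])^2 < s["r"]^2) * 1.0
  signal <- view$informativeness * (40 * tex + 30 * body)

  px <- 128 + signal + nuis$light + nuis$field + nuis$noise
  if (view$exposure_artifact) {
    px <- px + nuis$exp_amp *
      exp(-(((X - nuis$dx) - nuis$exp_cx)^2 + ((Y - nuis$dy) - nuis$exp_cy)^2) / (2 * 0.18^2))
  }
  round(clip8(px))
}

#' Generate an ordered frame sequence with planted near-duplicates
#'
#' Emulates consecutive video frames of one animal from one view. Each
#' frame after the first is, with probability `dup_rate`, a near-duplicate
#' of its predecessor (the same pixels plus sub-threshold sensor noise);
#' otherwise it is a fresh render with new pose/lighting/field jitter.
#' Ground-truth duplicate flags are returned so deduplication can be
#' scored exactly.
#'
#' @param bank An [make_identity_bank()] object.
#' @param identity Individual index.
#' @param view A [view_spec()].
#' @param n_frames Number of frames, at least 1.
#' @param dup_rate Probability in `[0, 1)` that a frame duplicates its
#'   predecessor.
#' @param seed RNG seed.
#' @param size Image side length.
#' @param scene_strength Multiplier applied to the view's pose jitter,
#'   random field, lighting jitter and pixel noise for fresh
#'   (non-duplicate) frames (default 4). Captures spaced seconds apart
#'   differ by posture shifts and scene drift much larger than the
#'   within-capture nuisance, which is what makes genuinely distinct
#'   frames separable from planted near-duplicates.
#' @return List with `frames` (list of matrices), `duplicate` (logical
#'   vector, `FALSE` for the first frame) and `frame_seeds`.
#' @export
generate_frame_sequence <- function(bank, identity, view, n_frames,
                                    dup_rate = 0, seed = 0L, size = 64L,
                                    scene_strength = 4) {
  stopifnot(n_frames >= 1, dup_rate >= 0, dup_rate < 1, scene_strength > 0)
  view <- view_spec(view$view,
                    informativeness = view$informativeness,
                    lighting_sd = view$lighting_sd * scene_strength,
                    pose_jitter = view$pose_jitter * scene_strength,
                    field_sd = view$field_sd * scene_strength,
                    noise_sd = view$noise_sd * scene_strength,
                    exposure_artifact = view$exposure_artifact)
  n_frames <- as.integer(n_frames)
  plan <- with_seed(seed_from(seed, paste0("seq-", identity, "-", view$view)), {
    list(dup = c(FALSE, runif(n_frames - 1L) < dup_rate),
         fs = sample.int(2147483646L, n_frames),
         noise_seeds = sample.int(2147483646L, n_frames))
  })
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    if (plan$dup[i]) {
      prev <- frames[[i - 1L]]
      frames[[i]] <- with_seed(plan$noise_seeds[i],
        round(clip8(prev + rnorm(length(prev), 0, 0.6))))
    } else {
      frames[[i]] <- render_view_image(bank, identity, view,
                                       frame_seed = plan$fs[i], size = size)
    }
  }
  list(frames = frames, duplicate = plan$dup, frame_seeds = plan$fs)
}

#' Simulate a herd manifest with realistic class imbalance
#'
#' Builds a dataset manifest (no pixels) for `n_identities` individuals
#' across the given views, with per-class image counts drawn uniformly
#' from `count_range`. The default range `[60, 448]` matches the extremes
#' observed in field recordings of a 54-animal herd.
#'
#' @param n_identities Herd size (default 54).
#' @param views View labels (default all five).
#' @param count_range Integer range for per-class image counts.
#' @param seed RNG seed.
#' @return Manifest `data.frame` with columns `path`, `identity`, `view`,
#'   `split` (all `"unassigned"`), `is_augmented`, `source_path`, `op`.
#' @export
simulate_herd_manifest <- function(n_identities = 54L, views = VIEW_LABELS,
                                   count_range = c(60L, 448L), seed = 0L) {
  stopifnot(n_identities >= 1, length(views) >= 1,
            count_range[1] >= 1, count_range[2] >= count_range[1])
  ids <- identity_labels(n_identities)
  recs <- with_seed(seed_from(seed, "herd-manifest"), {
    out <- vector("list", n_identities * length(views))
    k <- 0L
    for (v in views) for (id in ids) {
      k <- k + 1L
      cnt <- sample(count_range[1]:count_range[2], 1L)
      out[[k]] <- data.frame(
        path = sprintf("%s/%s/%05d.png", v, id, seq_len(cnt)),
        identity = id, view = v, split = "unassigned",
        is_augmented = FALSE, source_path = NA_character_,
        op = NA_character_, stringsAsFactors = FALSE)
    }
    out
  })
  do.call(rbind, recs)
}

#' Configure the classifier-confidence simulator
#'
#' @param n_identities Number of identities N (vector length of simulated
#'   confidence vectors).
#' @param per_view_accuracy Named numeric vector mapping view labels to the
#'   target top-1 accuracy of that view's simulated classifier; each value
#'   must exceed chance `1/N` and be at most 1.
#' @param concentration Positive shape parameter of the Beta draw governing
#'   how much probability mass lands on the predicted label (larger =
#'   more confident vectors). Correct predictions draw their top-1 mass
#'   from `Beta(concentration, 1)`; wrong predictions use the weaker
#'   `Beta(concentration/10, 1)`, so confidence carries information about
#'   correctness the way trained softmax classifiers' confidences do. The
#'   default of 40 puts roughly 98-99% of correct top-1 confidences above
#'   0.9, the regime reported for well-trained identification backbones.
#' @param seed RNG seed.
#' @return An object of class `confidence_sim_config`.
#' @export
confidence_sim_config <- function(n_identities, per_view_accuracy,
                                  concentration = 40, seed = 1L) {
  stopifnot(n_identities >= 2, concentration > 0)
  if (is.null(names(per_view_accuracy)) || any(!nzchar(names(per_view_accuracy))))
    stop("per_view_accuracy must be a named vector (view -> accuracy)", call. = FALSE)
  chance <- 1 / n_identities
  if (any(per_view_accuracy <= chance) || any(per_view_accuracy > 1))
    stop("invalid-accuracy: per-view accuracy must lie in (1/N, 1]", call. = FALSE)
  structure(list(n_identities = as.integer(n_identities),
                 per_view_accuracy = per_view_accuracy,
                 concentration = concentration, seed = seed),
            class = "confidence_sim_config")
}

#' Simulate softmax confidence vectors with controlled accuracy
#'
#' For each requested draw the predicted label equals the true identity
#' with probability `a_v` (the configured accuracy of `view`) and is
#' otherwise uniform over the wrong labels; the predicted label then
#' receives a top-1 mass `m = 1/N + (1 - 1/N) * Beta(c, 1)` (always above
#' `1/N`, so the argmax is the predicted label, making the empirical
#' accuracy exactly `a_v` in expectation) and the remaining mass is spread
#' uniformly over the other labels. The Beta shape `c` is
#' `cfg$concentration` for correct predictions and `cfg$concentration/10`
#' for wrong ones, so high confidence is evidence of correctness. Draws
#' are a pure function of the config seed, the view and the true-identity
#' vector.
#'
#' @param cfg A [confidence_sim_config()].
#' @param true_ids Integer vector of true identity indices (1-based).
#' @param view View label; must be named in `cfg$per_view_accuracy`.
#' @return `length(true_ids) x N` matrix of probabilities, rows on the
#'   simplex, columns named by [identity_labels()].
#' @export
simulate_confidence_vectors <- function(cfg, true_ids, view) {
  stopifnot(inherits(cfg, "confidence_sim_config"))
  if (!(view %in% names(cfg$per_view_accuracy)))
    stop("invalid-view: no accuracy configured for view ", view, call. = FALSE)
  N <- cfg$n_identities
  if (any(true_ids < 1) || any(true_ids > N))
    stop("true identity index out of range", call. = FALSE)
  a <- cfg$per_view_accuracy[[view]]
  n <- length(true_ids)
  key <- paste("confsim", view, n, sum(true_ids), sep = "-")
  with_seed(seed_from(cfg$seed, key), {
    correct <- runif(n) <= a
    pred <- true_ids
    wrong <- which(!correct)
    if (length(wrong)) {
      # uniform over the N-1 wrong labels
      off <- sample.int(N - 1L, length(wrong), replace = TRUE)
      pred[wrong] <- ifelse(off >= true_ids[wrong], off + 1L, off)
    }
    shape <- ifelse(correct, cfg$concentration, cfg$concentration / 10)
    m <- 1 / N + (1 - 1 / N) * rbeta(n, shape, 1)
    rest <- (1 - m) / (N - 1L)
    P <- matrix(rest, n, N)
    P[cbind(seq_len(n), pred)] <- m
    colnames(P) <- identity_labels(N)
    P
  })
}

#' Simulate a single confidence vector
#'
#' Convenience wrapper around [simulate_confidence_vectors()] returning a
#' [confidence_vector()] for one draw.
#'
#' @inheritParams simulate_confidence_vectors
#' @param true_id True identity index.
#' @param draw Draw index, varied to obtain distinct vectors for the same
#'   `(true_id, view)`.
#' @return A [confidence_vector()].
#' @export
simulate_confidence_vector <- function(cfg, true_id, view, draw = 1L) {
  cfg2 <- cfg
  cfg2$seed <- seed_from(cfg$seed, paste0("draw-", draw))
  P <- simulate_confidence_vectors(cfg2, true_id, view)
  confidence_vector(P[1, ], view = view,
                    label_order = identity_labels(cfg$n_identities))
}
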