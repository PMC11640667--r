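# Runtime acquisition policies. A deployed recogniser should not spend five
# camera views on an animal the side-body classifier already identifies
# with 0.99 confidence. Two strategies trade accuracy against acquisition
# cost:
#
# * single camera: accept a prediction whose top-1 confidence reaches
#   tau_accept; pool mid-confidence predictions (in [tau_reject,
#   tau_accept)) and accept once a strict majority agrees; discard
#   low-confidence images and reshoot.
# * multi camera: evaluate views cumulatively in a fixed order (side body
#   first), fusing all collected confidence vectors after each addition,
#   and accept as soon as the fused top-1 confidence reaches tau_accept.
#
# Both are lazy: once accepted, no further images or views are consumed.

#' Configure an identification policy
#'
#' @param tau_accept Confidence at or above which a prediction is trusted
#'   outright (default 0.9).
#' @param tau_reject Confidence below which a prediction is discarded
#'   without a vote (default 0.7); must not exceed `tau_accept`.
#' @param max_images Cap on images consumed per episode (default 5).
#' @param view_order Cascade order for the multi-camera policy (default
#'   side body, back body, front face, then the two side faces).
#' @param weights [fusion_weights()] (or named vector) used by the
#'   multi-camera fusion; typically the per-view validation accuracies.
#' @param min_votes Concordant mid-confidence predictions needed for a
#'   vote decision (default 2).
#' @return Object of class `policy_config`.
#' @export
policy_config <- function(tau_accept = 0.9, tau_reject = 0.7, max_images = 5L,
                          view_order = c("S", "B", "F", "L", "R"),
                          weights = NULL, min_votes = 2L) {
  stopifnot(tau_reject >= 0, tau_accept <= 1, tau_reject <= tau_accept,
            max_images >= 1, min_votes >= 2)
  if (anyDuplicated(view_order))
    stop("view_order must contain distinct labels", call. = FALSE)
  if (inherits(weights, "fusion_weights")) weights <- weights$weights
  structure(list(tau_accept = tau_accept, tau_reject = tau_reject,
                 max_images = as.integer(max_images), view_order = view_order,
                 weights = weights, min_votes = as.integer(min_votes)),
            class = "policy_config")
}

policy_outcome <- function(identity, confidence, images_consumed, views_used,
                           status) {
  structure(list(identity = identity, confidence = confidence,
                 images_consumed = images_consumed, views_used = views_used,
                 status = status),
            class = "policy_outcome")
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat(sprintf("policy_outcome: %s (conf %.3f) after %d image(s) [%s] -- %s\n",
              x$identity, x$confidence, x$images_consumed,
              paste(x$views_used, collapse = ","), x$status))
  invisible(x)
}

# normalise a stream argument (list of vectors or a function(i)) into a
# function returning the i-th confidence vector or NULL
as_stream <- function(stream) {
  if (is.function(stream)) return(stream)
  force(stream)
  function(i) if (i <= length(stream)) stream[[i]] else NULL
}

#' Single-camera identification with threshold, reshoot and voting
#'
#' Consumes confidence vectors from one view, one image at a time. Each
#' prediction is trusted immediately at confidence `>= tau_accept`; at
#' confidence in `[tau_reject, tau_accept)` its label joins a vote pool and
#' another image is requested; below `tau_reject` it is discarded without a
#' vote. As soon as the pool holds at least `min_votes` entries with a
#' strict majority label, that label is accepted by vote. If `max_images`
#' is reached (or the stream ends) without a decision, the modal pooled
#' label is returned (ties broken by higher mean confidence), or the
#' highest-confidence prediction seen when the pool is empty, flagged
#' `exhausted_low_confidence`.
#'
#' @param stream List of [confidence_vector()]s, or a function `f(i)`
#'   returning the i-th vector (NULL when no more are available).
#' @param cfg A [policy_config()].
#' @return A `policy_outcome` with fields `identity`, `confidence`,
#'   `images_consumed`, `views_used`, `status`.
#' @export
single_camera_identify <- function(stream, cfg = policy_config()) {
  get_vec <- as_stream(stream)
  votes_id <- character(0); votes_conf <- numeric(0)
  best_id <- NA_character_; best_conf <- -Inf
  view <- NA_character_
  consumed <- 0L
  for (i in seq_len(cfg$max_images)) {
    v <- get_vec(i)
    if (is.null(v)) break
    consumed <- i
    view <- v$view
    p <- predict_identity(v)
    if (p$confidence > best_conf) { best_conf <- p$confidence; best_id <- p$identity }
    if (p$confidence >= cfg$tau_accept) {
      return(policy_outcome(p$identity, p$confidence, consumed, view, "accepted"))
    }
    if (p$confidence >= cfg$tau_reject) {
      votes_id <- c(votes_id, p$identity)
      votes_conf <- c(votes_conf, p$confidence)
      if (length(votes_id) >= cfg$min_votes) {
        tab <- table(votes_id)
        top <- names(tab)[which.max(tab)]
        if (max(tab) > length(votes_id) / 2) {
          return(policy_outcome(top, mean(votes_conf[votes_id == top]),
                                consumed, view, "accepted_by_vote"))
        }
      }
    }
  }
  if (consumed == 0L) stop("no-input: the image stream is empty", call. = FALSE)
  if (length(votes_id)) {
    tab <- table(votes_id)
    cand <- names(tab)[tab == max(tab)]
    means <- vapply(cand, function(l) mean(votes_conf[votes_id == l]), 0)
    pick <- cand[which.max(means)]
    policy_outcome(pick, means[which.max(means)], consumed, view,
                   "exhausted_low_confidence")
  } else {
    policy_outcome(best_id, best_conf, consumed, view,
                   "exhausted_low_confidence")
  }
}

#' Multi-camera cascade identification with sequential view fusion
#'
#' Evaluates views cumulatively in `cfg$view_order` (side body first by
#' default). After each view is added, all collected confidence vectors are
#' fused by accuracy-weighted averaging with `cfg$weights`; the episode is
#' accepted as soon as the fused top-1 confidence reaches `tau_accept`
#' (for a single collected view the fusion is the identity, so this is the
#' plain single-view threshold rule). Views absent from `view_streams` are
#' skipped and recorded as gaps. If all views are exhausted below the
#' threshold, the final fused prediction is returned flagged
#' `exhausted_low_confidence`.
#'
#' @param view_streams Named list mapping view labels to
#'   [confidence_vector()]s (one captured image per view).
#' @param cfg A [policy_config()] whose `weights` cover the views used.
#' @return A `policy_outcome`; its `views_used` lists the consumed views in
#'   cascade order and an attribute `gaps` names any skipped views.
#' @export
multi_camera_identify <- function(view_streams, cfg = policy_config()) {
  first <- cfg$view_order[1]
  if (is.null(view_streams[[first]]))
    stop("no-input: first cascade view ", first, " is unavailable", call. = FALSE)
  collected <- list()
  gaps <- character(0)
  fused <- NULL
  for (view in cfg$view_order) {
    v <- view_streams[[view]]
    if (is.null(v)) { gaps <- c(gaps, view); next }
    collected[[length(collected) + 1L]] <- v
    fused <- if (length(collected) == 1L) v
             else fuse_confidences(collected, cfg$weights)
    p <- predict_identity(fused)
    if (p$confidence >= cfg$tau_accept) {
      out <- policy_outcome(p$identity, p$confidence, length(collected),
                            vapply(collected, function(x) x$view, ""),
                            "accepted")
      attr(out, "gaps") <- gaps
      return(out)
    }
  }
  p <- predict_identity(fused)
  out <- policy_outcome(p$identity, p$confidence, length(collected),
                        vapply(collected, function(x) x$view, ""),
                        "exhausted_low_confidence")
  attr(out, "gaps") <- gaps
  out
}

#' Simulate identification episodes under a policy
#'
#' Draws `n_episodes` animals uniformly from the herd, simulates per-view
#' classifier confidences with [simulate_confidence_vectors()] and runs the
#' chosen policy on each episode. For the single-camera mode the stream
#' yields up to `max_images` independent draws from `single_view`; for the
#' multi-camera mode each view contributes one draw and the cascade
#' consumes them in `cfg$view_order`.
#'
#' @param n_episodes Number of episodes.
#' @param sim_cfg A [confidence_sim_config()] covering the views used.
#' @param cfg A [policy_config()]; for the multi-camera mode its `weights`
#'   default to the simulator's per-view accuracies.
#' @param mode `"multi"` (default) or `"single"`.
#' @param single_view View used by the single-camera mode (default `"S"`).
#' @param seed RNG seed.
#' @return `data.frame` episode log: `episode`, `true_identity`,
#'   `decision`, `status`, `images_consumed`, `views_used`,
#'   `final_confidence`, `correct`.
#' @export
simulate_policy_episodes <- function(n_episodes, sim_cfg,
                                     cfg = policy_config(),
                                     mode = c("multi", "single"),
                                     single_view = "S", seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim_cfg, "confidence_sim_config"))
  N <- sim_cfg$n_identities
  labs <- identity_labels(N)
  if (mode == "multi" && is.null(cfg$weights))
    cfg$weights <- sim_cfg$per_view_accuracy
  true <- with_seed(seed_from(seed, "episode-ids"),
                    sample.int(N, n_episodes, replace = TRUE))
  views <- if (mode == "multi") {
    intersect(cfg$view_order, names(sim_cfg$per_view_accuracy))
  } else single_view

  # pre-draw confidence matrices (policies consume them lazily)
  draws <- list()
  if (mode == "multi") {
    scfg <- sim_cfg; scfg$seed <- seed_from(seed, "episode-draws")
    for (v in views) draws[[v]] <- simulate_confidence_vectors(scfg, true, v)
  } else {
    for (k in seq_len(cfg$max_images)) {
      scfg <- sim_cfg; scfg$seed <- seed_from(seed, paste0("episode-draws-", k))
      draws[[k]] <- simulate_confidence_vectors(scfg, true, single_view)
    }
  }

  log <- vector("list", n_episodes)
  for (e in seq_len(n_episodes)) {
    out <- if (mode == "multi") {
      vs <- setNames(lapply(views, function(v)
        confidence_vector(draws[[v]][e, ], view = v, label_order = labs)), views)
      multi_camera_identify(vs, cfg)
    } else {
      stream <- lapply(seq_len(cfg$max_images), function(k)
        confidence_vector(draws[[k]][e, ], view = single_view,
                          label_order = labs))
      single_camera_identify(stream, cfg)
    }
    log[[e]] <- data.frame(
      episode = e, true_identity = labs[true[e]], decision = out$identity,
      status = out$status, images_consumed = out$images_consumed,
      views_used = paste(out$views_used, collapse = "+"),
      final_confidence = out$confidence,
      correct = identical(out$identity, labs[true[e]]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, log)
}

#' Per-episode computation cost
#'
#' The cost of an episode is proportional to the number of images pushed
#' through a classifier: `images_consumed * per_image_cost`. With the
#' reference backend, `per_image_cost` can be taken as
#' [count_parameters()] of the view model.
#'
#' @param episodes Episode log from [simulate_policy_episodes()] (or any
#'   `data.frame` with an `images_consumed` column).
#' @param per_image_cost Cost of one classifier evaluation (default 1).
#' @return Numeric vector of per-episode costs.
#' @export
episode_cost <- function(episodes, per_image_cost = 1) {
  episodes$images_consumed * per_image_cost
}
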