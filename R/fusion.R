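# Decision-level fusion. Per-view confidence vectors v_i are combined by
# an accuracy-weighted average
#
#     v_avg = sum_i w_i v_i / sum_i w_i,
#
# where w_i is the top-1 accuracy of the single-view model for view i.
# The formula applies to any subset of 2..5 views (and degenerates to the
# identity for one view); being a convex combination of simplex points,
# v_avg is itself on the simplex, and scaling all weights by a positive
# constant leaves it unchanged. The fused identity is the argmax of v_avg.

#' Construct per-view fusion weights
#'
#' @param weights Named non-negative numeric vector mapping view labels to
#'   their single-view model accuracies `w_i`. At least one weight must be
#'   strictly positive and views must be distinct.
#' @return Object of class `fusion_weights`.
#' @export
fusion_weights <- function(weights) {
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("invalid-weights: weights must be named by distinct views", call. = FALSE)
  if (any(weights < 0) || all(weights == 0))
    stop("invalid-weights: need non-negative weights, at least one positive",
         call. = FALSE)
  structure(list(weights = weights, n = length(weights)),
            class = "fusion_weights")
}

#' Fuse per-view confidence vectors by accuracy-weighted averaging
#'
#' Computes `v_avg = sum(w_i * v_i) / sum(w_i)` element-wise over the
#' supplied views. All vectors must share the same label order and come
#' from distinct views; each view must have a weight. Weights are used
#' as-is (the only normalisation is the `sum(w_i)` denominator).
#'
#' @param vectors List of [confidence_vector()]s from distinct views.
#' @param weights A [fusion_weights()] object or named numeric vector.
#' @return A [confidence_vector()] whose `view` is the fused views joined
#'   with `"+"`.
#' @export
fuse_confidences <- function(vectors, weights) {
  if (!length(vectors)) stop("invalid-input: no vectors to fuse", call. = FALSE)
  if (inherits(weights, "fusion_weights")) weights <- weights$weights
  stopifnot(all(vapply(vectors, inherits, TRUE, "confidence_vector")))
  views <- vapply(vectors, function(v) v$view, "")
  if (anyDuplicated(views))
    stop("incompatible-vectors: vectors must come from distinct views", call. = FALSE)
  ref <- vectors[[1]]$label_order
  for (v in vectors) {
    if (!identical(v$label_order, ref))
      stop("incompatible-vectors: label orders differ", call. = FALSE)
  }
  if (!all(views %in% names(weights)))
    stop("invalid-weights: missing weight for view(s) ",
         paste(setdiff(views, names(weights)), collapse = ", "), call. = FALSE)
  w <- as.numeric(weights[views])
  if (any(w < 0) || sum(w) <= 0)
    stop("invalid-weights: need non-negative weights with positive sum",
         call. = FALSE)
  P <- vapply(vectors, function(v) v$probs, numeric(length(ref)))
  v_avg <- as.vector(P %*% w) / sum(w)
  confidence_vector(v_avg, view = paste(views, collapse = "+"),
                    label_order = ref)
}

#' Decode the predicted identity from a probability vector
#'
#' Returns the label at the maximum probability (ties broken by lowest
#' index) together with that maximum, the top-1 confidence.
#'
#' @param v A [confidence_vector()] or bare probability vector.
#' @param label_order Identity labels; taken from `v` when it is a
#'   `confidence_vector`.
#' @return List with `identity` (label) and `confidence` (max probability).
#' @export
predict_identity <- function(v, label_order = NULL) {
  if (inherits(v, "confidence_vector")) {
    label_order <- v$label_order
    v <- v$probs
  }
  if (length(v) == 0L) stop("invalid-input: empty vector", call. = FALSE)
  stopifnot(length(v) == length(label_order))
  i <- which.max(v) # which.max returns the first maximum: lowest-index tie-break
  list(identity = label_order[i], confidence = v[i])
}

#' Top-k labels of a probability vector
#'
#' The `k` labels with the highest probabilities, in descending order,
#' ties broken by lowest index.
#'
#' @param v A [confidence_vector()] or bare probability vector.
#' @param k Integer in `1..N`.
#' @param label_order Identity labels (from `v` when available).
#' @return Character vector of `k` labels.
#' @export
topk_labels <- function(v, k, label_order = NULL) {
  if (inherits(v, "confidence_vector")) {
    label_order <- v$label_order
    v <- v$probs
  }
  if (k < 1 || k > length(v))
    stop("invalid-k: k must lie in 1..N", call. = FALSE)
  ord <- order(-v, seq_along(v)) # descending prob, index tie-break
  label_order[ord[seq_len(k)]]
}

#' Fuse per-view confidence dumps into a fused dump
#'
#' Multi-view evaluation requires pairing each individual's test images
#' across views; the pairing rule used here matches images of the same
#' identity by per-identity sample rank (the i-th image of identity g in
#' view A is paired with the i-th in view B), truncating to the smallest
#' per-view count; `pairing = "random"` instead pairs by a seeded random
#' permutation within each identity.
#'
#' @param dumps Named list (view -> confidence dump) sharing identity
#'   columns.
#' @param weights A [fusion_weights()] or named numeric vector.
#' @param pairing `"rank"` (default) or `"random"`.
#' @param seed Seed for random pairing.
#' @return Fused dump `data.frame` with the shared probability columns plus
#'   `predicted_identity`, `top1_confidence` and `views_used`.
#' @export
fuse_dumps <- function(dumps, weights, pairing = c("rank", "random"),
                       seed = 0L) {
  pairing <- match.arg(pairing)
  stopifnot(length(dumps) >= 1, !is.null(names(dumps)))
  if (inherits(weights, "fusion_weights")) weights <- weights$weights
  views <- names(dumps)
  parts <- lapply(dumps, dump_probs)
  labs <- parts[[1]]$labels
  for (p in parts) stopifnot(identical(p$labels, labs))
  w <- as.numeric(weights[views])
  if (any(is.na(w)) || sum(w) <= 0)
    stop("invalid-weights: need a positive weight for every fused view",
         call. = FALSE)

  ids <- sort(Reduce(intersect, lapply(parts, function(p) unique(p$true))))
  out <- vector("list", length(ids))
  for (gi in seq_along(ids)) {
    g <- ids[gi]
    rows <- lapply(parts, function(p) which(p$true == g))
    m <- min(lengths(rows))
    rows <- lapply(seq_along(rows), function(j) {
      r <- rows[[j]]
      if (pairing == "random")
        r <- with_seed(seed_from(seed, paste0("pair-", g, "-", views[j])),
                       sample(r))
      r[seq_len(m)]
    })
    S <- matrix(0, m, length(labs))
    for (j in seq_along(parts))
      S <- S + w[j] * parts[[j]]$P[rows[[j]], , drop = FALSE]
    S <- S / sum(w)
    df <- data.frame(path = dumps[[1]]$path[rows[[1]]], true_identity = g,
                     view = paste(views, collapse = "+"),
                     stringsAsFactors = FALSE)
    out[[gi]] <- cbind(df, as.data.frame(S, col.names = labs))
  }
  fused <- do.call(rbind, out)
  names(fused)[-(1:3)] <- labs
  d <- dump_probs(fused)
  top <- max.col(d$P, ties.method = "first")
  fused$predicted_identity <- labs[top]
  fused$top1_confidence <- d$P[cbind(seq_len(nrow(d$P)), top)]
  fused$views_used <- paste(views, collapse = "+")
  rownames(fused) <- NULL
  fused
}
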