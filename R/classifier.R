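# Per-view identity classifier contract. A classifier maps an appearance
# image to a softmax confidence vector over the N known identities; the
# reference backend is multinomial softmax regression on flattened,
# downsampled, intensity-normalised pixels, trained by seeded mini-batch
# gradient descent on the cross-entropy. Heavier convolutional backends can
# implement the same contract (train/predict/evaluate on a manifest); all
# downstream fusion, metrics and policy code only ever sees confidence
# vectors, so it is backend-agnostic.

#' Construct a confidence vector
#'
#' @param probs Numeric probability vector over identities; entries in
#'   `[0, 1]` summing to 1 within 1e-6.
#' @param view View label the vector came from.
#' @param label_order Identity labels, one per entry of `probs`.
#' @return Object of class `confidence_vector` with fields `probs`, `view`,
#'   `label_order`.
#' @export
confidence_vector <- function(probs, view, label_order) {
  probs <- as.numeric(probs)
  if (length(probs) == 0L) stop("invalid-input: empty probability vector", call. = FALSE)
  if (length(probs) != length(label_order))
    stop("invalid-input: probs and label_order lengths differ", call. = FALSE)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12) || abs(sum(probs) - 1) > 1e-6)
    stop("invalid-input: probabilities must lie in [0,1] and sum to 1", call. = FALSE)
  structure(list(probs = probs, view = view,
                 label_order = as.character(label_order)),
            class = "confidence_vector")
}

#' @export
print.confidence_vector <- function(x, ...) {
  i <- which.max(x$probs)
  cat(sprintf("confidence_vector (view %s, N=%d): top-1 %s @ %.4f\n",
              x$view, length(x$probs), x$label_order[i], x$probs[i]))
  invisible(x)
}

#' Numerically stable softmax
#'
#' `exp(x - max(x)) / sum(exp(x - max(x)))`; the max subtraction avoids
#' overflow for large logits.
#'
#' @param logits Finite numeric vector.
#' @return Probability vector of the same length, summing to 1.
#' @export
softmax <- function(logits) {
  if (length(logits) == 0L) stop("invalid-input: empty logit vector", call. = FALSE)
  stopifnot(all(is.finite(logits)))
  e <- exp(logits - max(logits))
  e / sum(e)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Training configuration for the reference backend
#'
#' @param feature Downsample side length; images are resized to
#'   `feature x feature` and flattened (default 16).
#' @param epochs Gradient-descent epochs (default 200).
#' @param learning_rate Step size (default 1).
#' @param batch_size Mini-batch size (default 32).
#' @param seed RNG seed controlling shuffling; fixed seed gives identical
#'   parameters.
#' @return Object of class `train_config`.
#' @export
train_config <- function(feature = 16L, epochs = 200L, learning_rate = 1,
                         batch_size = 32L, seed = 0L) {
  stopifnot(feature >= 1, epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(feature = as.integer(feature), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "train_config")
}

# image -> standardized feature row: resize, scale to [0,1], flatten
featurize <- function(img, feature) {
  as.vector(bilinear_resize(to_grayscale(img), feature, feature)) / 255
}

manifest_features <- function(manifest, rows, images, root, feature) {
  X <- matrix(0, length(rows), feature * feature)
  for (i in seq_along(rows)) {
    X[i, ] <- featurize(load_frame(manifest[rows[i], , drop = FALSE],
                                   images = images, root = root), feature)
  }
  cbind(1, X) # intercept column
}

#' Train a per-view identity classifier (reference backend)
#'
#' Fits multinomial softmax regression on the view's training records by
#' seeded mini-batch gradient descent on the cross-entropy, starting from
#' zero weights. Deterministic for a fixed config seed.
#'
#' @param manifest Dataset manifest with `split == "train"` rows for the
#'   view covering at least two identities.
#' @param view View label to train on.
#' @param cfg A [train_config()].
#' @param images Optional in-memory frame store (see [load_frame()]).
#' @param root Image directory root for on-disk frames.
#' @return Object of class `view_classifier` with fields `view`,
#'   `label_order`, `W` (weights, `(features+1) x N`), `feature`,
#'   `train_meta`.
#' @export
train_view_classifier <- function(manifest, view, cfg = train_config(),
                                  images = NULL, root = ".") {
  rows <- which(manifest$view == view & manifest$split == "train")
  if (length(rows) == 0L) stop("no training records for view ", view, call. = FALSE)
  labels <- sort(unique(manifest$identity[rows]))
  if (length(labels) < 2L)
    stop("degenerate-labels: training set covers a single identity", call. = FALSE)
  y <- match(manifest$identity[rows], labels)
  X <- manifest_features(manifest, rows, images, root, cfg$feature)
  n <- nrow(X); K <- length(labels)
  Yhot <- matrix(0, n, K); Yhot[cbind(seq_len(n), y)] <- 1

  W <- matrix(0, ncol(X), K)
  with_seed(seed_from(cfg$seed, paste0("train-", view)), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        b <- ord[start:min(start + cfg$batch_size - 1L, n)]
        P <- row_softmax(X[b, , drop = FALSE] %*% W)
        G <- crossprod(X[b, , drop = FALSE], P - Yhot[b, , drop = FALSE]) / length(b)
        W <- W - cfg$learning_rate * G
      }
    }
  })
  structure(list(view = view, label_order = labels, W = W,
                 feature = cfg$feature,
                 train_meta = list(seed = cfg$seed, epochs = cfg$epochs,
                                   learning_rate = cfg$learning_rate,
                                   n_train = n)),
            class = "view_classifier")
}

#' @export
print.view_classifier <- function(x, ...) {
  cat(sprintf("view_classifier: view %s, %d identities, %d parameters\n",
              x$view, length(x$label_order), count_parameters(x)))
  invisible(x)
}

#' Predict a confidence vector for one image
#'
#' @param model A [train_view_classifier()] model.
#' @param image Frame conformable to the model's feature spec after
#'   standardisation.
#' @return A [confidence_vector()] over the model's `label_order`.
#' @export
predict_confidence <- function(model, image) {
  stopifnot(inherits(model, "view_classifier"))
  x <- c(1, featurize(image, model$feature))
  confidence_vector(softmax(as.vector(x %*% model$W)),
                    view = model$view, label_order = model$label_order)
}

#' Evaluate a view model on a manifest split
#'
#' Computes top-1 accuracy (fraction of images whose argmax matches the
#' true identity) and a per-image confidence dump: one row per image with
#' the path, true identity, view and a probability column per identity.
#' The dump is the input format of the fusion, metrics and policy modules.
#'
#' @param model A [train_view_classifier()] model.
#' @param manifest Dataset manifest.
#' @param split Split to evaluate, `"val"` or `"test"`.
#' @param images,root See [load_frame()].
#' @return List with `accuracy` (scalar) and `dump` (`data.frame`).
#' @export
evaluate_view_model <- function(model, manifest, split = c("val", "test"),
                                images = NULL, root = ".") {
  split <- match.arg(split)
  rows <- which(manifest$view == model$view & manifest$split == split)
  if (length(rows) == 0L)
    stop("empty-eval: no ", split, " records for view ", model$view, call. = FALSE)
  if (!all(manifest$identity[rows] %in% model$label_order))
    stop("model-dataset-mismatch: identities outside the model's label order",
         call. = FALSE)
  X <- manifest_features(manifest, rows, images, root, model$feature)
  P <- row_softmax(X %*% model$W)
  colnames(P) <- model$label_order
  dump <- data.frame(path = manifest$path[rows],
                     true_identity = manifest$identity[rows],
                     view = model$view, stringsAsFactors = FALSE)
  dump <- cbind(dump, as.data.frame(P))
  list(accuracy = accuracy_from_dump(dump), dump = dump)
}

#' Probability matrix and labels of a confidence dump
#'
#' @param dump Confidence dump `data.frame` (see [evaluate_view_model()]).
#' @return List with `P` (matrix), `labels` (identity order) and `true`
#'   (true identities).
#' @export
dump_probs <- function(dump) {
  meta <- c("path", "true_identity", "view", "views_used",
            "predicted_identity", "top1_confidence")
  labs <- setdiff(names(dump), meta)
  P <- as.matrix(dump[, labs, drop = FALSE])
  colnames(P) <- labs
  list(P = P, labels = labs, true = dump$true_identity)
}

#' Top-1 accuracy of a confidence dump
#'
#' Pure function of the dump: recomputing twice gives identical results.
#' Argmax ties break to the lowest index.
#'
#' @param dump Confidence dump `data.frame`.
#' @return Fraction of rows whose argmax column matches `true_identity`.
#' @export
accuracy_from_dump <- function(dump) {
  d <- dump_probs(dump)
  pred <- d$labels[max.col(d$P, ties.method = "first")]
  mean(pred == d$true)
}

#' Count trainable parameters of a classifier
#'
#' For the reference backend this is `(features + 1) * N` (weights plus
#' per-class intercepts), obtained by enumerating the parameter arrays.
#'
#' @param model A `view_classifier`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "view_classifier"))
  length(model$W)
}

#' Save / load a view classifier as portable JSON
#'
#' A single text file per view holding the label order, feature spec,
#' parameter array and training metadata; round-trips losslessly.
#'
#' @param model A `view_classifier`.
#' @param path File path.
#' @return `save_classifier`: `path`, invisibly. `load_classifier`: the
#'   restored `view_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "view_classifier"))
  obj <- list(view = model$view, label_order = model$label_order,
              feature = model$feature, dim = dim(model$W),
              W = as.vector(model$W), train_meta = model$train_meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(view = obj$view,
                 label_order = as.character(obj$label_order),
                 W = matrix(obj$W, obj$dim[1], obj$dim[2]),
                 feature = as.integer(obj$feature),
                 train_meta = obj$train_meta),
            class = "view_classifier")
}
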