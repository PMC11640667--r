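# Shared fixtures, all generated in code.

# Render an in-memory labelled image set for one or more views.
render_herd <- function(bank, views, n_train = 25, n_test = 10,
                        profile = default_view_profile(), seed = 100) {
  imgs <- list()
  rows <- list()
  labs <- identity_labels(bank$n_identities)
  for (v in views) for (i in seq_len(bank$n_identities)) {
    for (k in seq_len(n_train + n_test)) {
      p <- sprintf("%s/%s/%03d", v, labs[i], k)
      imgs[[p]] <- render_view_image(bank, i, profile[[v]],
                                     frame_seed = seed_from(seed, p))
      rows[[length(rows) + 1L]] <- data.frame(
        path = p, identity = labs[i], view = v,
        split = if (k <= n_train) "train" else "test",
        is_augmented = FALSE, source_path = NA_character_,
        op = NA_character_, stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, rows), images = imgs)
}

# Random point on the probability simplex.
random_simplex <- function(n) {
  x <- runif(n)
  x / sum(x)
}

# Small confidence dump with known per-row predictions.
toy_dump <- function(true, probs, labels, view = "S") {
  d <- data.frame(path = sprintf("img%03d", seq_along(true)),
                  true_identity = true, view = view,
                  stringsAsFactors = FALSE)
  P <- do.call(rbind, probs)
  colnames(P) <- labels
  cbind(d, as.data.frame(P, check.names = FALSE))
}
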