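test_that("softmax matches the direct formula and its symmetries", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(3, 3, 3)), rep(1 / 3, 3))
  x <- c(1, 2, 3)
  expect_equal(softmax(x), exp(x) / sum(exp(x)), tolerance = 1e-9)
  # shift invariance and overflow stability
  expect_equal(softmax(x + 1000), softmax(x), tolerance = 1e-12)
  expect_error(softmax(numeric(0)), "invalid-input")
})

test_that("confidence vectors are validated on construction", {
  v <- confidence_vector(c(0.2, 0.8), "S", c("0001", "0002"))
  expect_s3_class(v, "confidence_vector")
  expect_error(confidence_vector(c(0.2, 0.7), "S", c("0001", "0002")),
               "invalid-input")
  expect_error(confidence_vector(c(0.5, 0.5), "S", "0001"), "invalid-input")
  expect_error(confidence_vector(numeric(0), "S", character(0)),
               "invalid-input")
})

test_that("training separates a simple two-identity herd and is reproducible", {
  bank <- make_identity_bank(2, seed = 10)
  clean <- list(S = view_spec("S", informativeness = 1, lighting_sd = 1,
                              pose_jitter = 0.01, field_sd = 1, noise_sd = 2))
  d <- render_herd(bank, "S", n_train = 10, n_test = 5, profile = clean)
  cfg <- train_config(epochs = 60, seed = 3)
  m1 <- train_view_classifier(d$manifest, "S", cfg, images = d$images)
  m2 <- train_view_classifier(d$manifest, "S", cfg, images = d$images)
  expect_identical(m1$W, m2$W)

  # training accuracy 1.0 on the separable pair
  train_as_val <- d$manifest
  train_as_val$split[train_as_val$split == "train"] <- "val"
  expect_equal(evaluate_view_model(m1, train_as_val, "val",
                                   images = d$images)$accuracy, 1)
  expect_equal(evaluate_view_model(m1, d$manifest, "test",
                                   images = d$images)$accuracy, 1)

  # degenerate single-identity training set
  solo <- d$manifest[d$manifest$identity == "0001", ]
  expect_error(train_view_classifier(solo, "S", cfg, images = d$images),
               "degenerate-labels")
  expect_error(evaluate_view_model(m1, d$manifest, "val", images = d$images),
               "empty-eval")
})

test_that("predictions are valid simplex vectors and deterministic", {
  bank <- make_identity_bank(3, seed = 12)
  d <- render_herd(bank, "S", n_train = 8, n_test = 2)
  m <- train_view_classifier(d$manifest, "S", train_config(epochs = 40),
                             images = d$images)
  img <- d$images[[1]]
  v1 <- predict_confidence(m, img)
  expect_s3_class(v1, "confidence_vector")
  expect_equal(sum(v1$probs), 1, tolerance = 1e-9)
  expect_identical(v1, predict_confidence(m, img))
})

test_that("parameter counting equals enumeration of the weight array", {
  # (features + 1) * N closed form
  bank <- make_identity_bank(3, seed = 12)
  d <- render_herd(bank, "S", n_train = 6, n_test = 2)
  m8 <- train_view_classifier(d$manifest, "S",
                              train_config(feature = 8, epochs = 5),
                              images = d$images)
  expect_equal(count_parameters(m8), (8 * 8 + 1) * 3)
  expect_equal(count_parameters(m8), length(m8$W))
})

test_that("classifiers round-trip through their portable serialization", {
  bank <- make_identity_bank(3, seed = 13)
  d <- render_herd(bank, "S", n_train = 6, n_test = 3)
  m <- train_view_classifier(d$manifest, "S",
                             train_config(feature = 8, epochs = 20),
                             images = d$images)
  f <- tempfile(fileext = ".json")
  save_classifier(m, f)
  m2 <- load_classifier(f)
  expect_identical(m2$label_order, m$label_order)
  expect_equal(m2$W, m$W, tolerance = 1e-12)
  ev1 <- evaluate_view_model(m, d$manifest, "test", images = d$images)
  ev2 <- evaluate_view_model(m2, d$manifest, "test", images = d$images)
  expect_equal(ev1$accuracy, ev2$accuracy)
  expect_equal(accuracy_from_dump(ev1$dump), ev1$accuracy)
  unlink(f)
})

test_that("the reference backend agrees with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  bank <- make_identity_bank(3, seed = 21)
  clean <- list(S = view_spec("S", informativeness = 1, lighting_sd = 2,
                              pose_jitter = 0.01, field_sd = 2, noise_sd = 3))
  d <- render_herd(bank, "S", n_train = 12, n_test = 6, profile = clean)
  m <- train_view_classifier(d$manifest, "S",
                             train_config(feature = 8, epochs = 80),
                             images = d$images)
  # independent route: nnet::multinom on the same standardized features
  rows <- which(d$manifest$split == "train")
  X <- t(vapply(rows, function(i)
    as.vector(bilinear_resize(d$images[[d$manifest$path[i]]], 8, 8)) / 255,
    numeric(64)))
  y <- factor(d$manifest$identity[rows])
  fit <- nnet::multinom(y ~ X, trace = FALSE, maxit = 200, MaxNWts = 5000)

  te <- which(d$manifest$split == "test")
  Xte <- t(vapply(te, function(i)
    as.vector(bilinear_resize(d$images[[d$manifest$path[i]]], 8, 8)) / 255,
    numeric(64)))
  oracle_pred <- predict(fit, newdata = data.frame(X = I(Xte)))
  mine <- vapply(te, function(i) {
    predict_identity(predict_confidence(m, d$images[[d$manifest$path[i]]]))$identity
  }, "")
  # both routes classify the well-separated held-out herd identically
  expect_equal(as.character(oracle_pred), mine)
})

test_that("per-view accuracies on the default herd reproduce the view ordering", {
  bank <- make_identity_bank(20, seed = 11)
  acc <- vapply(c("S", "B", "F", "L", "R"), function(v) {
    d <- render_herd(bank, v)
    m <- train_view_classifier(d$manifest, v, train_config(seed = 42),
                               images = d$images)
    evaluate_view_model(m, d$manifest, "test", images = d$images)$accuracy
  }, 0)

  # calibration floor for the fusion testbed
  expect_true(all(acc >= 0.9), label = paste("accuracies:",
                                             paste(round(acc, 3), collapse = " ")))
  # qualitative ordering: side body strongest, side faces weakest
  expect_gt(acc[["S"]], acc[["L"]])
  expect_gt(acc[["S"]], acc[["R"]])
  expect_gte(acc[["S"]], acc[["B"]])
  expect_gt(mean(acc[c("S", "B")]), mean(acc[c("L", "R")]))
  # the chain is checked up to the sampling spread of this herd size:
  # two same-spec views (L, R) differ by up to ~0.04 on 200 test images
  slack <- 0.05
  expect_gte(acc[["B"]] + slack, acc[["F"]])
  expect_gte(acc[["F"]] + slack, max(acc[["L"]], acc[["R"]]))
})
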