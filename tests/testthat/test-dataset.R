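test_that("augmentation ops behave per their definitions", {
  img <- matrix(runif(48 * 48, 0, 255), 48, 48)
  cfg <- augmentation_config()

  # horizontal mirror is an involution
  expect_identical(augment_image(augment_image(img, "horizontal_mirror"),
                                 "horizontal_mirror"), img)

  # rotation by zero degrees is the identity
  expect_identical(augment_image(img, "random_rotation", cfg,
                                 params = list(angle = 0)), img)

  # brighten factor 1.25 on a constant-100 image: constant 125
  expect_identical(augment_image(matrix(100, 10, 10), "brighten", cfg,
                                 params = list(factor = 1.25)),
                   matrix(125, 10, 10))
  # darken clips at 0 and never exceeds the input
  dk <- augment_image(img, "darken", cfg)
  expect_true(all(dk <= img) && all(dk >= 0))

  # translation keeps dimensions; a known shift moves pixels
  tr <- augment_image(img, "translation", cfg, params = list(dx = 3, dy = 0))
  expect_equal(dim(tr), dim(img))
  expect_identical(tr[, 4:48], img[, 1:45])

  # deterministic for fixed seed
  expect_identical(augment_image(img, "random_rotation", cfg, seed = 11),
                   augment_image(img, "random_rotation", cfg, seed = 11))
  expect_error(augment_image(img, "zoom"), "invalid-augmentation")
})

test_that("class balancing hits the target count exactly from any starting count", {
  cfg <- augmentation_config(target_per_class = 450L, seed = 1)
  man60 <- data.frame(path = sprintf("F/0007/%03d", 1:60), identity = "0007",
                      view = "F", split = "unassigned", is_augmented = FALSE,
                      source_path = NA_character_, op = NA_character_,
                      stringsAsFactors = FALSE)
  b60 <- balance_manifest(man60, cfg)
  expect_equal(nrow(b60), 450)
  expect_equal(sum(b60$is_augmented), 390)
  expect_true(all(b60$source_path[b60$is_augmented] %in% man60$path))
  expect_true(all(b60$op[b60$is_augmented] %in%
                    c("horizontal_mirror", "random_rotation", "translation",
                      "brighten", "darken")))

  man448 <- data.frame(path = sprintf("S/0024/%03d", 1:448), identity = "0024",
                       view = "S", split = "unassigned", is_augmented = FALSE,
                       source_path = NA_character_, op = NA_character_,
                       stringsAsFactors = FALSE)
  b448 <- balance_manifest(man448, cfg)
  expect_equal(nrow(b448), 450)
  expect_equal(sum(b448$is_augmented), 2)

  man450 <- man448; man450 <- rbind(man450, man448[1:2, ])
  man450$path <- sprintf("S/0024/%03d", 1:450)
  b450 <- balance_manifest(man450, cfg)
  expect_equal(nrow(b450), 450)
  expect_false(any(b450$is_augmented))
  expect_setequal(b450$path, man450$path)

  # surplus: seeded subsampling without replacement
  man500 <- man450; man500 <- rbind(man500, man450[1:50, ])
  man500$path <- sprintf("S/0024/%03d", 1:500)
  b500 <- balance_manifest(man500, cfg)
  expect_equal(nrow(b500), 450)
  expect_equal(anyDuplicated(b500$path), 0)

  expect_error(balance_manifest(man60[0, ], cfg), "empty-class")
})

test_that("in-memory balance_class mirrors the manifest planner", {
  imgs <- lapply(1:5, function(i) matrix(i, 8, 8))
  out <- balance_class(imgs, augmentation_config(target_per_class = 12L,
                                                 seed = 3))
  expect_length(out, 12)
  srcs <- vapply(out[6:12], attr, 0L, "source")
  expect_true(all(srcs %in% 1:5))
})

test_that("test extraction precedes augmentation and is reproducible", {
  man <- simulate_herd_manifest(4, count_range = c(25L, 40L), seed = 2)
  m1 <- make_test_split(man, per_class = 5, seed = 9)
  expect_true(all(table(m1$identity[m1$split == "test"],
                        m1$view[m1$split == "test"]) == 5))
  expect_identical(m1, make_test_split(man, per_class = 5, seed = 9))
  expect_identical(make_test_split(man, per_class = 0), man)

  # class too small
  tiny <- simulate_herd_manifest(2, count_range = c(5L, 8L), seed = 1)
  expect_error(make_test_split(tiny, per_class = 10), "split-infeasible")

  # augmented rows present: refuse
  aug <- man; aug$is_augmented[1] <- TRUE
  expect_error(make_test_split(aug, per_class = 5), "split-infeasible")
})

test_that("train/val split is stratified, disjoint from test, and exact at 8:2", {
  man <- simulate_herd_manifest(3, count_range = c(30L, 60L), seed = 4)
  man <- make_test_split(man, per_class = 5, seed = 1)
  cfg <- augmentation_config(target_per_class = 50L, seed = 2)
  man <- balance_manifest(man, cfg)
  man <- make_train_val_split(man, val_fraction = 0.2, seed = 3)

  expect_setequal(unique(man$split), c("train", "val", "test"))
  tab <- table(man$identity, man$view, man$split)
  expect_true(all(tab[, , "val"] == 10))   # round(0.2 * 50)
  expect_true(all(tab[, , "train"] == 40))
  expect_true(all(tab[, , "test"] == 5))

  # no path in two splits; augmented rows never in test
  expect_equal(anyDuplicated(man$path), 0)
  expect_false(any(man$is_augmented & man$split == "test"))

  # val_fraction 0: everything trains
  all_train <- make_train_val_split(balance_manifest(
    make_test_split(simulate_herd_manifest(2, count_range = c(20L, 30L),
                                           seed = 5), 3, 1), cfg), 0, 1)
  expect_false(any(all_train$split == "val"))
})

test_that("augmented records reproduce their pixels through load_frame", {
  bank <- make_identity_bank(2, seed = 6)
  img <- render_view_image(bank, 1, default_view_profile()$S, frame_seed = 2)
  imgs <- list("S/0001/001" = img)
  man <- data.frame(path = "S/0001/001", identity = "0001", view = "S",
                    split = "unassigned", is_augmented = FALSE,
                    source_path = NA_character_, op = NA_character_,
                    stringsAsFactors = FALSE)
  cfg <- augmentation_config(target_per_class = 4L, seed = 8)
  b <- balance_manifest(man, cfg)
  expect_equal(nrow(b), 4)
  for (i in which(b$is_augmented)) {
    f1 <- load_frame(b[i, , drop = FALSE], images = imgs, cfg = cfg)
    f2 <- load_frame(b[i, , drop = FALSE], images = imgs, cfg = cfg)
    expect_identical(f1, f2)
    expect_equal(dim(f1), dim(img))
  }
})
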