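test_that("frame extraction keeps every interval-th frame in order", {
  frames <- as.list(seq_len(90))
  expect_identical(extract_frames(frames, 30), list(1L, 31L, 61L))
  expect_identical(extract_frames(frames, 1), frames)
  # 100 frames at interval 30 -> positions 0, 30, 60, 90: four frames
  expect_length(extract_frames(as.list(1:100), 30), 4)
  expect_identical(extract_frames(list(), 30), list())
})

test_that("dHash matches its definition on constructed images", {
  const <- matrix(100, 32, 32)
  h <- compute_dhash(const)
  expect_length(h, 64)
  expect_true(all(h == 0)) # strict > never fires

  # strictly decreasing left-to-right ramp: every bit set
  ramp <- matrix(rep(seq(255, 0, length.out = 36), each = 32), 32, 36)
  expect_true(all(compute_dhash(ramp) == 1))

  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(compute_dhash(img), compute_dhash(img))
  expect_error(compute_dhash("no"), "invalid-image")
})

test_that("Hamming distance counts differing bits", {
  h0 <- structure(rep(0L, 64), class = "perceptual_hash")
  h1 <- structure(rep(1L, 64), class = "perceptual_hash")
  expect_equal(hamming_distance(h0, h0), 0)
  expect_equal(hamming_distance(h0, h1), 64)

  set.seed(42)
  for (i in 1:20) {
    a <- sample(0:1, 64, replace = TRUE)
    b <- sample(0:1, 64, replace = TRUE)
    # brute-force bit loop oracle
    d <- 0L
    for (j in 1:64) if (a[j] != b[j]) d <- d + 1L
    expect_equal(hamming_distance(a, b), d)
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
  }
  expect_error(hamming_distance(rep(0, 10), rep(0, 64)), "invalid-hash")
})

test_that("dHash dedup drops repeats and honours the threshold direction", {
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  same <- list(img, img, img, img)
  r <- dedup_by_dhash(same, 5)
  expect_identical(r$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_length(r$frames, 1)

  # threshold 0: distance < 0 impossible, everything retained
  expect_true(all(dedup_by_dhash(same, 0)$keep))
})

test_that("SSIM agrees with the global-statistics formula on a single window", {
  set.seed(7)
  a <- matrix(runif(256, 0, 255), 16, 16)
  b <- matrix(runif(256, 0, 255), 16, 16)

  # independent single-window oracle with population moments
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mu1 <- mean(a); mu2 <- mean(b)
  v1 <- mean(a^2) - mu1^2; v2 <- mean(b^2) - mu2^2
  cv <- mean(a * b) - mu1 * mu2
  oracle <- ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
    ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))

  got <- compute_ssim(a, b, window = 16, gaussian = FALSE)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("SSIM is 1 at identity, symmetric, and penalises inversion", {
  set.seed(8)
  x <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_equal(compute_ssim(x, x), 1, tolerance = 1e-12)
  y <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_lt(abs(compute_ssim(x, y) - compute_ssim(y, x)), 1e-9)
  expect_lt(compute_ssim(x, 255 - x), 1)
  expect_error(compute_ssim(x, matrix(0, 8, 8)), "invalid-pair")
})

test_that("SSIM dedup collapses identical runs and respects threshold 1", {
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  other <- matrix(runif(64 * 64, 0, 255), 64, 64)
  r <- dedup_by_ssim(list(img, img, other), 0.7)
  expect_identical(r$keep, c(TRUE, FALSE, TRUE))
  # threshold 1 with distinct frames: nothing reaches SSIM >= 1, all retained
  expect_true(all(dedup_by_ssim(list(img, other, img), 1)$keep))
})

test_that("both dedup methods recover planted ground truth exactly", {
  bank <- make_identity_bank(4, seed = 3)
  prof <- default_view_profile()
  for (v in c("S", "B", "L")) {
    sq <- generate_frame_sequence(bank, 2, prof[[v]], n_frames = 40,
                                  dup_rate = 0.5, seed = 21)
    expect_identical(dedup_by_dhash(sq$frames, 5)$keep, !sq$duplicate,
                     label = paste("dHash ground truth, view", v))
    expect_identical(dedup_by_ssim(sq$frames, 0.7)$keep, !sq$duplicate,
                     label = paste("SSIM ground truth, view", v))
  }
})

test_that("dedup is idempotent, order-preserving and monotone in its threshold", {
  bank <- make_identity_bank(3, seed = 9)
  sq <- generate_frame_sequence(bank, 1, default_view_profile()$F,
                                n_frames = 30, dup_rate = 0.4, seed = 2)
  numbered <- lapply(seq_along(sq$frames), function(i) {
    f <- sq$frames[[i]]; attr(f, "idx") <- i; f
  })

  for (method in c("dhash", "ssim")) {
    dd <- if (method == "dhash") function(fr) dedup_by_dhash(fr, 5)
          else function(fr) dedup_by_ssim(fr, 0.7)
    once <- dd(numbered)
    twice <- dd(once$frames)
    expect_true(all(twice$keep), label = paste(method, "idempotence"))
    idx <- vapply(once$frames, attr, 0L, "idx")
    expect_identical(idx, sort(idx), label = paste(method, "order"))
  }

  # raising the dHash threshold can only drop more frames
  kept <- vapply(c(0, 3, 5, 10, 20), function(t)
    sum(dedup_by_dhash(sq$frames, t)$keep), 0)
  expect_true(all(diff(kept) <= 0))
  # raising the SSIM threshold can only retain more frames
  kept_s <- vapply(c(0.3, 0.5, 0.7, 0.9, 1), function(t)
    sum(dedup_by_ssim(sq$frames, t)$keep), 0)
  expect_true(all(diff(kept_s) >= 0))
})

test_that("ROI crop/resize is exact on identity boxes and matches a bilinear oracle", {
  img <- matrix(runif(224 * 224, 0, 255), 224, 224)
  out <- crop_resize_roi(img, c(0, 0, 224, 224))
  expect_identical(out, img)

  small <- matrix(runif(50 * 80, 0, 255), 50, 80)
  out2 <- crop_resize_roi(small, c(10, 5, 70, 45))
  expect_equal(dim(out2), c(224, 224))

  # 2x2 checkerboard upscaled to 4x4 vs an independent per-pixel oracle
  cb <- matrix(c(0, 255, 255, 0), 2, 2)
  got <- bilinear_resize(cb, 4, 4)
  oracle <- matrix(0, 4, 4)
  for (i in 0:3) for (j in 0:3) {
    sy <- min(max((i + 0.5) * 0.5 - 0.5, 0), 1)
    sx <- min(max((j + 0.5) * 0.5 - 0.5, 0), 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, 1); x1 <- min(x0 + 1, 1)
    wy <- sy - y0; wx <- sx - x0
    oracle[i + 1, j + 1] <-
      cb[y0 + 1, x0 + 1] * (1 - wy) * (1 - wx) +
      cb[y0 + 1, x1 + 1] * (1 - wy) * wx +
      cb[y1 + 1, x0 + 1] * wy * (1 - wx) +
      cb[y1 + 1, x1 + 1] * wy * wx
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(crop_resize_roi(small, c(0, 0, 100, 10)), "invalid-box")
  expect_error(crop_resize_roi(small, c(5, 5, 5, 10)), "invalid-box")
})

test_that("sharpness score drops under blurring", {
  bank <- make_identity_bank(2, seed = 5)
  img <- render_view_image(bank, 1, default_view_profile()$S, frame_seed = 1)
  blurred <- bilinear_resize(bilinear_resize(img, 16, 16), 64, 64)
  expect_gt(sharpness_score(img), sharpness_score(blurred))
})
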