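test_that("warmup factor ramps linearly and saturates at one fifth of training", {
  expect_equal(warmup_probability(0, 100), 0)
  expect_equal(warmup_probability(10, 100), 0.5)
  expect_equal(warmup_probability(20, 100), 1)
  expect_equal(warmup_probability(90, 100), 1)
  # non-decreasing, and exactly 1 from ceil(total/5) onward
  for (total in c(5, 30, 100, 137)) {
    p <- warmup_probability(0:total, total)
    expect_true(all(diff(p) >= 0))
    k <- ceiling(total / 5)
    expect_equal(p[k + 1], 1) # epoch k (0-based) is the saturation point
    if (k > 1) expect_lt(p[k], 1)
  }
  expect_error(warmup_probability(1, 0), "positive")
  expect_error(warmup_probability(-1, 10))
})

test_that("effective plan scales base probabilities elementwise", {
  pl <- effective_plan(8, 100, c(mosaic = 1.0, flip = 0.5))
  expect_equal(pl$warmup_factor, 0.4)
  expect_equal(pl$effective_probabilities,
               c(mosaic = 0.4, flip = 0.2))
  pl0 <- effective_plan(0, 100, c(flip = 0.5, mosaic = 1.0))
  expect_true(all(pl0$effective_probabilities == 0))
  pl1 <- effective_plan(50, 100, c(flip = 0.5))
  expect_equal(pl1$effective_probabilities, c(flip = 0.5))
  expect_error(effective_plan(1, 100, c(flip = 1.5)), "\\[0, 1\\]")
})

test_that("augmentations preserve label validity and are seed-reproducible", {
  set.seed(5)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  lab <- data.frame(class = 0L, cx = 0.2, cy = 0.5, w = 0.1, h = 0.1)
  # P = 0: identity
  a0 <- apply_augmentations(img, lab, effective_plan(0, 100), rng_seed = 1)
  expect_identical(a0$image, img)
  expect_identical(a0$labels, lab)
  expect_length(a0$fired, 0)
  # forced horizontal flip mirrors cx
  af <- apply_augmentations(img, lab, effective_plan(50, 100, c(fliplr = 1)),
                            rng_seed = 1)
  expect_equal(af$labels$cx, 0.8)
  expect_equal(af$labels$cy, 0.5)
  expect_equal(af$image, img[, 24:1, ])
  # determinism under a fixed seed and full pipeline
  pl <- effective_plan(50, 100)
  r1 <- suppressWarnings(apply_augmentations(img, lab, pl, rng_seed = 42))
  r2 <- suppressWarnings(apply_augmentations(img, lab, pl, rng_seed = 42))
  expect_identical(r1, r2)
  # labels remain normalized under repeated random transforms
  for (s in 1:20) {
    r <- suppressWarnings(apply_augmentations(img, lab, pl, rng_seed = s))
    if (nrow(r$labels)) {
      expect_true(all(r$labels$cx >= 0 & r$labels$cx <= 1))
      expect_true(all(r$labels$w > 0 & r$labels$w <= 1))
    }
  }
})

test_that("at full warmup each augmentation fires at its base frequency", {
  img <- array(0.5, c(8, 8, 3))
  lab <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.4, h = 0.4)
  base <- c(affine = 0.6, hsv = 0.3, fliplr = 0.5)
  pl <- effective_plan(40, 100, base) # P = 1
  n <- 1000
  fired <- matrix(FALSE, n, length(base), dimnames = list(NULL, names(base)))
  for (s in seq_len(n)) {
    r <- suppressWarnings(apply_augmentations(img, lab, pl, rng_seed = s))
    fired[s, r$fired] <- TRUE
  }
  freq <- colMeans(fired)
  se <- sqrt(base * (1 - base) / n)
  expect_true(all(abs(freq - base) < 3 * se))
})
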