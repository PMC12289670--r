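test_that("training is seeded, logs the warmup schedule and reduces the loss", {
  ds <- load_dataset(shared_dataset_dir())
  m <- build_model(model_config("n", num_classes = 4), seed = 5)
  tc <- train_config(epochs = 2, batch_size = 4, image_size = 96,
                     val_every = 0, seed = 1, verbose = FALSE)
  m1 <- suppressWarnings(train(m, ds, tc))
  h <- m1$history
  # epoch 0 has warmup factor 0 and no augmentations fired
  expect_equal(h$warmup_p[1], 0)
  expect_identical(h$augmentations_fired[1], 0L)
  expect_true(all(is.finite(h$loss)))
  # identical seeds give identical first-epoch loss
  m2 <- suppressWarnings(train(build_model(model_config("n", num_classes = 4),
                                           seed = 5), ds, tc))
  expect_identical(m2$history$loss[1], h$loss[1])
  # training moved the parameters and the loss
  expect_lt(h$loss[2], h$loss[1])
})

test_that("training rejects an empty dataset", {
  ds <- load_dataset(shared_dataset_dir())
  ds$items$train <- ds$items$train[0, ]
  m <- build_model(model_config("n", num_classes = 4), seed = 5)
  expect_error(suppressWarnings(train(m, ds, train_config(epochs = 1))),
               "empty dataset")
})

test_that("task-aligned assignment produces one-truth-per-anchor targets", {
  set.seed(21)
  A <- 64
  boxes <- cbind(runif(A, 0, 80), runif(A, 0, 80), 0, 0)
  boxes[, 3] <- boxes[, 1] + runif(A, 10, 30)
  boxes[, 4] <- boxes[, 2] + runif(A, 10, 30)
  cls <- matrix(runif(A * 4, 0, 0.5), A, 4)
  anch <- data.frame(ax = (boxes[, 1] + boxes[, 3]) / 2,
                     ay = (boxes[, 2] + boxes[, 4]) / 2, stride = 8)
  gt <- data.frame(class = c(0L, 2L), x1 = c(5, 40), y1 = c(5, 40),
                   x2 = c(45, 85), y2 = c(45, 85))
  as_ <- strawyolo:::tal_assign(boxes, cls, anch, gt)
  expect_true(all(as_$w > 0))
  expect_true(all(rowSums(as_$Y > 0) <= 1)) # one class target per anchor
  expect_lte(max(table(as_$fg)), 1)         # anchors assigned at most once
  # target scores are bounded by the best IoU of their truth
  M <- strawyolo:::iou_matrix(as.matrix(gt[, c("x1", "y1", "x2", "y2")]), boxes)
  for (k in seq_along(as_$fg))
    expect_lte(as_$w[k], max(M[as_$gt_idx[k], ]) + 1e-9)
  # no truths: no positives anywhere
  as0 <- strawyolo:::tal_assign(boxes, cls, anch, gt[0, ])
  expect_identical(sum(as0$Y), 0)
})

test_that("composite loss backpropagates finite gradients", {
  set.seed(22)
  m <- build_model(model_config("n", num_classes = 4), seed = 6)
  xs <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  gts <- list(data.frame(class = 0L, x1 = 10, y1 = 10, x2 = 40, y2 = 40),
              data.frame(class = 3L, x1 = 20, y1 = 5, x2 = 55, y2 = 45))
  fw <- model_forward(m, xs, training = TRUE)
  ls <- strawyolo:::detection_loss(fw$tape, fw$det, gts, 4, 64, 64,
                                   train_config(verbose = FALSE))
  expect_true(is.finite(ls$total$value))
  expect_gt(ls$n_fg, 0)
  strawyolo:::tape_backward(fw$tape, ls$total)
  grads <- strawyolo:::collect_grads(fw$leaves)
  gn <- vapply(ls(grads), function(p) max(abs(grads[[p]])), 0)
  expect_true(all(is.finite(gn)))
  expect_gt(max(gn), 0)
})
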