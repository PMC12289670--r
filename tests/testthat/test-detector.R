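test_that("parameter counts are invariant to the initialization seed", {
  cfg <- model_config("n", num_classes = 4)
  c1 <- count_parameters(build_model(cfg, seed = 1))
  c2 <- count_parameters(build_model(cfg, seed = 99))
  expect_identical(c1, c2)
  expect_identical(c1, strawyolo:::analytic_param_count(cfg))
})

test_that("attention variants add exactly their block nodes to the graph", {
  base <- build_model(model_config("s"), seed = 1)
  full <- build_model(model_config("s", use_se_msdwa = TRUE, use_cgfm = TRUE),
                      seed = 1)
  bt <- vapply(base$graph, `[[`, "", "type")
  ft <- vapply(full$graph, `[[`, "", "type")
  bi <- vapply(base$graph, `[[`, "", "id")
  fi <- vapply(full$graph, `[[`, "", "id")
  expect_identical(setdiff(fi, bi), c("se_p4", "se_p5"))
  expect_identical(sum(ft == "se_msdwa"), 2L)
  expect_identical(sum(ft == "cgfm"), 4L)
  expect_identical(sum(bt == "concat"), 4L)
  expect_identical(sum(ft == "concat"), 0L)
  # apart from concat -> cgfm and the two insertions, the graphs agree
  common <- intersect(bi, fi)
  for (id in common) {
    rb <- base$graph[[match(id, bi)]]; rf <- full$graph[[match(id, fi)]]
    if (rb$type == "concat") expect_identical(rf$type, "cgfm")
    else expect_identical(rf$type, rb$type)
  }
})

test_that("n and s scales differ only through depth/width multiples", {
  gn <- build_model(model_config("n"), seed = 1)
  gs <- build_model(model_config("s"), seed = 1)
  expect_identical(vapply(gn$graph, `[[`, "", "type"),
                   vapply(gs$graph, `[[`, "", "type"))
  expect_identical(gn$channels * 2L, gs$channels)
})

test_that("forward pass yields three prediction scales at strides 8/16/32", {
  m <- build_model(model_config("n", num_classes = 4), seed = 2)
  for (S in c(64L, 96L)) {
    x <- array(runif(S * S * 3 * 2), c(S, S, 3, 2))
    fw <- model_forward(m, x)
    expect_length(fw$det, 3)
    for (i in 1:3) {
      d <- dim(fw$det[[i]]$value)
      expect_identical(d, c(S %/% c(8L, 16L, 32L)[i],
                            S %/% c(8L, 16L, 32L)[i], 68L, 2L))
    }
  }
  expect_error(model_forward(m, array(0, c(50, 50, 3, 1))), "divisible")
})

test_that("shape contracts of the attention blocks hold on randomized shapes", {
  set.seed(9)
  for (i in 1:5) {
    C <- 4L * sample(1:6, 1); H <- sample(4:12, 1); W <- sample(4:12, 1)
    blk <- se_msdwa(C, reduction = 4)
    x <- array(rnorm(H * W * C), c(H, W, C, 1))
    expect_identical(dim(block_apply(blk, x)), dim(x))
    c1 <- 2L * sample(2:8, 1); c2 <- 2L * sample(2:8, 1)
    cg <- cgfm(c1, c2, heads = 2)
    y <- block_apply(cg, array(rnorm(H * W * c1), c(H, W, c1, 1)),
                     array(rnorm(H * W * c2), c(H, W, c2, 1)))
    expect_identical(dim(y), c(H, W, c1 + c2, 1L))
  }
})

test_that("nms equals the brute-force greedy suppressor", {
  for (s in 1:20) {
    set.seed(s)
    rb <- random_boxes(50)
    keep <- nms(rb$boxes, rb$scores, rb$classes, 0.5)
    ref <- oracle_nms(rb$boxes, rb$scores, rb$classes, 0.5)
    expect_identical(sort(keep), sort(ref))
  }
})

test_that("prediction decoding handles empty and duplicate cases", {
  # two identical boxes, same class: one survives
  b <- rbind(c(10, 10, 30, 30), c(10, 10, 30, 30))
  expect_length(nms(b, c(0.9, 0.8), c(0L, 0L), 0.5), 1)
  # different classes are suppressed independently
  expect_length(nms(b, c(0.9, 0.8), c(0L, 1L), 0.5), 2)
  # confidence floor of 1.01 can never be reached: empty result
  m <- build_model(model_config("n", num_classes = 4), seed = 3)
  d <- predict(m, array(0.5, c(64, 64, 3)), conf_thresh = 1.01)
  expect_identical(nrow(d), 0L)
  # boxes are clipped to image bounds
  d2 <- predict(m, array(runif(64 * 64 * 3), c(64, 64, 3)), conf_thresh = 0)
  if (nrow(d2)) {
    expect_true(all(d2$x1 >= 0 & d2$x2 <= 64))
    expect_true(all(d2$x1 < d2$x2 & d2$y1 < d2$y2))
    expect_true(all(d2$confidence >= 0 & d2$confidence <= 1))
  }
})

test_that("model checkpoints round-trip through save/load", {
  m <- build_model(model_config("n", num_classes = 4), seed = 4)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict(m, x, conf_thresh = 0.01)
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(count_parameters(m2), count_parameters(m))
  expect_equal(predict(m2, x, conf_thresh = 0.01), p1)
})
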