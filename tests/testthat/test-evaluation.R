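test_that("iou matches closed-form areas", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_warning(v <- iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
  expect_equal(v, 0)
})

test_that("greedy matching agrees with an exhaustive per-class oracle", {
  # perfect detections
  g <- data.frame(class = c(0L, 1L), x1 = c(0, 40), y1 = c(0, 40),
                  x2 = c(20, 60), y2 = c(20, 60))
  d <- data.frame(class = g$class, confidence = c(0.9, 0.8),
                  x1 = g$x1, y1 = g$y1, x2 = g$x2, y2 = g$y2)
  mc <- match_detections(d, g, 0.5)
  expect_equal(sum(mc$tp), 2); expect_equal(sum(mc$fp), 0)
  expect_equal(sum(mc$fn), 0)
  # no detections
  m0 <- match_detections(d[0, ], g, 0.5)
  expect_equal(sum(m0$tp) + sum(m0$fp), 0)
  expect_equal(sum(m0$fn), 2)
  # random boxes vs oracle
  for (s in 1:15) {
    set.seed(s)
    rd <- random_boxes(10); rg <- random_boxes(5)
    dets <- data.frame(class = rd$classes, confidence = rd$scores,
                       x1 = rd$boxes[, 1], y1 = rd$boxes[, 2],
                       x2 = rd$boxes[, 3], y2 = rd$boxes[, 4])
    gts <- data.frame(class = rg$classes, x1 = rg$boxes[, 1],
                      y1 = rg$boxes[, 2], x2 = rg$boxes[, 3],
                      y2 = rg$boxes[, 4])
    a <- match_detections(dets, gts, 0.4)
    b <- oracle_match(dets, gts, 0.4)
    expect_identical(a[order(a$class), ], b[order(b$class), ],
                     ignore_attr = TRUE)
  }
})

test_that("precision and recall follow their defining ratios with 0/0 -> 0", {
  expect_equal(precision_recall(data.frame(tp = 8, fp = 2, fn = 2)),
               c(precision = 0.8, recall = 0.8))
  expect_equal(precision_recall(data.frame(tp = 0, fp = 0, fn = 0)),
               c(precision = 0, recall = 0))
  set.seed(11)
  for (i in 1:10) {
    cts <- data.frame(tp = sample(0:20, 3, TRUE), fp = sample(0:20, 3, TRUE),
                      fn = sample(0:20, 3, TRUE))
    pr <- precision_recall(cts)
    TP <- sum(cts$tp); FP <- sum(cts$fp); FN <- sum(cts$fn)
    expect_equal(unname(pr["precision"]), if (TP + FP) TP / (TP + FP) else 0)
    expect_equal(unname(pr["recall"]), if (TP + FN) TP / (TP + FN) else 0)
  }
})

test_that("average precision: perfect and single-truth cases", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), rep(TRUE, 3), 3), 1)
  expect_equal(average_precision(0.5, TRUE, 1), 1)
  expect_equal(average_precision(numeric(), logical(), 5), 0)
  # rank statistic: invariant under uniform confidence rescaling
  set.seed(12)
  conf <- runif(30); tp <- runif(30) > 0.4
  expect_equal(average_precision(conf, tp, 20),
               average_precision(conf * 0.3, tp, 20))
})

test_that("coco map matches the exact step-integration oracle within 0.01", {
  ev <- synthetic_eval_set(20)
  res <- coco_map(ev$dets, ev$truths)
  thrs <- seq(0.5, 0.95, by = 0.05)
  for (ti in seq_along(thrs)) {
    for (cl in sort(unique(ev$truths$class))) {
      d <- ev$dets[ev$dets$class == cl, , drop = FALSE]
      d <- d[order(-d$confidence), , drop = FALSE]
      g <- ev$truths[ev$truths$class == cl, , drop = FALSE]
      fl <- strawyolo:::tp_flags(d, g, thrs[ti])
      exact <- oracle_ap_exact(d$confidence, fl, nrow(g))
      expect_lt(abs(res$ap[as.character(cl), ti] - exact), 0.01)
    }
  }
  # monotone in IoU threshold; all metrics in [0, 1]
  expect_lte(res$map5095, res$map50 + 1e-12)
  expect_true(all(res$ap >= 0 & res$ap <= 1))
  expect_true(res$precision >= 0 && res$precision <= 1)
  expect_true(res$recall >= 0 && res$recall <= 1)
})

test_that("a perfect detector scores AP = mAP = 1 at every threshold", {
  ev <- synthetic_eval_set(8)
  perfect <- ev$truths
  perfect$confidence <- 0.99
  res <- coco_map(perfect[, c("image", "class", "confidence",
                              "x1", "y1", "x2", "y2")], ev$truths)
  expect_equal(res$map50, 1)
  expect_equal(res$map5095, 1)
  expect_true(all(res$ap == 1))
})
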