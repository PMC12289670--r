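test_that("box depth takes the median of the central region in centimeters", {
  K <- camera_intrinsics(600, 600, 50, 50, depth_scale = 0.1)
  d <- matrix(219.3, 100, 100) # uniform depth, stored millimeters
  expect_equal(box_depth(c(20, 20, 60, 60), d, K), 21.93)
  # all-invalid region
  d0 <- matrix(0, 100, 100)
  expect_error(box_depth(c(20, 20, 60, 60), d0, K),
               class = "strawyolo_no_depth")
  # median is robust to an outlier
  d1 <- matrix(0, 100, 100)
  d1[40:41, 40:41] <- c(10, 10, 10, 999)
  expect_equal(box_depth(c(30, 30, 50, 50), d1, K), 10 * 0.1)
  expect_error(box_depth(c(-5, 0, 50, 50), d, K), "bounds")
})

test_that("backprojection follows the pinhole model and inverts projection", {
  K <- camera_intrinsics(600, 600, 320, 240)
  expect_equal(drop(backproject(320, 240, 50, K)), c(X = 0, Y = 0, Z = 50))
  expect_equal(unname(backproject(920, 240, 60, K)[, "X"]), 60)
  expect_error(backproject(0, 0, -1, K), "positive")
  set.seed(13)
  X <- runif(1000, -30, 30); Y <- runif(1000, -20, 20); Z <- runif(1000, 20, 90)
  uv <- strawyolo:::project(X, Y, Z, K)
  back <- backproject(uv[, "u"], uv[, "v"], Z, K)
  expect_lt(max(abs(back[, "X"] - X)), 1e-9)
  expect_lt(max(abs(back[, "Y"] - Y)), 1e-9)
})

test_that("detections are annotated with 3D positions and distance", {
  K <- camera_intrinsics(600, 600, 48, 48)
  sc <- render_scene(tiny_scene()$spec)
  dets <- data.frame(class = sc$labels$class, confidence = 0.9,
                     x1 = sc$boxes_px[, 1], y1 = sc$boxes_px[, 2],
                     x2 = sc$boxes_px[, 3], y2 = sc$boxes_px[, 4])
  out <- localize_detections(dets, sc$depth, K)
  expect_true(all(out$has_3d))
  # first object sits on the optical axis: distance equals its Z
  expect_equal(out$distance_cm[1], 50, tolerance = 1e-6)
  expect_equal(out$X[1], 0, tolerance = 1e-6)
  # raw-depth mode reports Z
  outz <- localize_detections(dets, sc$depth, K, mode = "z")
  expect_equal(outz$distance_cm, outz$Z)
  # empty input stays empty
  expect_identical(nrow(localize_detections(dets[0, ], sc$depth, K)), 0L)
  # no valid depth: flagged but kept
  out0 <- localize_detections(dets, matrix(0, 96, 96), K)
  expect_identical(nrow(out0), nrow(dets))
  expect_false(any(out0$has_3d))
})

test_that("place -> render -> localize recovers 3D positions within 0.5 cm", {
  # noiseless: one object per scene so no occluder contaminates the median
  set.seed(14)
  S <- 128L
  K <- camera_intrinsics(600 * S / 640, 600 * S / 640, S / 2, S / 2)
  err <- vapply(1:40, function(i) {
    obj <- random_objects(1, image_size = S, intrinsics = K)
    sc <- render_scene(scene_spec(obj, S, K, clutter = 0, seed = i))
    out <- localize_detections(
      data.frame(x1 = sc$boxes_px[1, 1], y1 = sc$boxes_px[1, 2],
                 x2 = sc$boxes_px[1, 3], y2 = sc$boxes_px[1, 4]),
      sc$depth, K)
    sqrt((out$X - obj$X)^2 + (out$Y - obj$Y)^2 + (out$Z - obj$Z)^2)
  }, 0)
  expect_lt(max(err), 0.5)
})

test_that("camera distance is invariant to in-plane rotation about the center", {
  K <- camera_intrinsics(600, 600, 48, 48)
  sc <- render_scene(tiny_scene()$spec)
  box <- sc$boxes_px[1, ] # centered object
  d1 <- localize_detections(
    data.frame(x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4]),
    sc$depth, K)$distance_cm
  rot <- t(sc$depth[nrow(sc$depth):1, ]) # 90-degree rotation
  d2 <- localize_detections(
    data.frame(x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4]),
    rot, K)$distance_cm
  expect_equal(d1, d2, tolerance = 1e-6)
})
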