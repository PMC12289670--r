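test_that("projection geometry follows similar triangles", {
  K <- camera_intrinsics(600, 600, 320, 320)
  obj <- data.frame(class = 3L, X = 0, Y = 0, Z = 50, radius = 2)
  sc <- render_scene(scene_spec(obj, 640, K, clutter = 0, seed = 1))
  # projected radius = fx * R / Z = 600 * 2 / 50 = 24 px, centered
  expect_equal(unname(sc$boxes_px[1, ]), c(320 - 24, 320 - 24, 320 + 24, 320 + 24))
  expect_equal(sc$labels$cx, 0.5)
  expect_equal(sc$labels$w, 48 / 640)
  # depth map carries Z at the center, background elsewhere
  expect_equal(sc$depth[320, 320] * K$depth_scale, 50)
  expect_equal(sc$depth[5, 5] * K$depth_scale, 150)
})

test_that("occlusion keeps the nearer object in the depth map", {
  K <- camera_intrinsics(600, 600, 48, 48)
  obj <- data.frame(class = c(3L, 2L), X = c(0, 0.5), Y = c(0, 0),
                    Z = c(50, 40), radius = c(2, 2))
  sc <- render_scene(scene_spec(obj, 96, K, clutter = 0, seed = 1))
  # overlap region: nearer Z (40 cm) wins
  expect_equal(sc$depth[48, 48] * K$depth_scale, 40)
  # object projecting outside the frame is rejected with its index
  bad <- data.frame(class = 0L, X = 30, Y = 0, Z = 35, radius = 2)
  expect_error(render_scene(scene_spec(bad, 96, K, seed = 1)), "outside")
})

test_that("rendering is byte-identical under a fixed seed", {
  sp <- tiny_scene()$spec
  expect_identical(render_scene(sp), render_scene(sp))
})

test_that("datasets split 7:2:1 with valid labels and matched depth", {
  dir <- file.path(tempdir(), "ds-splits")
  unlink(dir, recursive = TRUE)
  mf <- make_dataset(dir, n_images = 20, seed = 5, image_size = 96)
  ds <- load_dataset(dir)
  expect_identical(nrow(ds$items$train), 14L)
  expect_identical(nrow(ds$items$val), 4L)
  expect_identical(nrow(ds$items$test), 2L)
  K <- do.call(camera_intrinsics, ds$intrinsics)
  for (s in c("train", "val", "test")) {
    it <- ds$items[[s]]
    for (i in seq_len(nrow(it))) {
      lab <- strawyolo:::read_labels(it$label[i])
      expect_true(all(lab$class %in% 0:3))
      vals <- unlist(lab[, c("cx", "cy", "w", "h")])
      expect_true(all(vals >= 0 & vals <= 1))
      # depth/label consistency: central-crop median equals some object Z
      dep <- strawyolo:::read_depth(it$depth[i])
      S <- ds$image_size
      for (j in seq_len(nrow(lab))) {
        box <- c((lab$cx[j] - lab$w[j] / 2) * S, (lab$cy[j] - lab$h[j] / 2) * S,
                 (lab$cx[j] + lab$w[j] / 2) * S, (lab$cy[j] + lab$h[j] / 2) * S)
        z <- tryCatch(box_depth(box, dep, K), strawyolo_no_depth = function(e) NA)
        if (!is.na(z)) expect_true(z <= 81 || z >= 149) # object or background
      }
    }
  }
})

test_that("labels round-trip through files within a pixel", {
  sp <- tiny_scene()$spec
  sc <- render_scene(sp)
  f <- tempfile(fileext = ".txt")
  write.table(format(sc$labels, digits = 8, scientific = FALSE), f,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  back <- strawyolo:::read_labels(f)
  S <- 96
  expect_lt(max(abs(cbind((back$cx - back$w / 2) * S, (back$cy - back$h / 2) * S,
                          (back$cx + back$w / 2) * S, (back$cy + back$h / 2) * S)
                    - sc$boxes_px)), 1)
})

test_that("class mix is honored within binomial sampling error", {
  set.seed(31)
  obj <- random_objects(400, class_mix = rep(0.25, 4))
  counts <- table(factor(obj$class, levels = 0:3))
  sigma <- sqrt(400 * 0.25 * 0.75)
  expect_true(all(abs(counts - 100) <= 3 * sigma))
})

test_that("objects respect the resolvability floor at small render sizes", {
  set.seed(32)
  K96 <- camera_intrinsics(90, 90, 48, 48)
  obj <- random_objects(100, image_size = 96, intrinsics = K96)
  r_px <- 90 * obj$radius / obj$Z
  expect_true(all(2 * r_px >= 8 - 1e-9))
  # at the native 640 scale the floor never binds the stated size range
  K640 <- camera_intrinsics(600, 600, 320, 320)
  obj640 <- random_objects(200, image_size = 640, intrinsics = K640)
  expect_true(all(obj640$radius <= 2.6 + 1e-9))
  expect_true(all(obj640$Z >= 30 & obj640$Z <= 80))
})
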