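# Synthetic orchard scenes: parametric colored shapes standing in for the
# four strawberry growth stages (bud, flower, under-ripe fruit, ripe fruit),
# placed at known camera-frame 3D positions, rendered through the pinhole
# model onto an RGB canvas with leaf-green background clutter and an aligned
# depth map. Ground-truth labels are the exact projected boxes in YOLO
# normalized format, so detector training, metric evaluation and 3D
# localization can all be tested against known truth.

STAGE_CLASSES <- c("bud", "flower", "under_ripe", "ripe")

#' Scene specification
#'
#' @param objects data.frame with columns class (0-3 or stage name),
#'   X, Y, Z (centimeters, camera frame, Z > 0) and radius (centimeters).
#' @param image_size image side in pixels (square images).
#' @param intrinsics a [camera_intrinsics()]; default centers the principal
#'   point with focal length 600 px.
#' @param background_depth_cm depth assigned to background pixels.
#' @param clutter number of background clutter ellipses.
#' @param seed integer seed making the render byte-identical across runs.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(objects, image_size = 640L, intrinsics = NULL,
                       background_depth_cm = 150, clutter = 30L, seed = 1L) {
  if (is.null(intrinsics))
    intrinsics <- camera_intrinsics(600, 600, image_size / 2, image_size / 2)
  if (is.character(objects$class))
    objects$class <- match(objects$class, STAGE_CLASSES) - 1L
  if (any(objects$Z <= 0)) stop("objects must be in front of the camera (Z > 0)")
  structure(list(objects = objects, image_size = as.integer(image_size),
                 intrinsics = intrinsics,
                 background_depth_cm = background_depth_cm,
                 clutter = as.integer(clutter), seed = as.integer(seed)),
            class = "scene_spec")
}

stage_palette <- function(class_id, rng_offset = 0) {
  switch(class_id + 1L,
         list(base = c(0.82, 0.88, 0.72)),  # bud: pale green cluster
         list(base = c(0.97, 0.97, 0.95)),  # flower: white petals
         list(base = c(0.55, 0.75, 0.30)),  # under-ripe: green-red gradient
         list(base = c(0.85, 0.12, 0.10)))  # ripe: red with speckles
}

# Paint one object into image/depth. `ug`, `vg` are pixel-center coordinate
# matrices; returns modified (image, depth) in the enclosing environment.
draw_stage <- function(image, depth_cm, ug, vg, u, v, r_px, class_id, Z) {
  d2 <- (ug - u)^2 + (vg - v)^2
  disc <- d2 <= r_px^2
  nearer <- disc & (depth_cm == 0 | Z < depth_cm)
  if (class_id == 0L) {                      # bud: pale cluster of lobes
    col <- c(0.82, 0.88, 0.72)
    lob <- d2 <= (0.55 * r_px)^2
    for (a in seq(0, 2 * pi * 2 / 3, length.out = 3)) {
      lob <- lob | (((ug - (u + 0.5 * r_px * cos(a)))^2 +
                     (vg - (v + 0.5 * r_px * sin(a)))^2) <= (0.45 * r_px)^2)
    }
    paintmask <- lob & nearer
    for (k in 1:3) image[, , k][paintmask] <- col[k] - 0.05 * (k == 1) *
        (d2[paintmask] / r_px^2)
  } else if (class_id == 1L) {               # flower: white petals, green disc
    core <- d2 <= (0.45 * r_px)^2
    pet <- core & FALSE
    for (a in seq(0, 2 * pi * 4 / 5, length.out = 5)) {
      pet <- pet | (((ug - (u + 0.58 * r_px * cos(a)))^2 +
                     (vg - (v + 0.58 * r_px * sin(a)))^2) <= (0.4 * r_px)^2)
    }
    pm <- pet & nearer & !core
    cm <- core & nearer
    image[, , 1][pm] <- 0.97; image[, , 2][pm] <- 0.97; image[, , 3][pm] <- 0.95
    image[, , 1][cm] <- 0.35; image[, , 2][cm] <- 0.62; image[, , 3][cm] <- 0.18
    paintmask <- pm | cm
  } else if (class_id == 2L) {               # under-ripe: green->red gradient
    pm <- disc & nearer
    t <- pmin(1, pmax(0, (vg - (v - r_px)) / (2 * r_px)))
    image[, , 1][pm] <- 0.35 + 0.5 * t[pm]
    image[, , 2][pm] <- 0.72 - 0.5 * t[pm]
    image[, , 3][pm] <- 0.20
    paintmask <- pm
  } else {                                   # ripe: red disc, dark speckles
    pm <- disc & nearer
    image[, , 1][pm] <- 0.85; image[, , 2][pm] <- 0.12; image[, , 3][pm] <- 0.10
    spk <- pm & ((round(ug * 0.8) + round(vg * 0.8)) %% 5 == 0)
    image[, , 1][spk] <- 0.45; image[, , 2][spk] <- 0.25; image[, , 3][spk] <- 0.12
    paintmask <- pm
  }
  # the full projected disc occludes in depth regardless of paint pattern
  depth_cm[nearer] <- Z
  list(image = image, depth_cm = depth_cm, painted = nearer)
}

#' Render a synthetic scene
#'
#' Draws every object at its pinhole-projected location and size (projected
#' radius = focal length x radius / Z), nearest object winning per pixel in
#' the depth map; the background sits at the far depth. Labels are the exact
#' projected boxes.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H, W, 3 array in \[0,1\]), `depth` (matrix of
#'   stored units, millimeters by default: centimeters / depth_scale),
#'   `labels` (data.frame class, cx, cy, w, h), `boxes_px` (pixel boxes),
#'   and `objects`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  S <- spec$image_size
  K <- spec$intrinsics
  # leaf-green background with clutter ellipses
  image <- array(0, c(S, S, 3))
  image[, , 1] <- 0.20; image[, , 2] <- 0.38; image[, , 3] <- 0.12
  ug <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)  # x of pixel center
  vg <- matrix(rep(seq_len(S) - 0.5, times = S), S, S) # y of pixel center
  for (i in seq_len(spec$clutter)) {
    cu <- stats::runif(1, 0, S); cv <- stats::runif(1, 0, S)
    a <- stats::runif(1, S / 40, S / 8); b <- stats::runif(1, S / 40, S / 8)
    g <- stats::runif(1, 0.25, 0.6)
    m <- ((ug - cu) / a)^2 + ((vg - cv) / b)^2 <= 1
    image[, , 1][m] <- g * 0.5; image[, , 2][m] <- g; image[, , 3][m] <- g * 0.3
  }
  depth_cm <- matrix(0, S, S) # 0 = not yet assigned
  obj <- spec$objects
  if (nrow(obj)) {
    ord <- order(-obj$Z) # far to near, so paint respects occlusion
    boxes <- matrix(NA_real_, nrow(obj), 4)
    for (i in ord) {
      uv <- project(obj$X[i], obj$Y[i], obj$Z[i], K)
      r_px <- K$fx * obj$radius[i] / obj$Z[i]
      b <- c(uv[1] - r_px, uv[2] - r_px, uv[1] + r_px, uv[2] + r_px)
      if (b[1] < 0 || b[2] < 0 || b[3] > S || b[4] > S)
        stop("object ", i, " (class ", obj$class[i],
             ") projects outside the frame")
      dr <- draw_stage(image, depth_cm, ug, vg, uv[1], uv[2], r_px,
                       obj$class[i], obj$Z[i])
      image <- dr$image; depth_cm <- dr$depth_cm
      boxes[i, ] <- b
    }
    labels <- data.frame(class = obj$class,
                         cx = (boxes[, 1] + boxes[, 3]) / 2 / S,
                         cy = (boxes[, 2] + boxes[, 4]) / 2 / S,
                         w = (boxes[, 3] - boxes[, 1]) / S,
                         h = (boxes[, 4] - boxes[, 2]) / S)
  } else {
    labels <- empty_labels()
    boxes <- matrix(numeric(), 0, 4)
  }
  depth_cm[depth_cm == 0] <- spec$background_depth_cm
  list(image = image,
       depth = round(depth_cm / K$depth_scale), # stored units (mm)
       labels = labels, boxes_px = boxes, objects = obj)
}

#' Random scene objects within the camera frustum
#'
#' Places objects at shooting distances of 30-80 cm with physical radii of
#' 1.2-2.6 cm, rejection-free: pixel positions are drawn inside the frame
#' with a margin covering the projected radius, then back-projected.
#'
#' @param n_objects number of objects.
#' @param class_mix sampling probabilities over the 4 stages.
#' @param image_size,intrinsics as in [scene_spec()].
#' @param min_box_px resolvability floor: every object must subtend at
#'   least this many pixels, so that the coarsest anchor grid of the
#'   detector (stride 8) can be assigned to it. Non-binding at the native
#'   640-pixel scale; it only lifts radii in heavily downscaled fixtures.
#' @return data.frame suitable for [scene_spec()].
#' @export
random_objects <- function(n_objects, class_mix = rep(0.25, 4),
                           image_size = 640L, intrinsics = NULL,
                           min_box_px = 8) {
  if (is.null(intrinsics))
    intrinsics <- camera_intrinsics(600, 600, image_size / 2, image_size / 2)
  cls <- sample(0:3, n_objects, replace = TRUE, prob = class_mix)
  Z <- stats::runif(n_objects, 30, 80)
  radius <- stats::runif(n_objects, 1.2, 2.6)
  radius <- pmax(radius, min_box_px / 2 * Z / intrinsics$fx)
  r_px <- intrinsics$fx * radius / Z
  u <- stats::runif(n_objects, r_px + 1, image_size - r_px - 1)
  v <- stats::runif(n_objects, r_px + 1, image_size - r_px - 1)
  X <- (u - intrinsics$cx) * Z / intrinsics$fx
  Y <- (v - intrinsics$cy) * Z / intrinsics$fy
  data.frame(class = cls, X = X, Y = Y, Z = Z, radius = radius)
}

#' Generate a detector dataset on disk
#'
#' Renders `n_images` synthetic scenes and writes the detector's manifest
#' layout: `<dir>/{train,val,test}/{images,labels,depth}` plus a
#' `dataset.yaml` manifest. Images are split 7:2:1 by a seeded shuffle.
#' Depth maps are stored as plain-text integer matrices in millimeters.
#'
#' @param dir target directory (created).
#' @param n_images number of images (>= 10).
#' @param class_mix sampling probabilities over the 4 stages.
#' @param seed integer seed; the whole dataset is a pure function of it.
#' @param image_size image side in pixels.
#' @param objects_per_image integer range, objects drawn uniformly within.
#' @param write_depth write depth maps (disable to save space/time when
#'   only training is exercised).
#' @return path to the manifest file, invisibly a list with the manifest.
#' @export
make_dataset <- function(dir, n_images = 100L, class_mix = rep(0.25, 4),
                         seed = 1L, image_size = 640L,
                         objects_per_image = c(2L, 6L), write_depth = TRUE) {
  if (n_images < 10) stop("n_images must be >= 10")
  set.seed(seed)
  K <- camera_intrinsics(600 * image_size / 640, 600 * image_size / 640,
                         image_size / 2, image_size / 2)
  n_train <- round(0.7 * n_images)
  n_val <- round(0.2 * n_images)
  split <- c(rep("train", n_train), rep("val", n_val),
             rep("test", n_images - n_train - n_val))
  split <- split[sample.int(n_images)]
  for (s in unique(split))
    for (sub in c("images", "labels", if (write_depth) "depth"))
      dir.create(file.path(dir, s, sub), recursive = TRUE, showWarnings = FALSE)
  seeds <- sample.int(2^31 - 2, n_images)
  for (i in seq_len(n_images)) {
    nob <- sample(objects_per_image[1]:objects_per_image[2], 1)
    obj <- random_objects(nob, class_mix, image_size, K)
    sc <- render_scene(scene_spec(obj, image_size, K, clutter = 12L,
                                  seed = seeds[i]))
    stem <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(dir, split[i], "images",
                                      paste0(stem, ".png")))
    write.table(format(sc$labels, digits = 8, scientific = FALSE),
                file.path(dir, split[i], "labels", paste0(stem, ".txt")),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    if (write_depth)
      write.table(sc$depth, file.path(dir, split[i], "depth",
                                      paste0(stem, ".txt")),
                  row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(names = STAGE_CLASSES, nc = 4L,
                   image_size = as.integer(image_size),
                   intrinsics = list(fx = K$fx, fy = K$fy, cx = K$cx,
                                     cy = K$cy, depth_scale = K$depth_scale),
                   splits = list(train = "train", val = "val", test = "test"),
                   n_images = as.integer(n_images), seed = as.integer(seed))
  yaml::write_yaml(manifest, file.path(dir, "dataset.yaml"))
  invisible(c(manifest, list(path = normalizePath(dir))))
}

#' Load a dataset manifest
#'
#' @param dir dataset directory containing `dataset.yaml`.
#' @return list with the manifest plus per-split item tables.
#' @export
load_dataset <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  mf$path <- normalizePath(dir)
  mf$items <- lapply(setNames(nm = names(mf$splits)), function(s) {
    imgs <- sort(list.files(file.path(dir, s, "images"), full.names = TRUE))
    if (!length(imgs)) return(NULL)
    stems <- sub("\\.png$", "", basename(imgs))
    data.frame(stem = stems, image = imgs,
               label = file.path(dir, s, "labels", paste0(stems, ".txt")),
               depth = file.path(dir, s, "depth", paste0(stems, ".txt")))
  })
  mf
}

read_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) return(empty_labels())
  d <- read.table(path, col.names = c("class", "cx", "cy", "w", "h"))
  d$class <- as.integer(d$class)
  d
}

read_depth <- function(path) as.matrix(read.table(path))
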