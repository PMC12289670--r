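# Warmup-scheduled data augmentation. Augmentation probabilities ramp
# linearly from 0 to their configured base values over the first fifth of
# training: N = current_epoch * 5 / total_epochs, P = min(N, 1), and every
# augmentation fires with probability P times its base probability.
# Epochs are 0-based, so the very first epoch trains on clean images.

#' Warmup factor for data-augmentation probabilities
#'
#' @param current_epoch 0-based epoch index.
#' @param total_epochs total number of training epochs (>= 1).
#' @return the warmup factor P in \[0, 1\]: `current_epoch * 5 /
#'   total_epochs`, clamped at 1, so P reaches 1 at exactly one fifth of
#'   training.
#' @export
warmup_probability <- function(current_epoch, total_epochs) {
  if (length(total_epochs) != 1 || is.na(total_epochs) || total_epochs < 1)
    stop("total_epochs must be a positive integer")
  if (any(current_epoch < 0) || any(current_epoch > total_epochs))
    stop("current_epoch must lie in [0, total_epochs]")
  n <- current_epoch * 5 / total_epochs
  pmin(n, 1)
}

#' Base augmentation probabilities of the detector's default pipeline
#'
#' @return named numeric vector of per-augmentation base probabilities.
#' @export
default_augmentations <- function()
  c(mosaic = 1.0, affine = 1.0, hsv = 1.0, fliplr = 0.5)

#' Default augmentation magnitudes
#'
#' Hue shift fraction, saturation/value gains, translation fraction and
#' scale range used when the corresponding augmentation fires.
#' @return named list.
#' @export
default_magnitudes <- function()
  list(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4, translate = 0.1, scale = 0.5)

#' Per-epoch effective augmentation plan
#'
#' Scales every base probability by the warmup factor of the given epoch.
#' At P = 1 the plan equals the base pipeline.
#'
#' @param current_epoch 0-based epoch index.
#' @param total_epochs total epochs.
#' @param base named vector of base probabilities in \[0, 1\].
#' @return object of class `aug_plan` with elements `warmup_factor`,
#'   `base_probabilities`, `effective_probabilities`.
#' @export
effective_plan <- function(current_epoch, total_epochs,
                           base = default_augmentations()) {
  if (any(base < 0 | base > 1)) stop("base probabilities must be in [0, 1]")
  p <- warmup_probability(current_epoch, total_epochs)
  out <- list(warmup_factor = p, base_probabilities = base,
              effective_probabilities = p * base)
  class(out) <- "aug_plan"
  out
}

#' @export
print.aug_plan <- function(x, ...) {
  cat(sprintf("<aug_plan> warmup factor P = %.3f\n", x$warmup_factor))
  print(rbind(base = x$base_probabilities,
              effective = x$effective_probabilities))
  invisible(x)
}

## geometric / photometric transforms ------------------------------------------

flip_horizontal <- function(image, labels) {
  image <- image[, rev(seq_len(ncol(image))), , drop = FALSE]
  if (nrow(labels)) labels$cx <- 1 - labels$cx
  list(image = image, labels = labels)
}

hsv_jitter <- function(image, dh, ds, dv) {
  d <- dim(image)
  m <- matrix(aperm(image, c(3, 1, 2)), nrow = 3) # 3 x npix, rows r,g,b
  hsvm <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hsvm[1, ] <- (hsvm[1, ] + dh) %% 1
  hsvm[2, ] <- pmin(1, pmax(0, hsvm[2, ] * ds))
  hsvm[3, ] <- pmin(1, pmax(0, hsvm[3, ] * dv))
  # hsv() returns hex; convert back numerically instead
  h6 <- hsvm[1, ] * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  v <- hsvm[3, ]; s <- hsvm[2, ]
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- aperm(array(rbind(r, g, b), c(3, d[1], d[2])), c(2, 3, 1))
  out
}

# Random scale about the image center plus translation; nearest-neighbor
# resampling, gray fill outside the source.
affine_translate_scale <- function(image, labels, s, tx, ty, fill = 114 / 255) {
  d <- dim(image); H <- d[1]; W <- d[2]
  # destination pixel centers (normalized) map back to source coords
  xc <- (seq_len(W) - 0.5) / W
  yc <- (seq_len(H) - 0.5) / H
  sx <- (xc - 0.5 - tx) / s + 0.5
  sy <- (yc - 0.5 - ty) / s + 0.5
  jx <- round(sx * W + 0.5)
  jy <- round(sy * H + 0.5)
  okx <- jx >= 1 & jx <= W; oky <- jy >= 1 & jy <= H
  out <- array(fill, d)
  out[oky, okx, ] <- image[jy[oky], jx[okx], , drop = FALSE]
  if (nrow(labels)) {
    cx <- (labels$cx - 0.5) * s + 0.5 + tx
    cy <- (labels$cy - 0.5) * s + 0.5 + ty
    w <- labels$w * s; h <- labels$h * s
    x1 <- pmax(0, cx - w / 2); x2 <- pmin(1, cx + w / 2)
    y1 <- pmax(0, cy - h / 2); y2 <- pmin(1, cy + h / 2)
    keep <- (x2 - x1) > 1e-3 & (y2 - y1) > 1e-3
    if (any(!keep))
      warning(sum(!keep), " box(es) degenerate after affine transform; dropped",
              call. = FALSE)
    labels <- data.frame(class = labels$class[keep],
                         cx = (x1 + x2)[keep] / 2, cy = (y1 + y2)[keep] / 2,
                         w = (x2 - x1)[keep], h = (y2 - y1)[keep])
  }
  list(image = out, labels = labels)
}

# Four images at half scale in the quadrants of one canvas.
mosaic4 <- function(image, labels, pool_items) {
  d <- dim(image); H <- d[1]; W <- d[2]
  halves <- function(img) img[seq(1, nrow(img), by = 2),
                              seq(1, ncol(img), by = 2), , drop = FALSE]
  imgs <- c(list(list(image = image, labels = labels)), pool_items)
  out <- array(0, d)
  lab <- list()
  offs <- list(c(0, 0), c(0, 0.5), c(0.5, 0), c(0.5, 0.5)) # (y, x) offsets
  for (k in 1:4) {
    it <- imgs[[k]]
    hx <- halves(it$image)
    oy <- offs[[k]][1] * H; ox <- offs[[k]][2] * W
    out[oy + seq_len(nrow(hx)), ox + seq_len(ncol(hx)), ] <- hx
    if (nrow(it$labels)) {
      l <- it$labels
      lab[[k]] <- data.frame(class = l$class,
                             cx = l$cx / 2 + offs[[k]][2],
                             cy = l$cy / 2 + offs[[k]][1],
                             w = l$w / 2, h = l$h / 2)
    }
  }
  list(image = out, labels = do.call(rbind, c(lab, list(empty_labels()))))
}

empty_labels <- function()
  data.frame(class = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric())

#' Apply the augmentation pipeline to one image
#'
#' Each augmentation in the plan fires independently with its effective
#' probability. Boxes stay normalized and consistent with the geometric
#' transforms; boxes that degenerate to (near) zero area are dropped with a
#' warning. Fully reproducible given `rng_seed`.
#'
#' @param image (H, W, 3) array in \[0, 1\].
#' @param labels data.frame with columns class, cx, cy, w, h (normalized).
#' @param plan an [effective_plan()].
#' @param rng_seed optional integer seed.
#' @param pool optional list of `list(image=, labels=)` used by mosaic; if
#'   fewer than 3 are supplied, mosaic is skipped.
#' @param magnitudes see [default_magnitudes()].
#' @return `list(image, labels, fired)` where `fired` names the
#'   augmentations that fired.
#' @export
apply_augmentations <- function(image, labels, plan, rng_seed = NULL,
                                pool = NULL, magnitudes = default_magnitudes()) {
  stopifnot(inherits(plan, "aug_plan"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (nrow(labels) && (any(labels$cx < 0 | labels$cx > 1) ||
                       any(labels$w < 0 | labels$w > 1)))
    stop("labels must be YOLO-normalized in [0, 1]")
  p <- plan$effective_probabilities
  fires <- function(name) !is.na(p[name]) && stats::runif(1) < p[name]
  fired <- character()
  cur <- list(image = image, labels = labels)
  if (fires("mosaic")) {
    if (length(pool) >= 3) {
      idx <- sample(length(pool), 3)
      cur <- mosaic4(cur$image, cur$labels, pool[idx])
      fired <- c(fired, "mosaic")
    }
  }
  if (fires("affine")) {
    s <- stats::runif(1, 1 - magnitudes$scale, 1 + magnitudes$scale)
    tx <- stats::runif(1, -magnitudes$translate, magnitudes$translate)
    ty <- stats::runif(1, -magnitudes$translate, magnitudes$translate)
    cur <- affine_translate_scale(cur$image, cur$labels, s, tx, ty)
    fired <- c(fired, "affine")
  }
  if (fires("hsv")) {
    dh <- stats::runif(1, -magnitudes$hsv_h, magnitudes$hsv_h)
    ds <- stats::runif(1, 1 - magnitudes$hsv_s, 1 + magnitudes$hsv_s)
    dv <- stats::runif(1, 1 - magnitudes$hsv_v, 1 + magnitudes$hsv_v)
    cur$image <- hsv_jitter(cur$image, dh, ds, dv)
    fired <- c(fired, "hsv")
  }
  if (fires("fliplr")) {
    cur <- flip_horizontal(cur$image, cur$labels)
    fired <- c(fired, "fliplr")
  }
  list(image = cur$image, labels = cur$labels, fired = fired)
}
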