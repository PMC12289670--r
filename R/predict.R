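# Decoding raw head outputs to detections: softmax-expectation of the
# per-side distance distributions, anchor offsets, confidence filtering and
# class-wise greedy non-maximum suppression.

# Anchor centers (pixels) and strides for a given input size.
make_anchors <- function(H, W, strides = c(8L, 16L, 32L)) {
  out <- lapply(strides, function(s) {
    h <- H %/% s; w <- W %/% s
    k <- seq_len(h * w) - 1L
    data.frame(ax = ((k %/% h) + 0.5) * s, ay = ((k %% h) + 0.5) * s,
               stride = s)
  })
  do.call(rbind, out)
}

# (A, 64) distance logits -> (A, 4) expected distances in grid units.
dist_expectation <- function(dl) {
  out <- matrix(0, nrow(dl), 4)
  for (side in 1:4) {
    z <- dl[, (side - 1L) * REG_MAX + seq_len(REG_MAX), drop = FALSE]
    z <- z - apply(z, 1, max)
    e <- exp(z)
    out[, side] <- (e %*% (seq_len(REG_MAX) - 1)) / rowSums(e)
  }
  out
}

# Stack raw head arrays of one image into (A, 4+nc): decoded pixel boxes
# plus class probabilities.
decode_raw <- function(raw, n, nc, H, W) {
  anch <- make_anchors(H, W)
  mats <- lapply(raw, function(a) {
    d <- dim(a)
    m <- a[, , , n]
    dim(m) <- c(d[1] * d[2], d[3])
    m
  })
  m <- do.call(rbind, mats)
  dist <- dist_expectation(m[, seq_len(4 * REG_MAX), drop = FALSE])
  cls <- 1 / (1 + exp(-m[, 4 * REG_MAX + seq_len(nc), drop = FALSE]))
  boxes <- cbind(anch$ax - dist[, 1] * anch$stride,
                 anch$ay - dist[, 2] * anch$stride,
                 anch$ax + dist[, 3] * anch$stride,
                 anch$ay + dist[, 4] * anch$stride)
  list(boxes = boxes, cls = cls, anchors = anch)
}

#' Class-wise greedy non-maximum suppression
#'
#' Detections are visited in descending score order; a detection is
#' suppressed if it overlaps an already-kept detection of the same class
#' with IoU above the threshold.
#'
#' @param boxes (n x 4) pixel boxes (x1, y1, x2, y2).
#' @param scores confidence scores.
#' @param classes class ids.
#' @param iou_threshold suppression threshold.
#' @return integer indices of the kept detections (in score order).
#' @export
nms <- function(boxes, scores, classes, iou_threshold = 0.7) {
  if (!length(scores)) return(integer())
  o <- order(-scores)
  keep <- integer()
  for (i in o) {
    same <- keep[classes[keep] == classes[i]]
    if (length(same)) {
      M <- iou_matrix(boxes[i, , drop = FALSE], boxes[same, , drop = FALSE])
      if (any(M > iou_threshold)) next
    }
    keep <- c(keep, i)
  }
  keep
}

#' Detect objects in an image
#'
#' Runs the network in inference mode, decodes the three prediction scales,
#' filters by confidence, applies class-wise NMS and clips boxes to the
#' image bounds.
#'
#' @param object a `straw_model`.
#' @param image (H, W, 3) array in \[0,1\], or a PNG file path. Sides must
#'   be divisible by 32.
#' @param conf_thresh,iou_thresh overrides of the model config defaults.
#' @param ... unused.
#' @return data.frame of detections: class, confidence, x1, y1, x2, y2.
#' @export
predict.straw_model <- function(object, image, conf_thresh = NULL,
                                iou_thresh = NULL, ...) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image: ", image)
    image <- png::readPNG(image)
  }
  if (length(dim(image)) == 2L) image <- array(rep(image, 3), c(dim(image), 3))
  conf_thresh <- conf_thresh %||% object$cfg$conf_thresh
  iou_thresh <- iou_thresh %||% object$cfg$iou_thresh
  d <- dim(image)
  x <- image[, , 1:3, drop = FALSE]
  dim(x) <- c(d[1], d[2], 3L, 1L)
  fw <- model_forward(object, x, training = FALSE)
  raw <- lapply(fw$det, `[[`, "value")
  dets_from_raw(raw, 1L, object$cfg$num_classes, d[1], d[2],
                conf_thresh, iou_thresh)
}

# Shared decode path (also used on training batches).
dets_from_raw <- function(raw, n, nc, H, W, conf_thresh, iou_thresh) {
  dec <- decode_raw(raw, n, nc, H, W)
  best <- max.col(dec$cls, ties.method = "first")
  conf <- dec$cls[cbind(seq_len(nrow(dec$cls)), best)]
  sel <- which(conf >= conf_thresh)
  if (!length(sel))
    return(data.frame(class = integer(), confidence = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  boxes <- dec$boxes[sel, , drop = FALSE]
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), W)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), H)
  cl <- best[sel] - 1L
  sc <- conf[sel]
  keep <- nms(boxes, sc, cl, iou_thresh)
  data.frame(class = cl[keep], confidence = sc[keep],
             x1 = boxes[keep, 1], y1 = boxes[keep, 2],
             x2 = boxes[keep, 3], y2 = boxes[keep, 4])
}

#' Evaluate a detector on a dataset split
#'
#' Runs inference on every image of the split and computes COCO-style
#' metrics against the YOLO-format labels.
#'
#' @param model a `straw_model`.
#' @param items item table from [load_dataset()] (columns image, label), or
#'   a list of in-memory `list(image=, labels=)` scenes.
#' @param conf_thresh low confidence floor for ranking (default 0.001).
#' @param iou_thresh NMS threshold.
#' @return [coco_map()] result.
#' @export
evaluate_model <- function(model, items, conf_thresh = 0.001,
                           iou_thresh = 0.7) {
  dets <- list(); truths <- list()
  get_item <- function(i) {
    if (is.data.frame(items))
      list(image = png::readPNG(items$image[i]),
           labels = read_labels(items$label[i]))
    else items[[i]]
  }
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  for (i in seq_len(n)) {
    it <- get_item(i)
    H <- dim(it$image)[1]; W <- dim(it$image)[2]
    d <- predict(model, it$image, conf_thresh = conf_thresh,
                 iou_thresh = iou_thresh)
    if (nrow(d)) { d$image <- i; dets[[length(dets) + 1L]] <- d }
    l <- it$labels
    if (nrow(l))
      truths[[length(truths) + 1L]] <- data.frame(
        image = i, class = l$class,
        x1 = (l$cx - l$w / 2) * W, y1 = (l$cy - l$h / 2) * H,
        x2 = (l$cx + l$w / 2) * W, y2 = (l$cy + l$h / 2) * H)
  }
  dets <- do.call(rbind, c(dets, list(data.frame(image = integer(),
    class = integer(), confidence = numeric(), x1 = numeric(),
    y1 = numeric(), x2 = numeric(), y2 = numeric())[0, ])))
  truths <- do.call(rbind, truths)
  if (is.null(truths) || !nrow(truths)) stop("no ground truths in items")
  coco_map(dets[, c("image", "class", "confidence", "x1", "y1", "x2", "y2")],
           truths)
}
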