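# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written from first principles, not by
# calling back into the package's own implementation.

# Plain-loop IoU used by the oracles below.
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

# Brute-force greedy non-maximum suppression: repeatedly pick the highest
# remaining score and discard same-class overlaps above the threshold.
oracle_nms <- function(boxes, scores, classes, thr) {
  remaining <- seq_along(scores)
  kept <- integer()
  while (length(remaining)) {
    i <- remaining[which.max(scores[remaining])]
    kept <- c(kept, i)
    drop <- vapply(remaining, function(j)
      j != i && classes[j] == classes[i] &&
        oracle_iou(boxes[i, ], boxes[j, ]) > thr, TRUE)
    remaining <- setdiff(remaining[!drop], i)
  }
  kept
}

# Exhaustive greedy matcher (per class, confidence order, best unmatched
# IoU above threshold), independent of the package's vectorized matcher.
oracle_match <- function(dets, truths, thr) {
  classes <- sort(unique(c(dets$class, truths$class)))
  do.call(rbind, lapply(classes, function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    g <- truths[truths$class == cl, , drop = FALSE]
    used <- logical(nrow(g))
    tp <- 0L
    for (i in seq_len(nrow(d))) {
      best <- 0; bj <- 0L
      for (j in seq_len(nrow(g))) {
        if (used[j]) next
        v <- oracle_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                        as.numeric(g[j, c("x1", "y1", "x2", "y2")]))
        if (v >= thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0L) { used[bj] <- TRUE; tp <- tp + 1L }
    }
    data.frame(class = cl, tp = tp, fp = nrow(d) - tp, fn = sum(!used))
  }))
}

# Exact integration of the interpolated precision envelope over recall:
# AP = sum over recall steps of step width times envelope precision.
oracle_ap_exact <- function(confidence, is_tp, n_truth) {
  if (n_truth == 0) return(NA_real_)
  if (!length(confidence)) return(0)
  o <- order(-confidence)
  tp <- cumsum(is_tp[o]); fp <- cumsum(!is_tp[o])
  rec <- c(0, tp / n_truth)
  prec <- tp / (tp + fp)
  env <- numeric(length(prec))
  run <- 0
  for (i in rev(seq_along(prec))) { run <- max(run, prec[i]); env[i] <- run }
  sum((rec[-1] - rec[-length(rec)]) * env)
}

# Random pixel-space boxes for NMS / matching tests.
random_boxes <- function(n, size = 100, n_classes = 3) {
  x1 <- runif(n, 0, size - 10); y1 <- runif(n, 0, size - 10)
  w <- runif(n, 5, size / 2); h <- runif(n, 5, size / 2)
  list(boxes = cbind(x1, y1, pmin(x1 + w, size), pmin(y1 + h, size)),
       scores = runif(n),
       classes = sample(0:(n_classes - 1), n, replace = TRUE))
}

# A small deterministic multi-image detection problem: jittered copies of
# the truths plus decoys, for metric tests.
synthetic_eval_set <- function(n_images = 20, seed = 99) {
  set.seed(seed)
  dets <- list(); truths <- list()
  for (img in seq_len(n_images)) {
    ng <- sample(1:4, 1)
    g <- random_boxes(ng)
    truths[[img]] <- data.frame(image = img, class = g$classes,
                                x1 = g$boxes[, 1], y1 = g$boxes[, 2],
                                x2 = g$boxes[, 3], y2 = g$boxes[, 4])
    # jittered true detections
    jit <- g$boxes + matrix(rnorm(4 * ng, 0, 3), ng, 4)
    d1 <- data.frame(image = img, class = g$classes,
                     confidence = runif(ng, 0.5, 1),
                     x1 = pmin(jit[, 1], jit[, 3] - 1), y1 = pmin(jit[, 2], jit[, 4] - 1),
                     x2 = pmax(jit[, 3], jit[, 1] + 1), y2 = pmax(jit[, 4], jit[, 2] + 1))
    # decoys
    nd <- sample(0:3, 1)
    dk <- random_boxes(max(nd, 1))
    d2 <- if (nd) data.frame(image = img, class = dk$classes[seq_len(nd)],
                             confidence = runif(nd, 0, 0.6),
                             x1 = dk$boxes[seq_len(nd), 1],
                             y1 = dk$boxes[seq_len(nd), 2],
                             x2 = dk$boxes[seq_len(nd), 3],
                             y2 = dk$boxes[seq_len(nd), 4]) else NULL
    dets[[img]] <- rbind(d1, d2)
  }
  list(dets = do.call(rbind, dets), truths = do.call(rbind, truths))
}

n_params_of <- function(blk) as.integer(strawyolo:::n_params(blk))

digest_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  paste(as.character(readBin(con, "raw", file.size(path))), collapse = "")
}

# A tiny rendered scene reused by several files.
tiny_scene <- function(seed = 7, image_size = 96) {
  K <- camera_intrinsics(600 * image_size / 640, 600 * image_size / 640,
                         image_size / 2, image_size / 2)
  obj <- data.frame(class = c(3L, 1L), X = c(0, 2), Y = c(0, -1),
                    Z = c(50, 60), radius = c(2, 1.5))
  list(spec = scene_spec(obj, image_size, K, clutter = 6, seed = seed), K = K)
}

# Small on-disk dataset shared by training/CLI tests (built once per run).
shared_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "strawyolo-shared-ds")
      if (!file.exists(file.path(dir, "dataset.yaml")))
        make_dataset(dir, n_images = 12, seed = 3, image_size = 96)
    }
    dir
  }
})
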