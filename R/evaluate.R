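# Detection metrics: IoU, greedy confidence-ordered matching, precision and
# recall (P = TP/(TP+FP), R = TP/(TP+FN)), average precision as the area
# under the interpolated precision envelope (101-point convention), mAP as
# the unweighted class mean, and mAP@0.5:0.95 as the mean over IoU
# thresholds 0.50 to 0.95 in steps of 0.05.

#' Intersection over union of two boxes
#'
#' Boxes are (x1, y1, x2, y2), 0-based, half-open. A degenerate (zero-area)
#' box yields IoU 0 with a warning.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    warning("degenerate box; IoU defined as 0", call. = FALSE)
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Pairwise IoU matrix between rows of two (n x 4) box matrices.
iou_matrix <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(matrix(0, nrow(A), nrow(B)))
  ax1 <- A[, 1]; ay1 <- A[, 2]; ax2 <- A[, 3]; ay2 <- A[, 4]
  bx1 <- B[, 1]; by1 <- B[, 2]; bx2 <- B[, 3]; by2 <- B[, 4]
  iw <- pmax(0, outer(ax2, bx2, pmin) - outer(ax1, bx1, pmax))
  ih <- pmax(0, outer(ay2, by2, pmin) - outer(ay1, by1, pmax))
  inter <- iw * ih
  areaA <- pmax(0, ax2 - ax1) * pmax(0, ay2 - ay1)
  areaB <- pmax(0, bx2 - bx1) * pmax(0, by2 - by1)
  un <- outer(areaA, areaB, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

#' Greedy one-to-one matching of detections to ground truths
#'
#' Detections are processed in descending confidence per class; each is a
#' true positive if its best-IoU unmatched truth reaches the threshold,
#' otherwise a false positive. Unmatched truths are false negatives.
#'
#' @param dets data.frame with columns class, confidence, x1, y1, x2, y2.
#' @param truths data.frame with columns class, x1, y1, x2, y2.
#' @param iou_threshold IoU threshold.
#' @return data.frame with one row per class: class, tp, fp, fn.
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  classes <- sort(unique(c(dets$class, truths$class)))
  out <- lapply(classes, function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    g <- truths[truths$class == cl, , drop = FALSE]
    used <- logical(nrow(g))
    tp <- 0L
    if (nrow(d) && nrow(g)) {
      M <- iou_matrix(as.matrix(d[, c("x1", "y1", "x2", "y2")]),
                      as.matrix(g[, c("x1", "y1", "x2", "y2")]))
      for (i in seq_len(nrow(d))) {
        cand <- which(!used & M[i, ] >= iou_threshold)
        if (length(cand)) {
          j <- cand[which.max(M[i, cand])]
          used[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
    data.frame(class = cl, tp = tp, fp = nrow(d) - tp,
               fn = nrow(g) - sum(used))
  })
  do.call(rbind, c(out, list(data.frame(class = integer(), tp = integer(),
                                        fp = integer(), fn = integer()))))
}

#' Precision and recall from match counts
#'
#' 0/0 is defined as 0.
#'
#' @param counts data.frame from [match_detections()] (summed over classes),
#'   or a list/vector with elements tp, fp, fn.
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r)
}

# True-positive flags for one class at one threshold, pooled over images;
# detections must already be sorted by descending confidence.
tp_flags <- function(d, g, iou_threshold) {
  flags <- logical(nrow(d))
  for (img in unique(d$image)) {
    di <- which(d$image == img)
    gi <- g[g$image == img, , drop = FALSE]
    if (!nrow(gi)) next
    M <- iou_matrix(as.matrix(d[di, c("x1", "y1", "x2", "y2")]),
                    as.matrix(gi[, c("x1", "y1", "x2", "y2")]))
    used <- logical(nrow(gi))
    for (k in seq_along(di)) {
      cand <- which(!used & M[k, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(M[k, cand])]
        used[j] <- TRUE
        flags[di[k]] <- TRUE
      }
    }
  }
  flags
}

#' Average precision from confidence-ranked true-positive flags
#'
#' The precision-recall curve is reduced to its monotone envelope and
#' integrated at 101 equally spaced recall points (the de-facto COCO
#' convention for AP = the area under P(R)).
#'
#' @param confidence detection confidences.
#' @param is_tp logical true-positive flags (same order).
#' @param n_truth number of ground-truth objects of the class.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(confidence, is_tp, n_truth) {
  if (n_truth == 0) return(NA_real_)
  if (!length(confidence)) return(0)
  o <- order(-confidence)
  tp <- cumsum(is_tp[o])
  fp <- cumsum(!is_tp[o])
  rec <- tp / n_truth
  prec <- tp / (tp + fp)
  # monotone precision envelope from the right
  env <- rev(cummax(rev(prec)))
  rpts <- seq(0, 1, length.out = 101)
  idx <- findInterval(rpts, rec, left.open = TRUE) + 1
  pr <- ifelse(idx <= length(env), env[idx], 0)
  mean(pr)
}

#' Mean average precision over classes
#'
#' @param aps per-class AP values; `NA` (classes without truths) are
#'   excluded with a warning.
#' @return unweighted mean AP.
#' @export
mean_ap <- function(aps) {
  if (anyNA(aps)) {
    warning("excluding ", sum(is.na(aps)), " class(es) without ground truths",
            call. = FALSE)
    aps <- aps[!is.na(aps)]
  }
  if (!length(aps)) return(NA_real_)
  mean(aps)
}

#' COCO-style mAP evaluation
#'
#' @param dets data.frame of detections over a dataset: image, class,
#'   confidence, x1, y1, x2, y2.
#' @param truths data.frame of ground truths: image, class, x1, y1, x2, y2.
#' @param iou_thresholds IoU thresholds (default 0.50 to 0.95 by 0.05).
#' @return list with `map50`, `map5095`, `ap` (class x threshold matrix),
#'   `precision`, `recall` (at IoU 0.5 over all supplied detections).
#' @export
coco_map <- function(dets, truths,
                     iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(truths$class))
  extra <- setdiff(unique(dets$class), classes)
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(classes, iou_thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    g <- truths[truths$class == cl, , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      fl <- tp_flags(d, g, iou_thresholds[ti])
      ap[ci, ti] <- average_precision(d$confidence, fl, nrow(g))
    }
  }
  counts <- do.call(rbind, lapply(unique(c(dets$image, truths$image)),
    function(img) match_detections(dets[dets$image == img, , drop = FALSE],
                                   truths[truths$image == img, , drop = FALSE],
                                   0.5)))
  pr <- precision_recall(counts)
  list(map50 = mean(ap[, 1]),
       map5095 = mean(rowMeans(ap)),
       ap = ap,
       precision = unname(pr["precision"]),
       recall = unname(pr["recall"]),
       ignored_detection_classes = extra)
}
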