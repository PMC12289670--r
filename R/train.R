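# Training: task-aligned assignment of anchors to ground truths, the
# standard composite detection loss (binary cross-entropy classification +
# complete-IoU box loss + distribution focal loss on the discretized box
# sides), Adam with cosine-annealed learning rate, warmup-scheduled
# augmentation, and best-checkpoint retention by validation mAP.

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param batch_size images per optimizer step (default 32).
#' @param image_size square input side, divisible by 32 (default 640).
#' @param lr0 initial Adam learning rate (default 0.01).
#' @param lrf final learning-rate fraction of `lr0` reached by the cosine
#'   annealing schedule.
#' @param seed RNG seed governing shuffling, augmentation and weight
#'   initialization downstream.
#' @param base_augmentations,magnitudes the augmentation pipeline gated by
#'   the warmup schedule.
#' @param box_gain,cls_gain,dfl_gain loss component weights.
#' @param val_every evaluate the validation split every this many epochs
#'   (0 disables; the best checkpoint by mAP@0.5:0.95 is retained).
#' @param clip_norm global gradient-norm clip.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, image_size = 640L,
                         lr0 = 0.01, lrf = 0.01, seed = 0L,
                         base_augmentations = default_augmentations(),
                         magnitudes = default_magnitudes(),
                         box_gain = 7.5, cls_gain = 0.5, dfl_gain = 1.5,
                         val_every = 5L, clip_norm = 10, verbose = TRUE) {
  if (image_size %% 32 != 0) stop("image_size must be divisible by 32")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size), lr0 = lr0, lrf = lrf,
                 seed = as.integer(seed),
                 base_augmentations = base_augmentations,
                 magnitudes = magnitudes, box_gain = box_gain,
                 cls_gain = cls_gain, dfl_gain = dfl_gain,
                 val_every = as.integer(val_every), clip_norm = clip_norm,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

## task-aligned assigner --------------------------------------------------------

# One image. boxes/cls decoded predictions (A x 4 pixels, A x nc probs);
# gt: data.frame(class 0-based, x1, y1, x2, y2 pixels). Returns target
# score matrix (A x nc) and fg assignment table.
tal_assign <- function(boxes, cls, anch, gt, topk = 10L,
                       alpha = 0.5, beta = 6.0) {
  A <- nrow(boxes); nc <- ncol(cls)
  Y <- matrix(0, A, nc)
  if (!nrow(gt))
    return(list(Y = Y, fg = integer(), gt_idx = integer(), w = numeric()))
  G <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
  M <- iou_matrix(G, boxes)                      # (n_gt, A)
  S <- t(cls[, gt$class + 1L, drop = FALSE])     # (n_gt, A) class scores
  align <- pmax(S, 0)^alpha * M^beta
  inside <- outer(G[, 1], anch$ax, "<") & outer(G[, 3], anch$ax, ">") &
            outer(G[, 2], anch$ay, "<") & outer(G[, 4], anch$ay, ">")
  align[!inside] <- 0
  mask <- matrix(FALSE, nrow(G), A)
  for (g in seq_len(nrow(G))) {
    cand <- which(align[g, ] > 0)
    if (!length(cand)) next
    sel <- cand[order(-align[g, cand])][seq_len(min(topk, length(cand)))]
    mask[g, sel] <- TRUE
  }
  # resolve anchors claimed by several truths: keep the highest-IoU truth
  claimed <- colSums(mask) > 1
  for (a in which(claimed)) {
    gs <- which(mask[, a])
    mask[gs[gs != gs[which.max(M[gs, a])]], a] <- FALSE
  }
  fg <- integer(); gt_idx <- integer(); w <- numeric()
  for (g in seq_len(nrow(G))) {
    sel <- which(mask[g, ])
    if (!length(sel)) next
    mx_a <- max(align[g, sel]); mx_i <- max(M[g, sel])
    t <- align[g, sel] * mx_i / (mx_a + 1e-9)
    Y[cbind(sel, gt$class[g] + 1L)] <- t
    fg <- c(fg, sel); gt_idx <- c(gt_idx, rep(g, length(sel))); w <- c(w, t)
  }
  list(Y = Y, fg = fg, gt_idx = gt_idx, w = w)
}

## loss -------------------------------------------------------------------------

# Complete-IoU between predicted box nodes (vectors) and constant gt boxes.
ciou_node <- function(tape, px1, py1, px2, py2, G) {
  eps <- 1e-9
  gx1 <- G[, 1]; gy1 <- G[, 2]; gx2 <- G[, 3]; gy2 <- G[, 4]
  w1 <- op_sub(tape, px2, px1); h1 <- op_sub(tape, py2, py1)
  w2 <- gx2 - gx1; h2 <- gy2 - gy1
  iw <- op_clamp_min(tape, op_sub(tape, op_vmin(tape, px2, tp_node(tape, gx2)),
                                  op_vmax(tape, px1, tp_node(tape, gx1))), 0)
  ih <- op_clamp_min(tape, op_sub(tape, op_vmin(tape, py2, tp_node(tape, gy2)),
                                  op_vmax(tape, py1, tp_node(tape, gy1))), 0)
  inter <- op_mul(tape, iw, ih)
  un <- op_addc(tape, op_sub(tape, op_add(tape, op_mul(tape, w1, h1),
                                          tp_node(tape, w2 * h2)), inter), eps)
  iou_n <- op_div(tape, inter, un)
  cw <- op_sub(tape, op_vmax(tape, px2, tp_node(tape, gx2)),
               op_vmin(tape, px1, tp_node(tape, gx1)))
  ch <- op_sub(tape, op_vmax(tape, py2, tp_node(tape, gy2)),
               op_vmin(tape, py1, tp_node(tape, gy1)))
  c2 <- op_addc(tape, op_add(tape, op_mul(tape, cw, cw),
                             op_mul(tape, ch, ch)), eps)
  dx <- op_addc(tape, op_add(tape, px1, px2), -(gx1 + gx2))
  dx <- op_scale(tape, op_mul(tape, dx, dx), 0.25)
  dy <- op_addc(tape, op_add(tape, py1, py2), -(gy1 + gy2))
  dy <- op_scale(tape, op_mul(tape, dy, dy), 0.25)
  rho2 <- op_add(tape, dx, dy)
  ar <- op_atan(tape, op_div(tape, w1, op_clamp_min(tape, h1, eps)))
  dv <- op_addc(tape, ar, -atan(w2 / pmax(h2, eps)))
  v <- op_scale(tape, op_mul(tape, dv, dv), 4 / pi^2)
  alpha <- v$value / (v$value - iou_n$value + 1 + eps) # detached
  op_sub(tape, op_sub(tape, iou_n, op_div(tape, rho2, c2)),
         op_mulc(tape, v, alpha))
}

# Composite detection loss on a training batch. raw_nodes: list of 3 head
# nodes (H, W, 4*REG_MAX + nc, N); gts: list of per-image data.frames
# (class, x1, y1, x2, y2 in pixels).
detection_loss <- function(tape, raw_nodes, gts, nc, H, W, cfg) {
  N <- dim(raw_nodes[[1]]$value)[4]
  anch <- make_anchors(H, W)
  A_l <- vapply(raw_nodes, function(x) prod(dim(x$value)[1:2]), 0)
  # (A_l * N, C) per level, image-major within level, then stacked
  mats <- lapply(raw_nodes, function(x) {
    d <- dim(x$value)
    m <- op_reshape(tape, x, c(d[1] * d[2], d[3], d[4]))
    m <- op_aperm(tape, m, c(1, 3, 2))
    op_reshape(tape, m, c(d[1] * d[2] * d[4], d[3]))
  })
  all_m <- op_rbind(tape, mats)
  # global row index for (level, image, anchor-within-level)
  lvl_off <- c(0, cumsum(A_l * N))
  row_of <- function(n) { # rows of image n across levels, anchor order
    unlist(lapply(seq_along(A_l), function(l)
      lvl_off[l] + (n - 1) * A_l[l] + seq_len(A_l[l])))
  }
  raw_vals <- lapply(raw_nodes, `[[`, "value")
  Ytot <- matrix(0, sum(A_l) * N, nc)
  fg_rows <- integer(); fg_w <- numeric(); fg_G <- NULL
  n_gt_total <- 0L
  for (n in seq_len(N)) {
    dec <- decode_raw(raw_vals, n, nc, H, W)
    gt <- gts[[n]]
    n_gt_total <- n_gt_total + nrow(gt)
    as_ <- tal_assign(dec$boxes, dec$cls, anch, gt)
    rows <- row_of(n)
    Ytot[rows, ] <- as_$Y
    if (length(as_$fg)) {
      fg_rows <- c(fg_rows, rows[as_$fg])
      fg_w <- c(fg_w, as_$w)
      fg_G <- rbind(fg_G, as.matrix(gt[as_$gt_idx, c("x1", "y1", "x2", "y2")]))
    }
  }
  cls_node <- op_cols(tape, all_m, 4 * REG_MAX + seq_len(nc))
  ts_sum <- max(sum(Ytot), 1)
  l_cls <- op_scale(tape, op_bce_sum(tape, cls_node, Ytot), 1 / ts_sum)
  if (length(fg_rows)) {
    # anchor row -> anchor record: rows are (level, image, anchor); anchor
    # table `anch` is level-major so index = anchor-within-level offset
    aidx <- integer(length(fg_rows))
    for (k in seq_along(fg_rows)) {
      r <- fg_rows[k] - 1L
      l <- findInterval(r, lvl_off, left.open = FALSE)
      within <- (r - lvl_off[l]) %% A_l[l]
      aidx[k] <- sum(head(A_l, l - 1)) + within + 1L
    }
    ax <- anch$ax[aidx]; ay <- anch$ay[aidx]; st <- anch$stride[aidx]
    dist_node <- op_rows(tape, op_cols(tape, all_m, seq_len(4 * REG_MAX)),
                         fg_rows)
    nfg <- length(fg_rows)
    d3 <- op_reshape(tape, dist_node, c(nfg, REG_MAX, 4L))
    d3 <- op_aperm(tape, d3, c(1, 3, 2))
    dmat <- op_reshape(tape, d3, c(nfg * 4L, REG_MAX)) # rows: side-major blocks
    sm <- op_softmax_rows(tape, dmat)
    de <- op_mm_const(tape, sm, matrix(seq_len(REG_MAX) - 1, REG_MAX, 1))
    dists <- op_reshape(tape, de, c(nfg, 4L))
    dl <- op_col(tape, dists, 1); dt <- op_col(tape, dists, 2)
    dr <- op_col(tape, dists, 3); db <- op_col(tape, dists, 4)
    px1 <- op_addc(tape, op_mulc(tape, dl, -st), ax)
    py1 <- op_addc(tape, op_mulc(tape, dt, -st), ay)
    px2 <- op_addc(tape, op_mulc(tape, dr, st), ax)
    py2 <- op_addc(tape, op_mulc(tape, db, st), ay)
    ci <- ciou_node(tape, px1, py1, px2, py2, fg_G)
    one_m <- op_addc(tape, op_scale(tape, ci, -1), 1)
    l_box <- op_scale(tape, op_sum(tape, one_m, w = fg_w), 1 / ts_sum)
    # distribution focal targets: distances in grid units, two-hot bins
    tgt <- cbind((ax - fg_G[, 1]) / st, (ay - fg_G[, 2]) / st,
                 (fg_G[, 3] - ax) / st, (fg_G[, 4] - ay) / st)
    tgt <- pmin(pmax(tgt, 0), REG_MAX - 1 - 0.01)
    tvec <- as.vector(tgt)                      # side-major, matches dmat rows
    il <- floor(tvec); wl <- il + 1 - tvec; wh <- tvec - il
    Tm <- matrix(0, nfg * 4L, REG_MAX)
    Tm[cbind(seq_along(tvec), il + 1)] <- wl
    Tm[cbind(seq_along(tvec), pmin(il + 2, REG_MAX))] <-
      Tm[cbind(seq_along(tvec), pmin(il + 2, REG_MAX))] + wh
    l_dfl <- op_scale(tape, op_softce_sum(tape, dmat, Tm, rep(fg_w, 4) / 4),
                      1 / ts_sum)
  } else {
    l_box <- tp_node(tape, 0); l_dfl <- tp_node(tape, 0)
  }
  total <- op_add(tape, op_add(tape, op_scale(tape, l_box, cfg$box_gain),
                               op_scale(tape, l_cls, cfg$cls_gain)),
                  op_scale(tape, l_dfl, cfg$dfl_gain))
  list(total = total, box = l_box$value, cls = l_cls$value,
       dfl = l_dfl$value, n_fg = length(fg_rows), n_gt = n_gt_total)
}

## parameter plumbing -----------------------------------------------------------

# Path components for unnamed list elements are positional ("1", "2", ...);
# they must index, not name, so numeric keys become integer subscripts.
path_key <- function(x, key) {
  if (is.environment(x)) return(key)
  if (grepl("^[0-9]+$", key) &&
      (is.null(names(x)) || !key %in% names(x))) as.integer(key) else key
}

get_by_path <- function(params, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  x <- params
  for (p in parts) x <- x[[path_key(x, p)]]
  x
}

set_by_path <- function(params, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  rec <- function(x, i) {
    k <- path_key(x, parts[i])
    if (is.environment(x)) { x[[k]] <- value; return(x) } # BN env, in place
    if (i == length(parts)) { x[[k]] <- value; return(x) }
    x[[k]] <- rec(x[[k]], i + 1)
    x
  }
  rec(params, 1)
}

bn_envs <- function(p) {
  out <- list()
  rec <- function(q) {
    if (is.environment(q)) out[[length(out) + 1L]] <<- q
    else if (is.list(q)) lapply(q, rec)
    invisible(NULL)
  }
  rec(p)
  out
}

# Precise batch-norm recalibration: with few optimizer steps the momentum-
# based running statistics lag far behind the trained weights, so inference
# mode diverges from training mode. Reset the statistics and replace them
# by the plain average of batch statistics over (up to) max_batches clean
# training batches.
bn_recalibrate <- function(model, cache, batch_size, max_batches = 16L) {
  envs <- bn_envs(model$params)
  for (e in envs) { e$rm[] <- 0; e$rv[] <- 0 }
  S <- dim(cache[[1]]$image)[1]
  nb <- min(max_batches, ceiling(length(cache) / batch_size))
  for (i in seq_len(nb)) {
    idx <- ((i - 1) * batch_size + 1):min(i * batch_size, length(cache))
    xs <- array(0, c(S, S, 3, length(idx)))
    for (j in seq_along(idx)) xs[, , , j] <- cache[[idx[j]]]$image
    for (e in envs) e$momentum_override <- 1 / i
    invisible(model_forward(model, xs, training = TRUE))
  }
  for (e in envs) rm("momentum_override", envir = e)
  invisible(model)
}

# Deep copy including batch-norm environments (running statistics).
clone_params <- function(p) {
  if (is.environment(p)) {
    e <- new.env(parent = emptyenv())
    for (nm in ls(p)) e[[nm]] <- p[[nm]]
    e
  } else if (is.list(p)) {
    out <- lapply(p, clone_params)
    attributes(out) <- attributes(p)
    out
  } else p
}

all_param_paths <- function(params) {
  out <- character()
  for (id in names(params))
    walk_params(params[[id]], id, function(path, env, slot)
      out[[length(out) + 1L]] <<- path)
  out
}

## training loop ----------------------------------------------------------------

resize_nearest <- function(img, H, W) {
  d <- dim(img)
  if (d[1] == H && d[2] == W) return(img)
  img[ceiling(seq_len(H) / H * d[1]), ceiling(seq_len(W) / W * d[2]), ,
      drop = FALSE]
}

#' Train a detector
#'
#' Per epoch, the warmup schedule sets the effective augmentation
#' probabilities; batches are built from the (augmented) training split and
#' optimized with Adam under cosine learning-rate annealing. When a
#' validation split is present the best checkpoint by mAP@0.5:0.95 is
#' retained. Fully seeded and reproducible.
#'
#' @param model a `straw_model` (its class count must match the dataset).
#' @param dataset a directory path or [load_dataset()] result.
#' @param cfg a [train_config()].
#' @return the trained model, with `$history` (per-epoch log) and
#'   `$best_map` attached.
#' @export
train <- function(model, dataset, cfg = train_config()) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  if (is.null(dataset$items) && !is.null(dataset$path))
    dataset <- load_dataset(dataset$path)
  items <- dataset$items$train
  if (is.null(items) || !nrow(items)) stop("empty dataset: no training items")
  if (model$cfg$num_classes < length(dataset$names))
    stop("model has fewer classes than the dataset")
  set.seed(cfg$seed)
  S <- cfg$image_size
  cache <- lapply(seq_len(nrow(items)), function(i)
    list(image = resize_nearest(png::readPNG(items$image[i]), S, S),
         labels = read_labels(items$label[i])))
  val_items <- dataset$items$val
  paths <- all_param_paths(model$params)
  adam_m <- new.env(); adam_v <- new.env(); tstep <- 0L
  history <- list()
  best_map <- -Inf; best_params <- NULL
  nb <- ceiling(length(cache) / cfg$batch_size)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    plan <- effective_plan(epoch, cfg$epochs, cfg$base_augmentations)
    lr <- cfg$lr0 * (cfg$lrf + (1 - cfg$lrf) *
                       (1 + cos(pi * epoch / cfg$epochs)) / 2)
    ord <- sample.int(length(cache))
    fired_n <- 0L; eloss <- c(box = 0, cls = 0, dfl = 0, total = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                    length(cache))]
      xs <- array(0, c(S, S, 3, length(idx)))
      gts <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        it <- cache[[idx[j]]]
        aug <- apply_augmentations(it$image, it$labels, plan,
                                   pool = cache[setdiff(seq_along(cache),
                                                        idx[j])],
                                   magnitudes = cfg$magnitudes)
        fired_n <- fired_n + length(aug$fired)
        xs[, , , j] <- aug$image
        l <- aug$labels
        gts[[j]] <- if (nrow(l)) data.frame(
          class = l$class,
          x1 = (l$cx - l$w / 2) * S, y1 = (l$cy - l$h / 2) * S,
          x2 = (l$cx + l$w / 2) * S, y2 = (l$cy + l$h / 2) * S)
        else data.frame(class = integer(), x1 = numeric(), y1 = numeric(),
                        x2 = numeric(), y2 = numeric())
      }
      fw <- model_forward(model, xs, training = TRUE)
      ls <- detection_loss(fw$tape, fw$det, gts, model$cfg$num_classes,
                           S, S, cfg)
      if (!is.finite(ls$total$value))
        stop("non-finite loss at epoch ", epoch, " batch ", b,
             " (box=", ls$box, " cls=", ls$cls, " dfl=", ls$dfl, ")")
      tape_backward(fw$tape, ls$total)
      grads <- collect_grads(fw$leaves)
      # global gradient-norm clip
      gn <- sqrt(sum(vapply(ls(grads), function(p) sum(grads[[p]]^2), 0)))
      sc <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
      tstep <- tstep + 1L
      b1 <- 0.9; b2 <- 0.999
      for (p in paths) {
        g <- grads[[p]]
        if (is.null(g)) next
        g <- g * sc
        m <- if (is.null(adam_m[[p]])) g * 0 else adam_m[[p]]
        v <- if (is.null(adam_v[[p]])) g * 0 else adam_v[[p]]
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        adam_m[[p]] <- m; adam_v[[p]] <- v
        mh <- m / (1 - b1^tstep); vh <- v / (1 - b2^tstep)
        upd <- get_by_path(model$params, p) - lr * mh / (sqrt(vh) + 1e-8)
        model$params <- set_by_path(model$params, p, upd)
      }
      eloss <- eloss + c(ls$box, ls$cls, ls$dfl, ls$total$value)
    }
    eloss <- eloss / nb
    vmap <- NA_real_
    if (!is.null(val_items) && nrow(val_items) && cfg$val_every > 0 &&
        (epoch %% cfg$val_every == 0 || epoch == cfg$epochs - 1)) {
      bn_recalibrate(model, cache, cfg$batch_size)
      ev <- suppressWarnings(evaluate_model(model, val_items))
      vmap <- ev$map5095
      if (vmap > best_map) {
        best_map <- vmap
        best_params <- clone_params(model$params)
      }
    }
    history[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, warmup_p = plan$warmup_factor,
      augmentations_fired = fired_n, loss_box = eloss[1], loss_cls = eloss[2],
      loss_dfl = eloss[3], loss = eloss[4], val_map5095 = vmap)
    if (cfg$verbose)
      message(sprintf(
        "epoch %3d  P=%.2f  lr=%.5f  fired=%3d  loss=%.4f (box %.3f cls %.3f dfl %.3f)%s",
        epoch, plan$warmup_factor, lr, fired_n, eloss[4], eloss[1], eloss[2],
        eloss[3], if (is.na(vmap)) "" else sprintf("  val mAP50-95=%.3f", vmap)))
  }
  if (!is.null(best_params) && best_map > -Inf) model$params <- best_params
  else bn_recalibrate(model, cache, cfg$batch_size)
  model$history <- do.call(rbind, history)
  model$best_map <- if (best_map > -Inf) best_map else NA_real_
  model
}

## checkpoints ------------------------------------------------------------------

params_to_plain <- function(p) {
  if (is.environment(p))
    list(.bn = TRUE, gamma = p$gamma, beta = p$beta, rm = p$rm, rv = p$rv)
  else if (is.list(p)) { out <- lapply(p, params_to_plain)
    attributes(out) <- attributes(p)[names(attributes(p)) != "class"]
    out }
  else p
}

plain_to_params <- function(p) {
  if (is.list(p) && isTRUE(p$.bn)) {
    e <- new.env(parent = emptyenv())
    e$gamma <- p$gamma; e$beta <- p$beta; e$rm <- p$rm; e$rv <- p$rv
    e
  } else if (is.list(p)) { out <- lapply(p, plain_to_params)
    attributes(out) <- attributes(p)[names(attributes(p)) != "class"]
    out }
  else p
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it stores the model configuration and
#' all weights (including batch-norm running statistics).
#'
#' @param model a `straw_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg),
               params = lapply(model$params, params_to_plain),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$cfg; class(cfg) <- "straw_config"
  m <- build_model(do.call(model_config,
                           cfg[setdiff(names(cfg),
                                       c("depth_multiple", "width_multiple"))]))
  m$params <- lapply(ck$params, plain_to_params)
  m$history <- ck$history
  m
}
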