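# Detector assembly: CSP-style backbone (stem, staged cross-stage blocks,
# spatial-pyramid fast-pooling tail), path-aggregation neck, decoupled
# anchor-free head with distribution-based box regression. Optional
# SE-MSDWA insertions at the deep end of the backbone and CGFM nodes in
# place of the neck's channel concatenations.

SCALE_PRESETS <- list(n = c(depth = 1 / 3, width = 0.25),
                      s = c(depth = 1 / 3, width = 0.50))

#' Detector model configuration
#'
#' @param scale compound scaling preset, `"n"` or `"s"`; sets the depth and
#'   width multiples (n: 0.33/0.25, s: 0.33/0.50).
#' @param num_classes number of object classes (the standard COCO head has
#'   80; the strawberry growth-stage head has 4).
#' @param use_se_msdwa insert SE-MSDWA attention blocks at the end of the
#'   backbone.
#' @param se_insertions which deep backbone positions receive an SE-MSDWA
#'   block: `"p5"` (after the pyramid-pooling tail) and/or `"p4"` (end of
#'   the next-deepest stage).
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @param se_conv_bias biases on the SE-MSDWA convolution layers.
#' @param use_cgfm replace all four neck concatenation nodes with CGFM.
#' @param cgfm_heads attention heads per CGFM node.
#' @param cgfm_embed optional numeric vector of length 4 overriding the
#'   attention embedding width of each CGFM node (order: the two top-down
#'   nodes, then the two bottom-up nodes).
#' @param conf_thresh,iou_thresh decoding defaults: confidence floor and
#'   class-wise NMS IoU threshold.
#' @return a `straw_config` list.
#' @export
model_config <- function(scale = "s", num_classes = 80L,
                         use_se_msdwa = FALSE,
                         se_insertions = c("p5", "p4"),
                         se_reduction = 4L, se_conv_bias = FALSE,
                         use_cgfm = FALSE, cgfm_heads = 4L,
                         cgfm_embed = NULL,
                         conf_thresh = 0.25, iou_thresh = 0.7) {
  scale <- match.arg(scale, names(SCALE_PRESETS))
  if (num_classes < 1) stop("num_classes must be >= 1")
  cfg <- list(scale = scale,
              depth_multiple = SCALE_PRESETS[[scale]]["depth"],
              width_multiple = SCALE_PRESETS[[scale]]["width"],
              num_classes = as.integer(num_classes),
              use_se_msdwa = isTRUE(use_se_msdwa),
              se_insertions = match.arg(se_insertions, c("p5", "p4"),
                                        several.ok = TRUE),
              se_reduction = as.integer(se_reduction),
              se_conv_bias = isTRUE(se_conv_bias),
              use_cgfm = isTRUE(use_cgfm),
              cgfm_heads = as.integer(cgfm_heads),
              cgfm_embed = cgfm_embed,
              conf_thresh = conf_thresh, iou_thresh = iou_thresh)
  class(cfg) <- "straw_config"
  cfg
}

# The layer graph as a list of rows (id, from, type, args). `from` refers to
# ids, so inserting attention nodes never renumbers anything.
model_graph <- function(cfg) {
  w <- cfg$width_multiple; d <- cfg$depth_multiple
  ch <- as.integer(round(c(64, 128, 256, 512, 1024) * w))
  n1 <- max(1L, as.integer(round(3 * d)))
  n2 <- max(1L, as.integer(round(6 * d)))
  se_p4 <- cfg$use_se_msdwa && "p4" %in% cfg$se_insertions
  se_p5 <- cfg$use_se_msdwa && "p5" %in% cfg$se_insertions
  fuse <- if (cfg$use_cgfm) "cgfm" else "concat"
  embeds <- cfg$cgfm_embed
  emb <- function(i, ct)
    if (!is.null(embeds)) as.integer(embeds[i]) else
      cgfm_embed_default(ct, cfg$cgfm_heads)
  row <- function(id, from, type, ...) list(id = id, from = from, type = type,
                                            args = list(...))
  p4_out <- if (se_p4) "se_p4" else "b6"
  p5_out <- if (se_p5) "se_p5" else "b9"
  g <- list(
    row("b0", "in", "conv", c1 = 3L, c2 = ch[1], k = 3L, s = 2L),
    row("b1", "b0", "conv", c1 = ch[1], c2 = ch[2], k = 3L, s = 2L),
    row("b2", "b1", "c2f", c1 = ch[2], c2 = ch[2], n = n1, shortcut = TRUE),
    row("b3", "b2", "conv", c1 = ch[2], c2 = ch[3], k = 3L, s = 2L),
    row("b4", "b3", "c2f", c1 = ch[3], c2 = ch[3], n = n2, shortcut = TRUE),
    row("b5", "b4", "conv", c1 = ch[3], c2 = ch[4], k = 3L, s = 2L),
    row("b6", "b5", "c2f", c1 = ch[4], c2 = ch[4], n = n2, shortcut = TRUE))
  if (se_p4)
    g <- c(g, list(row("se_p4", "b6", "se_msdwa", channels = ch[4])))
  g <- c(g, list(
    row("b7", p4_out, "conv", c1 = ch[4], c2 = ch[5], k = 3L, s = 2L),
    row("b8", "b7", "c2f", c1 = ch[5], c2 = ch[5], n = n1, shortcut = TRUE),
    row("b9", "b8", "sppf", c1 = ch[5], c2 = ch[5])))
  if (se_p5)
    g <- c(g, list(row("se_p5", "b9", "se_msdwa", channels = ch[5])))
  g <- c(g, list(
    row("u10", p5_out, "upsample"),
    row("f11", c("u10", p4_out), fuse, c1 = ch[5], c2 = ch[4],
        embed = emb(1L, ch[5] + ch[4])),
    row("h12", "f11", "c2f", c1 = ch[5] + ch[4], c2 = ch[4], n = n1,
        shortcut = FALSE),
    row("u13", "h12", "upsample"),
    row("f14", c("u13", "b4"), fuse, c1 = ch[4], c2 = ch[3],
        embed = emb(2L, ch[4] + ch[3])),
    row("h15", "f14", "c2f", c1 = ch[4] + ch[3], c2 = ch[3], n = n1,
        shortcut = FALSE),
    row("d16", "h15", "conv", c1 = ch[3], c2 = ch[3], k = 3L, s = 2L),
    row("f17", c("d16", "h12"), fuse, c1 = ch[3], c2 = ch[4],
        embed = emb(3L, ch[3] + ch[4])),
    row("h18", "f17", "c2f", c1 = ch[3] + ch[4], c2 = ch[4], n = n1,
        shortcut = FALSE),
    row("d19", "h18", "conv", c1 = ch[4], c2 = ch[4], k = 3L, s = 2L),
    row("f20", c("d19", p5_out), fuse, c1 = ch[4], c2 = ch[5],
        embed = emb(4L, ch[4] + ch[5])),
    row("h21", "f20", "c2f", c1 = ch[4] + ch[5], c2 = ch[5], n = n1,
        shortcut = FALSE),
    row("det", c("h15", "h18", "h21"), "detect",
        nc = cfg$num_classes, ch = ch[3:5])))
  attr(g, "ch") <- ch
  g
}

layer_new <- function(r, cfg) {
  a <- r$args
  switch(r$type,
    conv = unit_new(a$c1, a$c2, a$k, a$s),
    c2f = c2f_new(a$c1, a$c2, a$n, a$shortcut),
    sppf = sppf_new(a$c1, a$c2),
    se_msdwa = se_msdwa(a$channels, reduction = cfg$se_reduction,
                        conv_bias = cfg$se_conv_bias),
    cgfm = cgfm(a$c1, a$c2, heads = cfg$cgfm_heads, embed_dim = a$embed),
    detect = detect_new(a$nc, a$ch),
    upsample = ,
    concat = list(),
    stop("unknown layer type: ", r$type))
}

layer_count <- function(r, cfg) {
  a <- r$args
  switch(r$type,
    conv = unit_count(a$c1, a$c2, a$k),
    c2f = c2f_count(a$c1, a$c2, a$n),
    sppf = sppf_count(a$c1, a$c2),
    se_msdwa = msdwa_param_count(a$channels, reduction = cfg$se_reduction,
                                 conv_bias = cfg$se_conv_bias),
    cgfm = cgfm_count(a$c1, a$c2, a$embed, cfg$cgfm_heads),
    detect = detect_count(a$nc, a$ch),
    0)
}

#' Build a detector
#'
#' Assembles the configured architecture variant and initializes its
#' parameters. Builds are deterministic given the configuration and seed.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `straw_model`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  if (!inherits(cfg, "straw_config")) stop("cfg must come from model_config()")
  if (!is.null(seed)) set.seed(seed)
  g <- model_graph(cfg)
  params <- lapply(g, layer_new, cfg = cfg)
  names(params) <- vapply(g, `[[`, "", "id")
  m <- list(cfg = cfg, graph = g, params = params,
            channels = attr(g, "ch"))
  class(m) <- "straw_model"
  m
}

#' Count learnable parameters
#'
#' Enumerates every learnable scalar of a built model (convolution and
#' projection weights, biases, batch-norm affine terms; batch-norm running
#' statistics and the fixed distribution-expectation projection of the head
#' carry no learnable scalars).
#'
#' @param model a `straw_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "straw_model"))
  sum(vapply(model$params, n_params, 0))
}

# Closed-form count from the configuration alone; the structural oracle
# against which the enumeration is tested.
analytic_param_count <- function(cfg) {
  g <- model_graph(cfg)
  sum(vapply(g, layer_count, 0, cfg = cfg))
}

#' Parameter count in printed millions
#'
#' Model sizes are conventionally printed in millions with two decimals,
#' truncated (11,166,544 scalars prints as 11.16 M).
#'
#' @param model a `straw_model` or an integer count.
#' @return numeric, millions truncated to two decimals.
#' @export
params_millions <- function(model) {
  n <- if (inherits(model, "straw_model")) count_parameters(model) else model
  floor(n / 1e6 * 100) / 100
}

#' Per-layer parameter table
#'
#' @param model a `straw_model`.
#' @return data.frame with layer id, type and parameter count.
#' @export
model_param_table <- function(model) {
  data.frame(id = vapply(model$graph, `[[`, "", "id"),
             type = vapply(model$graph, `[[`, "", "type"),
             params = vapply(model$params, n_params, 0),
             row.names = NULL)
}

# Forward through the layer graph. `x` is (H, W, 3, N) in [0, 1]. Returns
# the tape nodes of every layer output plus the raw head outputs.
model_forward <- function(model, x, tape = NULL, training = FALSE,
                          leaves = NULL) {
  d <- dim(x)
  if (length(d) != 4L || d[3] != 3L)
    stop("input must be (H, W, 3, N)")
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("input spatial size must be divisible by 32")
  if (is.null(tape)) tape <- tape_new()
  if (is.null(leaves))
    leaves <- lapply(stats::setNames(names(model$params), names(model$params)),
                     function(id) wrap_leaves(tape, model$params[[id]], id))
  outs <- list(`in` = tp_leaf(tape, x))
  for (r in model$graph) {
    p <- model$params[[r$id]]; lv <- leaves[[r$id]]
    inp <- lapply(r$from, function(f) outs[[f]])
    outs[[r$id]] <- switch(r$type,
      conv = unit_fw(tape, inp[[1]], p, lv, training),
      c2f = c2f_fw(tape, inp[[1]], p, lv, training),
      sppf = sppf_fw(tape, inp[[1]], p, lv, training),
      se_msdwa = se_msdwa_fw(tape, inp[[1]], p, lv, training),
      cgfm = cgfm_fw(tape, inp[[1]], inp[[2]], p, lv, training)$out,
      upsample = op_upsample2(tape, inp[[1]]),
      concat = op_concat_c(tape, inp),
      detect = detect_fw(tape, inp, p, lv, training))
  }
  list(tape = tape, outs = outs, det = outs$det, leaves = leaves)
}

#' @export
print.straw_model <- function(x, ...) {
  v <- c(if (x$cfg$use_se_msdwa) "SE-MSDWA",
         if (x$cfg$use_cgfm) "CGFM")
  cat(sprintf("<straw_model> scale %s, %d classes%s\n", x$cfg$scale,
              x$cfg$num_classes,
              if (length(v)) paste0(" + ", paste(v, collapse = " + ")) else ""))
  cat(sprintf("  layers: %d   parameters: %s (%.2f M)\n", length(x$graph),
              format(count_parameters(x), big.mark = ","),
              params_millions(x)))
  invisible(x)
}

#' @export
summary.straw_model <- function(object, ...) {
  tab <- model_param_table(object)
  print(object)
  print(tab, row.names = FALSE)
  invisible(tab)
}
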