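# Reverse-mode automatic differentiation on a flat tape.
#
# Feature maps are numeric arrays with dim (H, W, C, N); intermediate loss
# algebra uses matrices, vectors and scalars. Each operation appends a node
# (an environment holding the value, its parents and a backward closure) to
# the tape; `tape_backward()` walks the tape in reverse creation order and
# accumulates gradients into `$grad`. Parameter leaves carry a `$pref` key so
# the optimizer can collect their gradients after a backward pass.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$bw <- bw
  nd$grad <- NULL
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

tp_leaf <- function(tape, value, pref = NULL) {
  nd <- tp_node(tape, value)
  nd$pref <- pref
  nd
}

tp_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Interior gradients are freed as soon as they have been propagated;
# parameter leaves (nodes with a $pref) keep theirs for the optimizer.
tape_backward <- function(tape, root) {
  root$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$bw)) {
      gs <- nd$bw(nd$grad, nd)
      for (j in seq_along(gs))
        if (!is.null(gs[[j]])) tp_acc(nd$parents[[j]], gs[[j]])
    }
    if (is.null(nd$pref)) nd$grad <- NULL
  }
  invisible(NULL)
}

## ---- 4-D feature-map primitives ------------------------------------------

op_conv <- function(tape, x, w, b, stride = 1L, pad = 0L, groups = 1L) {
  if (length(pad) == 1L) pad <- c(pad, pad)
  y <- .conv2d_fw(x$value, w$value, if (is.null(b)) NULL else b$value,
                  as.integer(stride), as.integer(pad[1]), as.integer(pad[2]),
                  as.integer(groups))
  has_b <- !is.null(b)
  parents <- if (has_b) list(x, w, b) else list(x, w)
  tp_node(tape, y, parents, function(g, nd) {
    r <- .conv2d_bw(nd$parents[[1]]$value, nd$parents[[2]]$value, g,
                    as.integer(stride), as.integer(pad[1]), as.integer(pad[2]),
                    as.integer(groups), has_b)
    if (has_b) list(r$dx, r$dw, r$db) else list(r$dx, r$dw)
  })
}

op_bn <- function(tape, x, gamma, beta, rm, rv, training = TRUE,
                  momentum = 0.03, eps = 1e-5, state = NULL) {
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  hw <- H * W
  if (training) {
    m3 <- x$value; dim(m3) <- c(hw, C, N)
    mu <- rowSums(colSums(m3)) / (hw * N)
    ctr <- x$value - rep(mu, each = hw)
    c3 <- ctr * ctr; dim(c3) <- c(hw, C, N)
    va <- rowSums(colSums(c3)) / (hw * N)
    if (!is.null(state)) { # update running stats in the layer's store
      mom <- state$momentum_override %||% momentum
      state$rm <- (1 - mom) * state$rm + mom * mu
      state$rv <- (1 - mom) * state$rv + mom * va *
        (hw * N) / max(1, hw * N - 1)
    }
    sd_ <- sqrt(va + eps)
    xhat <- ctr / rep(sd_, each = hw)
    y <- xhat * rep(gamma$value, each = hw) + rep(beta$value, each = hw)
    tp_node(tape, y, list(x, gamma, beta), function(g, nd) {
      m <- hw * N
      dxhat <- g * rep(gamma$value, each = hw)
      s3 <- dxhat * xhat; dim(s3) <- c(hw, C, N)
      sum_dxhat_xhat <- rowSums(colSums(s3))
      s4 <- dxhat; dim(s4) <- c(hw, C, N)
      sum_dxhat <- rowSums(colSums(s4))
      dx <- (dxhat - rep(sum_dxhat / m, each = hw) -
             xhat * rep(sum_dxhat_xhat / m, each = hw)) / rep(sd_, each = hw)
      g3 <- g * xhat; dim(g3) <- c(hw, C, N)
      dgamma <- rowSums(colSums(g3))
      g4 <- g; dim(g4) <- c(hw, C, N)
      dbeta <- rowSums(colSums(g4))
      list(dx, dgamma, dbeta)
    })
  } else {
    sd_ <- sqrt(rv + eps)
    scale <- gamma$value / sd_
    y <- (x$value - rep(rm, each = hw)) * rep(scale, each = hw) +
      rep(beta$value, each = hw)
    tp_node(tape, y, list(x, gamma, beta), function(g, nd) {
      dx <- g * rep(scale, each = hw)
      xhat <- (x$value - rep(rm, each = hw)) / rep(sd_, each = hw)
      g3 <- g * xhat; dim(g3) <- c(hw, C, N)
      g4 <- g; dim(g4) <- c(hw, C, N)
      list(dx, rowSums(colSums(g3)), rowSums(colSums(g4)))
    })
  }
}

op_silu <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  tp_node(tape, x$value * s, list(x), function(g, nd)
    list(g * s * (1 + x$value * (1 - s))))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  tp_node(tape, s, list(x), function(g, nd) list(g * s * (1 - s)))
}

op_add <- function(tape, a, b)
  tp_node(tape, a$value + b$value, list(a, b), function(g, nd) list(g, g))

op_mul <- function(tape, a, b)
  tp_node(tape, a$value * b$value, list(a, b), function(g, nd)
    list(g * b$value, g * a$value))

# x: (H,W,C,N); s: (C,N) per-channel scale, broadcast over H,W.
op_cmul <- function(tape, x, s) {
  d <- dim(x$value); hw <- d[1] * d[2]
  sb <- rep(s$value, each = hw); dim(sb) <- d
  tp_node(tape, x$value * sb, list(x, s), function(g, nd) {
    gx <- g * sb
    gs <- g * x$value; dim(gs) <- c(hw, d[3], d[4])
    ds <- colSums(gs); dim(ds) <- c(d[3], d[4])
    list(gx, ds)
  })
}

op_concat_c <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, function(d) d[3], 0)
  d1 <- ds[[1]]
  y <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$value)[3]
    y[, , at + seq_len(cc), ] <- x$value
    at <- at + cc
  }
  tp_node(tape, y, xs, function(g, nd) {
    out <- vector("list", length(cs)); at <- 0L
    for (i in seq_along(cs)) {
      out[[i]] <- g[, , at + seq_len(cs[i]), , drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

op_slice_c <- function(tape, x, idx) {
  d <- dim(x$value)
  tp_node(tape, x$value[, , idx, , drop = FALSE], list(x), function(g, nd) {
    dx <- array(0, d)
    dx[, , idx, ] <- g
    list(dx)
  })
}

# y[i, j, , ] = x[hidx[i], widx[j], , ]; covers nearest upsample, stride
# subsampling and nearest restore. Backward scatter-adds over duplicates.
op_index_hw <- function(tape, x, hidx, widx) {
  d <- dim(x$value)
  y <- x$value[hidx, widx, , , drop = FALSE]
  tp_node(tape, y, list(x), function(g, nd) {
    gm <- g; dim(gm) <- c(length(hidx), length(widx) * d[3] * d[4])
    a <- rowsum(gm, group = hidx)        # collapse duplicated rows
    hk <- sort(unique(hidx))
    dim(a) <- c(length(hk), length(widx), d[3] * d[4])
    a <- aperm(a, c(2, 1, 3))
    dim(a) <- c(length(widx), length(hk) * d[3] * d[4])
    b <- rowsum(a, group = widx)
    wk <- sort(unique(widx))
    dim(b) <- c(length(wk), length(hk), d[3] * d[4])
    b <- aperm(b, c(2, 1, 3))
    dx <- array(0, d)
    dx[hk, wk, , ] <- b
    list(dx)
  })
}

op_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  op_index_hw(tape, x, rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2))
}

op_maxpool <- function(tape, x, k, stride = 1L, pad = 0L) {
  r <- .maxpool_fw(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  d <- dim(x$value)
  tp_node(tape, r$y, list(x), function(g, nd)
    list(.maxpool_bw(g, r$idx, as.integer(d))))
}

op_gap <- function(tape, x) { # global average pool -> (C, N)
  d <- dim(x$value); hw <- d[1] * d[2]
  m3 <- x$value; dim(m3) <- c(hw, d[3], d[4])
  y <- colSums(m3) / hw
  dim(y) <- c(d[3], d[4])
  tp_node(tape, y, list(x), function(g, nd) {
    dx <- rep(g / hw, each = hw); dim(dx) <- d
    list(dx)
  })
}

## ---- matrix / vector primitives ------------------------------------------

op_fc <- function(tape, x, w, b) { # x: (Cin, N); w: (Cout, Cin); b: (Cout)
  y <- w$value %*% x$value + b$value
  tp_node(tape, y, list(x, w, b), function(g, nd)
    list(crossprod(w$value, g), tcrossprod(g, x$value), rowSums(g)))
}

op_mm <- function(tape, a, b) { # both nodes, plain matrices
  tp_node(tape, a$value %*% b$value, list(a, b), function(g, nd)
    list(tcrossprod(g, b$value), crossprod(a$value, g)))
}

op_mm_const <- function(tape, a, M) { # a %*% M, M constant
  tp_node(tape, a$value %*% M, list(a), function(g, nd)
    list(tcrossprod(g, M)))
}

op_add_rowvec <- function(tape, x, b) { # x: (T, C); b: length C
  tp_node(tape, sweep(x$value, 2, b$value, "+"), list(x, b),
          function(g, nd) list(g, colSums(g)))
}

op_scale <- function(tape, x, k)
  tp_node(tape, x$value * k, list(x), function(g, nd) list(g * k))

op_tadd <- function(tape, a, b) op_add(tape, a, b)

op_sub <- function(tape, a, b)
  tp_node(tape, a$value - b$value, list(a, b), function(g, nd) list(g, -g))

op_div <- function(tape, a, b)
  tp_node(tape, a$value / b$value, list(a, b), function(g, nd)
    list(g / b$value, -g * a$value / (b$value * b$value)))

op_addc <- function(tape, x, k)
  tp_node(tape, x$value + k, list(x), function(g, nd) list(g))

op_vmax <- function(tape, a, b) {
  m <- a$value >= b$value
  tp_node(tape, pmax(a$value, b$value), list(a, b), function(g, nd)
    list(g * m, g * !m))
}

op_vmin <- function(tape, a, b) {
  m <- a$value <= b$value
  tp_node(tape, pmin(a$value, b$value), list(a, b), function(g, nd)
    list(g * m, g * !m))
}

op_clamp_min <- function(tape, x, k) {
  m <- x$value > k
  tp_node(tape, pmax(x$value, k), list(x), function(g, nd) list(g * m))
}

op_atan <- function(tape, x)
  tp_node(tape, atan(x$value), list(x), function(g, nd)
    list(g / (1 + x$value * x$value)))

op_reshape <- function(tape, x, newdim) {
  d <- dim(x$value)
  y <- x$value; dim(y) <- newdim
  tp_node(tape, y, list(x), function(g, nd) { dim(g) <- d; list(g) })
}

op_aperm <- function(tape, x, perm) {
  tp_node(tape, aperm(x$value, perm), list(x), function(g, nd)
    list(aperm(g, order(perm))))
}

op_rows <- function(tape, x, idx) { # gather matrix rows
  d <- dim(x$value)
  tp_node(tape, x$value[idx, , drop = FALSE], list(x), function(g, nd) {
    dx <- matrix(0, d[1], d[2])
    ag <- rowsum(g, group = idx)
    dx[sort(unique(idx)), ] <- ag
    list(dx)
  })
}

op_cols <- function(tape, x, idx) { # gather matrix cols (keeps matrix shape)
  d <- dim(x$value)
  tp_node(tape, x$value[, idx, drop = FALSE], list(x), function(g, nd) {
    dx <- matrix(0, d[1], d[2])
    dx[, idx] <- dx[, idx] + g
    list(dx)
  })
}

op_cbind <- function(tape, xs) { # column-bind vectors/matrices
  ncols <- vapply(xs, function(x) if (is.matrix(x$value)) ncol(x$value) else 1L, 0L)
  y <- do.call(cbind, lapply(xs, function(x) x$value))
  tp_node(tape, y, xs, function(g, nd) {
    out <- vector("list", length(ncols)); at <- 0L
    for (i in seq_along(ncols)) {
      gi <- g[, at + seq_len(ncols[i]), drop = FALSE]
      if (ncols[i] == 1L && !is.matrix(xs[[i]]$value)) gi <- drop(gi)
      out[[i]] <- gi
      at <- at + ncols[i]
    }
    out
  })
}

op_col <- function(tape, x, j) { # single column as plain vector
  d <- dim(x$value)
  tp_node(tape, x$value[, j], list(x), function(g, nd) {
    dx <- matrix(0, d[1], d[2]); dx[, j] <- g; list(dx)
  })
}

op_softmax_rows <- function(tape, x) {
  z <- x$value - apply(x$value, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  tp_node(tape, s, list(x), function(g, nd)
    list((g - rowSums(g * s)) * s))
}

op_sum <- function(tape, x, w = NULL) { # optionally weighted sum -> scalar
  v <- if (is.null(w)) sum(x$value) else sum(x$value * w)
  tp_node(tape, v, list(x), function(g, nd)
    list(if (is.null(w)) array(g, dim(x$value) %||% length(x$value))
         else g * w))
}

# Summed binary cross-entropy with logits; targets and weights constant.
op_bce_sum <- function(tape, logits, targets, weights = NULL) {
  z <- logits$value
  # log(1 + exp(-|z|)) formulation for stability
  l <- pmax(z, 0) - z * targets + log1p(exp(-abs(z)))
  if (!is.null(weights)) l <- l * weights
  tp_node(tape, sum(l), list(logits), function(g, nd) {
    d <- 1 / (1 + exp(-z)) - targets
    if (!is.null(weights)) d <- d * weights
    list(g * d)
  })
}

# Row-wise softmax cross-entropy against constant target distributions,
# with per-row constant weights; returns the weighted sum.
op_softce_sum <- function(tape, logits, target_probs, row_w) {
  z <- logits$value - apply(logits$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ll <- z - log(rowSums(e))
  v <- -sum(row_w * rowSums(target_probs * ll))
  tp_node(tape, v, list(logits), function(g, nd)
    list(g * row_w * (p - target_probs)))
}

# Extract image n of a (H,W,C,N) map as a (H*W, C) token matrix.
op_tokens <- function(tape, x, n) {
  d <- dim(x$value)
  y <- x$value[, , , n]
  dim(y) <- c(d[1] * d[2], d[3])
  tp_node(tape, y, list(x), function(g, nd) {
    dx <- array(0, d)
    gi <- g; dim(gi) <- c(d[1], d[2], d[3])
    dx[, , , n] <- gi
    list(dx)
  })
}

# Stack per-image (H*W, C) token matrices back into a (H,W,C,N) map.
op_untokens <- function(tape, xs, H, W) {
  C <- ncol(xs[[1]]$value); N <- length(xs)
  y <- array(0, c(H, W, C, N))
  for (n in seq_len(N)) {
    v <- xs[[n]]$value; dim(v) <- c(H, W, C)
    y[, , , n] <- v
  }
  tp_node(tape, y, xs, function(g, nd)
    lapply(seq_len(N), function(n) {
      gi <- g[, , , n]; dim(gi) <- c(H * W, C); gi
    }))
}

op_mulc <- function(tape, x, k) # elementwise product with a constant array
  tp_node(tape, x$value * k, list(x), function(g, nd) list(g * k))

op_rbind <- function(tape, xs) { # stack matrices rowwise
  nr <- vapply(xs, function(x) nrow(x$value), 0L)
  tp_node(tape, do.call(rbind, lapply(xs, `[[`, "value")), xs,
          function(g, nd) {
            out <- vector("list", length(nr)); at <- 0L
            for (i in seq_along(nr)) {
              out[[i]] <- g[at + seq_len(nr[i]), , drop = FALSE]
              at <- at + nr[i]
            }
            out
          })
}

op_slice3 <- function(tape, x, n) { # x: (A, C, N) -> matrix (A, C)
  d <- dim(x$value)
  tp_node(tape, x$value[, , n], list(x), function(g, nd) {
    dx <- array(0, d); dx[, , n] <- g; list(dx)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
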