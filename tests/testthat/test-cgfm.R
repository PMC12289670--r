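test_that("attention rows are normalized and shape is preserved", {
  set.seed(4)
  mh <- mhsa(16, heads = 4)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16, 1))
  r <- block_apply(mh, x, return_attention = TRUE)
  expect_identical(dim(r$out), dim(x))
  for (a in r$attention) {
    expect_equal(unname(rowSums(a)), rep(1, nrow(a)), tolerance = 1e-5)
    expect_true(all(a >= 0))
  }
  expect_error(mhsa(16, heads = 3), "divisible")
})

test_that("a single spatial token attends only to itself", {
  set.seed(5)
  mh <- mhsa(6, heads = 2)
  x <- array(rnorm(6), c(1, 1, 6, 1))
  r <- block_apply(mh, x, return_attention = TRUE)
  for (a in r$attention) expect_equal(a, matrix(1, 1, 1))
  # softmax over one logit is 1, so the output is the merged value path:
  # out = (x' V) W_o + b_o with the attention weight exactly 1
  v <- drop(x[1, 1, , 1] %*% mh$wv) + mh$bv
  expected <- drop(v %*% mh$wo) + mh$bo
  expect_equal(drop(r$out), expected, tolerance = 1e-12)
})

test_that("cgfm conserves channels and spatial size with bounded gates", {
  set.seed(6)
  for (cfgd in list(c(8L, 4L), c(4L, 8L), c(6L, 6L))) {
    cg <- cgfm(cfgd[1], cfgd[2], heads = 2)
    x1 <- array(rnorm(10 * 12 * cfgd[1]), c(10, 12, cfgd[1], 1))
    x2 <- array(rnorm(10 * 12 * cfgd[2]), c(10, 12, cfgd[2], 1))
    y <- block_apply(cg, x1, x2)
    expect_identical(dim(y), c(10L, 12L, cfgd[1] + cfgd[2], 1L))
  }
  cg <- cgfm(128, 128, heads = 4)
  x1 <- array(rnorm(40 * 40 * 128), c(40, 40, 128, 1))
  x2 <- array(rnorm(40 * 40 * 128), c(40, 40, 128, 1))
  expect_identical(dim(block_apply(cg, x1, x2)), c(40L, 40L, 256L, 1L))
  # spatial mismatch
  expect_error(block_apply(cg, x1, x2[1:20, , , , drop = FALSE]), "spatial")
})

test_that("with saturated gates and zeroed cross terms cgfm degenerates to concat", {
  set.seed(7)
  cg <- cgfm(5, 3, heads = 2, embed_dim = 8, attn_stride = 1)
  # force: attention output >> 0 so sigmoid gates -> 1; cross projections -> 0
  cg$attn$wo[] <- 0; cg$attn$bo[] <- 50
  cg$w21[] <- 0; cg$b21[] <- 0
  cg$w12[] <- 0; cg$b12[] <- 0
  x1 <- array(rnorm(6 * 6 * 5), c(6, 6, 5, 2))
  x2 <- array(rnorm(6 * 6 * 3), c(6, 6, 3, 2))
  y <- block_apply(cg, x1, x2)
  expected <- array(0, c(6, 6, 8, 2))
  expected[, , 1:5, ] <- x1; expected[, , 6:8, ] <- x2
  expect_equal(y, expected, tolerance = 1e-10)
})

test_that("gate values stay strictly inside (0, 1)", {
  set.seed(8)
  cg <- cgfm(4, 4, heads = 2)
  x1 <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  x2 <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  # reconstruct the gates from the degenerate identity: with zero inputs the
  # blended maps are g (.) 0 + proj(0) = bias terms only; instead probe via
  # linearity: y = g1 (.) x1 + conv(x2) on the first block of channels
  tp <- strawyolo:::tape_new()
  lv <- strawyolo:::wrap_leaves(tp, cg, "c")
  r <- strawyolo:::cgfm_fw(tp, strawyolo:::tp_leaf(tp, x1),
                           strawyolo:::tp_leaf(tp, x2), cg, lv,
                           training = FALSE)
  # the sigmoid node is the parent chain of the split gates; recompute
  z <- strawyolo:::op_conv(tp, strawyolo:::op_concat_c(tp, list(
    strawyolo:::tp_leaf(tp, x1), strawyolo:::tp_leaf(tp, x2))), lv$zw, lv$zb)
  a <- strawyolo:::mhsa_fw(tp, z, cg$attn, lv$attn)$out
  g <- 1 / (1 + exp(-a$value))
  expect_true(all(g > 0 & g < 1))
})
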