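test_that("axial attention matches the nested-loop oracle on random windows", {
  set.seed(31)
  shapes <- list(c(1, 4, 5, 8), c(2, 3, 3, 6), c(1, 7, 7, 4), c(3, 2, 6, 8),
                 c(2, 5, 2, 12))
  heads_for <- list(2, 3, 2, 4, 3)
  n_checked <- 0
  for (rep_i in 1:4) {
    for (si in seq_along(shapes)) {
      d <- shapes[[si]]
      lay <- ada_layer(d[4], heads_for[[si]])
      x <- array(rnorm(prod(d)), d)
      got <- ada_forward(lay, x)$value
      want <- oracle_ada(lay, x)
      expect_equal(got, want, tolerance = 1e-5)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("axial attention weights are softmax-normalized per row", {
  set.seed(32)
  lay <- ada_layer(8, 2)
  x <- array(rnorm(2 * 4 * 5 * 8), c(2, 4, 5, 8))
  det <- ada_forward(lay, x, details = TRUE)
  # temporal weights: (B*H*heads, W, W); frequency: (B*W*heads, H, H)
  expect_equal(dim(det$attn_t), c(2 * 4 * 2, 5, 5))
  expect_equal(dim(det$attn_f), c(2 * 5 * 2, 4, 4))
  expect_equal(as.vector(apply(det$attn_t, c(1, 2), sum)),
               rep(1, 2 * 4 * 2 * 5), tolerance = 1e-6)
  expect_equal(as.vector(apply(det$attn_f, c(1, 2), sum)),
               rep(1, 2 * 5 * 2 * 4), tolerance = 1e-6)
  expect_true(all(det$attn_t > 0), all(det$attn_f > 0))
})

test_that("with a single frequency row the temporal branch is plain multi-head attention", {
  set.seed(33)
  lay <- ada_layer(12, 3)
  x <- array(rnorm(1 * 1 * 6 * 12), c(1, 1, 6, 12))
  det <- ada_forward(lay, x, details = TRUE)
  want <- oracle_mha_1d(lay$qkv$w$value, lay$qkv$b$value,
                        matrix(x[1, 1, , ], 6, 12), heads = 3)
  got <- matrix(det$score_t[1, 1, , ], 6, 12)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("permuting time columns permutes the temporal branch output identically", {
  set.seed(34)
  lay <- ada_layer(8, 2)
  x <- array(rnorm(2 * 4 * 6 * 8), c(2, 4, 6, 8))
  perm <- sample(6)
  base <- ada_forward(lay, x, details = TRUE)
  shuf <- ada_forward(lay, x[, , perm, , drop = FALSE], details = TRUE)
  expect_equal(shuf$score_t, base$score_t[, , perm, , drop = FALSE],
               tolerance = 1e-10)
})

test_that("adaptive merging halves space, doubles channels, masks stay in (0,1)", {
  set.seed(35)
  lay <- asap_layer(6)
  x <- array(rnorm(2 * 8 * 10 * 6), c(2, 8, 10, 6))
  det <- asap_forward(lay, x, details = TRUE)
  expect_equal(dim(det$out$value), c(2, 4 * 5, 12))
  expect_true(all(det$mask > 0 & det$mask < 1))
  expect_true(all(det$salience > 0 & det$salience < 1))
  expect_error(asap_forward(lay, array(0, c(1, 5, 5, 6))), "even")
})

test_that("saturated mask reduces adaptive merging to pool-then-project", {
  set.seed(36)
  lay <- asap_layer(6)
  lay$alpha$value <- -1000
  x <- array(rnorm(1 * 6 * 8 * 6), c(1, 6, 8, 6))
  got <- asap_forward(lay, x)$value
  want <- oracle_pool_conv(x, lay$expand$w$value, lay$expand$b$value)
  dim(want) <- c(1, 3 * 4, 12)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("the learnable salience threshold receives a finite nonzero gradient", {
  set.seed(37)
  lay <- asap_layer(4)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  out <- asap_forward(lay, x)
  loss <- caprilung:::ad_node(sum(out$value^2), list(out),
                              function(g) list(2 * g * out$value))
  caprilung:::ad_backward(loss)
  ga <- lay$alpha$grad
  expect_false(is.null(ga))
  expect_true(is.finite(ga))
  expect_gt(abs(ga), 0)
})

test_that("frequency-band heights follow the floor split", {
  expect_identical(fam_band_heights(56), c(18L, 18L, 20L))
  expect_identical(fam_band_heights(7), c(2L, 2L, 3L))
  expect_identical(fam_band_heights(14), c(4L, 4L, 6L))
  expect_identical(fam_band_heights(28), c(9L, 9L, 10L))
  expect_error(fam_band_heights(2), "height >= 3")
})

test_that("band-split feed-forward preserves shape across stage heights", {
  set.seed(38)
  for (h in c(7, 14, 28, 56)) {
    lay <- fam_layer(4)
    x <- array(rnorm(1 * h * 3 * 4), c(1, h * 3, 4))
    out <- fam_forward(lay, x, h = h)
    expect_identical(dim(out$value), dim(x))
  }
  expect_error(fam_forward(fam_layer(4), array(0, c(1, 4, 4)), h = 2), "height >= 3")
})

test_that("zero input with zeroed biases propagates to zero output", {
  lay <- fam_layer(6)
  for (p in caprilung:::collect_params(lay))
    if (length(dim(p$value)) < 2) p$value <- p$value * 0
  x <- array(0, c(2, 12, 6))
  expect_true(all(fam_forward(lay, x, h = 4)$value == 0))
})
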