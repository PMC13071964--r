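# Building blocks of the lung-sound classifier: axial decomposed attention
# (ADA), the baseline windowed multi-head self-attention it replaces,
# salience-masked adaptive patch merging (ASAP), the frequency-band-aware
# feed-forward block (FAM), and the index bookkeeping for window
# partitioning and cyclic shifts.

## ---- extra graph ops used only here ---------------------------------------

# Non-injective gather (duplicated sources allowed): backward accumulates.
ad_gather_accum <- function(x, idx, out_dim) {
  xv <- x$value
  out <- xv[idx]
  dim(out) <- out_dim
  in_dim <- dim(xv)
  n_in <- length(xv)
  ad_node(out, list(x), function(g) {
    acc <- rowsum(as.vector(g), idx)
    gi <- numeric(n_in)
    gi[as.integer(rownames(acc))] <- acc
    if (!is.null(in_dim)) dim(gi) <- in_dim
    list(gi)
  })
}

# k * (x - alpha), alpha a scalar parameter node.
ad_shift_scale <- function(x, alpha, k) {
  xv <- x$value
  ad_node(k * (xv - alpha$value), list(x, alpha), function(g) {
    list(keep_dim(k * g, xv), -k * sum(g))
  })
}

## ---- index helpers (all layout changes are index bijections) ---------------

seq_array <- function(dims) array(seq_len(prod(dims)), dims)

aperm_idx <- function(dims, perm) as.vector(aperm(seq_array(dims), perm))

inverse_idx <- function(idx) order(idx)

# (B, H, W, C) -> (B*nWh*nWw, ws, ws, C); window id nesting: b, wh, ww.
window_partition_idx <- function(b, h, w, cc, ws) {
  nwh <- h %/% ws; nww <- w %/% ws
  arr <- seq_array(c(b, ws, nwh, ws, nww, cc))
  as.vector(aperm(arr, c(1, 3, 5, 2, 4, 6)))
}

# Cyclic shift by (-s, -s): out[b, h, w, c] = x[b, h + s (mod H), w + s (mod W), c].
roll_idx <- function(b, h, w, cc, s) {
  hi <- ((seq_len(h) - 1 + s) %% h) + 1
  wi <- ((seq_len(w) - 1 + s) %% w) + 1
  arr <- seq_array(c(b, h, w, cc))
  as.vector(arr[, hi, wi, , drop = FALSE])
}

# Region codes along one axis for the shifted-window boundary mask.
axis_region_codes <- function(len, ws, s) {
  codes <- integer(len)
  if (len > ws) {
    codes[seq_len(len - ws)] <- 0L
    codes[(len - ws + 1):(len - s)] <- 1L
    codes[(len - s + 1):len] <- 2L
  }
  codes
}

# 1-D boundary masks per window position along an axis: (nW_axis, ws, ws).
axial_shift_mask <- function(len, ws, s) {
  codes <- axis_region_codes(len, ws, s)
  nw <- len %/% ws
  m <- array(0, c(nw, ws, ws))
  for (k in seq_len(nw)) {
    ck <- codes[((k - 1) * ws + 1):(k * ws)]
    m[k, , ] <- ifelse(outer(ck, ck, "!="), -100, 0)
  }
  m
}

# 2-D boundary masks per window: (nWh*nWw, ws^2, ws^2); window id wh + nWh*(ww-1).
window_shift_mask <- function(h, w, ws, s) {
  ch <- axis_region_codes(h, ws, s)
  cw <- axis_region_codes(w, ws, s)
  img <- outer(ch, 3L * cw, "+")                   # (H, W) region codes
  nwh <- h %/% ws; nww <- w %/% ws
  m <- array(0, c(nwh * nww, ws * ws, ws * ws))
  for (ww in seq_len(nww)) for (wh in seq_len(nwh)) {
    blk <- img[((wh - 1) * ws + 1):(wh * ws), ((ww - 1) * ws + 1):(ww * ws)]
    v <- as.vector(blk)                            # token order: row fastest
    m[wh + nwh * (ww - 1), , ] <- ifelse(outer(v, v, "!="), -100, 0)
  }
  m
}

# Relative-position index for a ws x ws window, tokens ordered row-fastest.
relpos_index <- function(ws) {
  r <- rep(seq_len(ws), times = ws)
  cc <- rep(seq_len(ws), each = ws)
  dr <- outer(r, r, "-") + ws - 1                  # 0 .. 2ws-2
  dc <- outer(cc, cc, "-") + ws - 1
  dr * (2L * ws - 1L) + dc + 1L                    # (S x S) in 1..(2ws-1)^2
}

cache_get <- function(cache, key, fn) {
  if (is.null(cache[[key]])) assign(key, fn(), envir = cache)
  cache[[key]]
}

## ---- axial decomposed attention (ADA) --------------------------------------

#' Create an axial decomposed attention layer
#'
#' The layer replaces windowed joint self-attention with two axis-restricted
#' attentions: a temporal branch attending across time positions within each
#' frequency row, and a frequency branch attending across frequency positions
#' within each time column. A single shared linear projection produces the
#' query, key and value tensors for both branches; the branch outputs are
#' concatenated on channels and projected back from 2C to C.
#'
#' @param dim Channel count C of the input features.
#' @param heads Number of attention heads; must divide `dim`.
#' @param qkv_bias Add a bias to the shared QKV projection.
#' @param init `"trunc_normal"` (default) or `"zeros"` weight initialization.
#' @return A layer object to be applied with [ada_forward()].
#' @export
ada_layer <- function(dim, heads, qkv_bias = TRUE, init = "trunc_normal") {
  stopifnot(dim %% heads == 0)
  structure(list(
    dim = dim, heads = heads,
    qkv = nn_linear_params(dim, 3 * dim, bias = qkv_bias, init = init),
    proj = nn_linear_params(2 * dim, dim, bias = TRUE, init = init)
  ), class = "ada_layer")
}

#' Apply axial decomposed attention to a feature window
#'
#' @param layer An [ada_layer()].
#' @param x Numeric array or graph node of shape (B, H, W, C): batch,
#'   frequency rows, time columns, channels.
#' @param mask_t,mask_f Optional lists `list(m = array(nW, S, S), gidx =
#'   integer)` adding boundary masks to the temporal / frequency scores
#'   (used by shifted-window blocks).
#' @param details Return branch outputs and attention weights alongside the
#'   fused output.
#' @return Graph node of shape (B, H, W, C), or a list when `details = TRUE`
#'   with elements `out`, `score_t`, `score_f` (branch outputs as arrays) and
#'   `attn_t`, `attn_f` (softmax weight arrays, rows summing to one).
#' @export
ada_forward <- function(layer, x, mask_t = NULL, mask_f = NULL, details = FALSE) {
  if (!is_ad_node(x)) x <- ad_const(x)
  d <- dim(x$value)
  b <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  stopifnot(cc == layer$dim)
  nh <- layer$heads
  dk <- cc %/% nh
  n <- b * h * w
  tokens <- ad_reshape(x, c(n, cc))
  qkv <- ad_linear(tokens, layer$qkv$w, layer$qkv$b)   # (N, 3C)

  # qkv columns viewed as (dk, head, slot); full view (B,H,W,dk,nh,3)
  full <- c(b, h, w, dk, nh, 3)
  arr <- seq_array(full)
  idx_t <- lapply(1:3, function(s) {
    sub <- arr[, , , , , s, drop = FALSE]; dim(sub) <- full[1:5]
    as.vector(aperm(sub, c(1, 2, 5, 3, 4)))            # (B,H,nh,W,dk)
  })
  idx_f <- lapply(1:3, function(s) {
    sub <- arr[, , , , , s, drop = FALSE]; dim(sub) <- full[1:5]
    as.vector(aperm(sub, c(1, 3, 5, 2, 4)))            # (B,W,nh,H,dk)
  })
  gt <- b * h * nh
  gf <- b * w * nh
  qt <- ad_gather(qkv, idx_t[[1]], c(gt, w, dk))
  kt <- ad_gather(qkv, idx_t[[2]], c(gt, w, dk))
  vt <- ad_gather(qkv, idx_t[[3]], c(gt, w, dk))
  qf <- ad_gather(qkv, idx_f[[1]], c(gf, h, dk))
  kf <- ad_gather(qkv, idx_f[[2]], c(gf, h, dk))
  vf <- ad_gather(qkv, idx_f[[3]], c(gf, h, dk))
  scale <- 1 / sqrt(dk)
  ot <- ad_attention(qt, kt, vt, scale,
                     mask = mask_t$m, mask_gidx = mask_t$gidx,
                     return_weights = details)
  of <- ad_attention(qf, kf, vf, scale,
                     mask = mask_f$m, mask_gidx = mask_f$gidx,
                     return_weights = details)
  # back to token-major (N, C)
  back_t <- as.vector(aperm(seq_array(c(b, h, nh, w, dk)), c(1, 2, 4, 5, 3)))
  back_f <- as.vector(aperm(seq_array(c(b, w, nh, h, dk)), c(1, 4, 2, 5, 3)))
  st <- ad_gather(ot, back_t, c(n, cc))
  sf <- ad_gather(of, back_f, c(n, cc))
  fused <- ad_linear(ad_concat_cols(st, sf), layer$proj$w, layer$proj$b)
  out <- ad_reshape(fused, d)
  if (!details) return(out)
  sv_t <- st$value; dim(sv_t) <- d
  sv_f <- sf$value; dim(sv_f) <- d
  list(out = out,
       score_t = sv_t, score_f = sv_f,
       attn_t = attr(ot$value, "attn_weights"),
       attn_f = attr(of$value, "attn_weights"))
}

## ---- baseline windowed multi-head self-attention ---------------------------

wmsa_layer <- function(dim, heads, ws, qkv_bias = TRUE, init = "trunc_normal") {
  stopifnot(dim %% heads == 0)
  structure(list(
    dim = dim, heads = heads, ws = ws,
    qkv = nn_linear_params(dim, 3 * dim, bias = qkv_bias, init = init),
    proj = nn_linear_params(dim, dim, bias = TRUE, init = init),
    relpos = ad_param(nn_init(c((2 * ws - 1)^2, heads),
                              if (init == "zeros") "zeros" else "trunc_normal"))
  ), class = "wmsa_layer")
}

# win: node (Bw, ws, ws, C); mask: list(m = (nW, S, S), gidx) or NULL.
wmsa_forward <- function(layer, win, mask = NULL) {
  d <- dim(win$value)
  bw <- d[1]; ws <- d[2]; cc <- d[4]
  nh <- layer$heads
  dk <- cc %/% nh
  s <- ws * ws
  n <- bw * s
  tokens <- ad_reshape(win, c(n, cc))
  qkv <- ad_linear(tokens, layer$qkv$w, layer$qkv$b)
  full <- c(bw, s, dk, nh, 3)
  arr <- seq_array(full)
  grab <- function(slot) {
    sub <- arr[, , , , slot, drop = FALSE]; dim(sub) <- full[1:4]
    as.vector(aperm(sub, c(1, 4, 2, 3)))               # (Bw, nh, S, dk)
  }
  g_n <- bw * nh
  q <- ad_gather(qkv, grab(1), c(g_n, s, dk))
  k <- ad_gather(qkv, grab(2), c(g_n, s, dk))
  v <- ad_gather(qkv, grab(3), c(g_n, s, dk))
  ridx <- relpos_index(ws)                             # (S x S)
  m_tab <- (2 * ws - 1)^2
  bidx <- as.vector(outer(as.vector(ridx), m_tab * (seq_len(nh) - 1L), "+"))
  bias <- ad_gather_accum(layer$relpos, bidx, c(s, s, nh))
  bias_gidx <- rep(seq_len(nh), each = bw)
  out <- ad_attention(q, k, v, 1 / sqrt(dk),
                      bias = bias, bias_gidx = bias_gidx,
                      mask = mask$m, mask_gidx = mask$gidx)
  back <- as.vector(aperm(seq_array(c(bw, nh, s, dk)), c(1, 3, 4, 2)))
  merged <- ad_gather(out, back, c(n, cc))
  proj <- ad_linear(merged, layer$proj$w, layer$proj$b)
  ad_reshape(proj, d)
}

## ---- adaptive spatial aggregation patch merging (ASAP) ----------------------

#' Create a salience-masked adaptive patch-merging layer
#'
#' Downsamples a stage feature map by 2x while doubling channels. A salience
#' map is computed from the layer-normalized input by a depthwise 3x3
#' convolution followed by a pointwise channel-reduction convolution and a
#' sigmoid; a steep sigmoid (fixed slope 10) around a learnable threshold
#' `alpha` converts it into a soft spatial mask. The raw input weighted by
#' the mask is 2x2 average-pooled and expanded from C to 2C channels by a
#' 1x1 convolution.
#'
#' @param dim Input channel count C.
#' @param alpha_init Initial value of the learnable salience threshold.
#' @param init Weight initialization kind.
#' @return A layer object applied with [asap_forward()].
#' @export
asap_layer <- function(dim, alpha_init = 0.5, init = "trunc_normal") {
  structure(list(
    dim = dim,
    norm = nn_layernorm_params(dim),
    dw_w = ad_param(nn_init(c(3, 3, dim), if (init == "zeros") "zeros" else "trunc_normal")),
    dw_b = ad_param(nn_init(dim, "zeros")),
    pw = nn_linear_params(dim, 1, bias = TRUE, init = init),
    alpha = ad_param(alpha_init),
    expand = nn_linear_params(dim, 2 * dim, bias = TRUE, init = init)
  ), class = "asap_layer")
}

#' Apply adaptive spatial aggregation patch merging
#'
#' @param layer An [asap_layer()].
#' @param x Array or node of shape (B, L, C) with `L = H * W`, or (B, H, W, C).
#' @param h,w Spatial extent when `x` is given as (B, L, C); both must be even.
#' @param details Also return the salience and mask arrays.
#' @return Node of shape (B, H/2 * W/2, 2C) (or a list when `details = TRUE`).
#' @export
asap_forward <- function(layer, x, h = NULL, w = NULL, details = FALSE) {
  if (!is_ad_node(x)) x <- ad_const(x)
  d <- dim(x$value)
  if (length(d) == 4) { b <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4] }
  else {
    if (is.null(h)) stop("spatial height h is required for (B, L, C) input")
    b <- d[1]; cc <- d[3]
    if (is.null(w)) w <- d[2] %/% h
  }
  if (h %% 2 != 0 || w %% 2 != 0)
    stop("adaptive patch merging needs even spatial dimensions, got ",
         h, " x ", w)
  stopifnot(cc == layer$dim)
  n <- b * h * w
  tokens <- ad_reshape(x, c(n, cc))
  normed <- ad_layernorm(tokens, layer$norm$g, layer$norm$b)
  spat_n <- ad_reshape(normed, c(b, h, w, cc))
  dw <- ad_dwconv3(spat_n, layer$dw_w, layer$dw_b)
  sal <- ad_sigmoid(ad_linear(ad_reshape(dw, c(n, cc)), layer$pw$w, layer$pw$b))
  mask <- ad_sigmoid(ad_shift_scale(sal, layer$alpha, 10))
  weighted <- ad_rowscale(tokens, mask)                # raw input x mask
  pooled <- ad_avgpool2(ad_reshape(weighted, c(b, h, w, cc)))
  n2 <- b * (h %/% 2) * (w %/% 2)
  out <- ad_linear(ad_reshape(pooled, c(n2, cc)), layer$expand$w, layer$expand$b)
  out <- ad_reshape(out, c(b, (h %/% 2) * (w %/% 2), 2 * cc))
  if (!details) return(out)
  sv <- as.vector(sal$value); dim(sv) <- c(b, h, w)
  mv <- as.vector(mask$value); dim(mv) <- c(b, h, w)
  list(out = out, salience = sv, mask = mv)
}

## ---- frequency-aware MLP (FAM) ---------------------------------------------

#' Frequency-band heights used by the band-split feed-forward block
#'
#' @param h Stage height (frequency extent); must be at least 3.
#' @return Integer vector `c(low, mid, high)` with `floor(h/3)`, `floor(h/3)`
#'   and the remainder.
#' @export
fam_band_heights <- function(h) {
  if (h < 3) stop("frequency-band split needs height >= 3, got ", h)
  lo <- as.integer(h %/% 3)
  c(lo, lo, as.integer(h) - 2L * lo)
}

#' Create a frequency-aware feed-forward layer
#'
#' Replaces the per-block MLP: the feature map is split along the frequency
#' axis into low, mid and high bands; the low band passes through a
#' half-capacity bottleneck with GELU, the mid band through a same-capacity
#' network with GELU, and the high band through a double-capacity expansion
#' with SiLU. Band outputs are re-assembled along frequency and fused by a
#' final C-to-C linear layer.
#'
#' @param dim Channel count C (must be even).
#' @param init Weight initialization kind.
#' @return A layer object applied with [fam_forward()].
#' @export
fam_layer <- function(dim, init = "trunc_normal") {
  stopifnot(dim %% 2 == 0)
  structure(list(
    dim = dim,
    low1 = nn_linear_params(dim, dim %/% 2, init = init),
    low2 = nn_linear_params(dim %/% 2, dim, init = init),
    mid1 = nn_linear_params(dim, dim, init = init),
    mid2 = nn_linear_params(dim, dim, init = init),
    high1 = nn_linear_params(dim, 2 * dim, init = init),
    high2 = nn_linear_params(2 * dim, dim, init = init),
    fuse = nn_linear_params(dim, dim, init = init)
  ), class = "fam_layer")
}

#' Apply the frequency-aware feed-forward block
#'
#' @param layer A [fam_layer()].
#' @param x Array or node of shape (B, L, C) with `L = H * W`, or (B, H, W, C).
#' @param h Stage height (frequency extent) when `x` is (B, L, C).
#' @return Node with the same shape as the input.
#' @export
fam_forward <- function(layer, x, h = NULL) {
  if (!is_ad_node(x)) x <- ad_const(x)
  d <- dim(x$value)
  if (length(d) == 4) { b <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4] }
  else {
    if (is.null(h)) stop("stage height h is required for (B, L, C) input")
    b <- d[1]; cc <- d[3]; w <- d[2] %/% h
  }
  hb <- fam_band_heights(h)
  stopifnot(cc == layer$dim)
  arr <- seq_array(c(b, h, w, cc))
  bounds <- cumsum(c(0, hb))
  spat_dim <- c(b, h, w, cc)
  branch <- function(band, w1, a1, w2) {
    rows <- (bounds[band] + 1):bounds[band + 1]
    idx <- as.vector(arr[, rows, , , drop = FALSE])
    nb <- b * hb[band] * w
    tok <- ad_gather(x, idx, c(nb, cc))
    hdn <- a1(ad_linear(tok, w1$w, w1$b))
    out <- ad_linear(hdn, w2$w, w2$b)
    ad_scatter(out, idx, spat_dim)
  }
  lo <- branch(1, layer$low1, ad_gelu, layer$low2)
  mi <- branch(2, layer$mid1, ad_gelu, layer$mid2)
  hi <- branch(3, layer$high1, ad_silu, layer$high2)
  joined <- ad_add(ad_add(lo, mi), hi)
  fused <- ad_linear(ad_reshape(joined, c(b * h * w, cc)),
                     layer$fuse$w, layer$fuse$b)
  ad_reshape(fused, d)
}
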