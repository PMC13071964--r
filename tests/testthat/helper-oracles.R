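# Independent brute-force oracles, written with explicit scalar loops and
# kept deliberately separate from the vectorized implementation paths.

# Axial decomposed attention: shared QKV projection, per-axis softmax
# attention scaled by 1/sqrt(dk), channel concatenation, 2C -> C projection.
oracle_ada <- function(layer, x) {
  d <- dim(x)
  nb <- d[1]; nh_rows <- d[2]; nw <- d[3]; cc <- d[4]
  heads <- layer$heads
  dk <- cc %/% heads
  wqkv <- layer$qkv$w$value
  bqkv <- if (is.null(layer$qkv$b)) numeric(3 * cc) else layer$qkv$b$value
  wp <- layer$proj$w$value
  bp <- layer$proj$b$value
  out <- array(0, d)
  for (b in seq_len(nb)) {
    q <- array(0, c(nh_rows, nw, cc)); k <- q; v <- q
    for (i in seq_len(nh_rows)) for (j in seq_len(nw)) {
      z <- as.vector(x[b, i, j, ] %*% wqkv) + bqkv
      q[i, j, ] <- z[seq_len(cc)]
      k[i, j, ] <- z[cc + seq_len(cc)]
      v[i, j, ] <- z[2 * cc + seq_len(cc)]
    }
    st <- array(0, c(nh_rows, nw, cc))
    sf <- array(0, c(nh_rows, nw, cc))
    for (hd in seq_len(heads)) {
      ch <- ((hd - 1) * dk + 1):(hd * dk)
      for (i in seq_len(nh_rows)) for (j in seq_len(nw)) {
        # temporal branch: attend over time positions j2 in row i
        sc <- numeric(nw)
        for (j2 in seq_len(nw)) sc[j2] <- sum(q[i, j, ch] * k[i, j2, ch]) / sqrt(dk)
        a <- exp(sc - max(sc)); a <- a / sum(a)
        acc <- numeric(dk)
        for (j2 in seq_len(nw)) acc <- acc + a[j2] * v[i, j2, ch]
        st[i, j, ch] <- acc
        # frequency branch: attend over frequency positions i2 in column j
        sc <- numeric(nh_rows)
        for (i2 in seq_len(nh_rows)) sc[i2] <- sum(q[i, j, ch] * k[i2, j, ch]) / sqrt(dk)
        a <- exp(sc - max(sc)); a <- a / sum(a)
        acc <- numeric(dk)
        for (i2 in seq_len(nh_rows)) acc <- acc + a[i2] * v[i2, j, ch]
        sf[i, j, ch] <- acc
      }
    }
    for (i in seq_len(nh_rows)) for (j in seq_len(nw)) {
      out[b, i, j, ] <- as.vector(c(st[i, j, ], sf[i, j, ]) %*% wp) + bp
    }
  }
  out
}

# Plain multi-head self-attention over a 1-D sequence (for the H = 1
# degeneracy check), same projection weights as an ADA layer but only the
# sequence axis is attended.
oracle_mha_1d <- function(wqkv, bqkv, x_seq, heads) {
  nw <- nrow(x_seq); cc <- ncol(x_seq)
  dk <- cc %/% heads
  z <- sweep(x_seq %*% wqkv, 2, -bqkv)
  q <- z[, seq_len(cc), drop = FALSE]
  k <- z[, cc + seq_len(cc), drop = FALSE]
  v <- z[, 2 * cc + seq_len(cc), drop = FALSE]
  out <- matrix(0, nw, cc)
  for (hd in seq_len(heads)) {
    ch <- ((hd - 1) * dk + 1):(hd * dk)
    sc <- (q[, ch, drop = FALSE] %*% t(k[, ch, drop = FALSE])) / sqrt(dk)
    a <- exp(sc - apply(sc, 1, max))
    a <- a / rowSums(a)
    out[, ch] <- a %*% v[, ch, drop = FALSE]
  }
  out
}

# Average-pool 2x2 then 1x1 convolution of the raw input (the saturated-mask
# limit of adaptive patch merging).
oracle_pool_conv <- function(x, w, b) {
  d <- dim(x)
  nb <- d[1]; h <- d[2]; ww <- d[3]; cc <- d[4]
  out <- array(0, c(nb, h %/% 2, ww %/% 2, 2 * cc))
  for (bi in seq_len(nb)) for (i in seq_len(h %/% 2)) for (j in seq_len(ww %/% 2)) {
    pooled <- (x[bi, 2 * i - 1, 2 * j - 1, ] + x[bi, 2 * i, 2 * j - 1, ] +
               x[bi, 2 * i - 1, 2 * j, ] + x[bi, 2 * i, 2 * j, ]) / 4
    out[bi, i, j, ] <- as.vector(pooled %*% w) + b
  }
  out
}

# Direct time-domain convolution of a signal with FIR taps (causal part).
oracle_fir_convolve <- function(x, taps) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    kmax <- min(i, length(taps))
    y[i] <- sum(taps[seq_len(kmax)] * x[i - seq_len(kmax) + 1])
  }
  y
}

# Exhaustive same-class nearest neighbours by scalar loops.
oracle_knn <- function(mat, k) {
  n <- nrow(mat)
  res <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- numeric(n)
    for (j in seq_len(n)) d2[j] <- sum((mat[i, ] - mat[j, ])^2)
    d2[i] <- Inf
    res[i, ] <- order(d2)[seq_len(k)]
  }
  res
}
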