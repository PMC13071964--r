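# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Nodes are environments holding a value, a list of parent nodes and a
# backward closure mapping the node's cotangent to parent cotangents.
# Node ids increase with creation order and every parent is created before
# its children, so reverse-id order is a valid topological order for the
# backward sweep. All of this is internal machinery for the classifier.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  # force the promises first: nested constructor calls must receive their
  # ids before this node does, or reverse-id order stops being topological
  force(value)
  force(parents)
  e <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  e$is_param <- FALSE
  class(e) <- "ad_node"
  e
}

ad_param <- function(value) {
  n <- ad_node(value)
  n$is_param <- TRUE
  n
}

ad_const <- function(value) ad_node(value)

is_ad_node <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad_node(x)) x$value else x

# Reachable subgraph from `root`, unordered.
ad_collect <- function(root) {
  nodes <- vector("list", 64L)
  n_nodes <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes[seq_len(n_nodes)]
}

# Accumulate cotangents of every node reachable from the scalar `loss`.
ad_backward <- function(loss) {
  nodes <- ad_collect(loss)
  for (nd in nodes) nd$grad <- NULL
  loss$grad <- 1
  ids <- vapply(nodes, function(n) n$id, integer(1))
  for (nd in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(gs)) {
      if (is.null(gs[[i]])) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(loss)
}

keep_dim <- function(g, template) {
  if (!is.null(dim(template))) dim(g) <- dim(template)
  g
}

## ---- elementwise and linear-algebra primitives -----------------------------

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ad_scale <- function(a, k) {
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b),
          function(g) list(keep_dim(g * bv, av), keep_dim(g * av, bv)))
}

# X (N x C) %*% W (C x D) + b (D); b may be NULL.
ad_linear <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  out <- xv %*% wv
  if (!is.null(b)) {
    out <- out + rep(b$value, each = nrow(out))
    ad_node(out, list(x, w, b), function(g) {
      list(g %*% t(wv), crossprod(xv, g), colSums(g))
    })
  } else {
    ad_node(out, list(x, w), function(g) {
      list(g %*% t(wv), crossprod(xv, g))
    })
  }
}

# Scale each row of X (N x C) by s (length N).
ad_rowscale <- function(x, s) {
  xv <- x$value; sv <- as.vector(s$value)
  ad_node(xv * sv, list(x, s), function(g) {
    list(g * sv, rowSums(g * xv))
  })
}

# Injective index map: out[i] <- x[idx[i]], reshaped to out_dim.
ad_gather <- function(x, idx, out_dim) {
  xv <- x$value
  out <- xv[idx]
  dim(out) <- out_dim
  n_in <- length(xv)
  in_dim <- dim(xv)
  ad_node(out, list(x), function(g) {
    gi <- numeric(n_in)
    gi[idx] <- g
    if (!is.null(in_dim)) dim(gi) <- in_dim
    list(gi)
  })
}

# Injective scatter into zeros of dim out_dim: out[idx] <- x.
ad_scatter <- function(x, idx, out_dim) {
  xv <- x$value
  out <- numeric(prod(out_dim))
  out[idx] <- xv
  dim(out) <- out_dim
  in_dim <- dim(xv)
  ad_node(out, list(x), function(g) {
    gi <- g[idx]
    if (!is.null(in_dim)) dim(gi) <- in_dim
    list(gi)
  })
}

ad_reshape <- function(x, new_dim) {
  xv <- x$value
  old_dim <- dim(xv)
  out <- xv
  dim(out) <- new_dim
  ad_node(out, list(x), function(g) {
    dim(g) <- old_dim
    list(g)
  })
}

# Concatenate two matrices column-wise.
ad_concat_cols <- function(a, b) {
  av <- a$value; bv <- b$value
  na <- ncol(av)
  ad_node(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

## ---- activations -----------------------------------------------------------

ad_gelu <- function(x) {
  xv <- x$value
  ph <- stats::pnorm(xv)
  ad_node(xv * ph, list(x), function(g) {
    list(keep_dim(g * (ph + xv * stats::dnorm(xv)), xv))
  })
}

ad_silu <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  ad_node(xv * s, list(x), function(g) {
    list(keep_dim(g * s * (1 + xv * (1 - s)), xv))
  })
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(g) list(keep_dim(g * s * (1 - s), s)))
}

## ---- normalization and pooling --------------------------------------------

# Layer normalization over the channel (last) axis of a token matrix (N x C).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  n <- nrow(xv); cc <- ncol(xv)
  mu <- .rowMeans(xv, n, cc)
  xc <- xv - mu
  v <- .rowMeans(xc * xc, n, cc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$value
  out <- xhat * rep(gv, each = n) + rep(beta$value, each = n)
  ad_node(out, list(x, gamma, beta), function(g) {
    ghat <- g * rep(gv, each = n)
    m1 <- .rowMeans(ghat, n, cc)
    m2 <- .rowMeans(ghat * xhat, n, cc)
    gx <- inv * (ghat - m1 - xhat * m2)
    list(gx, .colSums(g * xhat, n, cc), .colSums(g, n, cc))
  })
}

# Mean over the token axis: x is (B*L x C), rows ordered batch-fastest.
ad_mean_tokens <- function(x, b, l) {
  xv <- x$value
  cc <- ncol(xv)
  a <- xv
  dim(a) <- c(b, l, cc)
  out <- colMeans(aperm(a, c(2, 1, 3)))      # (B x C)
  dim(out) <- c(b, cc)
  ad_node(out, list(x), function(g) {
    gt <- array(g / l, c(b, cc, l))
    gt <- aperm(gt, c(1, 3, 2))
    dim(gt) <- c(b * l, cc)
    list(gt)
  })
}

# 2x2 average pooling, stride 2, on (B, H, W, C).
ad_avgpool2 <- function(x) {
  xv <- x$value
  d <- dim(xv)
  b <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  oh <- seq(1, h, by = 2); eh <- oh + 1
  ow <- seq(1, w, by = 2); ew <- ow + 1
  out <- (xv[, oh, ow, , drop = FALSE] + xv[, eh, ow, , drop = FALSE] +
          xv[, oh, ew, , drop = FALSE] + xv[, eh, ew, , drop = FALSE]) / 4
  ad_node(out, list(x), function(g) {
    gi <- array(0, d)
    q <- g / 4
    gi[, oh, ow, ] <- q
    gi[, eh, ow, ] <- gi[, eh, ow, , drop = FALSE] + q
    gi[, oh, ew, ] <- gi[, oh, ew, , drop = FALSE] + q
    gi[, eh, ew, ] <- gi[, eh, ew, , drop = FALSE] + q
    list(gi)
  })
}

# Depthwise 3x3 convolution, stride 1, zero padding 1, on (B, H, W, C).
# w: (3, 3, C) per-channel kernels; b: (C) bias. Implemented on a padded
# buffer so each kernel tap is one contiguous block read.
ad_dwconv3 <- function(x, w, b) {
  xv <- x$value
  d <- dim(xv)
  bb <- d[1]; h <- d[2]; ww <- d[3]; cc <- d[4]
  wv <- w$value
  nhw <- bb * h * ww
  xp <- array(0, c(bb, h + 2, ww + 2, cc))
  xp[, 2:(h + 1), 2:(ww + 1), ] <- xv
  out <- array(rep(b$value, each = nhw), d)
  for (dy in -1:1) for (dx in -1:1) {
    xs <- xp[, (2 + dy):(h + 1 + dy), (2 + dx):(ww + 1 + dx), , drop = FALSE]
    out <- out + xs * rep(wv[dy + 2, dx + 2, ], each = nhw)
  }
  ad_node(out, list(x, w, b), function(g) {
    gp <- array(0, c(bb, h + 2, ww + 2, cc))
    gw <- array(0, dim(wv))
    gm <- g
    dim(gm) <- c(nhw, cc)
    for (dy in -1:1) for (dx in -1:1) {
      ys <- (2 + dy):(h + 1 + dy); xs_ <- (2 + dx):(ww + 1 + dx)
      blk <- xp[, ys, xs_, , drop = FALSE]
      dim(blk) <- c(nhw, cc)
      gw[dy + 2, dx + 2, ] <- .colSums(blk * gm, nhw, cc)
      gp[, ys, xs_, ] <- gp[, ys, xs_, , drop = FALSE] +
        g * rep(wv[dy + 2, dx + 2, ], each = nhw)
    }
    gx <- gp[, 2:(h + 1), 2:(ww + 1), , drop = FALSE]
    dim(gx) <- d
    list(gx, gw, .colSums(gm, nhw, cc))
  })
}

## ---- attention -------------------------------------------------------------

# Fused scaled-dot-product attention over groups.
# q: (G, Sq, dk); k, v: (G, Sk, dk). Optional additive terms on the score
# tensor (G, Sq, Sk) before the softmax:
#   * bias: trainable node of dim (Sq, Sk, nh) with bias_gidx (length G)
#     selecting the slice per group (relative-position bias);
#   * mask: constant array (nM, Sq, Sk) with mask_gidx (length G) selecting
#     the slice per group (shifted-window boundary mask).
# Returns (G, Sq, dk); with return_weights=TRUE attaches the softmax weights.
ad_attention <- function(q, k, v, scale,
                         bias = NULL, bias_gidx = NULL,
                         mask = NULL, mask_gidx = NULL,
                         return_weights = FALSE) {
  qv <- q$value; kv <- k$value; vv <- v$value
  dq <- dim(qv)
  g_n <- dq[1]; sq <- dq[2]; dk <- dq[3]
  sk <- dim(kv)[2]
  # matricized views: column block of position i holds its dk channels
  qm <- qv; dim(qm) <- c(g_n, sq * dk)
  km <- kv; dim(km) <- c(g_n, sk * dk)
  vm <- vv; dim(vm) <- c(g_n, sk * dk)
  qcols <- lapply(seq_len(sq), function(i) i + sq * (seq_len(dk) - 1L))
  kcols <- lapply(seq_len(sk), function(j) j + sk * (seq_len(dk) - 1L))
  sc_col <- function(i, j) i + sq * (j - 1L)
  scores <- matrix(0, g_n, sq * sk)
  for (j in seq_len(sk)) {
    kj <- km[, kcols[[j]], drop = FALSE]
    for (i in seq_len(sq))
      scores[, sc_col(i, j)] <-
        .rowSums(qm[, qcols[[i]], drop = FALSE] * kj, g_n, dk) * scale
  }
  if (!is.null(bias)) {
    bm <- bias$value; dim(bm) <- c(sq * sk, dim(bias$value)[3])
    for (cix in seq_len(sq * sk))
      scores[, cix] <- scores[, cix] + bm[cix, bias_gidx]
  }
  if (!is.null(mask)) {
    mm <- mask; dim(mm) <- c(dim(mask)[1], sq * sk)
    for (cix in seq_len(sq * sk))
      scores[, cix] <- scores[, cix] + mm[mask_gidx, cix]
  }
  dim(scores) <- c(g_n * sq, sk)            # softmax rows: fixed (g, i)
  mx <- scores[, 1]
  if (sk > 1) for (j in 2:sk) mx <- pmax(mx, scores[, j])
  e <- exp(scores - mx)
  p <- e / .rowSums(e, g_n * sq, sk)
  pm <- p; dim(pm) <- c(g_n, sq * sk)
  om <- matrix(0, g_n, sq * dk)
  for (i in seq_len(sq)) {
    oi <- pm[, sc_col(i, 1)] * vm[, kcols[[1]], drop = FALSE]
    if (sk > 1) for (j in 2:sk)
      oi <- oi + pm[, sc_col(i, j)] * vm[, kcols[[j]], drop = FALSE]
    om[, qcols[[i]]] <- oi
  }
  dim(om) <- c(g_n, sq, dk)
  parents <- list(q, k, v)
  has_bias <- !is.null(bias)
  if (has_bias) parents <- c(parents, list(bias))
  nd <- ad_node(om, parents, function(g) {
    gm <- g; dim(gm) <- c(g_n, sq * dk)
    gvm <- matrix(0, g_n, sk * dk)
    dpm <- matrix(0, g_n, sq * sk)
    for (j in seq_len(sk)) {
      vj <- vm[, kcols[[j]], drop = FALSE]
      acc <- NULL
      for (i in seq_len(sq)) {
        gi <- gm[, qcols[[i]], drop = FALSE]
        dpm[, sc_col(i, j)] <- .rowSums(gi * vj, g_n, dk)
        contrib <- pm[, sc_col(i, j)] * gi
        acc <- if (is.null(acc)) contrib else acc + contrib
      }
      gvm[, kcols[[j]]] <- acc
    }
    dim(dpm) <- c(g_n * sq, sk)
    srow <- .rowSums(dpm * p, g_n * sq, sk)
    ds <- p * (dpm - srow)
    dim(ds) <- c(g_n, sq * sk)
    gqm <- matrix(0, g_n, sq * dk)
    gkm <- matrix(0, g_n, sk * dk)
    for (i in seq_len(sq)) {
      acc <- ds[, sc_col(i, 1)] * km[, kcols[[1]], drop = FALSE]
      if (sk > 1) for (j in 2:sk)
        acc <- acc + ds[, sc_col(i, j)] * km[, kcols[[j]], drop = FALSE]
      gqm[, qcols[[i]]] <- acc * scale
    }
    for (j in seq_len(sk)) {
      acc <- ds[, sc_col(1, j)] * qm[, qcols[[1]], drop = FALSE]
      if (sq > 1) for (i in 2:sq)
        acc <- acc + ds[, sc_col(i, j)] * qm[, qcols[[i]], drop = FALSE]
      gkm[, kcols[[j]]] <- acc * scale
    }
    dim(gqm) <- dq
    dim(gkm) <- dim(kv)
    dim(gvm) <- dim(vv)
    grads <- list(gqm, gkm, gvm)
    if (has_bias) {
      gb_m <- rowsum(ds, bias_gidx)              # (nh x Sq*Sk)
      gb_m <- gb_m[order(as.integer(rownames(gb_m))), , drop = FALSE]
      gb <- array(t(gb_m), dim(bias$value))
      grads <- c(grads, list(gb))
    }
    grads
  })
  if (return_weights) {
    pa <- p; dim(pa) <- c(g_n, sq, sk)
    attr(nd$value, "attn_weights") <- pa
  }
  nd
}

## ---- loss ------------------------------------------------------------------

# Mean cross-entropy of logits (B x K) against integer labels (1-based).
ad_cross_entropy <- function(logits, y) {
  lv <- logits$value
  b <- nrow(lv)
  mx <- apply(lv, 1, max)
  e <- exp(lv - mx)
  z <- rowSums(e)
  p <- e / z
  idx <- cbind(seq_len(b), y)
  loss <- mean(log(z) - (lv[idx] - mx))
  ad_node(loss, list(logits), function(g) {
    gl <- p
    gl[idx] <- gl[idx] - 1
    list(gl * (g / b))
  })
}

## ---- dropout ---------------------------------------------------------------

ad_dropout <- function(x, p, training = TRUE) {
  if (!training || p <= 0) return(x)
  xv <- x$value
  mask <- (stats::runif(length(xv)) >= p) / (1 - p)
  dim(mask) <- dim(xv)
  ad_node(xv * mask, list(x), function(g) list(keep_dim(g * mask, xv)))
}
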