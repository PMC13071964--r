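# Parameter containers, initializers and the Adam optimizer used by the
# classifier. Parameters are ad_param nodes kept in nested named lists.

nn_init <- function(dims, kind = c("trunc_normal", "zeros", "ones"), sd = 0.02) {
  kind <- match.arg(kind)
  n <- prod(dims)
  v <- switch(kind,
    trunc_normal = pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd),
    zeros = numeric(n),
    ones = rep(1, n))
  if (length(dims) > 1L) dim(v) <- dims
  v
}

nn_linear_params <- function(c_in, c_out, bias = TRUE, init = "trunc_normal") {
  p <- list(w = ad_param(nn_init(c(c_in, c_out), if (init == "zeros") "zeros" else "trunc_normal")))
  if (bias) p$b <- ad_param(nn_init(c_out, "zeros"))
  p
}

nn_layernorm_params <- function(cc, init = "trunc_normal") {
  list(g = ad_param(nn_init(cc, "ones")), b = ad_param(nn_init(cc, "zeros")))
}

# Flatten a nested parameter list into a flat list of ad_param nodes.
collect_params <- function(x) {
  out <- list()
  walk <- function(p, prefix) {
    if (is_ad_node(p)) {
      out[[prefix]] <<- p
    } else if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(p[[i]], paste0(prefix, ".", nm))
      }
    }
  }
  walk(x, "p")
  out
}

adam_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) numeric(length(p$value))),
       v = lapply(params, function(p) numeric(length(p$value))))
}

adam_step <- function(state, params) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- as.vector(g)
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    mhat <- state$m[[i]] / corr1
    vhat <- state$v[[i]] / corr2
    upd <- state$lr * mhat / (sqrt(vhat) + state$eps)
    val <- p$value
    p$value <- keep_dim(as.vector(val) - upd, val)
  }
  state
}

# Deep copies of parameter values (for checkpointing the best epoch).
params_snapshot <- function(params) lapply(params, function(p) p$value)

params_restore <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]
  invisible(params)
}
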