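# Assembly of the hierarchical windowed-attention classifier, its
# configuration, parameter counting and an analytic multiply-accumulate
# estimate.

#' Configuration of the lung-sound classifier
#'
#' Describes the four-stage hierarchical windowed-attention backbone and the
#' three substitutable modules: axial decomposed attention (`use_ada`),
#' salience-masked adaptive patch merging (`use_asap`) and the
#' frequency-aware feed-forward block (`use_fam`). With all three flags off
#' the model is the standard tiny windowed-transformer baseline.
#'
#' @param input_side Side of the square 3-channel input image (pixels).
#' @param patch Patch side for the initial embedding.
#' @param in_chans Input channels.
#' @param embed_dim Channels after patch embedding.
#' @param depths Blocks per stage.
#' @param heads Attention heads per stage.
#' @param window Attention window side (clamped per stage to the feature side).
#' @param num_classes Output classes.
#' @param mlp_ratio Hidden expansion of the baseline MLP.
#' @param use_ada,use_asap,use_fam Module ablation flags.
#' @param asap_alpha_init Initial learnable salience threshold.
#' @param drop Dropout rate applied after attention projection and MLP.
#' @param qkv_bias Use a bias in QKV projections.
#' @return A `model_config` list, validated.
#' @export
model_config <- function(input_side = 224, patch = 4, in_chans = 3,
                         embed_dim = 96, depths = c(2, 2, 6, 2),
                         heads = c(3, 6, 12, 24), window = 7,
                         num_classes = 4, mlp_ratio = 4,
                         use_ada = FALSE, use_asap = FALSE, use_fam = FALSE,
                         asap_alpha_init = 0.5, drop = 0, qkv_bias = TRUE) {
  stopifnot(length(depths) == length(heads), input_side %% patch == 0)
  ns <- length(depths)
  side0 <- input_side %/% patch
  if (side0 %% 2^(ns - 1) != 0)
    stop("input_side / patch must be divisible by 2^(stages - 1)")
  for (s in seq_len(ns)) {
    side <- side0 %/% 2^(s - 1)
    cc <- embed_dim * 2^(s - 1)
    if (cc %% heads[s] != 0) stop("heads must divide channel dim at stage ", s)
    ws <- min(window, side)
    if (side %% ws != 0) stop("window must tile the stage side at stage ", s)
    if (use_fam && side < 3) stop("frequency-band split needs stage side >= 3")
  }
  if (use_fam && embed_dim %% 2 != 0) stop("embed_dim must be even with use_fam")
  cfg <- list(input_side = input_side, patch = patch, in_chans = in_chans,
              embed_dim = embed_dim, depths = depths, heads = heads,
              window = window, num_classes = num_classes,
              mlp_ratio = mlp_ratio, use_ada = use_ada, use_asap = use_asap,
              use_fam = use_fam, asap_alpha_init = asap_alpha_init,
              drop = drop, qkv_bias = qkv_bias)
  class(cfg) <- "model_config"
  cfg
}

#' Build the classifier network
#'
#' @param cfg A [model_config()].
#' @param init `"trunc_normal"` (training) or `"zeros"` (e.g. for parameter
#'   accounting without random draws).
#' @param seed Optional seed for the weight initialization.
#' @return A `caprilung_model` object holding the parameter graph nodes.
#' @export
build_model <- function(cfg, init = "trunc_normal", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(cfg$depths)
  side0 <- cfg$input_side %/% cfg$patch
  params <- list(
    embed = nn_linear_params(cfg$patch^2 * cfg$in_chans, cfg$embed_dim, init = init),
    embed_norm = nn_layernorm_params(cfg$embed_dim)
  )
  stages <- vector("list", ns)
  for (s in seq_len(ns)) {
    cc <- cfg$embed_dim * 2^(s - 1)
    side <- side0 %/% 2^(s - 1)
    ws <- min(cfg$window, side)
    blocks <- vector("list", cfg$depths[s])
    for (i in seq_len(cfg$depths[s])) {
      shift <- if (i %% 2 == 0 && side > ws) ws %/% 2 else 0L
      blk <- list(dim = cc, ws = ws, shift = shift,
                  norm1 = nn_layernorm_params(cc),
                  norm2 = nn_layernorm_params(cc))
      blk$attn <- if (cfg$use_ada) {
        ada_layer(cc, cfg$heads[s], qkv_bias = cfg$qkv_bias, init = init)
      } else {
        wmsa_layer(cc, cfg$heads[s], ws, qkv_bias = cfg$qkv_bias, init = init)
      }
      if (cfg$use_fam) {
        blk$ffn <- fam_layer(cc, init = init)
      } else {
        hid <- cfg$mlp_ratio * cc
        blk$ffn <- list(fc1 = nn_linear_params(cc, hid, init = init),
                        fc2 = nn_linear_params(hid, cc, init = init))
      }
      blocks[[i]] <- blk
    }
    st <- list(blocks = blocks, dim = cc, side = side, ws = ws)
    if (s < ns) {
      st$merge <- if (cfg$use_asap) {
        asap_layer(cc, alpha_init = cfg$asap_alpha_init, init = init)
      } else {
        list(norm = nn_layernorm_params(4 * cc),
             red = nn_linear_params(4 * cc, 2 * cc, bias = FALSE, init = init))
      }
    }
    stages[[s]] <- st
  }
  params$stages <- stages
  cc_last <- cfg$embed_dim * 2^(ns - 1)
  params$final_norm <- nn_layernorm_params(cc_last)
  params$head <- nn_linear_params(cc_last, cfg$num_classes, init = init)
  structure(list(cfg = cfg, params = params, cache = new.env(parent = emptyenv())),
            class = "caprilung_model")
}

# Windowed attention wrapper handling cyclic shift, partitioning and masks.
block_attention <- function(blk, x_spat, b, h, w, cfg, cache) {
  cc <- blk$dim; ws <- blk$ws; s <- blk$shift
  nwh <- h %/% ws; nww <- w %/% ws
  if (s > 0) {
    ridx <- cache_get(cache, sprintf("roll_%d_%d_%d_%d_%d", b, h, w, cc, s),
                      function() roll_idx(b, h, w, cc, s))
    x_spat <- ad_gather(x_spat, ridx, c(b, h, w, cc))
  }
  widx <- cache_get(cache, sprintf("win_%d_%d_%d_%d_%d", b, h, w, cc, ws),
                    function() window_partition_idx(b, h, w, cc, ws))
  bw <- b * nwh * nww
  win <- ad_gather(x_spat, widx, c(bw, ws, ws, cc))
  nh <- blk$attn$heads
  if (inherits(blk$attn, "ada_layer")) {
    masks <- if (s > 0) {
      cache_get(cache, sprintf("amask_%d_%d_%d_%d_%d_%d", b, h, w, ws, s, nh), function() {
        ww_of_bw <- rep(seq_len(nww), each = b * nwh)
        wh_of_bw <- rep(rep(seq_len(nwh), each = b), times = nww)
        list(t = list(m = axial_shift_mask(w, ws, s),
                      gidx = rep(ww_of_bw, times = ws * nh)),
             f = list(m = axial_shift_mask(h, ws, s),
                      gidx = rep(wh_of_bw, times = ws * nh)))
      })
    } else NULL
    out <- ada_forward(blk$attn, win, mask_t = masks$t, mask_f = masks$f)
  } else {
    mask <- if (s > 0) {
      cache_get(cache, sprintf("wmask_%d_%d_%d_%d_%d_%d", b, h, w, ws, s, nh), function() {
        list(m = window_shift_mask(h, w, ws, s),
             gidx = rep(rep(seq_len(nwh * nww), each = b), times = nh))
      })
    } else NULL
    out <- wmsa_forward(blk$attn, win, mask = mask)
  }
  un_widx <- cache_get(cache, sprintf("unwin_%d_%d_%d_%d_%d", b, h, w, cc, ws),
                       function() inverse_idx(window_partition_idx(b, h, w, cc, ws)))
  x_spat <- ad_gather(out, un_widx, c(b, h, w, cc))
  if (s > 0) {
    unridx <- cache_get(cache, sprintf("unroll_%d_%d_%d_%d_%d", b, h, w, cc, s),
                        function() inverse_idx(roll_idx(b, h, w, cc, s)))
    x_spat <- ad_gather(x_spat, unridx, c(b, h, w, cc))
  }
  x_spat
}

block_forward <- function(blk, tokens, b, h, w, cfg, cache, training) {
  cc <- blk$dim
  n <- b * h * w
  shortcut <- tokens
  x <- ad_layernorm(tokens, blk$norm1$g, blk$norm1$b)
  x <- block_attention(blk, ad_reshape(x, c(b, h, w, cc)), b, h, w, cfg, cache)
  x <- ad_dropout(ad_reshape(x, c(n, cc)), cfg$drop, training)
  tokens <- ad_add(shortcut, x)
  shortcut <- tokens
  x <- ad_layernorm(tokens, blk$norm2$g, blk$norm2$b)
  if (inherits(blk$ffn, "fam_layer")) {
    x <- fam_forward(blk$ffn, ad_reshape(x, c(b, h * w, cc)), h = h)
    x <- ad_reshape(x, c(n, cc))
  } else {
    x <- ad_linear(ad_gelu(ad_linear(x, blk$ffn$fc1$w, blk$ffn$fc1$b)),
                   blk$ffn$fc2$w, blk$ffn$fc2$b)
  }
  x <- ad_dropout(x, cfg$drop, training)
  ad_add(shortcut, x)
}

merge_forward <- function(mrg, tokens, b, h, w, cc, cache) {
  if (inherits(mrg, "asap_layer")) {
    out <- asap_forward(mrg, ad_reshape(tokens, c(b, h * w, cc)), h = h, w = w)
    return(ad_reshape(out, c(b * (h %/% 2) * (w %/% 2), 2 * cc)))
  }
  idx <- cache_get(cache, sprintf("mrg_%d_%d_%d_%d", b, h, w, cc), function() {
    arr <- seq_array(c(b, h, w, cc))
    oh <- seq(1, h, 2); eh <- oh + 1
    ow <- seq(1, w, 2); ew <- ow + 1
    c(as.vector(arr[, oh, ow, , drop = FALSE]),
      as.vector(arr[, eh, ow, , drop = FALSE]),
      as.vector(arr[, oh, ew, , drop = FALSE]),
      as.vector(arr[, eh, ew, , drop = FALSE]))
  })
  n2 <- b * (h %/% 2) * (w %/% 2)
  # channel-group order (C, 4 offsets) via the (B,H/2,W/2,C,4) view
  x4 <- ad_gather(tokens, idx, c(b, h %/% 2, w %/% 2, cc, 4))
  x4 <- ad_reshape(x4, c(n2, 4 * cc))
  x4 <- ad_layernorm(x4, mrg$norm$g, mrg$norm$b)
  ad_linear(x4, mrg$red$w)
}

forward_logits <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  cache <- model$cache
  d <- dim(x)
  stopifnot(length(d) == 4, d[2] == cfg$input_side, d[4] == cfg$in_chans)
  b <- d[1]
  p <- cfg$patch
  side0 <- cfg$input_side %/% p
  pidx <- cache_get(cache, sprintf("patch_%d", b), function() {
    arr <- seq_array(c(b, p, side0, p, side0, cfg$in_chans))
    as.vector(aperm(arr, c(1, 3, 5, 2, 4, 6)))
  })
  xn <- ad_const(x)
  patches <- ad_gather(xn, pidx, c(b * side0^2, p^2 * cfg$in_chans))
  tokens <- ad_linear(patches, model$params$embed$w, model$params$embed$b)
  tokens <- ad_layernorm(tokens, model$params$embed_norm$g, model$params$embed_norm$b)
  h <- side0; w <- side0
  ns <- length(cfg$depths)
  for (s in seq_len(ns)) {
    st <- model$params$stages[[s]]
    for (blk in st$blocks)
      tokens <- block_forward(blk, tokens, b, h, w, cfg, cache, training)
    if (s < ns) {
      tokens <- merge_forward(st$merge, tokens, b, h, w, st$dim, cache)
      h <- h %/% 2; w <- w %/% 2
    }
  }
  tokens <- ad_layernorm(tokens, model$params$final_norm$g, model$params$final_norm$b)
  pooled <- ad_mean_tokens(tokens, b, h * w)
  ad_linear(pooled, model$params$head$w, model$params$head$b)
}

#' Forward pass returning class logits
#'
#' @param model A [build_model()] network.
#' @param x Input array of shape (B, side, side, 3), standardized per sample.
#' @return Numeric matrix (B x num_classes) of logits.
#' @export
predict_model <- function(model, x) {
  forward_logits(model, x, training = FALSE)$value
}

#' Count trainable parameters
#'
#' @param model A built network.
#' @return Trainable scalar count in millions.
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model$params)
  sum(vapply(ps, function(p) length(p$value), numeric(1))) / 1e6
}

#' Analytic multiply-accumulate estimate for one forward pass
#'
#' Counts the MACs of all linear projections, attention score/value products
#' and convolutions at the configured input resolution. Elementwise and
#' normalization work is excluded, the usual convention of FLOP counters.
#'
#' @param cfg A [model_config()] or a built model.
#' @return Estimated multiply-accumulate operations per forward pass (scalar).
#' @export
estimate_flops <- function(cfg) {
  if (inherits(cfg, "caprilung_model")) cfg <- cfg$cfg
  ns <- length(cfg$depths)
  side0 <- cfg$input_side %/% cfg$patch
  total <- side0^2 * cfg$embed_dim * cfg$patch^2 * cfg$in_chans
  for (s in seq_len(ns)) {
    side <- side0 %/% 2^(s - 1)
    n <- side^2
    cc <- cfg$embed_dim * 2^(s - 1)
    ws <- min(cfg$window, side)
    attn <- if (cfg$use_ada) {
      3 * n * cc^2 + 2 * n * cc^2 + 4 * n * ws * cc
    } else {
      3 * n * cc^2 + n * cc^2 + 2 * n * ws^2 * cc
    }
    ffn <- if (cfg$use_fam) {
      hb <- fam_band_heights(side)
      cc^2 * side * (hb[1] + 2 * hb[2] + 4 * hb[3]) + n * cc^2
    } else {
      2 * cfg$mlp_ratio * n * cc^2
    }
    total <- total + cfg$depths[s] * (attn + ffn)
    if (s < ns) {
      total <- total + if (cfg$use_asap) {
        10 * n * cc + (n / 4) * 2 * cc^2
      } else {
        (n / 4) * 8 * cc^2
      }
    }
  }
  total + cfg$embed_dim * 2^(ns - 1) * cfg$num_classes
}

#' Save / load model checkpoints
#'
#' Checkpoints hold the configuration and a flat list of parameter values.
#'
#' @param model A built network.
#' @param path File path.
#' @return `load_checkpoint` returns a rebuilt `caprilung_model`.
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model$params)
  saveRDS(list(cfg = unclass(model$cfg), values = lapply(ps, function(p) p$value)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$cfg)
  model <- build_model(cfg, init = "zeros")
  ps <- collect_params(model$params)
  stopifnot(length(ps) == length(ck$values))
  for (i in seq_along(ps)) ps[[i]]$value <- ck$values[[i]]
  model
}
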