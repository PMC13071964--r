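# k-fold cross-validated training and the respiratory-sound metrics:
# Accuracy over all four classes, sensitivity over the abnormal classes
# (rhonchi + tachypnea), specificity over normal lung sounds, and their
# arithmetic mean (Score).

#' Stratified (optionally grouped) k-fold plan
#'
#' Without groups, samples are dealt class by class round-robin after a
#' seeded shuffle, so fold sizes differ by at most one overall and per
#' class. With `group_ids`, all segments of one source recording stay in a
#' single fold (overlapping segments of one recording would otherwise leak
#' across the train/test boundary); groups are assigned greedily to the
#' currently smallest fold, so exact size balance is no longer guaranteed.
#'
#' @param labels Class codes per sample.
#' @param k Number of folds.
#' @param seed Seed for the shuffles.
#' @param group_ids Optional per-sample source identifiers.
#' @return A `fold_plan`: list of disjoint index vectors covering all samples.
#' @export
make_folds <- function(labels, k = 5, seed, group_ids = NULL) {
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  folds <- vector("list", k)
  if (is.null(group_ids)) {
    classes <- sort(unique(labels))
    for (cl in classes) {
      if (sum(labels == cl) < k)
        stop("class ", cl, " has fewer than k = ", k, " members")
    }
    pos <- 0L
    for (cl in classes) {
      members <- sample(which(labels == cl))
      for (m in members) {
        f <- (pos %% k) + 1L
        folds[[f]] <- c(folds[[f]], m)
        pos <- pos + 1L
      }
    }
  } else {
    stopifnot(length(group_ids) == n)
    groups <- split(seq_len(n), group_ids)
    groups <- groups[sample(length(groups))]
    groups <- groups[order(-vapply(groups, length, integer(1)))]
    sizes <- integer(k)
    for (g in groups) {
      f <- which.min(sizes)
      folds[[f]] <- c(folds[[f]], g)
      sizes[f] <- sizes[f] + length(g)
    }
  }
  structure(list(folds = lapply(folds, sort), k = k, seed = seed,
                 stratified = is.null(group_ids), grouped = !is.null(group_ids)),
            class = "fold_plan")
}

#' Confusion matrix of a trained network on a test set
#'
#' @param model A built (trained) network.
#' @param x Input array (N, side, side, 3).
#' @param y Integer class codes 0:3.
#' @param batch Forward batch size.
#' @return 4x4 integer matrix, rows = true class, columns = predicted.
#' @export
evaluate_model <- function(model, x, y, batch = 32) {
  n <- dim(x)[1]
  if (n == 0) stop("empty test set")
  pred <- integer(n)
  for (i0 in seq(1, n, by = batch)) {
    i1 <- min(i0 + batch - 1, n)
    logits <- predict_model(model, x[i0:i1, , , , drop = FALSE])
    pred[i0:i1] <- max.col(logits, ties.method = "first") - 1L
  }
  cm <- matrix(0L, 4, 4, dimnames = list(true = CLASS_NAMES, pred = CLASS_NAMES))
  for (i in seq_len(n)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Respiratory-sound classification metrics
#'
#' Given a 4x4 confusion matrix (rows true, columns predicted, class order
#' normal, rhonchi, tachypnea, noise):
#' Accuracy = total correct / total; Se = (correct rhonchi + correct
#' tachypnea) / (rhonchi + tachypnea totals); Sp = correct normal / normal
#' total; Score = (Se + Sp) / 2. The noise class contributes to Accuracy
#' only. All values are percentages.
#'
#' @param cm 4x4 confusion matrix.
#' @return A `metrics_report` list with `accuracy`, `se`, `sp`, `score`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(4, 4)), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  if (sum(cm[1, ]) == 0) stop("specificity undefined: no normal samples")
  if (sum(cm[2:3, ]) == 0) stop("sensitivity undefined: no abnormal samples")
  acc <- 100 * sum(diag(cm)) / total
  se <- 100 * (cm[2, 2] + cm[3, 3]) / sum(cm[2:3, ])
  sp <- 100 * cm[1, 1] / sum(cm[1, ])
  structure(list(accuracy = acc, se = se, sp = sp, score = (se + sp) / 2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy %.2f%%  Se %.2f%%  Sp %.2f%%  Score %.2f%%\n",
              x$accuracy, x$se, x$sp, x$score))
  invisible(x)
}

#' Decimal half-up rounding
#'
#' Rounds on the decimal scale with halves going up (the convention of
#' reported percentage tables), immune to binary floating-point artefacts
#' such as 88.065 being stored just below the true half.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Score from printed sensitivity and specificity
#'
#' @param se,sp Percentages.
#' @param digits Optional decimal digits for half-up rounding.
#' @return `(se + sp) / 2`, optionally rounded.
#' @export
score_from_sesp <- function(se, sp, digits = NULL) {
  s <- (se + sp) / 2
  if (is.null(digits)) s else round_half_up(s, digits)
}

#' Training hyperparameters
#'
#' Defaults are the training regime the classifier was designed around:
#' Adam, learning rate 1e-4, batch 32, 50 epochs, cross-entropy loss.
#'
#' @param lr Learning rate.
#' @param batch Batch size.
#' @param epochs Training epochs.
#' @param seed Seed controlling shuffling and any dropout.
#' @param steps Optional fixed step count overriding the epoch loop (full
#'   passes are still made in shuffled minibatches).
#' @return A `train_spec` list.
#' @export
train_spec <- function(lr = 1e-4, batch = 32, epochs = 50, seed = 1, steps = NULL) {
  stopifnot(lr > 0, batch >= 1, epochs >= 0)
  structure(list(lr = lr, batch = batch, epochs = epochs, seed = seed,
                 steps = steps), class = "train_spec")
}

#' Train the classifier
#'
#' Minibatch Adam on the cross-entropy loss. With validation data the
#' parameters of the best validation-accuracy epoch are restored at the end.
#' A non-finite loss aborts with an error rather than being swallowed.
#'
#' @param model A built network (or a [model_config()], which is built with
#'   the spec's seed).
#' @param x,y Training inputs (N, side, side, 3) and class codes 0:3.
#' @param spec A [train_spec()].
#' @param x_val,y_val Optional validation split.
#' @param verbose Print per-epoch progress.
#' @return List with `model`, `history` (data frame of per-epoch loss and
#'   accuracy) and `step_losses` (per-step training losses).
#' @export
train_model <- function(model, x, y, spec = train_spec(), x_val = NULL,
                        y_val = NULL, verbose = FALSE) {
  if (inherits(model, "model_config"))
    model <- build_model(model, seed = spec$seed)
  n <- dim(x)[1]
  stopifnot(n >= 1, length(y) == n)
  params <- collect_params(model$params)
  if (spec$epochs == 0 && is.null(spec$steps))
    return(list(model = model, history = data.frame(), step_losses = numeric()))
  opt <- adam_state(params, lr = spec$lr)
  set.seed(spec$seed)
  y1 <- as.integer(y) + 1L
  step_losses <- numeric()
  hist <- list()
  best_acc <- -Inf
  best_snap <- NULL
  total_steps <- 0L
  n_epochs <- if (is.null(spec$steps)) spec$epochs else .Machine$integer.max
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n)
    ep_losses <- c()
    correct <- 0L
    for (i0 in seq(1, n, by = spec$batch)) {
      ids <- ord[i0:min(i0 + spec$batch - 1, n)]
      xb <- x[ids, , , , drop = FALSE]
      logits <- forward_logits(model, xb, training = TRUE)
      loss <- ad_cross_entropy(logits, y1[ids])
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss at step ", total_steps + 1L)
      ad_backward(loss)
      opt <- adam_step(opt, params)
      step_losses <- c(step_losses, loss$value)
      ep_losses <- c(ep_losses, loss$value)
      correct <- correct + sum(max.col(logits$value) == y1[ids])
      total_steps <- total_steps + 1L
      if (!is.null(spec$steps) && total_steps >= spec$steps) break
    }
    ep_acc <- 100 * correct / n
    val_acc <- NA_real_
    if (!is.null(x_val)) {
      cmv <- confusion_counts(model, x_val, y_val)
      val_acc <- 100 * sum(diag(cmv)) / sum(cmv)
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_snap <- params_snapshot(params)
      }
    }
    hist[[length(hist) + 1]] <- data.frame(
      epoch = ep, loss = mean(ep_losses), train_acc = ep_acc, val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f train %.1f%% val %s", ep,
                      mean(ep_losses), ep_acc,
                      if (is.na(val_acc)) "-" else sprintf("%.1f%%", val_acc)))
    if (!is.null(spec$steps) && total_steps >= spec$steps) break
  }
  if (!is.null(best_snap)) params_restore(params, best_snap)
  list(model = model, history = do.call(rbind, hist), step_losses = step_losses)
}

# bare confusion matrix without class checks (internal; any label mix)
confusion_counts <- function(model, x, y, batch = 32) {
  n <- dim(x)[1]
  pred <- integer(n)
  for (i0 in seq(1, n, by = batch)) {
    i1 <- min(i0 + batch - 1, n)
    logits <- predict_model(model, x[i0:i1, , , , drop = FALSE])
    pred[i0:i1] <- max.col(logits, ties.method = "first") - 1L
  }
  cm <- matrix(0L, 4, 4)
  for (i in seq_len(n)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Cross-validated training and evaluation
#'
#' Runs the k-fold protocol: per fold, optional SMOTE balancing of the
#' training portion only (`smote = "train"`, the default, mirroring an
#' augmented training set evaluated against an untouched test fold;
#' `"none"` disables balancing), training, and metric computation on the
#' held-out fold.
#'
#' @param x,y Dataset inputs and class codes.
#' @param cfg A [model_config()].
#' @param spec A [train_spec()].
#' @param k Folds.
#' @param seed Seed for the fold plan.
#' @param group_ids Optional grouping (see [make_folds()]).
#' @param smote `"train"` or `"none"`.
#' @param k_neighbors SMOTE neighbourhood size.
#' @return List with per-fold `metrics`, their `mean` and `sd`, and the
#'   fold plan.
#' @export
cross_validate <- function(x, y, cfg, spec = train_spec(), k = 5, seed = 1,
                           group_ids = NULL, smote = c("train", "none"),
                           k_neighbors = 5) {
  smote <- match.arg(smote)
  plan <- make_folds(y, k = k, seed = seed, group_ids = group_ids)
  side <- dim(x)[2]
  per_fold <- list()
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_len(dim(x)[1]), test_idx)
    xtr <- x[train_idx, , , , drop = FALSE]
    ytr <- y[train_idx]
    if (smote == "train") {
      counts <- table(factor(ytr, levels = 0:3))
      if (length(unique(as.integer(counts))) > 1) {
        flat <- matrix(xtr[, , , 1], nrow = length(train_idx))
        tab <- lapply(split(seq_along(ytr), ytr), function(ix)
          flat[ix, , drop = FALSE])
        bal <- smote_balance(tab, k_neighbors = k_neighbors,
                             seed = derive_seed(seed, f))
        xs <- list(); ys <- integer()
        for (cl in names(bal)) {
          m <- bal[[cl]]
          xs[[cl]] <- m
          ys <- c(ys, rep(as.integer(cl), nrow(m)))
        }
        flat_all <- do.call(rbind, xs)
        xtr <- array(0, c(nrow(flat_all), side, side, 3))
        for (ch in 1:3) xtr[, , , ch] <- flat_all
        ytr <- ys
      }
    }
    fit <- train_model(cfg, xtr, ytr, spec = spec)
    cm <- evaluate_model(fit$model, x[test_idx, , , , drop = FALSE], y[test_idx])
    per_fold[[f]] <- compute_metrics(cm)
  }
  m <- sapply(per_fold, function(r) unlist(r[c("accuracy", "se", "sp", "score")]))
  list(metrics = per_fold, mean = rowMeans(m), sd = apply(m, 1, stats::sd),
       plan = plan)
}
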