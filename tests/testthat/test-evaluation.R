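test_that("metrics reproduce hand-worked confusion arithmetic", {
  # Nl=10 (8 right), W=5 (4), T=5 (3), Ne=10 (9)
  cm <- matrix(0L, 4, 4)
  cm[1, 1] <- 8; cm[1, 2] <- 2
  cm[2, 2] <- 4; cm[2, 1] <- 1
  cm[3, 3] <- 3; cm[3, 4] <- 2
  cm[4, 4] <- 9; cm[4, 1] <- 1
  r <- compute_metrics(cm)
  expect_equal(r$accuracy, 80)
  expect_equal(r$se, 70)
  expect_equal(r$sp, 80)
  expect_equal(r$score, 75)
  # perfect classification
  perfect <- diag(c(5L, 5L, 5L, 5L))
  rp <- compute_metrics(perfect)
  expect_equal(unlist(rp[c("accuracy", "se", "sp", "score")]),
               c(accuracy = 100, se = 100, sp = 100, score = 100))
  # count-scaling invariance
  r3 <- compute_metrics(cm * 3L)
  expect_equal(unlist(r3), unlist(r))
  # undefined denominators are errors
  no_normal <- cm; no_normal[1, ] <- 0L
  expect_error(compute_metrics(no_normal), "specificity")
  no_abn <- cm; no_abn[2:3, ] <- 0L
  expect_error(compute_metrics(no_abn), "sensitivity")
})

test_that("the balanced score of the reported operating point rounds half-up", {
  expect_equal(score_from_sesp(86.99, 89.14, digits = 2), 88.07)
  expect_equal(score_from_sesp(86.99, 89.14), 88.065, tolerance = 1e-12)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.5, 0), 0)
})

test_that("stratified folds are disjoint, covering and balanced", {
  set.seed(1)
  labels <- sample(rep(0:3, c(40, 25, 10, 25)))
  plan <- make_folds(labels, k = 5, seed = 9)
  all_idx <- sort(unlist(plan$folds))
  expect_identical(all_idx, seq_along(labels))
  sizes <- vapply(plan$folds, length, integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (cl in 0:3) {
    per_fold <- vapply(plan$folds, function(f) sum(labels[f] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  expect_identical(vapply(make_folds(rep(0:3, 25), k = 5, seed = 2)$folds,
                          length, integer(1)), rep(20L, 5))
  expect_error(make_folds(c(0, 0, 1), k = 2, seed = 1), "fewer than k")
})

test_that("grouped folds never split a source recording", {
  set.seed(2)
  groups <- rep(sprintf("goat%02d", 1:20), each = 6)
  labels <- rep(sample(0:3, 20, replace = TRUE), each = 6)
  plan <- make_folds(labels, k = 5, seed = 4, group_ids = groups)
  expect_identical(sort(unlist(plan$folds)), seq_along(labels))
  for (g in unique(groups)) {
    in_fold <- vapply(plan$folds, function(f) any(groups[f] == g), logical(1))
    expect_identical(sum(in_fold), 1L)
  }
})

test_that("every sample is tested exactly once across the k rounds", {
  labels <- rep(0:3, each = 30)
  plan <- make_folds(labels, k = 5, seed = 11)
  seen <- integer(length(labels))
  for (f in plan$folds) seen[f] <- seen[f] + 1L
  expect_true(all(seen == 1L))
})

test_that("training on a fixed batch reduces loss and is seed-deterministic", {
  cfg <- model_config(input_side = 32, patch = 4, embed_dim = 8,
                      depths = c(1, 1), heads = c(2, 2), window = 4,
                      use_ada = TRUE, use_asap = TRUE)
  set.seed(12)
  x <- array(rnorm(8 * 32 * 32 * 3), c(8, 32, 32, 3))
  y <- rep(0:3, 2)
  spec <- train_spec(lr = 1e-3, batch = 8, epochs = 10, seed = 21)
  fit1 <- train_model(cfg, x, y, spec = spec)
  expect_lt(mean(tail(fit1$step_losses, 3)), mean(head(fit1$step_losses, 3)))
  fit2 <- train_model(cfg, x, y, spec = spec)
  expect_identical(fit1$step_losses, fit2$step_losses)
  # zero epochs returns the initialized network untouched
  m0 <- build_model(cfg, seed = 21)
  before <- predict_model(m0, x[1:2, , , , drop = FALSE])
  fit0 <- train_model(m0, x, y, spec = train_spec(epochs = 0, seed = 21))
  expect_identical(predict_model(fit0$model, x[1:2, , , , drop = FALSE]), before)
  expect_identical(nrow(fit0$history), 0L)
})

test_that("evaluation produces a row-sum-correct confusion matrix", {
  cfg <- model_config(input_side = 32, patch = 4, embed_dim = 8,
                      depths = c(1, 1), heads = c(2, 2), window = 4)
  m <- build_model(cfg, seed = 30)
  set.seed(30)
  x <- array(rnorm(12 * 32 * 32 * 3), c(12, 32, 32, 3))
  y <- rep(0:3, 3)
  cm <- evaluate_model(m, x, y)
  expect_identical(unname(rowSums(cm)), rep(3, 4))
  expect_identical(sum(cm), 12L)
  expect_error(evaluate_model(m, x[0, , , , drop = FALSE], integer(0)), "empty")
})
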