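# Light-attention classifier: forward contracts, gradients, metrics,
# training behaviour and batch classification.

small_cfg <- function(...) {
  classifier_config(channels = 8L, learning_rate = 1e-3, seed = 3L, ...)
}

test_that("forward pass satisfies the shape and pooling contracts", {
  cfg <- small_cfg()
  st <- init_classifier(cfg, dim = 12L)
  for (L in c(9, 37, 80)) {
    e <- matrix(rnorm(L * 12), L, 12)
    fw <- forward_classifier(e, st)
    expect_length(fw$pooled, 16L)          # 2 * channels, any length
    expect_length(fw$profile, L)
    expect_true(fw$prob >= 0 && fw$prob <= 1)
  }
  # below the filter width the input is rejected
  expect_error(forward_classifier(matrix(rnorm(8 * 12), 8, 12), st),
               class = "embrep_input_error")
})

test_that("a zero-initialised head outputs probability exactly 0.5", {
  st <- init_classifier(small_cfg(), dim = 10L)
  st$w_out[] <- 0; st$b_out <- 0
  for (L in c(12, 33)) {
    fw <- forward_classifier(matrix(rnorm(L * 10), L, 10), st)
    expect_identical(fw$prob, 0.5)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- classifier_config(channels = 4L, dropout_rate = 0, seed = 2L)
  st <- init_classifier(cfg, dim = 6L)
  set.seed(4)
  E <- matrix(rnorm(15 * 6), 15, 6)
  X <- embrep:::im2col(E, cfg$filter_size)
  target <- 1
  fw <- embrep:::forward_from_X(X, st)
  g <- embrep:::backward_classifier(fw, st, target)
  eps <- 1e-6
  loss_of <- function(state) {
    p <- embrep:::forward_from_X(X, state)$prob
    embrep:::bce_loss(p, target)
  }
  for (nm in c("W_att", "W_feat", "w_out", "b_att", "b_feat", "b_out")) {
    w <- st[[nm]]
    idx <- if (length(w) > 1) sample(length(w), min(5, length(w))) else 1
    for (k in idx) {
      sp <- st; sp[[nm]][k] <- sp[[nm]][k] + eps
      sm <- st; sm[[nm]][k] <- sm[[nm]][k] - eps
      fd <- (loss_of(sp) - loss_of(sm)) / (2 * eps)
      expect_equal(unname(as.vector(g[[nm]])[k]), fd, tolerance = 1e-4)
    }
  }
})

test_that("precision, recall and F1 follow the defining formulas", {
  m <- prf_metrics(list(TP = 8, FP = 2, FN = 1))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  z <- prf_metrics(list(TP = 0, FP = 0, FN = 0))
  expect_equal(unlist(z), c(precision = 0, recall = 0, f1 = 0))
  p <- prf_metrics(list(TP = 5, FP = 0, FN = 0))
  expect_equal(unlist(p), c(precision = 1, recall = 1, f1 = 1))
  expect_error(prf_metrics(list(TP = -1, FP = 0, FN = 0)),
               class = "embrep_input_error")
})

test_that("training is deterministic, stops early and restores the best", {
  ds <- make_classifier_dataset(30, 30, dim = 24, seed = 8)
  cfg <- classifier_config(channels = 8L, learning_rate = 1e-3,
                           max_epochs = 25L, patience = 5L, seed = 9L)
  f1 <- train_classifier(ds, cfg)
  f2 <- train_classifier(ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$state$W_att, f2$state$W_att)
  # early-stop accounting: run ends patience epochs after the best one
  # (unless max_epochs hit first)
  if (nrow(f1$history) < cfg$max_epochs)
    expect_equal(nrow(f1$history), f1$best_epoch + cfg$patience)
  # restored state reproduces the best recorded held-out loss
  probs <- vapply(f1$test_idx, function(i)
    forward_classifier(ds$embeddings[[i]], f1$state)$prob, numeric(1))
  loss <- mean(embrep:::bce_loss(probs, ds$labels[f1$test_idx]))
  expect_equal(loss, min(f1$history$test_loss), tolerance = 1e-10)
})

test_that("single-class datasets are rejected", {
  ds <- make_classifier_dataset(6, 6, dim = 16, seed = 2)
  ds$labels <- rep(1L, 12)
  expect_error(train_classifier(ds, small_cfg()),
               class = "embrep_training_error")
})

test_that("trained attention mass concentrates on repeat regions", {
  ds <- make_classifier_dataset(100, 100, seed = 8)
  cfg <- classifier_config(channels = 16L, learning_rate = 1e-3,
                           max_epochs = 60L, seed = 4L)
  fit <- train_classifier(ds, cfg)
  expect_gte(fit$metrics$f1, 0.9)
  ok <- 0; n <- 0
  for (i in fit$test_idx) {
    if (ds$labels[i] != 1) next
    fw <- forward_classifier(ds$embeddings[[i]], fit$state)
    rs <- ds$info$repeat_start[i]; re <- ds$info$repeat_end[i]
    flank <- setdiff(seq_len(ds$embeddings[[i]]$L), rs:re)
    n <- n + 1
    ok <- ok + (mean(fw$attention[rs:re]) > mean(fw$attention[flank]))
  }
  expect_gte(ok / n, 0.8)
})

test_that("batch classification is order-preserving and threshold-exact", {
  ds <- make_classifier_dataset(6, 6, dim = 16, seed = 3)
  st <- init_classifier(classifier_config(channels = 4L, seed = 1L), 16L)
  tab <- classify_batch(ds$embeddings, st)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))
  # batch equals one-by-one
  solo <- vapply(ds$embeddings, function(e)
    forward_classifier(e, st)$prob, numeric(1))
  expect_equal(tab$probability, unname(solo))
  # permuting the batch permutes, not changes, the probabilities
  perm <- sample(12)
  tab2 <- classify_batch(ds$embeddings[perm], st)
  expect_equal(tab2$probability, tab$probability[perm])
  # boundary: probability == threshold is called positive
  thr <- tab$probability[1]
  expect_equal(classify_batch(ds$embeddings[1], st, thr)$label, 1L)
  expect_true(all(classify_batch(ds$embeddings, st, 1.1)$label == 0L))
})
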