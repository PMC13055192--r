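# Light-attention binary classifier over per-residue embeddings, usable as a
# fast repeat/non-repeat pre-filter.  Two 1D convolutions over the length
# axis produce attention logits and feature maps; per-channel softmax
# attention weights the features, the weighted sum is concatenated with the
# per-channel max, and a linear head with a sigmoid gives the repeat
# probability.  Forward and backward passes are implemented directly with
# matrix algebra (the model is small) and trained with Adam on binary
# cross-entropy.

#' Classifier configuration
#'
#' Production defaults mirror the standard light-attention setup on
#' language-model embeddings: filter size 9, 1024 output channels, Adam at
#' learning rate 1e-6, early stopping with patience 20 on the held-out loss,
#' 9:1 train/test split.  For controlled synthetic data a much smaller model
#' (e.g. `channels = 32`, `learning_rate = 1e-3`) trains in seconds and
#' separates the classes just as well; dropout probability and the use of a
#' global max pool are configurable choices, not fixed by the architecture.
#'
#' @param filter_size Odd convolution width along the sequence.
#' @param channels Output channels of both convolutions; the pooled vector
#'   has length `2 * channels` regardless of sequence length.
#' @param dropout_rate Dropout on the feature maps during training.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience (epochs without held-out
#'   improvement).
#' @param max_epochs Hard cap on training epochs.
#' @param batch_size Minibatch size.
#' @param train_fraction Fraction of the dataset used for training.
#' @param seed Integer seed; training is deterministic given it.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(filter_size = 9L, channels = 1024L,
                              dropout_rate = 0.25, learning_rate = 1e-6,
                              patience = 20L, max_epochs = 200L,
                              batch_size = 32L, train_fraction = 0.9,
                              seed = 1L) {
  filter_size <- as.integer(filter_size)
  if (filter_size %% 2L == 0L) stop_param("filter_size must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_param("dropout_rate must be in [0, 1)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_param("train_fraction must be in (0, 1)")
  structure(list(filter_size = filter_size, channels = as.integer(channels),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Initialise classifier weights
#'
#' @param config [classifier_config()].
#' @param dim Embedding dimension D of the inputs.
#' @return A `classifier_state` list of weight matrices: `W_att`, `b_att`
#'   (attention convolution), `W_feat`, `b_feat` (feature convolution),
#'   `w_out`, `b_out` (linear head), plus `config` and `dim`.
#' @export
init_classifier <- function(config, dim) {
  k <- config$filter_size; C <- config$channels; D <- as.integer(dim)
  withr::with_seed(config$seed, {
    sd0 <- 1 / sqrt(k * D)
    structure(list(
      W_att = matrix(rnorm(k * D * C, sd = sd0), k * D, C),
      b_att = numeric(C),
      W_feat = matrix(rnorm(k * D * C, sd = sd0), k * D, C),
      b_feat = numeric(C),
      w_out = rnorm(2L * C, sd = 0.01),
      b_out = 0,
      config = config, dim = D),
      class = "classifier_state")
  })
}

# unfold the embedding into sliding windows: row l of the result is the
# zero-padded concatenation of rows l-h..l+h of E
im2col <- function(E, k) {
  L <- nrow(E); D <- ncol(E); h <- (k - 1L) %/% 2L
  X <- matrix(0, L, k * D)
  for (t in seq_len(k)) {
    src <- seq_len(L) + (t - 1L - h)
    ok <- src >= 1L & src <= L
    X[ok, ((t - 1L) * D + 1L):(t * D)] <- E[src[ok], , drop = FALSE]
  }
  X
}

col_softmax <- function(A) {
  S <- exp(sweep(A, 2L, apply(A, 2L, max)))
  sweep(S, 2L, colSums(S), "/")
}

#' Classifier forward pass
#'
#' @param e A [residue_embedding()] or L x D matrix with `L >= filter_size`.
#' @param state [init_classifier()] output (possibly trained).
#' @param dropout_mask Optional 0/1 matrix applied to the feature maps
#'   (training only); `NULL` disables dropout.
#' @return List with `prob` (repeat probability), `profile` (per-residue
#'   attention score: channel mean of the raw attention logits before the
#'   softmax, length L), `attention` (per-residue attention mass: channel
#'   mean of the softmax attention weights -- the share of pooling weight
#'   each residue actually receives; on sign-symmetric embeddings the
#'   signed logit mean cancels across channels, so this is the quantity
#'   that localises what the model attends to), `pooled` (vector of length
#'   `2 * channels`), and `cache` (intermediates for the backward pass).
#' @export
forward_classifier <- function(e, state, dropout_mask = NULL) {
  E <- emb_values(e)
  k <- state$config$filter_size
  if (nrow(E) < k)
    stop_input(sprintf("sequence length %d below filter size %d",
                       nrow(E), k))
  if (ncol(E) != state$dim)
    stop_input("embedding dimension does not match the model")
  X <- im2col(E, k)
  forward_from_X(X, state, dropout_mask)
}

forward_from_X <- function(X, state, dropout_mask = NULL) {
  A <- sweep(X %*% state$W_att, 2L, state$b_att, "+")
  FF <- sweep(X %*% state$W_feat, 2L, state$b_feat, "+")
  profile <- rowMeans(A)
  Fd <- if (is.null(dropout_mask)) FF else
    FF * dropout_mask / (1 - state$config$dropout_rate)
  S <- col_softmax(A)
  z1 <- colSums(S * Fd)
  imax <- apply(Fd, 2L, which.max)
  z2 <- Fd[cbind(imax, seq_len(ncol(Fd)))]
  pooled <- c(z1, z2)
  y <- sum(pooled * state$w_out) + state$b_out
  list(prob = plogis(y), profile = profile, attention = rowMeans(S),
       pooled = pooled,
       cache = list(X = X, A = A, Fd = Fd, S = S, z1 = z1, imax = imax,
                    dropout_mask = dropout_mask))
}

# gradient of the binary cross-entropy w.r.t. every weight, for one sample
backward_classifier <- function(fw, state, target) {
  cc <- fw$cache
  C <- state$config$channels
  dy <- fw$prob - target                 # dL/dy through the sigmoid
  dpooled <- dy * state$w_out
  g <- list(w_out = dy * fw$pooled, b_out = dy)
  dz1 <- dpooled[seq_len(C)]
  dz2 <- dpooled[C + seq_len(C)]
  dFd <- sweep(cc$S, 2L, dz1, "*")
  dFd[cbind(cc$imax, seq_len(C))] <- dFd[cbind(cc$imax, seq_len(C))] + dz2
  dS <- sweep(cc$Fd, 2L, dz1, "*")
  inner <- colSums(cc$S * dS)
  dA <- cc$S * sweep(dS, 2L, inner, "-")
  dFF <- if (is.null(cc$dropout_mask)) dFd else
    dFd * cc$dropout_mask / (1 - state$config$dropout_rate)
  g$W_att <- crossprod(cc$X, dA)
  g$b_att <- colSums(dA)
  g$W_feat <- crossprod(cc$X, dFF)
  g$b_feat <- colSums(dFF)
  g
}

bce_loss <- function(p, t) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(t * log(p) + (1 - t) * log(1 - p))
}

WEIGHT_NAMES <- c("W_att", "b_att", "W_feat", "b_feat", "w_out", "b_out")

#' Train the light-attention classifier
#'
#' Splits the dataset into train/test at `train_fraction`, optimises binary
#' cross-entropy with Adam, and stops early when the held-out loss has not
#' improved for `patience` epochs (the best-epoch weights are restored).
#' Fully deterministic given `config$seed`.
#'
#' @param dataset List with `embeddings` (list of [residue_embedding()]s or
#'   matrices) and `labels` (0/1 vector), e.g. from
#'   [make_classifier_dataset()].
#' @param config [classifier_config()].
#' @return A `classifier_fit`: list with `state` (trained weights),
#'   `history` (tibble: epoch, train_loss, test_loss), `metrics`
#'   (precision/recall/f1 on the held-out split), `best_epoch`,
#'   `test_idx`.  [tidy()] returns the history, [glance()] the metrics.
#' @export
train_classifier <- function(dataset, config = classifier_config()) {
  labels <- as.numeric(dataset$labels)
  embs <- dataset$embeddings
  n <- length(embs)
  if (length(labels) != n) stop_input("labels/embeddings length mismatch")
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    rlang::abort("training needs at least two examples per class",
                 class = "embrep_training_error")
  k <- config$filter_size
  D <- ncol(emb_values(embs[[1]]))
  state <- init_classifier(config, D)
  Xs <- lapply(embs, function(e) im2col(emb_values(e), k))
  Ls <- vapply(Xs, nrow, integer(1))
  if (any(Ls < k)) stop_input("all sequences must be at least filter_size long")

  withr::with_seed(config$seed + 1L, {
    test_idx <- sort(sample.int(n, max(1L, round((1 - config$train_fraction) * n))))
    train_idx <- setdiff(seq_len(n), test_idx)

    adam_m <- lapply(state[WEIGHT_NAMES], function(w) w * 0)
    adam_v <- adam_m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    best_loss <- Inf; best_state <- state; best_epoch <- 0L; wait <- 0L
    history <- vector("list", config$max_epochs)

    test_loss_of <- function(st) {
      mean(vapply(test_idx, function(i)
        bce_loss(forward_from_X(Xs[[i]], st)$prob, labels[i]), numeric(1)))
    }

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (batch in batches) {
        grads <- lapply(state[WEIGHT_NAMES], function(w) w * 0)
        for (i in batch) {
          mask <- if (config$dropout_rate > 0)
            matrix(rbinom(Ls[i] * config$channels, 1L,
                          1 - config$dropout_rate),
                   Ls[i], config$channels)
          fw <- forward_from_X(Xs[[i]], state, mask)
          ep_loss <- ep_loss + bce_loss(fw$prob, labels[i])
          g <- backward_classifier(fw, state, labels[i])
          for (nm in WEIGHT_NAMES) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        step <- step + 1L
        for (nm in WEIGHT_NAMES) {
          gb <- grads[[nm]] / length(batch)
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gb
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gb^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          state[[nm]] <- state[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      tl <- test_loss_of(state)
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = ep_loss / length(train_idx),
                                 test_loss = tl)
      if (tl < best_loss - 1e-12) {
        best_loss <- tl; best_state <- state
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    state <- best_state
  })

  probs <- vapply(test_idx, function(i)
    forward_from_X(Xs[[i]], state)$prob, numeric(1))
  pred <- as.integer(probs >= 0.5)
  truth <- labels[test_idx]
  counts <- confusion_counts(pred, truth)
  structure(list(state = state,
                 history = dplyr::bind_rows(history),
                 metrics = prf_metrics(counts),
                 counts = counts,
                 best_epoch = best_epoch,
                 test_idx = test_idx),
            class = "classifier_fit")
}

#' @export
print.classifier_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<classifier_fit> best epoch %d; held-out precision %.3f recall %.3f F1 %.3f\n",
    x$best_epoch, m$precision, m$recall, m$f1))
  invisible(x)
}

#' @export
tidy.classifier_fit <- function(x, ...) x$history

#' @export
glance.classifier_fit <- function(x, ...) {
  tibble(best_epoch = x$best_epoch, epochs_run = nrow(x$history),
         precision = x$metrics$precision, recall = x$metrics$recall,
         f1 = x$metrics$f1)
}

#' Held-out loss curve of a classifier fit
#'
#' @param object A `classifier_fit`.
#' @param ... Unused.
#' @export
autoplot.classifier_fit <- function(object, ...) {
  h <- tidyr_longer(object$history)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL)
}

# minimal pivot (avoids a tidyr dependency for one reshape)
tidyr_longer <- function(h) {
  dplyr::bind_rows(
    tibble(epoch = h$epoch, loss = h$train_loss, split = "train"),
    tibble(epoch = h$epoch, loss = h$test_loss, split = "test"))
}

confusion_counts <- function(pred, truth) {
  list(TP = sum(pred == 1 & truth == 1),
       FP = sum(pred == 1 & truth == 0),
       FN = sum(pred == 0 & truth == 1),
       TN = sum(pred == 0 & truth == 0))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `f1 = 2 P R / (P + R)`; any zero denominator yields 0 by convention.
#'
#' @param counts List or named vector with `TP`, `FP`, `FN` (and optionally
#'   `TN`).
#' @return Named list with `precision`, `recall`, `f1`.
#' @export
prf_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (any(c(tp, fp, fn) < 0)) stop_input("confusion counts must be >= 0")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Classify a batch of embeddings
#'
#' Stateless and order-preserving: each probability depends only on its own
#' input.  The decision rule is `probability >= threshold`.
#'
#' @param embeddings List of [residue_embedding()]s or matrices.
#' @param state Trained `classifier_state` (or a `classifier_fit`).
#' @param threshold Decision threshold (default 0.5).
#' @return Tibble with `sequence_id`, `probability`, `label`.
#' @export
classify_batch <- function(embeddings, state, threshold = 0.5) {
  if (inherits(state, "classifier_fit")) state <- state$state
  probs <- vapply(embeddings, function(e)
    forward_classifier(e, state)$prob, numeric(1))
  tibble(sequence_id = vapply(seq_along(embeddings), function(i)
           emb_id(embeddings[[i]], sprintf("seq%d", i)), character(1)),
         probability = probs,
         label = as.integer(probs >= threshold))
}

#' Build a labelled synthetic dataset for the classifier
#'
#' Positives are planted-repeat embeddings whose base units are drawn
#' around a small dictionary of shared repeat motifs, emulating the
#' knowledge-based setting the pre-filter is meant for: natural repeat
#' units fall into recurring families, so repeat-region residues carry a
#' signature that recurs across proteins, and that signature -- not the
#' duplication itself -- is what a light-attention classifier can learn
#' from residue embeddings.  Each positive's base unit row is
#' `normalize(sqrt(tau) * motif + sqrt(1 - tau) * individual)` for one of
#' `n_motifs` dictionary motifs; copies of the base unit are then generated
#' at `within_unit_cosine` fidelity exactly as in [generate_synthetic()].
#' Negatives are background-only embeddings of matched lengths.
#'
#' @param n_pos,n_neg Number of positive / negative examples.
#' @param dim Embedding dimension.
#' @param within_unit_cosine Within-unit similarity of the positives.
#' @param unit_length Planted unit length.
#' @param copies_range Range the per-protein copy number is drawn from.
#' @param flank_range Range each flank length is drawn from.
#' @param n_motifs Size of the shared motif dictionary.
#' @param motif_weight tau, the share of a unit row carried by its motif.
#' @param seed Integer seed.
#' @return List with `embeddings`, `labels` (1 = repeat), and `info` (tibble
#'   with per-example repeat-region span, 0/0 for negatives).
#' @export
make_classifier_dataset <- function(n_pos = 200L, n_neg = 200L, dim = 64L,
                                    within_unit_cosine = 0.95,
                                    unit_length = 10L,
                                    copies_range = c(6L, 10L),
                                    flank_range = c(10L, 25L),
                                    n_motifs = 8L, motif_weight = 0.5,
                                    seed = 1L) {
  rho <- within_unit_cosine
  embeddings <- vector("list", n_pos + n_neg)
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  rep_start <- integer(n_pos + n_neg)
  rep_end <- integer(n_pos + n_neg)
  withr::with_seed(seed, {
    motifs <- lapply(seq_len(n_motifs), function(k)
      normalize_rows(matrix(rnorm(unit_length * dim), ncol = dim)))
    copies <- resample_int(copies_range[1]:copies_range[2], n_pos)
    fl <- resample_int(flank_range[1]:flank_range[2], n_pos)
    fr <- resample_int(flank_range[1]:flank_range[2], n_pos)
    motif_of <- sample.int(n_motifs, n_pos, replace = TRUE)
    for (i in seq_len(n_pos)) {
      base <- normalize_rows(
        sqrt(motif_weight) * motifs[[motif_of[i]]] +
        sqrt(1 - motif_weight) *
          normalize_rows(matrix(rnorm(unit_length * dim), ncol = dim)))
      rows <- list(if (fl[i] > 0)
        normalize_rows(matrix(rnorm(fl[i] * dim), ncol = dim)))
      for (k in seq_len(copies[i]))
        rows[[length(rows) + 1L]] <- normalize_rows(
          sqrt(rho) * base + sqrt(1 - rho) *
            normalize_rows(matrix(rnorm(unit_length * dim), ncol = dim)))
      rows[[length(rows) + 1L]] <- if (fr[i] > 0)
        normalize_rows(matrix(rnorm(fr[i] * dim), ncol = dim))
      values <- do.call(rbind, rows)
      embeddings[[i]] <- residue_embedding(values, sprintf("pos%03d", i))
      rep_start[i] <- fl[i] + 1L
      rep_end[i] <- fl[i] + copies[i] * unit_length
    }
    for (i in seq_len(n_neg)) {
      match_len <- embeddings[[((i - 1L) %% n_pos) + 1L]]$L
      embeddings[[n_pos + i]] <- residue_embedding(
        normalize_rows(matrix(rnorm(match_len * dim), ncol = dim)),
        sprintf("neg%03d", i))
    }
  })
  list(embeddings = embeddings, labels = labels,
       info = tibble(sequence_id = vapply(embeddings, `[[`, character(1),
                                          "sequence_id"),
                     label = labels,
                     repeat_start = rep_start, repeat_end = rep_end))
}
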