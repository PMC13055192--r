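# Score-matrix stage: accumulate trace scores into the dot-plot-like matrix
# M_s, estimate candidate repeat lengths from off-diagonal sums, localise the
# representative repeat with a position-weighted sliding window, and build
# its profile-like weighted embedding.

#' Accumulate traces into the score matrix
#'
#' Cell (i, j) holds the sum of the scores of all traces whose alignment
#' contains the pair (i, j); pairs are mirrored into both triangles so the
#' matrix is symmetric, and untouched cells stay zero.
#'
#' @param traces List of [alignment_trace()]s.
#' @param L Sequence length (matrix dimension).
#' @return L x L numeric score matrix.
#' @export
build_score_matrix <- function(traces, L) {
  M <- matrix(0, L, L)
  for (t in traces) {
    p <- t$pairs
    if (any(p < 1L) || any(p > L))
      stop_input("trace pairs outside [1, L]")
    M[p] <- M[p] + t$score
    M[p[, c(2, 1), drop = FALSE]] <- M[p[, c(2, 1), drop = FALSE]] + t$score
  }
  M
}

#' Candidate repeat lengths from diagonal score sums
#'
#' For each distance d from 1 to floor(L/2), sums the score-matrix cells of
#' the upper triangle at |i - j| = d; every distance with a positive sum is a
#' candidate repeat unit length.  Periodic repeats concentrate trace mass at
#' multiples of the unit length, so the top candidate is the length estimate.
#'
#' @param m Score matrix from [build_score_matrix()].
#' @return Tibble with columns `d` and `diagonal_sum`, sorted by decreasing
#'   sum; zero-sum distances are omitted.
#' @export
candidate_lengths <- function(m) {
  L <- nrow(m)
  dmax <- L %/% 2L
  if (dmax < 1L)
    return(tibble(d = integer(0), diagonal_sum = numeric(0)))
  sums <- vapply(seq_len(dmax), function(d)
    sum(m[cbind(seq_len(L - d), seq_len(L - d) + d)]), numeric(1))
  out <- tibble(d = seq_len(dmax), diagonal_sum = sums)
  out <- out[out$diagonal_sum > 0, , drop = FALSE]
  out[order(-out$diagonal_sum, out$d), ]
}

#' Position weights of the sliding window
#'
#' Conserved regions tend to sit in the middle of a repeat unit while the
#' boundaries accumulate substitutions and indels, so window columns are
#' weighted by a symmetric triangle peaking at the centre:
#' `w(p) = min(p, l - p + 1) - 1/2` for p = 1..l.
#'
#' @param l Repeat length (window width), >= 1.
#' @return A `window_weights` list with elements `l` and `weights`.
#' @export
window_weights <- function(l) {
  l <- as.integer(l)
  if (l < 1L) stop_param("l must be >= 1")
  p <- seq_len(l)
  structure(list(l = l, weights = pmin(p, l - p + 1L) - 0.5),
            class = "window_weights")
}

#' Localise the representative repeat
#'
#' Slides an l-column window along the score matrix and scores each start c
#' as `sum_i sum_p w(p) * m[i, c + p - 1]` with the triangle weights of
#' [window_weights()]; the representative repeat starts at the maximising
#' window (leftmost on ties).
#'
#' @param m Score matrix.
#' @param l Candidate repeat length.
#' @return A `representative_repeat`: list with `start` (1-based column),
#'   `length` and `window_score`.
#' @export
locate_representative <- function(m, l) {
  L <- nrow(m)
  l <- as.integer(l)
  if (l > L) stop_param("window length l exceeds the sequence length")
  w <- window_weights(l)$weights
  cs <- colSums(m)
  starts <- seq_len(L - l + 1L)
  scores <- vapply(starts, function(c)
    sum(w * cs[c:(c + l - 1L)]), numeric(1))
  best <- which.max(scores)  # ties: smallest start
  structure(list(start = starts[best], length = l,
                 window_score = scores[best]),
            class = "representative_repeat")
}

#' Profile-like weighted embedding of the representative repeat
#'
#' Each representative row r is the sum over all sequence positions i of
#' `m[i, start + r - 1] * e[i, ]`: the columns of the score matrix under the
#' representative window weight the full-length embedding rows, analogous to
#' building a profile from the columns of an MSA.  A window column whose
#' score-matrix weights are all zero falls back to the raw embedding row at
#' that position (avoiding zero vectors; cosine scoring makes the overall
#' scale irrelevant).
#'
#' @param m Score matrix.
#' @param e_fl Full-length [residue_embedding()] (or matrix).
#' @param rep A `representative_repeat` from [locate_representative()].
#' @return Numeric matrix (l x D), the weighted representative embedding.
#' @export
weighted_repeat_embedding <- function(m, e_fl, rep) {
  E <- emb_values(e_fl)
  l <- rep$length
  cols <- rep$start:(rep$start + l - 1L)
  if (rep$start < 1L || max(cols) > nrow(E))
    stop_param("representative window out of bounds")
  W <- m[, cols, drop = FALSE]
  Er <- crossprod(W, E)
  zero <- colSums(abs(W)) == 0
  if (any(zero))
    Er[zero, ] <- E[cols[zero], , drop = FALSE]
  Er
}

#' Mask identified repeat regions out of the score matrix
#'
#' Sets to zero every row and column whose index lies in any of the given
#' spans; other cells are unchanged.  Masking is idempotent and strictly
#' shrinks the nonzero mass whenever the spans cover signal, which is what
#' guarantees termination of the masking loop.
#'
#' @param m Score matrix.
#' @param spans Two-column matrix / data frame of spans (`start`, `end`,
#'   1-based inclusive).
#' @return The masked score matrix.
#' @export
mask_score_matrix <- function(m, spans) {
  spans <- as.matrix(as.data.frame(spans)[, 1:2])
  if (!nrow(spans)) return(m)
  if (any(spans < 1L) || any(spans > nrow(m)))
    stop_input("mask spans out of bounds")
  idx <- unique(unlist(lapply(seq_len(nrow(spans)), function(k)
    spans[k, 1]:spans[k, 2])))
  m[idx, ] <- 0
  m[, idx] <- 0
  m
}
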