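# Local alignment engine: Smith-Waterman over a cosine similarity matrix with
# a single linear gap penalty, traceback started at every pair-ending local
# maximum of the score landscape, followed by length/score/significance
# filtering, maximality pruning and redundancy deduplication.

MASK_VAL <- -4  # below any cosine; masked cells can never contribute a pair

#' Construct an alignment trace
#'
#' A trace is one suboptimal alignment path: an ordered set of aligned
#' (i, j) index pairs (1-based, strictly increasing in both coordinates;
#' coordinate jumps > 1 are gaps) plus its windowed score.
#'
#' @param pairs Two-column integer matrix of aligned pairs.
#' @param score Trace score (windowed mean similarity).
#' @param origin `"primary"` (from the aligner) or `"transitive"`.
#' @param mean_sim Mean per-pair similarity (optional, used by filters).
#' @return An `alignment_trace` list.
#' @export
alignment_trace <- function(pairs, score = NA_real_, origin = "primary",
                            mean_sim = NA_real_) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  if (nrow(pairs) < 1L) stop_input("a trace needs at least one pair")
  if (nrow(pairs) > 1L) {
    di <- diff(pairs[, 1]); dj <- diff(pairs[, 2])
    if (any(di < 1L) || any(dj < 1L))
      stop_input("trace pairs must be strictly increasing in both coordinates")
  }
  structure(list(pairs = pairs, score = score, origin = origin,
                 mean_sim = mean_sim, npairs = nrow(pairs)),
            class = "alignment_trace")
}

#' @export
print.alignment_trace <- function(x, ...) {
  cat(sprintf("<alignment_trace %s> %d pairs, score %.4f, (%d,%d)..(%d,%d)\n",
              x$origin, x$npairs, x$score,
              x$pairs[1, 1], x$pairs[1, 2],
              x$pairs[x$npairs, 1], x$pairs[x$npairs, 2]))
  invisible(x)
}

pair_keys <- function(pairs, m) pairs[, 1] * (m + 1) + pairs[, 2]

# fraction of t1's pairs lying within Chebyshev distance `dist` of some pair
# of t2 (both pair sets monotone, so a window over sorted i suffices)
frac_near <- function(p1, p2, dist = 2L) {
  i2 <- p2[, 1]; j2 <- p2[, 2]
  near <- vapply(seq_len(nrow(p1)), function(k) {
    lo <- findInterval(p1[k, 1] - dist - 0.5, i2) + 1L
    hi <- findInterval(p1[k, 1] + dist + 0.5, i2)
    if (hi < lo) return(FALSE)
    any(abs(j2[lo:hi] - p1[k, 2]) <= dist)
  }, logical(1))
  mean(near)
}

order_traces <- function(traces) {
  if (!length(traces)) return(traces)
  sc <- vapply(traces, `[[`, numeric(1), "score")
  np <- vapply(traces, `[[`, integer(1), "npairs")
  i1 <- vapply(traces, function(t) t$pairs[1, 1], integer(1))
  j1 <- vapply(traces, function(t) t$pairs[1, 2], integer(1))
  traces[order(-sc, -np, i1, j1)]
}

# maximality: drop traces whose pair set is a strict subset of another's
prune_subpaths <- function(traces, m) {
  if (length(traces) < 2L) return(traces)
  keys <- lapply(traces, function(t) pair_keys(t$pairs, m))
  np <- lengths(keys)
  drop <- rep(FALSE, length(traces))
  for (a in seq_along(traces)) {
    if (drop[a]) next
    for (b in seq_along(traces)) {
      if (a == b || drop[b]) next
      if (np[a] < np[b] && all(keys[[a]] %in% keys[[b]])) {
        drop[a] <- TRUE
        break
      }
    }
  }
  traces[!drop]
}

# redundancy: two traces are redundant when >= `frac` of either one's pairs
# lie within Chebyshev distance `dist` of the other's; the higher-scoring
# trace is kept (greedy over the deterministic trace ordering)
dedup_traces <- function(traces, frac = 0.7, dist = 2L) {
  traces <- order_traces(traces)
  kept <- list()
  for (t in traces) {
    redundant <- FALSE
    for (k in kept) {
      if (frac_near(t$pairs, k$pairs, dist) >= frac ||
          frac_near(k$pairs, t$pairs, dist) >= frac) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- t
  }
  kept
}

drop_exact_duplicates <- function(traces, m) {
  if (length(traces) < 2L) return(traces)
  sig <- vapply(traces, function(t)
    paste(pair_keys(t$pairs, m), collapse = ","), character(1))
  traces[!duplicated(sig)]
}

# Shared trace extraction for self-alignment (square, symmetric, diagonal
# band excluded, upper triangle reported) and representative-vs-full search
# (rectangular, no exclusion).  `mu`/`sigma` are the significance statistics
# of the similarity background; `mask_cols` columns are forbidden.
local_align_traces <- function(sim, params, self = FALSE,
                               min_span = params$min_span,
                               mu = NULL, sigma = NULL,
                               mask_cols = integer(0)) {
  n <- nrow(sim); m <- ncol(sim)
  if (n < min_span || m < min_span) return(list())
  w <- sim
  if (self) {
    dd <- col(w) - row(w)
    w[dd <= params$diagonal_exclusion] <- MASK_VAL  # lower triangle + band
  }
  if (length(mask_cols)) w[, mask_cols] <- MASK_VAL
  if (is.null(mu)) {
    # significance statistics come from the unmasked similarity background:
    # all off-diagonal entries for self-comparison, all unmasked entries for
    # rectangular search
    use <- if (self) sim[col(sim) != row(sim)] else
      sim[, setdiff(seq_len(m), mask_cols), drop = FALSE]
    mu <- mean(use); sigma <- sd(use)
  }
  # a free/cheap gap penalty lets a DP-optimal path chain several distinct
  # alignment bands through low-similarity jumps, so suboptimal alignments
  # are extracted as the maximal segments of every traceback path whose
  # smoothed per-pair similarity stays at or above the score cutoff;
  # tracebacks are seeded at the end of every maximal diagonal run (every
  # other traceback is a prefix of one of those)
  segs <- sw_suboptimal_segments(w, sim, params$gap_open,
                                 params$gap_extension,
                                 params$window_length, params$score_cutoff,
                                 min_span)
  thr <- mu + params$sigma_factor * sigma
  out <- list()
  for (seg in segs) {
    vals <- sim[seg]
    ms <- mean(vals)
    if (ms < thr) next
    sc <- mean(smooth_window(vals, params$window_length))
    if (sc < params$score_cutoff) next
    out[[length(out) + 1L]] <- alignment_trace(seg, score = sc,
                                               origin = "primary",
                                               mean_sim = ms)
  }
  out <- drop_exact_duplicates(out, m)
  out <- prune_subpaths(out, m)
  out <- dedup_traces(out)
  order_traces(out)
}

#' Local self-alignment of an embedding
#'
#' Runs Smith-Waterman over the cosine self-similarity matrix and reports all
#' suboptimal alignment traces that pass the filters: at least `min_span`
#' aligned pairs, windowed score >= `score_cutoff`, mean per-pair similarity
#' >= mu + `sigma_factor` * sigma of the off-diagonal similarity
#' distribution.  Tracebacks start at the end of every maximal diagonal run
#' of the deterministic predecessor landscape (every other traceback path is
#' a prefix of one of those), and each path is segmented at positions where
#' its smoothed per-pair similarity falls below the cutoff.  The diagonal band
#' `|i - j| <= diagonal_exclusion` is excluded (the trivial self-identity
#' alignment is not a repeat signal) and mirror traces are reported once, in
#' the upper triangle.  Reported traces are maximal (no strict sub-paths)
#' and deduplicated: two traces are redundant when at least 70% of either
#' one's pairs lie within Chebyshev distance 2 of the other's, in which case
#' the higher-scoring one is kept.
#'
#' @param e A [residue_embedding()] (or numeric matrix).
#' @param params [alignment_params()].
#' @return List of [alignment_trace()] objects, ordered by decreasing score.
#'   Empty when the sequence is shorter than `min_span`.
#' @export
local_self_align <- function(e, params = alignment_params()) {
  sim <- cosine_similarity(e)
  local_align_traces(sim, params, self = TRUE)
}
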