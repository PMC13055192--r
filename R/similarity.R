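#' Cosine substitution matrix between two embeddings
#'
#' The context-dependent substitution matrix of the pipeline: entry (i, j) is
#' the cosine similarity between row i of `a` and row j of `b`.  For
#' self-comparison (`b` missing or identical to `a`) the result is symmetric
#' with a unit main diagonal.  Cosine is scale-invariant, so multiplying any
#' row by a positive constant leaves the matrix unchanged.
#'
#' @param a,b [residue_embedding()]s or numeric matrices with equal column
#'   count; `b` defaults to `a`.
#' @return Numeric matrix (L_a x L_b) of cosine similarities in [-1, 1], with
#'   attributes `query_id` and `target_id`.
#' @export
cosine_similarity <- function(a, b = a) {
  va <- emb_values(a); vb <- emb_values(b)
  if (ncol(va) != ncol(vb))
    stop_input("embeddings have different dimensions D")
  na <- sqrt(rowSums(va^2)); nb <- sqrt(rowSums(vb^2))
  if (any(na == 0))
    stop_input(sprintf("zero-norm row %d in first embedding", which(na == 0)[1]))
  if (any(nb == 0))
    stop_input(sprintf("zero-norm row %d in second embedding", which(nb == 0)[1]))
  s <- tcrossprod(va / na, vb / nb)
  s[s > 1] <- 1; s[s < -1] <- -1
  attr(s, "query_id") <- emb_id(a, "query")
  attr(s, "target_id") <- emb_id(b, "target")
  s
}

# moving-average smoothing used by the trace score: centered window of
# `window_length`, truncated at the ends of the value vector
smooth_window <- function(vals, window_length) {
  n <- length(vals)
  h <- window_length %/% 2L
  cs <- cumsum(c(0, vals))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h); hi <- pmin(n, idx + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Windowed score of an alignment trace
#'
#' Per-pair similarities along the trace are smoothed with a centered moving
#' average of `window_length` positions (truncated at the trace ends), and the
#' smoothed values are averaged; a single-pair trace scores its own
#' similarity.  The result lies in [-1, 1] and is the TraceScore used for
#' filtering and score-matrix accumulation.
#'
#' @param trace A trace object (see [local_self_align()]) or a two-column
#'   matrix of aligned (i, j) pairs, 1-based.
#' @param sim Similarity matrix covering all pairs.
#' @param window_length Smoothing window (default 15).
#' @return A single numeric score.
#' @export
windowed_trace_score <- function(trace, sim, window_length = 15L) {
  pairs <- if (is.list(trace) && !is.null(trace$pairs)) trace$pairs else trace
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) stop_input("trace has no pairs")
  if (any(pairs < 1L) || any(pairs[, 1] > nrow(sim)) ||
      any(pairs[, 2] > ncol(sim)))
    stop_input("trace pairs outside the similarity matrix")
  mean(smooth_window(sim[pairs], window_length))
}

#' Alignment parameters
#'
#' Defaults follow the tool's standard operating point: smoothing window 15,
#' minimum span 15 aligned pairs, significance gate at mean + 2 sd of the
#' off-diagonal similarities, bounded affine gaps (opening penalty 1.0, extension
#' penalty 0), windowed-score cutoff 0.3, and a +/-2 band around the main
#' diagonal excluded from self-alignment.  `overlap_max`, `hypothesis_budget`, `max_iterations` and
#' `selection_metric` govern the repeat-extraction stage.
#'
#' @param window_length Moving-average window for trace scoring.
#' @param min_span Minimum number of aligned pairs per reported trace.
#' @param sigma_factor Significance filter: a trace's mean per-pair
#'   similarity must reach `mu + sigma_factor * sigma` of the off-diagonal
#'   similarity distribution.
#' @param gap_open Gap-opening penalty (> 0); a strictly positive opening
#'   cost keeps parallel suboptimal alignment bands separable.  Gap runs are
#'   bounded by the smoothing half-window (`window_length %/% 2`): a longer
#'   jump is a change of alignment band, not a gap.
#' @param gap_extension Gap-extension penalty per step (>= 0).
#' @param score_cutoff Minimum windowed trace score, in [0, 1].
#' @param diagonal_exclusion Half-width of the excluded diagonal band.
#' @param overlap_max Maximum pairwise overlap between accepted repeat
#'   instances, as a fraction of the shorter span.
#' @param hypothesis_budget Number of top length candidates evaluated per
#'   masking iteration.
#' @param max_iterations Maximum masking iterations in [detect_repeats()].
#' @param selection_metric `"covered_residues"` (default),
#'   `"mean_coverage"` or `"total_aligned_residues"` (see
#'   [select_best_length()]).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(window_length = 15L, min_span = 15L,
                             sigma_factor = 2.0, gap_open = 1.0,
                             gap_extension = 0.0,
                             score_cutoff = 0.3, diagonal_exclusion = 2L,
                             overlap_max = 0.5, hypothesis_budget = 10L,
                             max_iterations = 5L,
                             selection_metric = "covered_residues") {
  if (min_span < 1L) stop_param("min_span must be >= 1")
  if (gap_open <= 0) stop_param("gap_open must be > 0")
  if (gap_extension < 0) stop_param("gap_extension must be >= 0")
  if (score_cutoff < 0 || score_cutoff > 1)
    stop_param("score_cutoff must be in [0, 1]")
  if (diagonal_exclusion < 0L) stop_param("diagonal_exclusion must be >= 0")
  if (overlap_max < 0 || overlap_max > 1)
    stop_param("overlap_max must be in [0, 1]")
  if (!selection_metric %in% c("covered_residues", "mean_coverage",
                               "total_aligned_residues"))
    stop_param("unknown selection_metric")
  structure(list(window_length = as.integer(window_length),
                 min_span = as.integer(min_span),
                 sigma_factor = sigma_factor,
                 gap_open = gap_open,
                 gap_extension = gap_extension,
                 score_cutoff = score_cutoff,
                 diagonal_exclusion = as.integer(diagonal_exclusion),
                 overlap_max = overlap_max,
                 hypothesis_budget = as.integer(hypothesis_budget),
                 max_iterations = as.integer(max_iterations),
                 selection_metric = selection_metric),
            class = "alignment_params")
}
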