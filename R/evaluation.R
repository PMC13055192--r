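# Benchmark harness: repeat-level correctness by reciprocal span overlap
# against ground-truth units, protein-level calls by the "more than half of
# the predictions mutually aligned" rule, and corpus-level totals.

#' Correctness parameters for the benchmark
#'
#' The structural correctness criterion of repeat benchmarks (TM-score > 0.5
#' with > 50% coverage) is replaced by a sequence-level surrogate, since this
#' package operates on embeddings only: reciprocal span overlap of at least
#' `min_coverage` against a ground-truth unit at the repeat level, and
#' embedding global-alignment score plus mutual coverage at least
#' `min_mutual_fraction` between two predictions at the protein level.
#'
#' @param min_mutual_fraction Minimum mutual coverage between two aligned
#'   predictions, in (0, 1].
#' @param min_coverage Minimum reciprocal overlap against a truth unit, in
#'   (0, 1].
#' @return A `correctness_params` list.
#' @export
correctness_params <- function(min_mutual_fraction = 0.5,
                               min_coverage = 0.5) {
  if (min_mutual_fraction <= 0 || min_mutual_fraction > 1 ||
      min_coverage <= 0 || min_coverage > 1)
    stop_param("correctness thresholds must be in (0, 1]")
  structure(list(min_mutual_fraction = min_mutual_fraction,
                 min_coverage = min_coverage),
            class = "correctness_params")
}

#' Is a predicted repeat correct?
#'
#' TRUE iff some ground-truth unit overlaps the prediction reciprocally: the
#' overlap length divided by the prediction length AND by the unit length
#' must both exceed `min_coverage` (strict, matching the "coverage greater
#' than 50%" convention of structural benchmarks).  A prediction blanketing
#' two whole equal units therefore fails: each side of the overlap is
#' exactly, not more than, half of the prediction.
#'
#' @param start,end Predicted span, 1-based inclusive.
#' @param truth A [ground_truth()].
#' @param params [correctness_params()].
#' @return Logical flag.
#' @export
repeat_correct <- function(start, end, truth, params = correctness_params()) {
  if (end < start) stop_input("prediction span with end < start")
  u <- truth$units
  if (!nrow(u)) return(FALSE)
  plen <- end - start + 1L
  ov <- pmax(0L, pmin(end, u$end) - pmax(start, u$start) + 1L)
  any(ov / plen > params$min_coverage &
      ov / (u$end - u$start + 1L) > params$min_coverage)
}

#' Protein-level repeat call from pairwise prediction agreement
#'
#' A protein is called repeat-containing when strictly more than half of its
#' predicted repeats align correctly with at least one other prediction of
#' the same protein.
#'
#' @param pairwise_correct Square symmetric logical matrix over the
#'   predictions of one protein (diagonal FALSE).
#' @return Logical call; FALSE for zero predictions.
#' @export
protein_level_call <- function(pairwise_correct) {
  n <- NROW(pairwise_correct)
  if (n == 0L) return(FALSE)
  pc <- as.matrix(pairwise_correct)
  if (nrow(pc) != ncol(pc)) stop_input("flag matrix must be square")
  if (any(pc != t(pc))) stop_input("flag matrix must be symmetric")
  diag(pc) <- FALSE
  aligned <- sum(rowSums(pc) > 0)
  aligned > n / 2
}

# embedding surrogate for "two predictions align correctly": global-align
# the two instance embeddings, require score >= score_cutoff and mutual
# coverage >= min_mutual_fraction on both sides
predictions_aligned <- function(E, s1, e1, s2, e2, params, cparams) {
  ga <- global_align(E[s1:e1, , drop = FALSE], E[s2:e2, , drop = FALSE],
                     params$gap_extension)
  nmatch <- nrow(ga$pairs)
  ga$score >= params$score_cutoff &&
    nmatch / (e1 - s1 + 1L) > cparams$min_mutual_fraction &&
    nmatch / (e2 - s2 + 1L) > cparams$min_mutual_fraction
}

#' Run the two-level benchmark over a prediction corpus
#'
#' Repeat level: each prediction on a truth-positive protein is correct when
#' it reciprocally overlaps a ground-truth unit ([repeat_correct()]); every
#' prediction on a truth-negative protein counts as a false-positive repeat.
#' Protein level: predictions of one protein are pairwise globally aligned
#' in embedding space and the "> half mutually aligned" rule
#' ([protein_level_call()]) makes the call; a positive call on a negative
#' protein is a false-positive protein.
#'
#' @param predictions Tibble of predicted instances with columns
#'   `sequence_id`, `start`, `end` (1-based inclusive), e.g. from
#'   [tidy.detection_result()]; proteins without predictions simply have no
#'   rows.
#' @param truths Named list of [ground_truth()] objects for the positive
#'   proteins (an entry with zero units, or absence from the list combined
#'   with presence in `embeddings`, marks a negative).
#' @param embeddings Named list of [residue_embedding()]s covering every
#'   benchmarked protein; defines the protein universe.
#' @param params [alignment_params()] (for the pairwise alignment surrogate).
#' @param cparams [correctness_params()].
#' @return A `benchmark_result` with `per_protein` (tibble) and `totals`
#'   (list: `correct_proteins`, `false_positive_proteins`,
#'   `correct_repeats`, `false_positive_repeats`).  [tidy()] returns the
#'   per-protein table, [glance()] the totals as one row.
#' @export
benchmark_run <- function(predictions, truths, embeddings,
                          params = alignment_params(),
                          cparams = correctness_params()) {
  ids <- names(embeddings)
  if (is.null(ids) || any(!nzchar(ids)))
    stop_input("`embeddings` must be a named list")
  stray <- setdiff(unique(predictions$sequence_id), ids)
  if (length(stray))
    stop_input(sprintf("predictions for unknown sequence ids: %s",
                       paste(stray, collapse = ", ")))
  stray_t <- setdiff(names(truths), ids)
  if (length(stray_t))
    stop_input(sprintf("ground truth for unknown sequence ids: %s",
                       paste(stray_t, collapse = ", ")))

  per <- purrr::map_dfr(ids, function(id) {
    pr <- predictions[predictions$sequence_id == id, , drop = FALSE]
    pr <- pr[order(pr$start, pr$end), , drop = FALSE]
    gt <- truths[[id]]
    is_pos <- !is.null(gt) && nrow(gt$units) > 0
    n <- nrow(pr)
    flags <- if (is_pos && n)
      vapply(seq_len(n), function(k)
        repeat_correct(pr$start[k], pr$end[k], gt, cparams), logical(1))
    else logical(n)
    call <- FALSE
    if (n >= 2L) {
      E <- emb_values(embeddings[[id]])
      pc <- matrix(FALSE, n, n)
      for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        pc[a, b] <- pc[b, a] <- predictions_aligned(
          E, pr$start[a], pr$end[a], pr$start[b], pr$end[b],
          params, cparams)
      }
      call <- protein_level_call(pc)
    }
    tibble(sequence_id = id, is_repeat = is_pos, n_predicted = n,
           n_truth_units = if (is_pos) nrow(gt$units) else 0L,
           n_correct_repeats = if (is_pos) sum(flags) else 0L,
           n_false_repeats = if (is_pos) 0L else n,
           protein_call = call)
  })
  totals <- list(
    correct_proteins = sum(per$is_repeat & per$protein_call),
    false_positive_proteins = sum(!per$is_repeat & per$protein_call),
    correct_repeats = sum(per$n_correct_repeats),
    false_positive_repeats = sum(per$n_false_repeats))
  structure(list(per_protein = per, totals = totals,
                 params = params, cparams = cparams),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0(
    "<benchmark_result> %d proteins: %d correct / %d false-positive at ",
    "protein level; %d correct / %d false-positive repeats\n"),
    nrow(x$per_protein), t$correct_proteins, t$false_positive_proteins,
    t$correct_repeats, t$false_positive_repeats))
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) x$per_protein

#' @export
glance.benchmark_result <- function(x, ...) as_tibble(x$totals)
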