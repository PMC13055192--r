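# Instance extraction: search the weighted representative embedding against
# the full-length embedding, resolve overlapping candidate spans, and align
# each accepted instance globally to the representative.

#' Extract repeat instances with the representative embedding
#'
#' Runs a local alignment of the (weighted) representative embedding against
#' the full-length embedding; each resulting trace proposes a candidate span
#' on the full sequence.  Candidates are resolved greedily by descending
#' trace score with pairwise overlap at most `overlap_max` of the shorter
#' span, then each accepted span is globally aligned to the representative;
#' instances must reach `score_cutoff` on the global score.  For
#' representatives shorter than `min_span` the span filter is relaxed to
#' `max(5, floor(0.8 * l))`, otherwise units shorter than the default
#' minimum span could never be recovered.
#'
#' @param rep_embedding l x D matrix from [weighted_repeat_embedding()].
#' @param e_fl Full-length [residue_embedding()] (or matrix).
#' @param params [alignment_params()].
#' @param masked_spans Optional spans (start, end; 1-based inclusive) already
#'   claimed by earlier iterations; candidate instances touching them are
#'   discarded so families from different iterations stay disjoint.
#' @return List of `repeat_instance` objects: `start`, `end` (1-based
#'   inclusive), `alignment` (a [global_align()] result against the
#'   representative), `score`, `coverage` (fraction of representative
#'   columns matched).
#' @export
extract_instances <- function(rep_embedding, e_fl, params = alignment_params(),
                              masked_spans = NULL) {
  R <- as.matrix(rep_embedding)
  E <- emb_values(e_fl)
  l <- nrow(R)
  min_span_eff <- if (l < params$min_span) max(5L, as.integer(0.8 * l))
                  else params$min_span
  masked_idx <- integer(0)
  if (!is.null(masked_spans) && NROW(masked_spans) > 0) {
    ms <- as.matrix(as.data.frame(masked_spans)[, 1:2])
    masked_idx <- unique(unlist(lapply(seq_len(nrow(ms)), function(k)
      ms[k, 1]:ms[k, 2])))
  }
  sim <- cosine_similarity(R, E)
  traces <- local_align_traces(sim, params, self = FALSE,
                               min_span = min_span_eff,
                               mask_cols = masked_idx)
  if (!length(traces)) return(list())
  cand <- lapply(traces, function(t)
    list(start = min(t$pairs[, 2]), end = max(t$pairs[, 2]),
         score = t$score))
  # greedy overlap resolution, descending score
  sc <- vapply(cand, `[[`, numeric(1), "score")
  len <- vapply(cand, function(c) c$end - c$start + 1L, integer(1))
  st <- vapply(cand, `[[`, integer(1), "start")
  cand <- cand[order(-sc, -len, st)]
  kept <- list()
  for (c in cand) {
    clen <- c$end - c$start + 1L
    ok <- TRUE
    for (k in kept) {
      ov <- min(c$end, k$end) - max(c$start, k$start) + 1L
      if (ov > 0 && ov / min(clen, k$end - k$start + 1L) > params$overlap_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- c
  }
  out <- list()
  for (c in kept) {
    if (length(masked_idx) && any(c$start:c$end %in% masked_idx)) next
    ga <- global_align(E[c$start:c$end, , drop = FALSE], R,
                       params$gap_extension)
    if (ga$score < params$score_cutoff) next
    out[[length(out) + 1L]] <- structure(
      list(start = c$start, end = c$end, alignment = ga, score = ga$score,
           coverage = nrow(ga$pairs) / l),
      class = "repeat_instance")
  }
  st <- vapply(out, `[[`, integer(1), "start")
  out[order(st)]
}

#' Assemble a multiple alignment of repeat instances (A2M)
#'
#' Pairwise global alignments of each instance to the representative are
#' stitched column-wise: representative positions define the match columns
#' (uppercase), instance residues between representative positions become
#' insert states (lowercase), and skipped representative positions become
#' gap characters (`-`).  Rows are ordered by instance position along the
#' sequence.
#'
#' @param instances List of `repeat_instance`s from [extract_instances()].
#' @param rep_length Number of representative columns l.
#' @param sequence Optional full amino-acid sequence; instances take their
#'   letters from it ('X' when unknown).
#' @return Named character vector of A2M rows (names `start-end`).
#' @export
assemble_msa <- function(instances, rep_length, sequence = NULL) {
  rows <- vapply(instances, function(inst) {
    chars <- if (!is.null(sequence))
      strsplit(substr(sequence, inst$start, inst$end), "")[[1]]
    else rep("X", inst$end - inst$start + 1L)
    q <- 0L
    parts <- vapply(inst$alignment$ops, function(op) {
      if (op == "M") { q <<- q + 1L; toupper(chars[q]) }
      else if (op == "I") { q <<- q + 1L; tolower(chars[q]) }
      else "-"
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  names(rows) <- vapply(instances, function(inst)
    sprintf("%d-%d", inst$start, inst$end), character(1))
  rows
}

#' Select the best repeat-length hypothesis
#'
#' Competing hypotheses (one per candidate length) are compared on a
#' selection metric:
#'
#' * `"covered_residues"` (default): number of distinct sequence positions
#'   covered by the family's instances.  A fragment hypothesis (a window
#'   well inside the true unit) explains only a fraction of the repeat
#'   region, and a doubled-length hypothesis explains the same residues
#'   with fewer instances, so the true period wins through the tie-break
#'   chain; this makes the metric robust where per-instance coverage
#'   saturates at 1 for every candidate length.
#' * `"mean_coverage"`: average fraction of representative columns matched
#'   per instance.
#' * `"total_aligned_residues"`: total number of residues in all instances
#'   (overlapping instances counted twice).
#'
#' Every harmonic of the true period explains (nearly) the same residues, so
#' hypotheses whose metric is within a tolerance of the best are treated as
#' tied, and ties are broken towards the fundamental: more instances, then
#' smaller length, then smaller representative start.  The tolerance is
#' relative (`tolerance`) or, for the residue-count metric, an absolute
#' `tolerance_abs` residues, whichever is larger: alignment-edge smear is an
#' absolute effect (about half a smoothing window per instance boundary),
#' so a purely relative slack is too tight on short repeat regions.
#' `tolerance = 0, tolerance_abs = 0` gives strict argmax behaviour.
#'
#' @param hypotheses List of repeat-family hypotheses (as built by
#'   [detect_repeats()]): each has `l`, `representative`, `instances`,
#'   `msa`, `metric`.
#' @param metric_name Metric to rank on.
#' @param tolerance Relative slack within which hypotheses count as tied
#'   (default 0.1).
#' @param tolerance_abs Absolute slack in metric units, applied only to
#'   `"covered_residues"` (default 15, one smoothing window).
#' @return The winning hypothesis, or `NULL` for empty input (protein
#'   reported non-repetitive).
#' @export
select_best_length <- function(hypotheses,
                               metric_name = c("covered_residues",
                                               "mean_coverage",
                                               "total_aligned_residues"),
                               tolerance = 0.1, tolerance_abs = 15) {
  metric_name <- match.arg(metric_name)
  if (!length(hypotheses)) return(NULL)
  val <- vapply(hypotheses, function(h) family_metric(h, metric_name),
                numeric(1))
  ninst <- vapply(hypotheses, function(h) length(h$instances), integer(1))
  ll <- vapply(hypotheses, function(h) h$l, integer(1))
  pr <- vapply(hypotheses, function(h) h$representative$start, integer(1))
  slack <- (1 - tolerance) * max(val)
  if (metric_name == "covered_residues")
    slack <- min(slack, max(val) - tolerance_abs)
  tied <- val >= slack
  o <- order(-tied, -ninst, ll, pr, -val)
  hypotheses[[o[1]]]
}

family_metric <- function(h, metric_name) {
  switch(metric_name,
    covered_residues = length(unique(unlist(lapply(h$instances, function(i)
      i$start:i$end)))),
    mean_coverage = mean(vapply(h$instances, `[[`, numeric(1), "coverage")),
    total_aligned_residues = sum(vapply(h$instances, function(i)
      i$end - i$start + 1L, integer(1))))
}
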