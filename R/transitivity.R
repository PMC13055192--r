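#' Enrich self-alignment traces by one round of transitivity
#'
#' If residues i and j are aligned in one trace and j and k in another, then
#' i and k are taken to be aligned in a composed ("transitive") trace.  Every
#' ordered pair of primary traces (including a trace with itself, which turns
#' a long period-P band into its 2P harmonic) is composed through all shared
#' coordinates, in both orientations of each trace; composition of monotone
#' coordinate maps guarantees the composites are valid monotone traces.
#' Composites are scored with [windowed_trace_score()] on the similarity
#' matrix and must pass the same `min_span`, significance and score filters
#' as primary traces.  Exactly one round is applied: composites are never
#' composed again.  Composites that duplicate an existing trace's pair set
#' exactly are dropped.
#'
#' @param traces List of primary [alignment_trace()]s (from
#'   [local_self_align()]).
#' @param sim The cosine self-similarity matrix the traces came from.
#' @param params [alignment_params()].
#' @param min_span Minimum pairs per composite (defaults to
#'   `params$min_span`).
#' @return List of traces: the primaries followed by accepted composites
#'   (origin `"transitive"`).
#' @export
apply_transitivity <- function(traces, sim, params = alignment_params(),
                               min_span = params$min_span) {
  if (!length(traces)) return(traces)
  m <- ncol(sim)
  offdiag <- sim[col(sim) != row(sim)]
  thr <- mean(offdiag) + params$sigma_factor * sd(offdiag)
  dexcl <- params$diagonal_exclusion

  orientations <- function(t) list(
    fwd = list(from = t$pairs[, 1], to = t$pairs[, 2]),
    rev = list(from = t$pairs[, 2], to = t$pairs[, 1])
  )
  maps <- lapply(traces, orientations)

  composites <- list()
  for (a in seq_along(traces)) {
    for (b in seq_along(traces)) {
      for (m1 in maps[[a]]) {
        for (m2 in maps[[b]]) {
          hit <- match(m1$to, m2$from)
          ok <- !is.na(hit)
          if (!any(ok)) next
          x <- m1$from[ok]
          z <- m2$to[hit[ok]]
          keep <- abs(x - z) > dexcl
          if (!any(keep)) next
          x <- x[keep]; z <- z[keep]
          # canonicalise to the upper triangle; a composite may cross the
          # diagonal, in which case sign-consistent runs become separate
          # candidates
          sgn <- sign(z - x)
          runs <- split(seq_along(x), cumsum(c(1L, diff(sgn) != 0)))
          for (r in runs) {
            xi <- x[r]; zi <- z[r]
            if (sgn[r[1]] < 0) { tmp <- xi; xi <- zi; zi <- tmp }
            if (length(xi) < min_span) next
            pairs <- cbind(xi, zi)
            vals <- sim[pairs]
            ms <- mean(vals)
            if (ms < thr) next
            sc <- mean(smooth_window(vals, params$window_length))
            if (sc < params$score_cutoff) next
            composites[[length(composites) + 1L]] <-
              alignment_trace(pairs, score = sc, origin = "transitive",
                              mean_sim = ms)
          }
        }
      }
    }
  }
  if (!length(composites)) return(traces)
  all_traces <- c(traces, composites)
  sig <- vapply(all_traces, function(t)
    paste(pair_keys(t$pairs, m), collapse = ","), character(1))
  all_traces[!duplicated(sig)]
}
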