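#' Global (end-to-end) alignment of two embeddings
#'
#' Needleman-Wunsch optimum on the cosine substitution matrix with a single
#' linear gap penalty.  Used to compare each extracted repeat instance to the
#' representative repeat.  Tie-breaking in the traceback is deterministic:
#' diagonal, then up (gap in the target), then left (gap in the query).
#'
#' @param a Query embedding ([residue_embedding()] or matrix).
#' @param b Target embedding with the same dimension D.
#' @param gap_extension Linear gap penalty (>= 0, default 0).
#' @return A `global_alignment`: list with `pairs` (two-column matrix of
#'   matched (query, target) positions, 1-based), `ops` (character vector
#'   over the full path: `"M"` match, `"I"` query residue against a target
#'   gap, `"D"` target position skipped), `score` (mean cosine over matched
#'   pairs; 0 when nothing is matched), `query_id`, `target_id`.
#' @export
global_align <- function(a, b, gap_extension = 0) {
  va <- emb_values(a); vb <- emb_values(b)
  if (nrow(va) < 1L || nrow(vb) < 1L)
    stop_input("global alignment requires non-empty embeddings")
  sim <- cosine_similarity(va, vb)
  n <- nrow(sim); m <- ncol(sim)
  H <- nw_fill(sim, gap_extension)
  eps <- 1e-12
  ops <- character(n + m)
  qi <- integer(n + m); ti <- integer(n + m)
  k <- 0L
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    h <- H[i + 1L, j + 1L]
    k <- k + 1L
    if (i > 0L && j > 0L &&
        abs(h - (H[i, j] + sim[i, j])) <= eps) {
      ops[k] <- "M"; qi[k] <- i; ti[k] <- j
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(h - (H[i, j + 1L] - gap_extension)) <= eps) {
      ops[k] <- "I"; qi[k] <- i; ti[k] <- 0L
      i <- i - 1L
    } else {
      ops[k] <- "D"; qi[k] <- 0L; ti[k] <- j
      j <- j - 1L
    }
  }
  ord <- rev(seq_len(k))
  ops <- ops[ord]; qi <- qi[ord]; ti <- ti[ord]
  mt <- ops == "M"
  pairs <- cbind(qi[mt], ti[mt])
  score <- if (nrow(pairs)) mean(sim[pairs]) else 0
  structure(list(pairs = pairs, ops = ops, score = score,
                 query_id = emb_id(a, "query"),
                 target_id = emb_id(b, "target")),
            class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> %s vs %s: %d matched pairs, score %.4f\n",
              x$query_id, x$target_id, nrow(x$pairs), x$score))
  invisible(x)
}
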