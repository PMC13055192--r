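#' Detect internal repeats in a protein embedding
#'
#' The full pipeline: local self-alignment of the embedding, one round of
#' transitive trace enrichment, accumulation into the score matrix, then an
#' iterative loop that (i) ranks candidate repeat lengths by off-diagonal
#' score sums, (ii) for each of the top candidates localises a
#' representative repeat, builds its weighted embedding and extracts
#' instances, (iii) reports the best hypothesis as a repeat family, and
#' (iv) masks the family's residues out of the score matrix before the next
#' round, so that additional repeat regions elsewhere in the protein can be
#' found.  The loop stops when no candidate lengths remain, no hypothesis
#' yields at least two instances, or `max_iterations` is reached.  The whole
#' procedure is deterministic given the embedding and parameters.
#'
#' @param e_fl A [residue_embedding()] (or numeric matrix).
#' @param params [alignment_params()].
#' @return A `detection_result`: list with `families` (each with
#'   `iteration`, `l`, `representative`, `instances`, `msa`, `metric`,
#'   `n_candidates`), `params`, `sequence_id`, `L`, `masked_spans` (per
#'   iteration), `n_traces` (primary and total after transitivity).
#'   [tidy()] gives the per-instance table, [glance()] a one-row summary,
#'   [autoplot()] the score-matrix dot plot.
#' @export
detect_repeats <- function(e_fl, params = alignment_params()) {
  E <- emb_values(e_fl)
  L <- nrow(E)
  sequence <- if (inherits(e_fl, "residue_embedding")) e_fl$sequence else NULL
  sim <- cosine_similarity(E)
  primary <- local_align_traces(sim, params, self = TRUE)
  traces <- apply_transitivity(primary, sim, params)
  M0 <- build_score_matrix(traces, L)

  families <- list()
  masked <- list()
  M <- M0
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    cands <- candidate_lengths(M)
    if (!nrow(cands)) break
    # hypothesis budget: top candidates by diagonal mass, and only those
    # carrying a non-negligible fraction of the strongest candidate's mass
    # (a period supported by a sliver of noise cannot be a real unit length,
    # but its profile would still leak perfect-looking instances)
    cands <- cands[cands$diagonal_sum >= 0.05 * cands$diagonal_sum[1], ,
                   drop = FALSE]
    cands <- head(cands, params$hypothesis_budget)
    masked_mat <- if (length(masked))
      do.call(rbind, lapply(masked, function(s) unname(as.matrix(s))))
    hyps <- list()
    for (k in seq_len(nrow(cands))) {
      l <- cands$d[k]
      if (l > L) next
      rep <- locate_representative(M, l)
      if (rep$window_score <= 0) next
      rep <- snap_to_lattice(M, l, rep)
      Er <- weighted_repeat_embedding(M, E, rep)
      instances <- extract_instances(Er, E, params,
                                     masked_spans = masked_mat)
      if (length(instances) < 2L) next
      hyps[[length(hyps) + 1L]] <- list(
        l = l, representative = rep, instances = instances,
        msa = assemble_msa(instances, l, sequence),
        metric = NA_real_)
    }
    best <- select_best_length(hyps, params$selection_metric)
    if (is.null(best)) break
    best$metric <- family_metric(best, params$selection_metric)
    best$iteration <- iter
    best$n_candidates <- nrow(cands)
    families[[length(families) + 1L]] <- best
    spans <- cbind(
      start = vapply(best$instances, `[[`, integer(1), "start"),
      end = vapply(best$instances, `[[`, integer(1), "end"))
    masked[[length(masked) + 1L]] <- spans
    M <- mask_score_matrix(M, spans)
  }

  structure(list(families = families, params = params,
                 sequence_id = emb_id(e_fl), L = L,
                 masked_spans = masked,
                 n_traces = c(primary = length(primary),
                              total = length(traces)),
                 score_matrix = M0),
            class = "detection_result")
}

# Re-anchor the representative window onto the repeat lattice.  The
# off-diagonal band of the score matrix is translation-invariant, so the
# window-score argmax fixes only the window's position relative to the
# repeat REGION, not its phase relative to the unit boundaries; a mid-unit
# window truncates the terminal instances and costs up to one unit of
# coverage.  The phase is visible only at the band endpoints: the d-band's
# first supported row marks the start of the first repeat unit, so the
# located start is shifted to the nearest lattice position of that anchor
# (kept only if the re-anchored window still carries positive score).
snap_to_lattice <- function(m, l, rep) {
  L <- nrow(m)
  band <- m[cbind(seq_len(L - l), seq_len(L - l) + l)]
  sup <- which(band > 0)
  if (!length(sup)) return(rep)
  a <- sup[1]
  c2 <- a + round((rep$start - a) / l) * l
  c2 <- max(1L, min(as.integer(c2), L - l + 1L))
  if (c2 == rep$start) return(rep)
  w <- window_weights(l)$weights
  cs <- colSums(m)
  ws <- sum(w * cs[c2:(c2 + l - 1L)])
  if (ws <= 0) return(rep)
  structure(list(start = c2, length = l, window_score = ws),
            class = "representative_repeat")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s (L = %d): %d repeat famil%s\n",
              x$sequence_id, x$L, length(x$families),
              if (length(x$families) == 1L) "y" else "ies"))
  for (f in x$families)
    cat(sprintf("  iter %d: unit length %d at %d, %d instances, %s = %.3f\n",
                f$iteration, f$l, f$representative$start,
                length(f$instances), x$params$selection_metric, f$metric))
  invisible(x)
}

#' Tidy a detection result into a per-instance tibble
#'
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return Tibble with one row per extracted repeat instance: `sequence_id`,
#'   `iteration`, `family`, `instance_index`, `start`, `end` (1-based
#'   inclusive), `length`, `score`, `coverage`, `unit_length`.
#' @export
tidy.detection_result <- function(x, ...) {
  if (!length(x$families))
    return(tibble(sequence_id = character(0), iteration = integer(0),
                  family = integer(0), instance_index = integer(0),
                  start = integer(0), end = integer(0), length = integer(0),
                  score = numeric(0), coverage = numeric(0),
                  unit_length = integer(0)))
  purrr::imap_dfr(x$families, function(f, fi) {
    tibble(sequence_id = x$sequence_id,
           iteration = f$iteration,
           family = as.integer(fi),
           instance_index = seq_along(f$instances),
           start = vapply(f$instances, `[[`, integer(1), "start"),
           end = vapply(f$instances, `[[`, integer(1), "end"),
           length = vapply(f$instances, function(i)
             i$end - i$start + 1L, integer(1)),
           score = vapply(f$instances, `[[`, numeric(1), "score"),
           coverage = vapply(f$instances, `[[`, numeric(1), "coverage"),
           unit_length = as.integer(f$l))
  })
}

#' One-row summary of a detection result
#'
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return Tibble with `sequence_id`, `L`, `n_families`, `n_instances`,
#'   `n_iterations`, `n_primary_traces`, `n_traces`, `top_unit_length`.
#' @export
glance.detection_result <- function(x, ...) {
  tibble(sequence_id = x$sequence_id, L = x$L,
         n_families = length(x$families),
         n_instances = sum(vapply(x$families, function(f)
           length(f$instances), integer(1))),
         n_iterations = if (length(x$families))
           max(vapply(x$families, `[[`, integer(1), "iteration")) else 0L,
         n_primary_traces = unname(x$n_traces["primary"]),
         n_traces = unname(x$n_traces["total"]),
         top_unit_length = if (length(x$families))
           as.integer(x$families[[1]]$l) else NA_integer_)
}

#' Dot-plot of the accumulated score matrix with detected instances
#'
#' @param object A `detection_result`.
#' @param ... Unused.
#' @return A ggplot object: the score matrix as a raster with instance spans
#'   marked along the diagonal.
#' @export
autoplot.detection_result <- function(object, ...) {
  M <- object$score_matrix
  df <- tibble(i = rep(seq_len(nrow(M)), times = ncol(M)),
               j = rep(seq_len(ncol(M)), each = nrow(M)),
               score = as.vector(M))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "midnightblue") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i", fill = "score",
                  title = object$sequence_id)
  inst <- tidy(object)
  if (nrow(inst))
    p <- p + ggplot2::annotate("rect",
      xmin = inst$start - 0.5, xmax = inst$end + 0.5,
      ymin = inst$start - 0.5, ymax = inst$end + 0.5,
      colour = "firebrick", fill = NA, linewidth = 0.3)
  p
}
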