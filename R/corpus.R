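# sample() semantics change for length-one x; always treat x as a set
resample_int <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

#' Generate a benchmark corpus of synthetic proteins
#'
#' Positives are planted-repeat proteins with unit length, copy number,
#' flank lengths and indel count drawn per protein from the given ranges
#' (defaults: units of 10-40 residues, 3-8 copies, within-unit cosine 0.9,
#' at most one indel per copy, flanks of 10-30 residues); negatives are
#' background-only proteins whose lengths match the positive length
#' distribution.  These defaults are the study conditions of the package's
#' own recovery and specificity benchmarks.
#'
#' @param n_pos,n_neg Number of positive / negative proteins.
#' @param seed Integer master seed; the corpus is a deterministic function
#'   of it.
#' @param unit_range,copies_range,flank_range Sampling ranges.
#' @param within_unit_cosine Within-unit similarity of the positives.
#' @param indel_max Maximum indels per copy (per-protein count drawn
#'   uniformly from 0..indel_max).
#' @param background_cosine_max Background similarity bound recorded in each
#'   generated protein's specification.
#' @param dim Embedding dimension.
#' @return List with `embeddings` (named list), `truths` (named list of
#'   [ground_truth()]s; negatives have no entry), and `info` (tibble of the
#'   drawn parameters per protein).
#' @export
make_detection_corpus <- function(n_pos, n_neg = 0L, seed = 1L,
                                  unit_range = c(10L, 40L),
                                  copies_range = c(3L, 8L),
                                  flank_range = c(10L, 30L),
                                  within_unit_cosine = 0.9,
                                  indel_max = 1L,
                                  background_cosine_max = 0.15,
                                  dim = 64L) {
  withr::with_seed(seed, {
    units <- resample_int(unit_range[1]:unit_range[2], n_pos)
    copies <- resample_int(copies_range[1]:copies_range[2], n_pos)
    fl <- resample_int(flank_range[1]:flank_range[2], n_pos)
    fr <- resample_int(flank_range[1]:flank_range[2], n_pos)
    indels <- if (indel_max > 0L)
      resample_int(0:indel_max, n_pos) else rep(0L, n_pos)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_pos + n_neg)
  })
  embeddings <- list(); truths <- list()
  info <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    id <- sprintf("pos%04d", i)
    spec <- synthetic_repeat_spec(units[i], copies[i],
                                  flank_left = fl[i], flank_right = fr[i],
                                  within_unit_cosine = within_unit_cosine,
                                  background_cosine_max = background_cosine_max,
                                  indel_per_copy = indels[i],
                                  dim = dim, seed = sub_seeds[i])
    g <- generate_synthetic(spec, id)
    embeddings[[id]] <- g$embedding
    truths[[id]] <- g$truth
    info[[i]] <- tibble(sequence_id = id, label = 1L,
                        unit_length = units[i], n_copies = copies[i],
                        indel_per_copy = indels[i], L = g$embedding$L)
  }
  pos_lengths <- if (n_pos) vapply(embeddings, `[[`, integer(1), "L")
  for (i in seq_len(n_neg)) {
    id <- sprintf("neg%04d", i)
    len <- if (n_pos) pos_lengths[[((i - 1L) %% n_pos) + 1L]] else {
      # no positives to match: draw a plausible protein length
      150L + (sub_seeds[n_pos + i] %% 151L)
    }
    embeddings[[id]] <- generate_background(len, dim,
                                            seed = sub_seeds[n_pos + i],
                                            sequence_id = id)
    info[[n_pos + i]] <- tibble(sequence_id = id, label = 0L,
                                unit_length = NA_integer_,
                                n_copies = NA_integer_,
                                indel_per_copy = NA_integer_,
                                L = len)
  }
  list(embeddings = embeddings, truths = truths,
       info = dplyr::bind_rows(info))
}
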