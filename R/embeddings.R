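#' Per-residue embedding matrix
#'
#' A `residue_embedding` holds the (L x D) matrix of per-residue vectors that
#' every stage of the repeat-detection pipeline consumes: one row per residue,
#' one column per embedding dimension.  Rows coming out of the synthetic
#' generator are unit-normalised; arbitrary providers may return unnormalised
#' rows, since all downstream scoring is by cosine similarity and therefore
#' scale-invariant.
#'
#' @param values Numeric matrix, L rows (residues) x D columns (dimensions).
#'   All entries must be finite and D >= 2.
#' @param sequence_id Identifier of the associated sequence.
#' @param sequence Optional amino-acid string of length L (used for MSA and
#'   FASTA output; `NULL` if unknown).
#'
#' @return An object of class `residue_embedding`: a list with elements
#'   `values`, `sequence_id`, `L`, `D` and `sequence`.
#' @export
residue_embedding <- function(values, sequence_id = "seq", sequence = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (nrow(values) < 1L)
    stop_input("embedding must have at least one row (L >= 1)")
  if (ncol(values) < 2L)
    stop_input("embedding dimension must be >= 2")
  if (!all(is.finite(values)))
    stop_input("embedding contains non-finite entries")
  if (!is.null(sequence)) {
    sequence <- as.character(sequence)
    if (nchar(sequence) != nrow(values))
      stop_input("`sequence` length must equal the number of embedding rows")
  }
  structure(
    list(values = unname(values), sequence_id = as.character(sequence_id),
         L = nrow(values), D = ncol(values), sequence = sequence),
    class = "residue_embedding"
  )
}

#' @export
print.residue_embedding <- function(x, ...) {
  cat(sprintf("<residue_embedding> %s: %d residues x %d dims\n",
              x$sequence_id, x$L, x$D))
  invisible(x)
}

#' @export
dim.residue_embedding <- function(x) c(x$L, x$D)

# Accept either a residue_embedding or a bare matrix.
emb_values <- function(e) {
  if (inherits(e, "residue_embedding")) return(e$values)
  if (is.matrix(e) && is.numeric(e)) return(unname(e))
  stop_input("expected a residue_embedding or a numeric matrix")
}

emb_id <- function(e, default = "seq") {
  if (inherits(e, "residue_embedding")) e$sequence_id else default
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

# ---------------------------------------------------------------------------
# Providers

#' Embedding providers
#'
#' A provider turns an amino-acid sequence into a `residue_embedding`.  Two
#' providers are built in:
#'
#' * `"synthetic"` -- a deterministic stand-in embedder: each residue vector
#'   is a seeded random basis vector for its amino-acid letter plus seeded
#'   positional noise, unit-normalised.  It carries no biological signal but
#'   satisfies the determinism and shape contracts, which is what offline
#'   tests need.
#' * `"custom"` -- wraps a user-supplied function `fun(sequence)` returning an
#'   L x D numeric matrix.  This is the adapter point for a real protein
#'   language model (typically giving D = 1024): any residue-wise
#'   embedder can be plugged in here.
#'
#' @param name Provider name, `"synthetic"` or `"custom"`.
#' @param dim Embedding dimension for the synthetic provider.
#' @param seed Integer seed controlling the synthetic provider (same sequence,
#'   provider and seed always give bitwise-identical output).
#' @param fun For `"custom"`: function of a sequence string returning a
#'   numeric matrix with one row per residue.
#' @return An `embedding_provider` object for use with [embed_sequence()].
#' @export
embedding_provider <- function(name = c("synthetic", "custom"),
                               dim = 64L, seed = 1L, fun = NULL) {
  if (!is.character(name) || length(name) != 1L)
    rlang::abort("provider `name` must be a single string",
                 class = "embrep_config_error")
  if (!name %in% c("synthetic", "custom"))
    rlang::abort(sprintf("unknown embedding provider '%s'", name),
                 class = "embrep_config_error")
  if (name == "custom" && !is.function(fun))
    rlang::abort("custom provider requires `fun`",
                 class = "embrep_config_error")
  structure(list(name = name, dim = as.integer(dim),
                 seed = as.integer(seed), fun = fun),
            class = "embedding_provider")
}

#' Embed an amino-acid sequence
#'
#' @param sequence Non-empty string over the 20 standard residues plus X.
#' @param provider An [embedding_provider()].
#' @param sequence_id Identifier attached to the result.
#' @return A [residue_embedding()] with one row per residue.
#' @export
embed_sequence <- function(sequence, provider, sequence_id = "seq") {
  if (!inherits(provider, "embedding_provider"))
    rlang::abort("`provider` must be an embedding_provider",
                 class = "embrep_config_error")
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop_input("`sequence` must be a non-empty string")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop_input(sprintf("sequence contains invalid residues: %s",
                       paste(bad, collapse = ", ")))
  values <- switch(provider$name,
    synthetic = synthetic_embed(chars, provider$dim, provider$seed),
    custom = {
      v <- provider$fun(sequence)
      if (!is.matrix(v) || nrow(v) != length(chars))
        stop_input("custom provider returned wrong shape")
      v
    })
  residue_embedding(values, sequence_id, sequence = sequence)
}

# Deterministic toy embedder: per-letter basis + positional noise, normalised.
synthetic_embed <- function(chars, dim, seed) {
  L <- length(chars)
  withr::with_seed(seed, {
    basis <- matrix(rnorm(length(AA_ALPHABET) * dim), ncol = dim,
                    dimnames = list(AA_ALPHABET, NULL))
    noise <- matrix(rnorm(L * dim), nrow = L)
    v <- basis[chars, , drop = FALSE] + 0.25 * noise
    normalize_rows(v)
  })
}

normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop_input(sprintf("zero-norm embedding row at index %d",
                       which(nrm == 0)[1]))
  m / nrm
}

# ---------------------------------------------------------------------------
# Synthetic planted-repeat generator

#' Specification of a synthetic planted-repeat protein
#'
#' The generator draws a base unit of `unit_length` random unit vectors and
#' emits `n_copies` noisy copies of it between unrelated flanks, giving direct
#' control over the similarity structure the detection pipeline consumes.
#' Each copy's row r is `normalize(sqrt(rho) * base_r + sqrt(1 - rho) * noise)`
#' with `rho = within_unit_cosine`, so the expected cosine between
#' corresponding positions of two distinct copies is close to
#' `within_unit_cosine`; flank rows are independent random unit vectors, whose
#' cosine against any repeat row stays below `background_cosine_max` on
#' average (at dimension D it concentrates around 0 with spread ~ 1/sqrt(D)).
#'
#' @param unit_length Integer >= 5, length of the repeated unit.
#' @param n_copies Integer >= 2, number of planted copies.
#' @param flank_left,flank_right Unrelated residues before/after the repeat
#'   region.
#' @param within_unit_cosine Target mean cosine between corresponding
#'   positions of different copies, in (0, 1].
#' @param background_cosine_max Upper bound for the mean unrelated-position
#'   cosine, in [0, 1); must be strictly below `within_unit_cosine`.
#' @param indel_per_copy Number of single-position insertions/deletions
#'   applied to each copy (at uniformly random interior offsets).
#' @param dim Embedding dimension D (default 64; the pipeline is
#'   dimension-agnostic, so tests use a dimension well below a real
#'   language model's 1024).
#' @param seed Integer seed; identical specs generate identical output.
#' @return A `synthetic_repeat_spec` list.
#' @export
synthetic_repeat_spec <- function(unit_length, n_copies,
                                  flank_left = 10L, flank_right = 10L,
                                  within_unit_cosine = 0.9,
                                  background_cosine_max = 0.15,
                                  indel_per_copy = 0L,
                                  dim = 64L, seed = 1L) {
  unit_length <- as.integer(unit_length); n_copies <- as.integer(n_copies)
  if (unit_length < 5L) stop_param("unit_length must be >= 5")
  if (n_copies < 2L) stop_param("n_copies must be >= 2")
  if (flank_left < 0L || flank_right < 0L) stop_param("flanks must be >= 0")
  if (!(within_unit_cosine > 0 && within_unit_cosine <= 1))
    stop_param("within_unit_cosine must be in (0, 1]")
  if (!(background_cosine_max >= 0 && background_cosine_max < 1))
    stop_param("background_cosine_max must be in [0, 1)")
  if (within_unit_cosine <= background_cosine_max)
    stop_param("infeasible geometry: within_unit_cosine must exceed background_cosine_max")
  if (indel_per_copy < 0L) stop_param("indel_per_copy must be >= 0")
  if (indel_per_copy >= unit_length - 2L)
    stop_param("indel_per_copy too large for unit_length")
  structure(list(unit_length = unit_length, n_copies = n_copies,
                 flank_left = as.integer(flank_left),
                 flank_right = as.integer(flank_right),
                 within_unit_cosine = within_unit_cosine,
                 background_cosine_max = background_cosine_max,
                 indel_per_copy = as.integer(indel_per_copy),
                 dim = as.integer(dim), seed = as.integer(seed)),
            class = "synthetic_repeat_spec")
}

stop_param <- function(msg) rlang::abort(msg, class = "embrep_param_error")

#' Generate a synthetic planted-repeat embedding with ground truth
#'
#' @param spec A [synthetic_repeat_spec()].
#' @param sequence_id Identifier for the generated protein.
#' @return A list with `embedding` (a [residue_embedding()], rows
#'   unit-normalised, with a random amino-acid sequence attached) and
#'   `truth` (a [ground_truth()] whose spans mark each planted copy).
#' @export
generate_synthetic <- function(spec, sequence_id = NULL) {
  stopifnot(inherits(spec, "synthetic_repeat_spec"))
  if (is.null(sequence_id))
    sequence_id <- sprintf("synth_u%d_c%d_s%d", spec$unit_length,
                           spec$n_copies, spec$seed)
  rho <- spec$within_unit_cosine
  withr::with_seed(spec$seed, {
    D <- spec$dim
    base <- normalize_rows(matrix(rnorm(spec$unit_length * D), ncol = D))
    copies <- vector("list", spec$n_copies)
    for (k in seq_len(spec$n_copies)) {
      noise <- normalize_rows(matrix(rnorm(spec$unit_length * D), ncol = D))
      cp <- normalize_rows(sqrt(rho) * base + sqrt(1 - rho) * noise)
      if (spec$indel_per_copy > 0L) {
        for (ev in seq_len(spec$indel_per_copy)) {
          n <- nrow(cp)
          pos <- sample(2:(n - 1), 1L)  # interior offset
          if (runif(1) < 0.5) {
            cp <- cp[-pos, , drop = FALSE]                       # deletion
          } else {
            ins <- normalize_rows(matrix(rnorm(D), ncol = D))    # insertion
            cp <- rbind(cp[1:(pos - 1), , drop = FALSE], ins,
                        cp[pos:n, , drop = FALSE])
          }
        }
      }
      copies[[k]] <- cp
    }
    flank_l <- if (spec$flank_left > 0L)
      normalize_rows(matrix(rnorm(spec$flank_left * D), ncol = D))
    flank_r <- if (spec$flank_right > 0L)
      normalize_rows(matrix(rnorm(spec$flank_right * D), ncol = D))
    values <- do.call(rbind, c(list(flank_l), copies, list(flank_r)))
    # ground-truth spans (1-based inclusive, in memory)
    starts <- integer(spec$n_copies); ends <- integer(spec$n_copies)
    at <- spec$flank_left
    for (k in seq_len(spec$n_copies)) {
      starts[k] <- at + 1L
      at <- at + nrow(copies[[k]])
      ends[k] <- at
    }
    sequence <- paste(sample(AA_ALPHABET[1:20], nrow(values), replace = TRUE),
                      collapse = "")
    list(
      embedding = residue_embedding(values, sequence_id, sequence = sequence),
      truth = ground_truth(sequence_id, starts, ends)
    )
  })
}

#' Generate a background-only embedding (no planted structure)
#'
#' Rows are independent random unit vectors, so all off-diagonal cosines
#' concentrate around zero with spread ~ 1/sqrt(dim); useful as a negative
#' control for specificity tests.
#'
#' @param length Number of residues.
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @param sequence_id Identifier.
#' @return A [residue_embedding()] with a random sequence attached.
#' @export
generate_background <- function(length, dim = 64L, seed = 1L,
                                sequence_id = NULL) {
  if (length < 1L) stop_param("length must be >= 1")
  if (is.null(sequence_id)) sequence_id <- sprintf("bg_L%d_s%d", length, seed)
  withr::with_seed(seed, {
    values <- normalize_rows(matrix(rnorm(length * dim), ncol = dim))
    sequence <- paste(sample(AA_ALPHABET[1:20], length, replace = TRUE),
                      collapse = "")
    residue_embedding(values, sequence_id, sequence = sequence)
  })
}

#' Ground-truth repeat-unit annotation
#'
#' Ordered, pairwise non-overlapping unit spans for one protein; spans are
#' held 1-based inclusive in memory and serialized 0-based half-open by
#' [write_ground_truth()].
#'
#' @param sequence_id Protein identifier.
#' @param start,end Integer vectors of unit spans (1-based inclusive).
#' @return A `ground_truth` object (tibble of units plus the id).
#' @export
ground_truth <- function(sequence_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop_input("start/end length mismatch")
  if (any(end < start)) stop_input("ground-truth span with end < start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1] <= end[-length(end)]))
    stop_input("ground-truth spans overlap")
  structure(list(sequence_id = as.character(sequence_id),
                 units = tibble(unit_index = seq_along(start),
                                start = start, end = end)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d units\n", x$sequence_id,
              nrow(x$units)))
  print(x$units)
  invisible(x)
}

#' Concatenate two planted-repeat constructions into a two-region protein
#'
#' Builds a single embedding containing two independent repeat regions (the
#' second spec's output appended after the first, including its flanks), the
#' multi-region situation that masking iterations are meant to resolve.
#'
#' @param spec1,spec2 Two [synthetic_repeat_spec()]s with equal `dim`.
#' @param sequence_id Identifier for the combined protein.
#' @return A list with `embedding`, `truth1`, `truth2` (unit spans of each
#'   region, in combined coordinates).
#' @export
generate_two_family <- function(spec1, spec2, sequence_id = "synth2fam") {
  if (spec1$dim != spec2$dim) stop_param("specs must share `dim`")
  g1 <- generate_synthetic(spec1, sequence_id)
  g2 <- generate_synthetic(spec2, sequence_id)
  off <- g1$embedding$L
  values <- rbind(g1$embedding$values, g2$embedding$values)
  sequence <- paste0(g1$embedding$sequence, g2$embedding$sequence)
  emb <- residue_embedding(values, sequence_id, sequence = sequence)
  t2 <- ground_truth(sequence_id, g2$truth$units$start + off,
                     g2$truth$units$end + off)
  list(embedding = emb, truth1 = g1$truth, truth2 = t2)
}
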