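# Readers and writers for every on-disk format the tool touches:
# embedding container (text TSV and binary dialects), ground-truth TSV
# (0-based half-open), repeat table TSV (1-based inclusive), A2M MSAs,
# FASTA, JSON reports.

#' Save a residue embedding to disk
#'
#' Two dialects of the same simple container: a text dialect (header line
#' `#embrep <id> <L> <D>` followed by L tab-separated rows, values printed
#' with 9 significant digits) and a binary dialect (magic `EMRB`, version,
#' id, dims, row-major doubles; lossless round-trip).  The dialect is chosen
#' from the file extension (`.bin` = binary, anything else text) unless
#' `format` is given.
#'
#' @param e A [residue_embedding()].
#' @param path Output path.
#' @param format `"auto"`, `"text"` or `"binary"`.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(e, path, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  v <- emb_values(e)
  if (format == "auto")
    format <- if (grepl("\\.bin$", path)) "binary" else "text"
  id <- emb_id(e)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#embrep\t%s\t%d\t%d", id, nrow(v), ncol(v)), con)
    rows <- apply(v, 1L, function(r)
      paste(formatC(r, digits = 9, format = "g"), collapse = "\t"))
    writeLines(rows, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("EMRB"), con)
    writeBin(1L, con, size = 4, endian = "little")
    idr <- charToRaw(id)
    writeBin(length(idr), con, size = 4, endian = "little")
    writeBin(idr, con)
    writeBin(c(nrow(v), ncol(v)), con, size = 4, endian = "little")
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
  }
  invisible(path)
}

fmt_err <- function(msg) rlang::abort(msg, class = "embrep_format_error")

#' Load a residue embedding from disk
#'
#' Detects the dialect from the leading bytes (binary files start with
#' `EMRB`).  Malformed files raise a format error naming the offending line
#' or byte offset.
#'
#' @param path File written by [write_embedding()].
#' @return A [residue_embedding()].
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) == 4L && rawToChar(magic) == "EMRB")
    read_embedding_binary(path)
  else
    read_embedding_text(path)
}

read_embedding_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#embrep"))
    fmt_err(sprintf("%s: line 1: missing '#embrep' header", path))
  hd <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hd) != 4L)
    fmt_err(sprintf("%s: line 1: header must have 4 fields", path))
  id <- hd[2]; L <- as.integer(hd[3]); D <- as.integer(hd[4])
  if (is.na(L) || is.na(D) || L < 1L || D < 2L)
    fmt_err(sprintf("%s: line 1: bad dimensions in header", path))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != L)
    fmt_err(sprintf("%s: header declares %d rows but payload has %d",
                    path, L, length(body)))
  rows <- lapply(seq_along(body), function(i) {
    r <- suppressWarnings(as.numeric(strsplit(body[i], "\t", fixed = TRUE)[[1]]))
    if (length(r) != D || anyNA(r))
      fmt_err(sprintf("%s: line %d: expected %d numeric values",
                      path, i + 1L, D))
    r
  })
  residue_embedding(do.call(rbind, rows), id)
}

read_embedding_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.size(path)
  rd_int <- function(n, at) {
    x <- readBin(con, "integer", n = n, size = 4, endian = "little")
    if (length(x) != n)
      fmt_err(sprintf("%s: truncated at byte offset %d", path, at))
    x
  }
  readBin(con, "raw", n = 4L)
  ver <- rd_int(1L, 4L)
  if (ver != 1L) fmt_err(sprintf("%s: byte offset 4: unknown version %d",
                                 path, ver))
  idlen <- rd_int(1L, 8L)
  if (idlen < 0L || idlen > sz)
    fmt_err(sprintf("%s: byte offset 8: bad id length", path))
  id <- rawToChar(readBin(con, "raw", n = idlen))
  dims <- rd_int(2L, 12L + idlen)
  L <- dims[1]; D <- dims[2]
  expected <- 20L + idlen + 8 * L * D
  if (sz != expected)
    fmt_err(sprintf(
      "%s: header dims (%d x %d) disagree with payload: expected %d bytes, file has %d",
      path, L, D, expected, sz))
  v <- readBin(con, "numeric", n = L * D, size = 8, endian = "little")
  residue_embedding(matrix(v, nrow = L, byrow = TRUE), id)
}

# ---------------------------------------------------------------------------
# Ground truth (BED-like TSV, 0-based half-open on disk)

#' Write / read ground-truth repeat annotations
#'
#' On disk the format is a BED-like TSV with columns `sequence_id`, `start`,
#' `end`, `unit_index`, 0-based half-open; in memory spans are 1-based
#' inclusive.
#'
#' @param truths A [ground_truth()] or list of them.
#' @param path TSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` a named list of [ground_truth()] objects.
#' @export
write_ground_truth <- function(truths, path) {
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  tab <- purrr::map_dfr(truths, function(gt)
    tibble(sequence_id = gt$sequence_id,
           start = gt$units$start - 1L,      # 0-based half-open on disk
           end = gt$units$end,
           unit_index = gt$units$unit_index))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sequence_id = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           unit_index = readr::col_integer()))
  by_id <- split(tab, tab$sequence_id)
  out <- lapply(by_id, function(d)
    ground_truth(d$sequence_id[1], d$start + 1L, d$end))
  out[unique(tab$sequence_id)]
}

# ---------------------------------------------------------------------------
# FASTA

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings for multi-record amino-acid FASTA.
#'
#' @param path FASTA path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop_input(sprintf("empty FASTA: %s", path))
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# A2M

#' Write a multiple alignment in A2M dialect
#'
#' Uppercase letters are matches to representative columns, lowercase letters
#' insert states, `-` deletions relative to the representative; rows may
#' therefore differ in length, as usual for A2M.
#'
#' @param msa Named character vector of A2M rows (as produced by
#'   [assemble_msa()]).
#' @param path Output path.
#' @export
write_a2m <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- names(msa)
  if (is.null(nm)) nm <- sprintf("row%d", seq_along(msa))
  for (i in seq_along(msa)) {
    writeLines(paste0(">", nm[i]), con)
    writeLines(msa[[i]], con)
  }
  invisible(path)
}

#' @rdname write_a2m
#' @return `read_a2m()` returns the named character vector back.
#' @export
read_a2m <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) fmt_err(sprintf("%s: no A2M records", path))
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vapply(seq_along(hdr), function(k)
    paste(lines[(hdr[k] + 1L):ends[k]], collapse = ""), character(1))
  names(out) <- sub("^>", "", lines[hdr])
  out
}

# ---------------------------------------------------------------------------
# Repeat table (user-facing, 1-based inclusive)

#' Write / read the per-protein repeat table
#'
#' Columns: `sequence_id`, `iteration`, `family`, `instance_index`, `start`,
#' `end` (1-based inclusive), `length`, `score`, `coverage`, `unit_length`.
#'
#' @param tab Tibble as produced by [tidy.detection_result()].
#' @param path TSV path.
#' @export
write_repeat_table <- function(tab, path) {
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_repeat_table
#' @export
read_repeat_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
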