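#' Read a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file, validates its structure, and
#' returns the records with sequences normalized to the RNA alphabet
#' (`T` becomes `U`). Record order is preserved.
#'
#' Parsing is delegated to [Biostrings::readBStringSet()] after a light
#' structural validation pass that reports the offending line for malformed
#' input (sequence data before the first header, or a record with an empty
#' sequence).
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) stop(sprintf("%s: empty FASTA file", path))
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[meaningful[1]]) {
    stop(sprintf("%s: line %d: sequence data before first '>' header",
                 path, meaningful[1]))
  }
  # a header immediately followed by another header (or EOF) is a
  # zero-length record
  header_lines <- which(is_header)
  for (h in header_lines) {
    after <- lines[seq.int(h + 1L, length.out = max(0L, length(lines) - h))]
    after_is_header <- c(startsWith(trimws(after), ">"), TRUE)
    seq_len_here <- sum(nchar(trimws(
      after[seq_len(which(after_is_header)[1] - 1L)])))
    if (seq_len_here == 0) {
      stop(sprintf("%s: line %d: record '%s' has an empty sequence",
                   path, h, sub("^>\\s*", "", trimws(lines[h]))))
    }
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids,
             sequence = normalize_rna(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' @param ids character vector of record ids.
#' @param sequences character vector of sequences (same length as `ids`).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path, width = 70) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records, preserving ids, sequences and per-base
#' qualities. Sequences are normalized to the RNA alphabet.
#'
#' @param path path to a FASTQ file.
#' @return a `data.frame` with columns `read_id`, `sequence`, `quality`.
#'   An empty file yields a zero-row data frame.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  n_lines <- length(readLines(path))
  if (n_lines == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n_lines %% 4 != 0) {
    stop(sprintf("%s: truncated FASTQ record (%d lines, not a multiple of 4)",
                 path, n_lines))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop(sprintf("%s: FASTQ parse error: %s",
                                     path, conditionMessage(e))))
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  seqs <- as.character(set)
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad) > 0) {
    stop(sprintf("%s: record %d ('%s'): sequence/quality length mismatch",
                 path, bad[1], names(set)[bad[1]]))
  }
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             sequence = normalize_rna(seqs),
             quality = quals,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default 3' adapter
#'
#' The TruSeq small-RNA 3' adapter, in the RNA alphabet.
#' @export
TRUSEQ_SMALL_RNA_ADAPTER <- "UGGAAUUCUCGGGUGCCAAGG"

#' Trim a 3' adapter from a read
#'
#' Removes the 3' adapter from a small-RNA read. A full occurrence of the
#' adapter inside the read (leftmost, allowing a mismatch fraction up to
#' `max_mismatch_frac`) takes precedence; otherwise the longest read suffix
#' matching a prefix of the adapter (length at least `min_overlap`,
#' mismatch fraction at most `max_mismatch_frac`) is removed. Reads with no
#' qualifying match are returned unchanged.
#'
#' @param sequence a single read sequence (character scalar).
#' @param adapter adapter sequence (default [TRUSEQ_SMALL_RNA_ADAPTER]).
#' @param min_overlap minimum adapter prefix length for a suffix match.
#' @param max_mismatch_frac maximum mismatching fraction of the aligned
#'   adapter bases, in `[0, 0.5)`.
#' @return a list with elements `sequence` (the trimmed insert) and
#'   `trimmed` (logical flag).
#' @export
trim_adapter <- function(sequence, adapter = TRUSEQ_SMALL_RNA_ADAPTER,
                         min_overlap = 6, max_mismatch_frac = 0.1) {
  if (length(adapter) != 1 || !nzchar(adapter)) stop("empty adapter")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 0.5) {
    stop("max_mismatch_frac must be in [0, 0.5)")
  }
  sequence <- normalize_rna(sequence)
  adapter <- normalize_rna(adapter)
  rc <- seq_chars(sequence)
  ac <- seq_chars(adapter)
  n <- length(rc)
  la <- length(ac)

  # leftmost full internal occurrence of the whole adapter
  if (n >= la) {
    allowed_full <- floor(max_mismatch_frac * la)
    for (s in seq_len(n - la + 1)) {
      mism <- sum(rc[s:(s + la - 1)] != ac)
      if (mism <= allowed_full) {
        return(list(sequence = substr(sequence, 1, s - 1), trimmed = TRUE))
      }
    }
  }
  # longest suffix of the read matching an adapter prefix
  max_k <- min(n, la - 1)
  if (max_k >= min_overlap) {
    for (k in max_k:min_overlap) {
      mism <- sum(rc[(n - k + 1):n] != ac[1:k])
      if (mism <= floor(max_mismatch_frac * k)) {
        return(list(sequence = substr(sequence, 1, n - k), trimmed = TRUE))
      }
    }
  }
  list(sequence = sequence, trimmed = FALSE)
}

#' Collapse identical reads into counted unique sequences
#'
#' Identical sequences are merged with summed counts. Sequences containing
#' `N`, or with a length outside `[min_length, max_length]`, are dropped;
#' the number dropped is reported in the `n_dropped` attribute of the
#' result. Output is sorted by decreasing count, then by sequence.
#'
#' @param sequences character vector of read sequences (one entry per read).
#' @param min_length,max_length inclusive length window; the default
#'   `[16, 28]` brackets miRNA-sized inserts.
#' @return a `data.frame` with columns `sequence` and `count`, carrying
#'   attribute `n_dropped` (number of reads removed by the N/length filter).
#' @export
collapse_reads <- function(sequences, min_length = 16, max_length = 28) {
  if (min_length > max_length) stop("min_length must be <= max_length")
  sequences <- normalize_rna(sequences)
  keep <- !grepl("N", sequences, fixed = TRUE) &
    nchar(sequences) >= min_length & nchar(sequences) <= max_length
  n_dropped <- sum(!keep)
  kept <- sequences[keep]
  if (length(kept) == 0) {
    out <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(kept)
    out <- data.frame(sequence = names(tab),
                      count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write collapsed reads as count-annotated FASTA
#'
#' Uses the common small-RNA interchange dialect `seqN_xCOUNT` for
#' headers (e.g. `seq1_x532`).
#'
#' @param collapsed a `data.frame` with columns `sequence`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  write_fasta(ids, collapsed$sequence, path)
}

#' Read count-annotated FASTA into a collapsed-read table
#'
#' Inverse of [write_collapsed_fasta()]: headers must end in `_xCOUNT`.
#'
#' @param path path to a collapsed FASTA file.
#' @return a `data.frame` with columns `sequence`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  fa <- read_fasta(path)
  m <- regmatches(fa$id, regexpr("_x([0-9]+)$", fa$id))
  if (length(m) != nrow(fa)) {
    stop(sprintf("%s: header without _xCOUNT suffix", path))
  }
  data.frame(sequence = fa$sequence,
             count = as.integer(sub("_x", "", m, fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Read/write a collapsed-read TSV (columns: sequence, count)
#'
#' @param path file path.
#' @return for the reader, a `data.frame` with columns `sequence`, `count`.
#' @export
read_collapsed_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(df))) {
    stop(sprintf("%s: expected columns 'sequence' and 'count'", path))
  }
  df$sequence <- normalize_rna(df$sequence)
  df$count <- as.integer(df$count)
  df[, c("sequence", "count")]
}

#' @rdname read_collapsed_tsv
#' @param collapsed a `data.frame` with columns `sequence`, `count`.
#' @export
write_collapsed_tsv <- function(collapsed, path) {
  utils::write.table(collapsed[, c("sequence", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
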