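#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' All sequences handled by the package are stored in the RNA alphabet:
#' `T` is rewritten to `U` on ingest (and lower case to upper case).
#' Characters outside `{A,C,G,U,N}` are rejected.
#'
#' @param x character vector of nucleotide sequences.
#' @param allow_n logical; keep `N` as a valid character (default `TRUE`).
#' @return character vector of the same length, RNA alphabet.
#' @export
normalize_rna <- function(x, allow_n = TRUE) {
  if (!is.character(x)) stop("sequences must be character")
  out <- chartr("acgtunT", "ACGUUNU", x)
  alphabet <- if (allow_n) "ACGUN" else "ACGU"
  bad <- grepl(sprintf("[^%s]", alphabet), out)
  if (any(bad)) {
    stop(sprintf("invalid nucleotide character in sequence %d: '%s'",
                 which(bad)[1], x[which(bad)[1]]))
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U/N).
#' @return character vector of reverse complements, RNA alphabet.
#' @export
reverse_complement_rna <- function(x) {
  x <- normalize_rna(x)
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# split a sequence into single characters (helper used throughout)
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
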