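#' Canonical seed-match site sequences for a 7-nt seed
#'
#' Given a miRNA seed (positions 2-8; element 1 of `seed7` is miRNA
#' position 2), returns the three canonical site sequences as they read
#' 5'-to-3' on the target mRNA:
#' \describe{
#'   \item{8mer}{reverse complement of miRNA positions 2-8, followed by A
#'     (the A opposite miRNA position 1).}
#'   \item{7mer-m8}{reverse complement of miRNA positions 2-8.}
#'   \item{7mer-A1}{reverse complement of miRNA positions 2-7, followed
#'     by A.}
#' }
#'
#' @param seed7 a 7-nt seed (A/C/G/U).
#' @return named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`.
#' @export
seed_sites <- function(seed7) {
  seed7 <- normalize_rna(seed7, allow_n = FALSE)
  if (length(seed7) != 1 || nchar(seed7) != 7) {
    stop("seed7 must be a single 7-nt sequence")
  }
  rc_2_8 <- reverse_complement_rna(seed7)
  rc_2_7 <- reverse_complement_rna(substr(seed7, 1, 6))
  c("8mer" = paste0(rc_2_8, "A"),
    "7mer-m8" = rc_2_8,
    "7mer-A1" = paste0(rc_2_7, "A"))
}

# all (possibly overlapping) 0-based start positions of `pattern` in `subject`
match_starts <- function(pattern, subject) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::RNAString(subject))
  BiocGenerics::start(hits) - 1L
}

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Reports every occurrence of the 8mer site, and each 7mer occurrence
#' not contained in an 8mer occurrence, with site-type precedence
#' 8mer > 7mer-m8 > 7mer-A1 (one site interval is reported once, with its
#' strongest type). Results are sorted by start. The UTR is scanned on
#' the given (mRNA sense) strand only.
#'
#' @param utr_id UTR identifier.
#' @param utr_sequence UTR sequence (T is normalized to U).
#' @param seed7 query seed (7 nt).
#' @param site_types which site types to report (default all three).
#' @return a `data.frame` with columns `utr_id`, `start` (0-based),
#'   `end` (half-open), `site_type`, `seed7`, `site_seq`.
#' @export
scan_utr <- function(utr_id, utr_sequence, seed7,
                     site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  utr_sequence <- normalize_rna(utr_sequence)
  empty <- data.frame(utr_id = character(), start = integer(),
                      end = integer(), site_type = character(),
                      seed7 = character(), site_seq = character(),
                      stringsAsFactors = FALSE)
  if (nchar(utr_sequence) < 7) return(empty)
  sites <- seed_sites(seed7)
  s8 <- match_starts(sites[["8mer"]], utr_sequence)
  rows <- list()
  if ("8mer" %in% site_types) {
    rows[["8mer"]] <- data.frame(start = s8, end = s8 + 8L,
                                 site_type = rep("8mer", length(s8)),
                                 stringsAsFactors = FALSE)
  }
  taken <- data.frame(start = s8, end = s8 + 8L)        # 8mer intervals
  for (tp in c("7mer-m8", "7mer-A1")) {
    if (!tp %in% site_types) next
    s7 <- match_starts(sites[[tp]], utr_sequence)
    # drop 7mers contained in an 8mer occurrence (8mer takes precedence)
    contained <- vapply(s7, function(p) {
      any(taken$start <= p & p + 7L <= taken$end)
    }, TRUE)
    s7 <- s7[!contained]
    # one interval, one type: a 7mer-A1 coinciding with a reported
    # 7mer-m8 interval (degenerate seeds) is suppressed
    if (tp == "7mer-A1" && !is.null(rows[["7mer-m8"]])) {
      s7 <- setdiff(s7, rows[["7mer-m8"]]$start)
    }
    rows[[tp]] <- data.frame(start = s7, end = s7 + 7L,
                             site_type = rep(tp, length(s7)),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$start, out$site_type), , drop = FALSE]
  data.frame(utr_id = utr_id, start = out$start, end = out$end,
             site_type = out$site_type, seed7 = normalize_rna(seed7),
             site_seq = substring(utr_sequence, out$start + 1L, out$end),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predicted target set of a seed over a collection of UTRs
#'
#' A UTR is a predicted target when it contains at least one seed-match
#' site of any requested type.
#'
#' @param utrs a `data.frame` with columns `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param seed7 query seed.
#' @param site_types site types that count as a match (default all).
#' @return character vector of target UTR ids (sorted, unique).
#' @export
predicted_targets <- function(utrs, seed7,
                              site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  if (nrow(utrs) == 0) stop("utrs must be non-empty")
  hit <- vapply(seq_len(nrow(utrs)), function(i) {
    nrow(scan_utr(utrs$id[i], utrs$sequence[i], seed7, site_types)) > 0
  }, TRUE)
  sort(unique(utrs$id[hit]))
}

#' Overlap statistics between two target sets
#'
#' @param set_a,set_b character vectors of ids.
#' @return list with `n_a`, `n_b`, `n_common`, `pct_of_a`, `pct_of_b`
#'   (percentages of each set that is shared; `NaN` for an empty set).
#' @export
overlap_counts <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_common <- length(intersect(set_a, set_b))
  list(n_a = length(set_a), n_b = length(set_b), n_common = n_common,
       pct_of_a = n_common / length(set_a) * 100,
       pct_of_b = n_common / length(set_b) * 100)
}

#' Scan many UTRs and bind the site tables
#'
#' @param utrs a `data.frame` with columns `id`, `sequence`.
#' @param seed7 query seed.
#' @param site_types site types to report.
#' @return row-bound [scan_utr()] results across all UTRs.
#' @export
scan_utr_set <- function(utrs, seed7,
                         site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  do.call(rbind, lapply(seq_len(nrow(utrs)), function(i) {
    scan_utr(utrs$id[i], utrs$sequence[i], seed7, site_types)
  }))
}
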