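#' Extract the 7-nt seed region of a miRNA sequence
#'
#' The seed is positions 2-8 (1-based) of the mature sequence, the primary
#' determinant of canonical target recognition. For the miR-101 reference
#' `UACAGUACUGUGAUAACUGAA` this is `ACAGUAC`; for its one-base-upstream
#' 5' variant `GUACAGUACUGUGAUAACUGA` it is `UACAGUA`.
#'
#' @param mature_sequence character vector of sequences, each >= 8 nt.
#' @return character vector of 7-mers.
#' @export
extract_seed <- function(mature_sequence) {
  mature_sequence <- normalize_rna(mature_sequence)
  if (any(nchar(mature_sequence) < 8)) {
    stop("sequence shorter than 8 nt has no seed region")
  }
  substr(mature_sequence, 2, 8)
}

#' Aggregate isomiR calls into a per-sample seed profile
#'
#' Counts are aggregated by observed 7-nt seed (so substitutions inside
#' nt 2-8 define new seed groups) and by mature locus;
#' `total_mirna_count` is the sum of all miRNA-assigned counts in the
#' sample and is the normalization denominator.
#'
#' @param calls a calls data frame from [call_sample()] (columns `seed7`,
#'   `mature_name`, `count`).
#' @param sample_id sample label.
#' @return an object of class `seed_profile`: list with `sample_id`,
#'   `seed_counts` (named numeric), `locus_counts` (named numeric),
#'   `total_mirna_count`. An empty input yields zero totals with
#'   attribute `empty = TRUE` and a warning.
#' @export
build_seed_profile <- function(calls, sample_id) {
  if (nrow(calls) == 0) {
    warning(sprintf("sample '%s': no miRNA-assigned reads", sample_id))
    out <- structure(list(sample_id = sample_id,
                          seed_counts = numeric(0),
                          locus_counts = numeric(0),
                          total_mirna_count = 0),
                     class = "seed_profile")
    attr(out, "empty") <- TRUE
    return(out)
  }
  seed_counts <- tapply(calls$count, calls$seed7, sum)
  locus_counts <- tapply(calls$count, calls$mature_name, sum)
  structure(list(sample_id = sample_id,
                 seed_counts = seed_counts[order(names(seed_counts))],
                 locus_counts = locus_counts[order(names(locus_counts))],
                 total_mirna_count = sum(calls$count)),
            class = "seed_profile")
}

#' @export
print.seed_profile <- function(x, ...) {
  cat(sprintf("<seed_profile> sample '%s': %d seeds, %d loci, %d miRNA reads\n",
              x$sample_id, length(x$seed_counts), length(x$locus_counts),
              x$total_mirna_count))
  invisible(x)
}

#' Normalized seed frequency (counts per million miRNA reads)
#'
#' `seed count / total miRNA-assigned count * 1e6`: the frequency of
#' sequences carrying a given seed relative to all sequences mapping onto
#' miRNAs, scaled to one million. A seed absent from the profile has
#' frequency 0.
#'
#' @param profile a `seed_profile`.
#' @param seed7 7-nt seed (character vector allowed).
#' @return per-million values.
#' @export
normalized_seed_frequency <- function(profile, seed7) {
  if (profile$total_mirna_count <= 0) {
    stop("profile has no miRNA-assigned reads; frequency undefined")
  }
  counts <- profile$seed_counts[seed7]
  counts[is.na(counts)] <- 0
  unname(counts / profile$total_mirna_count * 1e6)
}

#' Percentage of miRNA-mapped reads assigned to one locus
#'
#' @param profile a `seed_profile`.
#' @param mature_name locus name(s).
#' @return percentages of `total_mirna_count`.
#' @export
locus_abundance_percent <- function(profile, mature_name) {
  if (profile$total_mirna_count <= 0) {
    stop("profile has no miRNA-assigned reads; percentage undefined")
  }
  counts <- profile$locus_counts[mature_name]
  counts[is.na(counts)] <- 0
  unname(counts / profile$total_mirna_count * 100)
}

#' Ratio of two seed groups within a sample
#'
#' @param profile a `seed_profile`.
#' @param seed_a,seed_b the two 7-nt seeds; `seed_b` is the denominator.
#' @return `count(seed_a) / count(seed_b)`.
#' @export
seed_ratio <- function(profile, seed_a, seed_b) {
  b <- profile$seed_counts[seed_b]
  if (is.na(b) || b == 0) stop(sprintf("seed '%s' has zero count", seed_b))
  a <- profile$seed_counts[seed_a]
  if (is.na(a)) a <- 0
  unname(a / b)
}

#' Count-weighted variant-class proportions for one locus
#'
#' With `marginal = FALSE` (default) the composite variant labels (e.g.
#' `trim5+trim3`) partition the calls, so the proportions sum to 1, with
#' the total count over all calls taken as 100%. With `marginal = TRUE`
#' the marginal fraction of calls carrying each elementary label
#' (any-trim5, any-trim3, any-add3, any-substitution, reference) is
#' returned; these overlap and need not sum to 1.
#'
#' @param calls calls restricted to one mature locus (columns
#'   `variant_labels`, `count`).
#' @param marginal report marginal per-label fractions instead of the
#'   disjoint composite partition.
#' @return named numeric vector of fractions.
#' @export
variant_class_proportions <- function(calls, marginal = FALSE) {
  if (nrow(calls) == 0) stop("no calls: proportions undefined")
  if (length(unique(calls$mature_name)) > 1) {
    stop("calls span several loci; restrict to one mature locus")
  }
  total <- sum(calls$count)
  if (!marginal) {
    p <- tapply(calls$count, calls$variant_labels, sum) / total
    return(p[order(names(p))])
  }
  labels <- c("reference", "trim5", "trim3", "add3", "substitution")
  p <- vapply(labels, function(lab) {
    has <- vapply(strsplit(calls$variant_labels, "+", fixed = TRUE),
                  function(x) lab %in% x, TRUE)
    sum(calls$count[has]) / total
  }, 0)
  p
}

#' Filter a count table at a minimum-count threshold
#'
#' Retains rows whose `count` is strictly greater than `threshold`
#' (the conventional "more than 10 counts" reporting rule).
#'
#' @param table a data frame with a `count` column.
#' @param threshold keep rows with `count > threshold` (default 10).
#' @return the filtered table.
#' @export
filter_min_count <- function(table, threshold = 10) {
  if (threshold < 0) stop("threshold must be >= 0")
  out <- table[table$count > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a seed profile as tidy TSV tables
#'
#' @param profile a `seed_profile`.
#' @param seed_path,locus_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list with the two data frames.
#' @export
write_seed_profile <- function(profile, seed_path = NULL, locus_path = NULL) {
  seeds <- data.frame(
    sample_id = profile$sample_id,
    seed7 = names(profile$seed_counts),
    count = as.numeric(profile$seed_counts),
    normalized_per_million =
      normalized_seed_frequency(profile, names(profile$seed_counts)),
    stringsAsFactors = FALSE)
  loci <- data.frame(
    sample_id = profile$sample_id,
    mature_name = names(profile$locus_counts),
    count = as.numeric(profile$locus_counts),
    percent_of_mirna =
      locus_abundance_percent(profile, names(profile$locus_counts)),
    stringsAsFactors = FALSE)
  if (!is.null(seed_path)) {
    utils::write.table(seeds, seed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(locus_path)) {
    utils::write.table(loci, locus_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(seeds = seeds, loci = loci))
}
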