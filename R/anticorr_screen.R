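#' Per-sample expression profile of one miRNA variant
#'
#' Wraps the per-sample counts of a miRNA sequence variant together with
#' the log-transformed counts used for regression. Zero counts are made
#' finite with a pseudocount: `log(count + pseudocount)`.
#'
#' @param variant_id variant identifier (conventionally the full mature
#'   sequence).
#' @param counts non-negative per-sample counts, aligned with the
#'   expression samples.
#' @param pseudocount added before the log (default 1).
#' @return an object of class `mirna_age_profile`.
#' @export
mirna_age_profile <- function(variant_id, counts, pseudocount = 1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(variant_id = variant_id,
                 counts = counts,
                 log_counts = log(counts + pseudocount),
                 pseudocount = pseudocount),
            class = "mirna_age_profile")
}

#' Regress gene expression on miRNA log counts
#'
#' Ordinary least squares of expression on log counts, with the Pearson
#' product-moment correlation and the F-test p-value of the regression
#' (for a single predictor this equals the two-sided t-test p of the
#' slope).
#'
#' @param gene_expr numeric expression values.
#' @param mirna_log_counts numeric log counts, same length (>= 4).
#' @return list with `pearson_r`, `slope`, `p_value`.
#' @export
regress_pair <- function(gene_expr, mirna_log_counts) {
  if (length(gene_expr) != length(mirna_log_counts)) {
    stop("vectors must have equal length")
  }
  if (length(gene_expr) < 4) stop("need at least 4 paired observations")
  if (stats::var(gene_expr) == 0 || stats::var(mirna_log_counts) == 0) {
    stop("constant input vector: correlation undefined")
  }
  fit <- stats::lm(gene_expr ~ mirna_log_counts)
  fs <- summary(fit)$fstatistic
  list(pearson_r = stats::cor(gene_expr, mirna_log_counts),
       slope = unname(stats::coef(fit)[2]),
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
}

#' Anti-correlation screen over predicted targets of miRNA variants
#'
#' A gene is tested against a variant only when it is age-related and in
#' that variant's predicted-target set (seed match). For each gated pair,
#' expression is regressed on the variant's log counts; the pair passes
#' when the regression p-value is strictly below `alpha` and the Pearson
#' correlation is strictly below `r_max` (both thresholds strict,
#' defaults 0.01 and -0.70).
#'
#' @param age_genes a fit table (e.g. from [age_related_genes()]) whose
#'   `gene_id` rows are the age-related genes; a plain character vector
#'   of gene ids is also accepted.
#' @param targets_by_variant named list: variant id -> character vector
#'   of predicted target gene ids.
#' @param expr expression matrix with gene ids as rownames, columns
#'   aligned with the miRNA profiles.
#' @param profiles list of [mirna_age_profile()] objects (one per
#'   variant in `targets_by_variant`).
#' @param r_max pass threshold on Pearson r (default -0.70).
#' @param alpha pass threshold on the regression p (default 0.01).
#' @return a `data.frame` with one row per tested pair: `gene_id`,
#'   `variant_id`, `pearson_r`, `slope`, `p_value`, `seed_match`,
#'   `passes`; ordered by (`variant_id`, `gene_id`).
#' @export
screen_anticorrelation <- function(age_genes, targets_by_variant, expr,
                                   profiles, r_max = -0.70, alpha = 0.01) {
  gene_ids <- if (is.data.frame(age_genes)) age_genes$gene_id else age_genes
  profile_ids <- vapply(profiles, `[[`, "", "variant_id")
  missing_prof <- setdiff(names(targets_by_variant), profile_ids)
  if (length(missing_prof) > 0) {
    stop(sprintf("no miRNA profile for variant '%s'", missing_prof[1]))
  }
  rows <- list()
  for (variant in sort(names(targets_by_variant))) {
    prof <- profiles[[match(variant, profile_ids)]]
    if (length(prof$log_counts) != ncol(expr)) {
      stop(sprintf("profile '%s' not aligned with expression samples", variant))
    }
    tested <- sort(intersect(gene_ids, targets_by_variant[[variant]]))
    unresolvable <- setdiff(tested, rownames(expr))
    if (length(unresolvable) > 0) {
      stop(sprintf("gene '%s' not in the expression matrix", unresolvable[1]))
    }
    for (g in tested) {
      r <- regress_pair(expr[g, ], prof$log_counts)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, variant_id = variant,
        pearson_r = r$pearson_r, slope = r$slope, p_value = r$p_value,
        seed_match = TRUE,
        passes = r$p_value < alpha && r$pearson_r < r_max,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), variant_id = character(),
                      pearson_r = numeric(), slope = numeric(),
                      p_value = numeric(), seed_match = logical(),
                      passes = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample test of equal proportions (continuity-corrected)
#'
#' Compares `k1/n1` against `k2/n2` with the chi-square test of equal
#' proportions with Yates continuity correction, the default contract of
#' `prop.test` in R (which stands behind this function).
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `chi_square` and (two-sided) `p_value`.
#' @export
proportion_overlap_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("successes must lie in [0, n] for each group")
  }
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  list(chi_square = unname(ht$statistic), p_value = ht$p.value)
}
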