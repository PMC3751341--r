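#' The default family of age-trend models
#'
#' Eight nonlinear candidate trends for expression-versus-age profiles:
#' polynomials of degree 1-4 in age and of degree 1-4 in
#' `log2(age + offset)`. The log-age branch gives early-life changes
#' (days to a few years) leverage comparable to late-life decades. The
#' predictor is min-max scaled to `[0, 1]` before orthogonal-polynomial
#' expansion for numerical conditioning; F-test p-values are invariant to
#' this affine rescaling.
#'
#' The family is returned as a list so alternative bases can be
#' substituted: each member has a `name`, a predictor `transform`
#' (function of age in years) and a polynomial `degree`.
#'
#' @param log_offset offset (years) added to age before the log2
#'   transform, so ages of a few days stay finite; default 0.25.
#' @return list of 8 model descriptors.
#' @export
age_model_family <- function(log_offset = 0.25) {
  c(lapply(1:4, function(d) {
    list(name = sprintf("poly%d_age", d), transform = identity, degree = d)
  }),
  lapply(1:4, function(d) {
    list(name = sprintf("poly%d_logage", d),
         transform = function(a) log2(a + log_offset), degree = d)
  }))
}

# min-max scale to [0,1]; constant input is a rank-deficient design
scale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("ages are constant: rank-deficient design")
  (x - r[1]) / (r[2] - r[1])
}

#' Fit the age-trend model family to one expression profile
#'
#' Fits each candidate model by least squares and tests it against the
#' intercept-only model with the overall regression F-test. The best
#' model is the one with the smallest p-value (ties broken toward fewer
#' parameters); the gene is flagged age-related when that p-value is
#' strictly below `alpha`. No multiple-testing correction is applied, so
#' the flag rate on null genes exceeds `alpha` (the best-of-family
#' selection is a union over correlated tests); see the package vignette.
#'
#' @param expr_row numeric expression values, one per sample.
#' @param ages ages in years, aligned with `expr_row`.
#' @param family model family from [age_model_family()].
#' @param alpha flagging threshold on the best model's p-value
#'   (default 0.01, strict).
#' @return a list of class `age_model_fit`: `best_model`, `p_value`,
#'   `coefficients` (of the best model), `age_related`, and `p_values`
#'   (named vector across the family).
#' @export
fit_age_models <- function(expr_row, ages, family = age_model_family(),
                           alpha = 0.01) {
  if (length(expr_row) != length(ages)) {
    stop("expr_row and ages must have equal length")
  }
  if (any(!is.finite(ages)) || any(ages < 0)) {
    stop("ages must be finite and non-negative")
  }
  max_par <- max(vapply(family, `[[`, 0, "degree")) + 1
  if (length(ages) < max_par + 2) {
    stop("need at least 2 more samples than the largest model's parameters")
  }
  if (stats::var(expr_row) == 0) {
    # a flat profile carries no trend: every model explains nothing
    p <- stats::setNames(rep(1, length(family)),
                         vapply(family, `[[`, "", "name"))
    return(structure(list(best_model = family[[1]]$name, p_value = 1,
                          coefficients = c(`(Intercept)` = expr_row[1]),
                          age_related = FALSE, p_values = p),
                     class = "age_model_fit"))
  }
  fits <- lapply(family, function(m) {
    x <- scale01(m$transform(ages))
    stats::lm(expr_row ~ stats::poly(x, m$degree))
  })
  p_values <- vapply(fits, function(f) {
    fs <- summary(f)$fstatistic
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  }, 0)
  names(p_values) <- vapply(family, `[[`, "", "name")
  degrees <- vapply(family, `[[`, 0, "degree")
  best <- order(p_values, degrees)[1]
  structure(list(best_model = family[[best]]$name,
                 p_value = unname(p_values[best]),
                 coefficients = stats::coef(fits[[best]]),
                 age_related = unname(p_values[best]) < alpha,
                 p_values = p_values),
            class = "age_model_fit")
}

#' @export
print.age_model_fit <- function(x, ...) {
  cat(sprintf("<age_model_fit> best: %s, p = %.3g, age-related: %s\n",
              x$best_model, x$p_value, x$age_related))
  invisible(x)
}

#' Fit the age-model family to every gene of an expression matrix
#'
#' @param expr numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns aligned with `ages`.
#' @param ages ages in years, one per column.
#' @param family model family from [age_model_family()].
#' @param alpha flagging threshold (default 0.01).
#' @return a `data.frame` with one row per gene: `gene_id`, `best_model`,
#'   `p_value`, `age_related`.
#' @export
fit_age_models_matrix <- function(expr, ages, family = age_model_family(),
                                  alpha = 0.01) {
  if (ncol(expr) != length(ages)) stop("matrix columns must align with ages")
  if (nrow(expr) == 0) {
    return(data.frame(gene_id = character(), best_model = character(),
                      p_value = numeric(), age_related = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    f <- fit_age_models(expr[i, ], ages, family, alpha)
    data.frame(gene_id = rownames(expr)[i], best_model = f$best_model,
               p_value = f$p_value, age_related = f$age_related,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-related genes of an expression matrix
#'
#' Convenience wrapper around [fit_age_models_matrix()] returning only
#' the flagged subset (best-model F-test p strictly below `alpha`).
#'
#' @inheritParams fit_age_models_matrix
#' @return the flagged rows of the fit table.
#' @export
age_related_genes <- function(expr, ages, family = age_model_family(),
                              alpha = 0.01) {
  fits <- fit_age_models_matrix(expr, ages, family, alpha)
  out <- fits[fits$age_related, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix and its age series from TSV
#'
#' The expression TSV has gene ids in the first column and sample ids as
#' the header; the ages TSV has columns `sample_id`, `age_years`.
#'
#' @param expr_path,ages_path file paths.
#' @return list with `expr` (numeric matrix) and `ages` (data frame with
#'   `sample_id`, `age_years`), columns aligned.
#' @export
read_expression_dataset <- function(expr_path, ages_path) {
  expr_df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                               check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df[[1]]
  ages <- utils::read.delim(ages_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age_years") %in% names(ages))) {
    stop(sprintf("%s: expected columns sample_id, age_years", ages_path))
  }
  missing <- setdiff(colnames(expr), ages$sample_id)
  if (length(missing) > 0) {
    stop(sprintf("no age for sample '%s'", missing[1]))
  }
  ages <- ages[match(colnames(expr), ages$sample_id), ]
  if (any(!stats::complete.cases(expr))) stop("expression matrix has missing values")
  list(expr = expr, ages = ages)
}
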