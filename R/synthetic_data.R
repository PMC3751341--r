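#' miR-101 sequence constants
#'
#' The annotated mature human miR-101 sequence, its most abundant
#' one-base-upstream 5' variant, and their respective seed regions
#' (positions 2-8). The two seeds differ by a single-nucleotide register
#' shift, which is the dichotomy the whole analysis revolves around.
#'
#' @name mir101-constants
NULL

#' @rdname mir101-constants
#' @export
MIR101_MATURE <- "UACAGUACUGUGAUAACUGAA"

#' @rdname mir101-constants
#' @export
ISOMIR101_MATURE <- "GUACAGUACUGUGAUAACUGA"

#' @rdname mir101-constants
#' @export
MIR101_SEED <- "ACAGUAC"

#' @rdname mir101-constants
#' @export
ISOMIR101_SEED <- "UACAGUA"

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# every non-true window must sit >= min_dist mismatches away from every
# mature, so that a read within the variant bounds (<= 1 substitution)
# can only be decomposed at its true locus
reference_is_unambiguous <- function(references, min_dist = 4) {
  for (ref_m in references) {
    for (i in seq_len(nrow(ref_m$matures))) {
      m <- substr(ref_m$hairpin_seq, ref_m$matures$start[i] + 1,
                  ref_m$matures$end[i])
      lm <- nchar(m)
      for (ref_h in references) {
        hp <- ref_h$hairpin_seq
        for (o in 0:(nchar(hp) - lm)) {
          true_here <- identical(ref_h$hairpin_id, ref_m$hairpin_id) &&
            o == ref_m$matures$start[i]
          if (true_here) next
          if (hamming(m, substr(hp, o + 1, o + lm)) < min_dist) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Generate an unambiguous synthetic miRNA reference set
#'
#' Random hairpins with one embedded annotated mature each. The first
#' hairpin is miR-101-like: its mature is the annotated miR-101 sequence
#' [MIR101_MATURE], with the 5' flank ending in `CG` so that the
#' one-base-upstream 5' variant ([ISOMIR101_MATURE], starting with `G`)
#' is templated on the hairpin. Matures are kept at pairwise Hamming
#' distance >= 8 and, more stringently, every non-true hairpin window is
#' kept >= 4 mismatches from every mature, so that reads within the
#' variant bounds (up to 1 substitution) decompose at a unique locus.
#' This guard is what licenses exact label recovery on error-free
#' simulated reads.
#'
#' @param n_hairpins number of hairpins.
#' @param mature_length mature length for the random hairpins
#'   (default 21).
#' @param flank flanking sequence on each side of the mature
#'   (default 20; must be >= 4 to leave room for end shifts of +/- 3 plus
#'   addition discrimination).
#' @param rng_seed integer seed; the output is a deterministic function
#'   of the arguments.
#' @param include_mir101 embed the miR-101-like hairpin first
#'   (default `TRUE`).
#' @return list of [mirna_reference()] objects.
#' @export
make_reference <- function(n_hairpins, mature_length = 21, flank = 20,
                           rng_seed, include_mir101 = TRUE) {
  if (flank < 4) stop("flank must be >= 4 (room for end shifts + additions)")
  if (n_hairpins < 1) stop("n_hairpins must be >= 1")
  if (mature_length < 16) stop("mature_length must be >= 16")
  with_seed(rng_seed, {
    for (attempt in 1:300) {
      matures <- character(n_hairpins)
      if (include_mir101) matures[1] <- MIR101_MATURE
      ok <- TRUE
      for (i in seq_len(n_hairpins)) {
        if (include_mir101 && i == 1) next
        for (try_m in 1:50) {
          cand <- random_rna(mature_length)
          far <- all(vapply(seq_len(i - 1), function(j) {
            k <- min(nchar(cand), nchar(matures[j]))
            hamming(substr(cand, 1, k), substr(matures[j], 1, k)) >= 8
          }, TRUE)) || i == 1
          if (far) { matures[i] <- cand; break }
        }
        if (!nzchar(matures[i])) { ok <- FALSE; break }
      }
      if (!ok) next
      refs <- lapply(seq_len(n_hairpins), function(i) {
        f5 <- random_rna(flank)
        if (include_mir101 && i == 1) {
          # miR-101 precursor context: ...CG | UACAGUA...
          substr(f5, flank - 1, flank) <- "CG"
        }
        f3 <- random_rna(flank)
        hp <- paste0(f5, matures[i], f3)
        mirna_reference(
          hairpin_id = sprintf("synth-hp-%d", i),
          hairpin_seq = hp,
          matures = data.frame(
            mature_name = if (include_mir101 && i == 1) "miR-101"
                          else sprintf("synth-miR-%d", i),
            start = flank, end = flank + nchar(matures[i]),
            stringsAsFactors = FALSE))
      })
      if (reference_is_unambiguous(refs)) return(refs)
    }
    stop("could not generate an unambiguous reference with these parameters")
  })
}

#' Specification of a simulated isomiR read population
#'
#' @param t5_distribution named probability vector over 5' end offsets
#'   (names in -3..3; must sum to 1). The default puts 60% of reads at
#'   the annotated 5' end and ~30% one base upstream, mirroring a
#'   miR-101-like seed dichotomy.
#' @param t3_distribution named probability vector over templated 3' end
#'   offsets (names in -3..3; must sum to 1). 3' ends are more ragged
#'   than 5' ends by default.
#' @param addition_rate probability that a read carries non-templated 3'
#'   additions.
#' @param addition_base_probs base bias of added nucleotides (A/U-rich by
#'   default: A 0.4, U 0.4, G 0.1, C 0.1).
#' @param addition_length_probs probabilities of 1, 2, 3 added bases.
#' @param substitution_rate probability of one internal substitution per
#'   read.
#' @param sequencing_error_rate per-base error probability applied last.
#' @param depth total number of reads.
#' @param rng_seed integer seed.
#' @return an object of class `isomir_profile_spec`.
#' @export
isomir_profile_spec <- function(
    t5_distribution = c("-2" = 0.02, "-1" = 0.30, "0" = 0.60,
                        "1" = 0.05, "2" = 0.03),
    t3_distribution = c("-3" = 0.05, "-2" = 0.10, "-1" = 0.25,
                        "0" = 0.50, "1" = 0.10),
    addition_rate = 0.15,
    addition_base_probs = c(A = 0.4, U = 0.4, G = 0.1, C = 0.1),
    addition_length_probs = c(0.7, 0.2, 0.1),
    substitution_rate = 0.05,
    sequencing_error_rate = 0,
    depth = 10000,
    rng_seed = 1) {
  check_dist <- function(d, what, rng) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop(sprintf("%s must be non-negative and sum to 1", what))
    }
    offs <- as.integer(names(d))
    if (any(is.na(offs)) || any(abs(offs) > rng)) {
      stop(sprintf("%s offsets must be integers in [-%d, %d]", what, rng, rng))
    }
  }
  check_dist(t5_distribution, "t5_distribution", 3)
  check_dist(t3_distribution, "t3_distribution", 3)
  for (p in c(addition_rate, substitution_rate, sequencing_error_rate)) {
    if (p < 0 || p > 1) stop("rates must be probabilities in [0, 1]")
  }
  if (abs(sum(addition_base_probs) - 1) > 1e-9 ||
      abs(sum(addition_length_probs) - 1) > 1e-9) {
    stop("addition base/length probabilities must sum to 1")
  }
  if (depth < 1) stop("depth must be >= 1")
  structure(list(t5_distribution = t5_distribution,
                 t3_distribution = t3_distribution,
                 addition_rate = addition_rate,
                 addition_base_probs = addition_base_probs,
                 addition_length_probs = addition_length_probs,
                 substitution_rate = substitution_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 depth = depth, rng_seed = rng_seed),
            class = "isomir_profile_spec")
}

BASES <- c("A", "C", "G", "U")

#' Simulate small-RNA reads from a reference with planted truth
#'
#' Draws `depth` reads per the population spec: a locus, 5'/3' end
#' offsets, optional non-templated additions (each added base is redrawn
#' until it differs from the hairpin base it would occupy, so additions
#' remain non-templated by construction), an optional internal
#' substitution (placed >= 3 bases from either end so it cannot be
#' reinterpreted as an end variant), and finally uniform per-base
#' sequencing error. With `sequencing_error_rate = 0` on an unambiguous
#' reference, the caller recovers every planted label.
#'
#' @param references list of [mirna_reference()] objects (e.g. from
#'   [make_reference()]).
#' @param spec an [isomir_profile_spec()].
#' @param locus_weights optional per-locus sampling weights, one per
#'   mature across `references` (default uniform).
#' @return list with `reads` (collapsed `data.frame`: `sequence`,
#'   `count`) and `truth` (one row per simulated read: `sequence`,
#'   `hairpin_id`, `mature_name`, `t5`, `t3`, `additions`,
#'   `substitutions`, `n_seq_errors`).
#' @export
simulate_reads <- function(references, spec, locus_weights = NULL) {
  stopifnot(inherits(spec, "isomir_profile_spec"))
  loci <- do.call(rbind, lapply(references, function(r) {
    data.frame(hairpin_id = r$hairpin_id, mature_name = r$matures$mature_name,
               start = r$matures$start, end = r$matures$end,
               stringsAsFactors = FALSE)
  }))
  hp_seq <- stats::setNames(vapply(references, `[[`, "", "hairpin_seq"),
                            vapply(references, `[[`, "", "hairpin_id"))
  if (is.null(locus_weights)) locus_weights <- rep(1, nrow(loci))
  if (length(locus_weights) != nrow(loci)) {
    stop("locus_weights must have one entry per mature locus")
  }
  t5_offs <- as.integer(names(spec$t5_distribution))
  t3_offs <- as.integer(names(spec$t3_distribution))
  with_seed(spec$rng_seed, {
    n <- spec$depth
    li <- sample.int(nrow(loci), n, replace = TRUE, prob = locus_weights)
    t5 <- sample(t5_offs, n, replace = TRUE, prob = spec$t5_distribution)
    t3 <- sample(t3_offs, n, replace = TRUE, prob = spec$t3_distribution)
    rows <- vector("list", n)
    for (r in seq_len(n)) {
      hp <- hp_seq[[loci$hairpin_id[li[r]]]]
      start <- loci$start[li[r]] + t5[r]
      tend <- loci$end[li[r]] + t3[r]
      if (start < 0 || tend > nchar(hp)) {
        stop("reference flank too short for the requested end offsets")
      }
      core <- seq_chars(substr(hp, start + 1, tend))
      subs <- ""
      if (stats::runif(1) < spec$substitution_rate) {
        pos <- sample(4:(length(core) - 3), 1)      # 1-based, internal
        old <- core[pos]
        core[pos] <- sample(setdiff(BASES, old), 1)
        subs <- sprintf("%d:%s>%s", pos - 1L, old, core[pos])
      }
      additions <- ""
      if (stats::runif(1) < spec$addition_rate) {
        len <- sample(seq_along(spec$addition_length_probs), 1,
                      prob = spec$addition_length_probs)
        add <- character(len)
        for (j in seq_len(len)) {
          flank_base <- if (tend + j <= nchar(hp)) {
            substr(hp, tend + j, tend + j)
          } else NA_character_
          repeat {
            b <- sample(names(spec$addition_base_probs), 1,
                        prob = spec$addition_base_probs)
            if (is.na(flank_base) || b != flank_base) break
          }
          add[j] <- b
        }
        additions <- paste(add, collapse = "")
      }
      sequence <- paste0(paste(core, collapse = ""), additions)
      n_err <- 0L
      if (spec$sequencing_error_rate > 0) {
        sc <- seq_chars(sequence)
        hit <- which(stats::runif(length(sc)) < spec$sequencing_error_rate)
        for (p in hit) sc[p] <- sample(setdiff(BASES, sc[p]), 1)
        n_err <- length(hit)
        sequence <- paste(sc, collapse = "")
      }
      rows[[r]] <- data.frame(
        sequence = sequence,
        hairpin_id = loci$hairpin_id[li[r]],
        mature_name = loci$mature_name[li[r]],
        t5 = t5[r], t3 = t3[r], additions = additions,
        substitutions = subs, n_seq_errors = n_err,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(reads = collapse_reads(truth$sequence, min_length = 1,
                                max_length = 1000),
         truth = truth)
  })
}

#' Default 12-point age series (years)
#'
#' Twelve time points spanning early postnatal life (2 days) to old age
#' (98 years), the sampling structure of a lifespan brain expression
#' series.
#' @export
DEFAULT_AGES <- c(0.005, 0.5, 2, 5, 12, 20, 30, 40, 55, 70, 85, 98)

#' Simulate an age-series expression dataset with planted structure
#'
#' Generates (i) miRNA-variant count profiles over the age series with a
#' smooth log-scale age trend, (ii) age-related genes following randomly
#' drawn members of the trend-model family plus Gaussian noise, (iii)
#' pure-noise null genes, and (iv) planted anti-correlated
#' (variant, gene) pairs where gene expression is
#' `a + b * log(counts + 1) + noise` with `b < 0` and the noise standard
#' deviation calibrated so the population correlation equals `target_r`:
#' `sd(noise) = |b| * sd(x) * sqrt(1 / r^2 - 1)`.
#'
#' @param n_genes total number of genes.
#' @param ages age series in years (default [DEFAULT_AGES], 12 points).
#' @param frac_age_related fraction of the non-planted genes given an
#'   age trend.
#' @param trend_family model family used for the planted trends
#'   (default [age_model_family()]).
#' @param noise_sd residual standard deviation of trend and null genes
#'   (default 0.5; planted trend amplitude has standard deviation 1, so
#'   the default signal-to-noise ratio is 2).
#' @param planted_pairs `NULL`, or a `data.frame` with columns
#'   `variant_id`, `gene_id`, `target_r` (each `target_r` in (-1, 0));
#'   `gene_id` must name genes in `g1 ... g<n_genes>` format.
#' @param rng_seed integer seed.
#' @return list with `expr` (gene x sample matrix), `ages` (data frame
#'   `sample_id`, `age_years`), `profiles` (list of
#'   [mirna_age_profile()]), and `truth` (list with `gene_truth` and
#'   `planted_pairs` data frames).
#' @export
simulate_age_dataset <- function(n_genes, ages = DEFAULT_AGES,
                                 frac_age_related = 0.1,
                                 trend_family = age_model_family(),
                                 noise_sd = 0.5, planted_pairs = NULL,
                                 rng_seed = 1) {
  if (frac_age_related < 0 || frac_age_related > 1) {
    stop("frac_age_related must be in [0, 1]")
  }
  if (length(unique(ages)) < 8) stop("need at least 8 distinct ages")
  n <- length(ages)
  gene_ids <- sprintf("g%d", seq_len(n_genes))
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("variant_id", "gene_id", "target_r") %in%
                    names(planted_pairs)))
    if (any(abs(planted_pairs$target_r) >= 1 | planted_pairs$target_r == 0)) {
      stop("infeasible correlation: target_r must be in (-1, 0) or (0, 1)")
    }
    bad <- setdiff(planted_pairs$gene_id, gene_ids)
    if (length(bad) > 0) stop(sprintf("planted gene '%s' outside g1..g%d",
                                      bad[1], n_genes))
    if (anyDuplicated(planted_pairs$gene_id)) {
      stop("each planted gene may appear in one pair only")
    }
  }
  with_seed(rng_seed, {
    sample_ids <- sprintf("s%02d", seq_len(n))
    x_age <- scale01(log2(ages + 0.25))
    variants <- if (is.null(planted_pairs)) character(0) else
      sort(unique(planted_pairs$variant_id))
    profiles <- lapply(variants, function(v) {
      slope <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 2.0)
      lc <- log(2000) + slope * x_age + stats::rnorm(n, 0, 0.2)
      mirna_age_profile(v, pmax(0, round(exp(lc))))
    })
    names(profiles) <- variants

    planted_genes <- if (is.null(planted_pairs)) character(0) else
      planted_pairs$gene_id
    free <- setdiff(gene_ids, planted_genes)
    n_trend <- round(frac_age_related * length(free))
    trend_genes <- if (n_trend > 0) free[seq_len(n_trend)] else character(0)
    null_genes <- setdiff(free, trend_genes)

    expr <- matrix(NA_real_, n_genes, n,
                   dimnames = list(gene_ids, sample_ids))
    truth_rows <- list()
    for (g in null_genes) {
      expr[g, ] <- 7 + stats::rnorm(n, 0, noise_sd)
      truth_rows[[g]] <- data.frame(gene_id = g, class = "null",
                                    model = NA_character_,
                                    variant_id = NA_character_,
                                    target_r = NA_real_)
    }
    for (g in trend_genes) {
      m <- trend_family[[sample.int(length(trend_family), 1)]]
      x <- scale01(m$transform(ages))
      basis <- stats::poly(x, m$degree)
      trend <- drop(basis %*% stats::rnorm(m$degree))
      trend <- trend / stats::sd(trend)          # unit-amplitude signal
      expr[g, ] <- 7 + trend + stats::rnorm(n, 0, noise_sd)
      truth_rows[[g]] <- data.frame(gene_id = g, class = "age_related",
                                    model = m$name,
                                    variant_id = NA_character_,
                                    target_r = NA_real_)
    }
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        g <- planted_pairs$gene_id[i]
        v <- planted_pairs$variant_id[i]
        r <- planted_pairs$target_r[i]
        x <- profiles[[v]]$log_counts
        b <- sign(r)                              # b < 0 for target_r < 0
        sd_x <- sqrt(mean((x - mean(x))^2))
        sigma <- abs(b) * sd_x * sqrt(1 / r^2 - 1)
        expr[g, ] <- 7 + b * (x - mean(x)) + stats::rnorm(n, 0, sigma)
        truth_rows[[g]] <- data.frame(gene_id = g, class = "planted_pair",
                                      model = NA_character_,
                                      variant_id = v, target_r = r)
      }
    }
    gene_truth <- do.call(rbind, truth_rows[gene_ids])
    rownames(gene_truth) <- NULL
    list(expr = expr,
         ages = data.frame(sample_id = sample_ids, age_years = ages,
                           stringsAsFactors = FALSE),
         profiles = profiles,
         truth = list(gene_truth = gene_truth,
                      planted_pairs = planted_pairs))
  })
}
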