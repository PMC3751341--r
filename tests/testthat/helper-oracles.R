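# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain enumerations / closed forms, not calls into
# the package's own code paths.

# reverse complement by explicit character map
oracle_revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# exhaustive decomposition of a read against a reference: loops the full
# (mature, t5, t3, n_add) grid, derives the substitutions by direct
# comparison, and picks the minimum of (n_sub, n_add, |t5|+|t3|, t5, t3)
# with lexicographic mature_name as the final tie-break. Returns NULL when
# no decomposition exists within bounds.
oracle_decompose <- function(read, references, max_trim = 3, max_add = 3,
                             max_sub = 1) {
  best <- NULL
  for (ref in references) {
    hp <- ref$hairpin_seq
    for (i in seq_len(nrow(ref$matures))) {
      ms <- ref$matures$start[i]
      me <- ref$matures$end[i]
      for (t5 in -max_trim:max_trim) {
        for (t3 in -max_trim:max_trim) {
          for (n_add in 0:max_add) {
            core_start <- ms + t5
            core_end <- me + t3
            if (core_start < 0 || core_end > nchar(hp)) next
            core_len <- core_end - core_start
            if (core_len < 1) next
            if (core_len + n_add != nchar(read)) next
            core <- substr(hp, core_start + 1, core_end)
            rc <- strsplit(substr(read, 1, core_len), "")[[1]]
            cc <- strsplit(core, "")[[1]]
            mism <- which(rc != cc)
            if (length(mism) > max_sub) next
            cand <- list(
              mature_name = ref$matures$mature_name[i],
              t5 = t5, t3 = t3,
              additions = substr(read, core_len + 1, nchar(read)),
              substitutions = if (length(mism) == 0) "" else
                paste(sprintf("%d:%s>%s", mism - 1L, cc[mism], rc[mism]),
                      collapse = ";"),
              key = c(length(mism), n_add, abs(t5) + abs(t3), t5, t3))
            if (is.null(best)) { best <- cand; next }
            d <- cand$key - best$key
            nz <- which(d != 0)
            better <- (length(nz) > 0 && d[nz[1]] < 0) ||
              (length(nz) == 0 && cand$mature_name < best$mature_name)
            if (better) best <- cand
          }
        }
      }
    }
  }
  best
}

# sliding-window site scan: direct substring equality at every offset,
# then the documented precedence (8mer wins; one interval, one type)
oracle_scan <- function(utr, seed7) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  site8 <- paste0(rc(seed7), "A")
  site7m8 <- rc(seed7)
  site7a1 <- paste0(rc(substr(seed7, 1, 6)), "A")
  n <- nchar(utr)
  occ <- function(site) {
    w <- nchar(site)
    if (n < w) return(integer(0))
    starts <- 0:(n - w)
    starts[substring(utr, starts + 1, starts + w) == site]
  }
  s8 <- occ(site8)
  in8 <- function(p) any(s8 <= p & p + 7 <= s8 + 8)
  s7m8 <- Filter(function(p) !in8(p), occ(site7m8))
  s7a1 <- Filter(function(p) !in8(p) && !(p %in% s7m8), occ(site7a1))
  out <- rbind(
    if (length(s8)) data.frame(start = s8, type = "8mer"),
    if (length(s7m8)) data.frame(start = unlist(s7m8), type = "7mer-m8"),
    if (length(s7a1)) data.frame(start = unlist(s7a1), type = "7mer-A1"))
  if (is.null(out)) {
    return(data.frame(start = integer(0), type = character(0)))
  }
  out <- out[order(out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# continuity-corrected two-proportion chi-square, closed form (cell sums
# with the Yates term capped by the proportion difference)
oracle_prop_test <- function(k1, n1, k2, n2) {
  p_pool <- (k1 + k2) / (n1 + n2)
  O <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  E <- rbind(c(n1 * p_pool, n1 * (1 - p_pool)),
             c(n2 * p_pool, n2 * (1 - p_pool)))
  yates <- min(0.5, abs(k1 / n1 - k2 / n2) / (1 / n1 + 1 / n2))
  chi <- sum((abs(O - E) - yates)^2 / E)
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

# acceptance band for an observed count under Binomial(n, p)
binom_band <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a vector with exact sample correlation r against x (n >= 3)
vector_with_cor <- function(x, r, z = NULL) {
  if (is.null(z)) z <- rnorm(length(x))
  xs <- scale(x)[, 1]
  zr <- residuals(lm(z ~ x))
  zs <- zr / sd(zr)
  r * xs + sqrt(1 - r^2) * zs
}
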