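# Hand-built miR-101-like hairpin: the annotated mature is flanked so the
# one-base-upstream 5' variant (leading G) is templated, as on the real
# precursor.
hp101_reference <- function() {
  mirna_reference(
    hairpin_id = "hp101",
    hairpin_seq = paste0("GGCUACUGUCG", MIR101_MATURE, "AUGGGCUAAUC"),
    matures = data.frame(mature_name = "miR-101",
                         start = 11, end = 11 + nchar(MIR101_MATURE),
                         stringsAsFactors = FALSE))
}

# minimal calls table for seed_quant tests
make_calls <- function(seed7, mature_name, count,
                       variant_labels = "reference") {
  data.frame(sequence = NA_character_, count = count,
             mature_name = mature_name, seed7 = seed7,
             variant_labels = variant_labels, stringsAsFactors = FALSE)
}

# random single-mature reference without the ambiguity machinery, for
# fuzzing the decomposer against its oracle
random_reference <- function(hairpin_len = 80, mature_len = 21,
                             id = "fuzz-hp") {
  stopifnot(hairpin_len >= mature_len + 8)
  hp <- random_rna_string(hairpin_len)
  start <- sample(4:(hairpin_len - mature_len - 4), 1)
  mirna_reference(id, hp,
                  data.frame(mature_name = paste0(id, "-mat"),
                             start = start, end = start + mature_len,
                             stringsAsFactors = FALSE))
}

# a read derived from a reference by a random valid perturbation; may
# also return pure garbage (unassignable) when type == "random"
random_read <- function(ref, type = c("variant", "random")) {
  type <- match.arg(type)
  if (type == "random") return(random_rna_string(sample(16:28, 1)))
  m <- ref$matures
  repeat {
    t5 <- sample(-3:3, 1)
    t3 <- sample(-3:3, 1)
    start <- m$start[1] + t5
    end <- m$end[1] + t3
    if (start >= 0 && end <= nchar(ref$hairpin_seq) && end - start >= 10) break
  }
  core <- strsplit(substr(ref$hairpin_seq, start + 1, end), "")[[1]]
  if (runif(1) < 0.4) {
    pos <- sample(seq_along(core), 1)
    core[pos] <- sample(setdiff(c("A", "C", "G", "U"), core[pos]), 1)
  }
  additions <- if (runif(1) < 0.4) random_rna_string(sample(1:3, 1)) else ""
  paste0(paste(core, collapse = ""), additions)
}
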