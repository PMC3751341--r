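#!/usr/bin/env Rscript
# Stage 1: generate every input the pipeline consumes, with planted truth.
#
# Produces, under results/:
#   reference.fa / reference_matures.tsv  hairpins + mature annotations
#   reads_collapsed.tsv / .fa             one deep small-RNA sample
#   reads_truth.tsv                       per-read planted labels
#   utrs.fa                               3'UTR cohort (sites planted in
#                                         the UTRs of planted target genes)
#   expression.tsv / ages.tsv             12-point age series, 300 genes
#   mirna_counts.tsv                      per-sample counts of the two
#                                         miR-101-seed variants
#   gene_truth.tsv / planted_pairs.tsv    planted age/pair structure

suppressMessages(library(isomirage))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260930L
dir.create("results", showWarnings = FALSE)

message("Simulating with seed ", seed)

## small-RNA side -----------------------------------------------------------
refs <- make_reference(5, rng_seed = seed)
write_mirna_references(refs, "results/reference.fa",
                       "results/reference_matures.tsv")

spec <- isomir_profile_spec(depth = 20000, rng_seed = seed + 1L)
sim <- simulate_reads(refs, spec)
write_collapsed_tsv(sim$reads, "results/reads_collapsed.tsv")
write_collapsed_fasta(sim$reads, "results/reads_collapsed.fa")
write.table(sim$truth, "results/reads_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("  %d reads -> %d unique sequences",
                sum(sim$reads$count), nrow(sim$reads)))

## expression side ----------------------------------------------------------
n_genes <- 300
planted_pairs <- data.frame(
  variant_id = rep(c(MIR101_MATURE, ISOMIR101_MATURE), each = 6),
  gene_id = sprintf("g%d", 1:12),
  target_r = rep(c(-0.9, -0.85), each = 6),
  stringsAsFactors = FALSE)
ds <- simulate_age_dataset(n_genes, frac_age_related = 0.1,
                           planted_pairs = planted_pairs,
                           rng_seed = seed + 2L)
write.table(data.frame(gene_id = rownames(ds$expr), ds$expr,
                       check.names = FALSE),
            "results/expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ds$ages, "results/ages.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
counts <- do.call(rbind, lapply(ds$profiles, function(p) {
  data.frame(variant_id = p$variant_id, sample_id = ds$ages$sample_id,
             count = p$counts, stringsAsFactors = FALSE)
}))
write.table(counts, "results/mirna_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ds$truth$gene_truth, "results/gene_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(planted_pairs, "results/planted_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## UTR cohort ---------------------------------------------------------------
# one 500-nt UTR per gene; the UTRs of planted pair genes carry an 8mer
# site of their variant's seed so the screen's gating has true positives
set.seed(seed + 3L)
rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
utr_seq <- vapply(seq_len(n_genes), function(i) rna(500), "")
names(utr_seq) <- rownames(ds$expr)
seed_of <- c(setNames(MIR101_SEED, MIR101_MATURE),
             setNames(ISOMIR101_SEED, ISOMIR101_MATURE))
for (i in seq_len(nrow(planted_pairs))) {
  g <- planted_pairs$gene_id[i]
  site <- seed_sites(seed_of[[planted_pairs$variant_id[i]]])[["8mer"]]
  pos <- sample(480, 1)
  substr(utr_seq[g], pos, pos + 7) <- site
}
write_fasta(names(utr_seq), utr_seq, "results/utrs.fa")
message(sprintf("  %d genes, %d planted pairs, %d UTRs written",
                n_genes, nrow(planted_pairs), length(utr_seq)))
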