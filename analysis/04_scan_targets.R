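#!/usr/bin/env Rscript
# Stage 4: seed-match target prediction for the two miR-101 seeds over the
# UTR cohort. Writes results/target_sites.tsv and results/target_sets.tsv;
# reports the predicted-target overlap between the two seeds.

suppressMessages(library(isomirage))

utrs <- read_fasta("results/utrs.fa")
seeds <- c(setNames(MIR101_SEED, MIR101_MATURE),
           setNames(ISOMIR101_SEED, ISOMIR101_MATURE))

sites <- do.call(rbind, lapply(seeds, function(s) scan_utr_set(utrs, s)))
write.table(sites, "results/target_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sets <- lapply(seeds, function(s) predicted_targets(utrs, s))
write.table(do.call(rbind, lapply(names(sets), function(v) {
  if (length(sets[[v]]) == 0) return(NULL)
  data.frame(variant_id = v, utr_id = sets[[v]], stringsAsFactors = FALSE)
})), "results/target_sets.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

ov <- overlap_counts(sets[[1]], sets[[2]])
message(sprintf("Predicted targets: %d (reference seed), %d (5'-variant seed)",
                ov$n_a, ov$n_b))
message(sprintf("Common: %d (%.1f%% of reference, %.1f%% of variant set)",
                ov$n_common, ov$pct_of_a, ov$pct_of_b))
pt <- proportion_overlap_test(ov$n_common, ov$n_a, ov$n_common, ov$n_b)
message(sprintf("Equality of overlap proportions: chi^2 = %.3f, p = %.3g",
                pt$chi_square, pt$p_value))
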