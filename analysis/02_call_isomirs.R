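#!/usr/bin/env Rscript
# Stage 2: assign simulated reads to hairpin loci and classify variants.
# Writes results/isomirs.tsv and reports label recovery against the truth.

suppressMessages(library(isomirage))

refs <- read_mirna_references("results/reference.fa",
                              "results/reference_matures.tsv")
reads <- read_collapsed_tsv("results/reads_collapsed.tsv")
res <- call_sample(reads, refs)
write_isomir_table(res$calls, "results/isomirs.tsv")
message(sprintf("Called %d unique sequences (%d reads); %d unassigned",
                nrow(res$calls), sum(res$calls$count), nrow(res$unassigned)))

truth <- read.delim("results/reads_truth.tsv",
                    colClasses = c(additions = "character",
                                   substitutions = "character"))
truth$additions[is.na(truth$additions)] <- ""
truth$substitutions[is.na(truth$substitutions)] <- ""
tr <- unique(truth[, c("sequence", "mature_name", "t5", "t3",
                       "additions", "substitutions")])
m <- merge(res$calls, tr, by = "sequence", suffixes = c(".call", ".true"))
ok <- with(m, mature_name.call == mature_name.true & t5.call == t5.true &
             t3.call == t3.true & additions.call == additions.true &
             substitutions.call == substitutions.true)
message(sprintf("Label recovery: %d / %d reads (%.2f%%)",
                sum(m$count[ok]), sum(m$count),
                100 * sum(m$count[ok]) / sum(m$count)))
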