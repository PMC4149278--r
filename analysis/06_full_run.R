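#!/usr/bin/env Rscript
# Stage 6 — single-call end-to-end run: the same screen as stages 1-5 driven
# through run_pipeline(), which realizes each genome once and shares it
# between the unblot and PCR arms, then writes the joined per-locus report
# (predicted size + PCR carrier counts + band presence counts + chi-square).
#
# Self-contained; only needs a seed.

library(ervscreen)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

report <- run_pipeline(default_config(seed = seed))
write_run_report(report, "results/full_run")
print(report)

lt <- report$locus_table
inwin <- !lt$undetectable & lt$size >= 500 & lt$size <= 10000
concordant <- sum(lt$band_case_pos[inwin] == lt$case_pos[inwin] &
                    lt$band_ctrl_pos[inwin] == lt$ctrl_pos[inwin], na.rm = TRUE)
cat(sprintf("PCR/unblot concordance: %d of %d in-window loci\n",
            concordant, sum(inwin)))
cat("wrote results/full_run/\n")
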