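#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study materials: a reference panel (host
# mini-genome + proviral element family with an identity gradient to the
# youngest element) and a 25 + 25 diploid case-control cohort with known
# per-locus allele frequencies. Writes the panel and genotype ledger under
# results/.
#
# Run from the repository root: Rscript analysis/01_simulate.R [seed]

library(ervscreen)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

panel <- make_reference_panel(n_elements = 20, n_loci = 12, n_recent = 10,
                              seed = derive_seed(seed, 1L))
write_panel(panel, "results/panel")
cat(sprintf("panel: %d elements (identity %.1f-%.1f%%), %d loci\n",
            nrow(panel$elements), min(panel$elements$identity),
            max(panel$elements$identity), nrow(panel$loci)))

# moderate proviral allele frequencies, matching the mostly-common loci of a
# real screen, with two deliberately rarer insertions
freq <- data.frame(locus_id = panel$loci$locus_id,
                   f_case = rep(c(0.5, 0.3, 0.1, 0.7), 3),
                   f_control = rep(c(0.5, 0.3, 0.1, 0.7), 3))
cohort <- simulate_cohort(panel, n_cases = 25, n_controls = 25, freq = freq,
                          snp_rate = 0, seed = derive_seed(seed, 2L))
write_genotypes(cohort, "results/genotypes.tsv")
write_tsv(cohort$carrier_truth, "results/carrier_truth.tsv")
write_tsv(freq, "results/allele_frequencies.tsv")

tr <- cohort$carrier_truth
cat(sprintf("cohort: %d individuals; carrier counts per locus range %d-%d\n",
            nrow(cohort$individuals), min(tr$carriers), max(tr$carriers)))
cat("wrote results/panel/, results/genotypes.tsv, results/carrier_truth.tsv\n")
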