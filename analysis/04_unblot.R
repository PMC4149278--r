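#!/usr/bin/env Rscript
# Stage 4 — virtual unblot: realize each individual's diploid regional
# genomes, digest them, call probe-positive bands per lane, collate bands
# across the cohort into size clusters, and classify every cluster as a known
# locus, ambiguous, or a novel polymorphic band.
#
# Requires stages 1-3 (results/panel, results/genotypes.tsv,
# results/predicted_fragments.tsv, results/probe.fasta). Seed argument must
# match stage 1 so the realized genomes correspond to the simulated cohort.

library(ervscreen)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

panel <- read_panel("results/panel")
freq <- read_tsv("results/allele_frequencies.tsv")
cohort <- simulate_cohort(panel, 25, 25, freq = freq, snp_rate = 0,
                          seed = derive_seed(seed, 2L))
probe <- read_fasta("results/probe.fasta")[[1]]
fragments <- read_tsv("results/predicted_fragments.tsv")
enz <- default_enzymes()$BsrI

set.seed(derive_seed(seed, 3L))
patterns <- lapply(seq_len(nrow(cohort$individuals)), function(i) {
  id <- cohort$individuals$id[i]
  digest_pattern(realize_genome(id, cohort, panel), enz, probe, id = id,
                 group = cohort$individuals$group[i])
})
bands_per_lane <- vapply(patterns, function(p) length(p$sizes), integer(1))
cat(sprintf("virtual unblot: %d lanes, %d-%d bands per lane\n",
            length(patterns), min(bands_per_lane), max(bands_per_lane)))

collated <- collate_bands(patterns, rel_tolerance = 0.02)
pcr_calls <- genotype_cohort(cohort, panel)
classified <- classify_clusters(collated, fragments,
                                pcr_carriers = pcr_calls[, c("id", "locus_id",
                                                             "carrier")])
freq_table <- cluster_frequencies(classified, cohort$individuals)
write_tsv(freq_table, "results/band_clusters.tsv")
write_tsv(classified$members, "results/band_members.tsv")
write_tsv(pcr_calls, "results/pcr_calls.tsv")

tab <- table(freq_table$classification)
cat("cluster classification:",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
cat("wrote results/band_clusters.tsv, results/band_members.tsv, results/pcr_calls.tsv\n")
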