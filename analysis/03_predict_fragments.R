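#!/usr/bin/env Rscript
# Stage 3 — virtual digest: predict, for every locus, the size of the
# probe-containing junction fragment (nearest host cut 5' of the insertion to
# the first element cut 3' of the probe). This is the reference ladder the
# unblot bands are interpreted against.
#
# Requires results/panel and results/probe.fasta.

library(ervscreen)

panel <- read_panel("results/panel")
cand <- read_tsv("results/probe_candidates.tsv")
probe_region <- c(cand$start[1], cand$end[1])

fragments <- predict_all_fragments(panel, default_enzymes()$BsrI,
                                   probe_region = probe_region)
write_tsv(fragments, "results/predicted_fragments.tsv")

detectable <- !fragments$undetectable &
  fragments$size >= 500 & fragments$size <= 10000
cat(sprintf("predicted junction fragments: %d loci, %d within the detectable
  window (%.0f-%.0f bp)\n", nrow(fragments), sum(detectable),
            min(fragments$size, na.rm = TRUE), max(fragments$size, na.rm = TRUE)))
print(fragments[, c("locus_id", "allele", "size", "upstream_cut",
                    "downstream_cut")])
cat("wrote results/predicted_fragments.tsv\n")
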