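#!/usr/bin/env Rscript
# Stage 2 — probe selection and enzyme screening on the simulated panel.
# Ranks elements by identity to the reference, scans for a short window
# conserved among the recent integrations but diverged in older elements and
# proximal to (but outside) the 5'LTR, then confirms the digest enzyme cuts
# the element body without cutting the 5'LTR and maps all probe hits across
# the element family.
#
# Requires results/panel from analysis/01_simulate.R.

library(ervscreen)

panel <- read_panel("results/panel")
enz <- default_enzymes()$BsrI
ref_id <- panel$elements$element_id[1]

ranked <- rank_by_identity(panel$element_seqs, ref_id)
write_tsv(ranked, "results/identity_ranking.tsv")
cat(sprintf("identity ranking: %s first at %.0f%%, oldest at %.1f%%\n",
            ranked$element_id[1], ranked$identity[1], min(ranked$identity)))

cand <- find_conserved_window(panel$element_seqs, ref_id,
                              ltr5_end = panel$elements$ltr5_end[1],
                              recent_k = 10, L = 32, max_ltr_distance = 2000)
write_tsv(cand[seq_len(min(20, nrow(cand))), ], "results/probe_candidates.tsv")
probe <- cand$probe[1]
cat(sprintf("top probe window: columns %d-%d, %d bp past the 5'LTR, recent
  conservation %.3f, max identity in older elements %.3f\n",
            cand$start[1], cand$end[1], cand$distance[1],
            cand$recent_score[1], cand$older_max_identity[1]))

# probe specificity across the element family (<= 2 substitutions)
hits <- probe_hits(probe, panel$element_seqs, max_mismatch = 2)
cat(sprintf("probe hits in the element family: %d (of %d elements), %d exact\n",
            nrow(hits), nrow(panel$elements), sum(hits$mismatches == 0)))
write_tsv(hits, "results/probe_hits.tsv")

# enzyme screen: >= 1 cut in the element body, none in the 5'LTR
ok <- select_enzymes(panel$element_seqs[[ref_id]],
                     c(panel$elements$ltr5_start[1], panel$elements$ltr5_end[1]),
                     default_enzymes())
cat("enzymes passing the body-not-5'LTR rule:",
    paste(names(ok), collapse = ", "), "\n")
stopifnot("BsrI" %in% names(ok))

writeLines(c(">probe", probe), "results/probe.fasta")
cat("wrote results/probe.fasta, results/probe_candidates.tsv, results/probe_hits.tsv\n")
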