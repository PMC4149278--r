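# ervscreen

Case–control screening of insertionally polymorphic endogenous retroviruses
(ERVs), built around the youngest human ERV group, HERV-K(HML-2).

## The problem

A retroviral infection of the germ line leaves a provirus that is inherited
like any other allele. The HML-2 group contains the only human proviruses
still polymorphic in insertion site: at a given locus an individual may carry
the full **provirus**, a **solo LTR** (the recombination product that deletes
the internal sequence), or the ancestral **pre-integration (empty) site** —
and some loci segregate a **tandem** provirus (two bodies sharing one central
LTR). Because such structural alleles are invisible to SNP arrays, testing
whether any of them is enriched in a disease group needs dedicated machinery:

1. **Probe design** — rank a family of proviral sequences by nucleotide
   identity to a designated youngest element and scan for a short window
   (default 32 bp) that is conserved among the recent integrations, diverged
   in the older ones, and proximal to but outside the 5'LTR
   (`rank_by_identity()`, `find_conserved_window()`, `probe_hits()`).
2. **Virtual digest** — choose a restriction enzyme that cuts the provirus
   body but never its 5'LTR (`select_enzymes()`; BsrI, recognition `ACTGG`,
   cutting 1 nt downstream, is the shipped default) and predict the size of
   the probe-containing **junction fragment**: from the nearest cut in host
   DNA 5' of the insertion to the first cut in the element 3' of the probe
   (`predict_junction_fragment()`). Each occupied locus then shows up as one
   band of predictable size on a hybridization blot.
3. **Virtual unblot** — digest realized diploid genomes, read probe-positive
   bands per lane (`digest_pattern()`), cluster band sizes across the cohort
   at gel tolerance (`collate_bands()`, single-linkage on log size, 2%
   default), and classify each cluster as a known locus, ambiguous, or a
   candidate **novel** polymorphic insertion (`classify_clusters()`): novel
   means its size matches no prediction and its presence/absence pattern
   matches no PCR-typed locus.
4. **PCR genotyping** — a three-primer design per locus: set I spans the
   5'LTR junction (detects the proviral allele), set II spans the integration
   site and separates solo LTR from empty site by product size
   (`design_primers()`, `insilico_pcr()`, `genotype_locus()`).
5. **Association** — per-locus / per-band carrier 2×2 tables tested with the
   uncorrected Pearson chi-square on 1 df,
   `chi2 = N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`,
   plus the classical two-proportion sample-size formula and a Monte-Carlo
   size/power check (`chi_square_2x2()`, `association_scan()`,
   `sample_size_two_proportions()`, `empirical_power()`).

Everything runs on synthetic data with exact ground truth: a generator builds
a host mini-genome, an element family with a controlled identity gradient,
and diploid Hardy–Weinberg cohorts with known per-locus allele frequencies
(`make_reference_panel()`, `simulate_cohort()`, `realize_genome()`), so every
stage of the screen is testable end to end. Carrier frequency at allele
frequency *f* follows `1 − (1 − f)²`.

## Worked example

```r
library(ervscreen)

# a replication screen observing 6/100 case vs 11/100 control carriers
r <- chi_square_2x2(6, 94, 11, 89)
sprintf("chi2 = %.2f, p = %.2f", r$chi2, r$p)
#> "chi2 = 1.61, p = 0.20"            # no association at alpha = 0.05

# group size needed to detect a 0.04 vs 0.24 carrier split at 80% power
sample_size_two_proportions(0.04, 0.24, power = 0.80)
#> 47                                  # i.e. 94 samples in total

# a full synthetic screen: 4 loci, 25 + 25 cohort
report <- run_pipeline(default_config(n_elements = 8, n_loci = 4,
                                      n_recent = 4, recent_k = 4,
                                      n_cases = 25, n_controls = 25,
                                      seed = 42))
report
#> <erv_run_report: 4 loci, 5 band clusters, seed 42>
#>   locus_id size case_pos ctrl_pos band_case_pos band_ctrl_pos      chi2         p
#> 1  locus01 1933       13       11            13            11 0.3205128 0.5712996
#> 2  locus02 2077       13       14            13            14 0.0805153 0.7766003
#> 3  locus03 3578       13       10            13            10 0.7246377 0.3946269
#> 4  locus04 2447       16       12            16            12 1.2987013 0.2544506
```

Reading the report: `size` is the predicted junction-fragment size (bp);
`case_pos`/`ctrl_pos` are PCR carrier counts; `band_*_pos` are unblot band
presence counts — identical to the PCR counts here because the cohort was
simulated without SNPs; `chi2`/`p` test the carrier split. The fifth band
cluster is the tandem allele's extra internal fragment.

## The analysis workflow

Numbered drivers under `analysis/` run the screen stage by stage, writing
tables under `results/` (all regenerable; pass a seed as the one argument):

```sh
Rscript analysis/01_simulate.R 1           # panel + 25+25 cohort
Rscript analysis/02_probe_and_enzyme.R     # identity ranking, probe, enzyme
Rscript analysis/03_predict_fragments.R    # junction-fragment ladder
Rscript analysis/04_unblot.R 1             # band patterns, clusters, novel calls
Rscript analysis/05_association.R          # chi-square scans + power analysis
Rscript analysis/06_full_run.R 1           # the same screen in one call
```

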