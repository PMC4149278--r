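---
title: "Screening polymorphic endogenous retrovirus insertions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening polymorphic endogenous retrovirus insertions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscreen)
```

## Scope

`ervscreen` implements a complete case–control screen for insertionally
polymorphic endogenous retroviruses: probe selection from an identity-ranked
proviral family, restriction-enzyme selection and junction-fragment
prediction, a symbolic "unblot" (band patterns, cross-cohort clustering,
novel-band flagging), three-primer in-silico PCR genotyping, and carrier
association statistics. A synthetic-data module generates the reference
panel and diploid cohorts with exact ground truth, so the whole screen is
testable without any external sequence resources. This vignette records the
models, the tunable parameters and why their defaults are what they are, the
numerical conventions, and the limits of what the synthetic validation shows.

## The allele model

A polymorphic locus carries a repertoire drawn from four structural alleles:

* `pre` — the ancestral empty site: host flank unchanged;
* `pro` — host-left + TSD + full element + TSD + host-right;
* `solo` — as `pro` with the element replaced by a single LTR;
* `tandem` — as `pro` with two element bodies sharing one central LTR.

The target-site duplication (TSD) is modeled as the `tsd` host bases
immediately 3' of the insertion point, duplicated once per insert; the
default is 0 bp, which keeps fragment arithmetic transparent, and it is
configurable per locus because real TSD handling varies by report. The solo
allele retains the 5'LTR sequence; which LTR persists after recombination is
not observable in the data this models, and using the 5'LTR keeps the solo
allele consistent with the 5'-junction framing of the whole screen. On `-`
strand loci the insert is reverse-complemented.

Diploid genotypes are drawn per locus per haplotype (Hardy–Weinberg, no
linkage between loci — loci live on separate contigs and are treated as
independent throughout). The proviral allele has per-haplotype frequency
`f`; the remaining `1 − f` is split equally among the locus's non-carrier
alleles. Where a repertoire includes `tandem`, it takes a fixed 20% share of
`f`, so the carrier probability is always `1 − (1 − f)²` — the identity every
recovery test checks against. Group enrichment is parameterized as explicit
`(f_case, f_control)` pairs rather than odds ratios, because carrier
frequencies per group are what a prevalence table reports. Carrier frequency
(the fraction of individuals with ≥ 1 proviral or tandem allele) is the
quantity tabulated and tested everywhere; per-allele frequencies are
derivable from the genotype ledger but are not the screen's endpoint.

## The synthetic reference panel

`make_reference_panel()` emulates the materials a genome-mined screen starts
from:

* an element family (default 20 elements of 9,472 bp with 968-bp LTRs,
  matching the scale of a full-length HML-2 provirus) with a requested
  percent-identity gradient to the reference element; substitutions are
  placed uniformly, so requested and measured Hamming identity agree within
  ±1 percentage point;
* a probe window (default 32 bp starting 49 bp past the 5'LTR end, i.e.
  ~1 kb into the element) kept substitution-free in the `n_recent` youngest
  elements and deliberately diverged in the older ones — the synthetic
  analogue of a young-lineage diagnostic sequence;
* per-locus host contigs with the insertion point centred and a single
  enzyme recognition site planted at a per-locus upstream distance taken
  from a geometric ladder (defaults ~0.8–5 kb, ratio 1.18). The ladder makes
  the predicted junction fragments a resolvable ladder within the detectable
  window, as on a real single-enzyme blot where each locus has its own
  characteristic band; the window immediately upstream is scrubbed of other
  sites so the planted cut is the nearest one, and scrubbing works on *cut*
  positions (not recognition-site positions), which matters for
  downstream-cutting enzymes.

The generator also scrubs recognition sites from the 5'LTR and the pre-probe
leader of every element, so the default enzyme satisfies the
body-but-not-5'LTR rule and the probe always sits 5' of the first internal
cut. What the generator does **not** emulate: genome-scale background (each
locus region is a ~16-kb contig, so the band count per lane equals the
number of carried detectable loci rather than a genome-wide constant),
indels and rearrangements (substitution-only divergence), linkage, gapped
alignments (element rows are equal-length, so the "alignment" is gapless),
amplification bias, and gel artefacts. Passing tests therefore demonstrate
the correctness of the screen's logic and arithmetic, not robustness to
real-genome complications such as repeat-mediated cross-hybridization.

## Probe design

Elements are ranked by percent identity to the reference, computed over
shared non-gap columns. Candidate windows must lie strictly 3' of the 5'LTR
and end within `max_ltr_distance` (default 2,000 bp) of its end. Scoring is:

* `recent_score` — mean pairwise identity over the window among the
  `recent_k` top-ranked rows (default 10 in the demo panel configuration;
  the parameter trades specificity of "recent" against the number of
  detectable elements);
* `older_max_identity` — maximum identity of the recent-subset consensus
  window against any older row (distinctness);
* ranking: recent conservation descending, older identity ascending,
  distance from the LTR ascending, then leftmost column.

This scoring is a declared design choice: conservation-and-distinctness has
no canonical formula, and mean-pairwise/max-vs-consensus is the simplest
pair that is exactly reproducible by exhaustive enumeration (which the test
suite does). Gaps never match and windows whose consensus contains a gap are
skipped. Probe hits are an ungapped Hamming scan of both strands
(substitutions only, `max_mismatch` default 2): the probe is short, and
indel tolerance would change the fragment-containment logic without a
modeled benefit.

## Virtual digest and fragment prediction

An enzyme is a recognition sequence (IUPAC allowed, expanded at match time)
plus a top-strand cut offset relative to the recognition end; a recognition
occurrence on either strand is resolved to a single top-strand cut
coordinate by mirror symmetry. Fragment boundaries use actual cut positions
rather than recognition-site starts — the physically correct choice; the few
bp of difference are absorbed by gel tolerance downstream. For
IUPAC-palindromic sites the two strand readings give two staggered cuts per
occurrence, which is the documented behaviour.

The junction fragment of an occupied locus runs from the nearest host cut 5'
of the insertion (in the element's reading frame) to the first element cut
3' of the probe. `predict_junction_fragment()` digests a junction-local
composite (upstream host within a 20-kb horizon + TSD + oriented insert), so
recognition sites straddling the host–provirus junction are handled exactly;
the tests cross-check it against an independent oracle that realizes the full
diploid region, digests it with a regex-based cut scan, and finds the probe
by sequence match. If no host cut exists within the horizon the fragment is
reported as an "undetectably large" sentinel (`size = NA`) rather than an
error; a probe lying 3' of the first internal cut is a contract violation.
The detectable size window defaults to 500–10,000 bp, bracketing what a
standard agarose separation resolves.

## Band collation and classification

Per-lane band patterns keep distinct sizes only (diploid duplicates collapse,
as on a gel read for presence/absence). Cross-cohort clustering is
single-linkage on log size with relative tolerance 2% — a declared
approximation of agarose sizing precision; on a sorted axis this is a cut at
gaps exceeding `log(1 + tol)`. Single linkage can chain at high band
density; clusters spanning more than twice the tolerance are flagged `wide`
rather than split. A cluster is `known(locus)` only under dual evidence
when PCR calls are available: representative size within tolerance of one
predicted fragment *and* band-presence vector identical to that locus's PCR
carrier vector; size match with discordant carriers, or two predictions in
tolerance, is `ambiguous`; everything else is `novel`. Rare novel clusters
are reported as such with no further locus inference.

## PCR genotyping

Product size follows the common in-silico convention: 5' end of the forward
match to 5' end of the reverse site, inclusive. Primer binding is
perfect-match by default (`max_mismatch = 0`, 3'-anchored when a tolerance is
set): the modeled workflow validates primers by sequencing, not
thermodynamics, and no melting-temperature model is attempted. Set II
separates solo from pre by the nearer expected size (they differ by one LTR
plus TSD, far beyond the 50-bp product tolerance); the proviral allele gives
no set-II product because the element pushes the product past `max_product`
(default 4,000 bp), which is exactly what makes set II discriminating.
Tandem alleles amplify set I identically to `pro` and are called as
carriers — PCR cannot distinguish them, though the unblot sees the tandem's
extra internal fragment. When only a merged product set is available the
call degrades gracefully to `carrier-only`.

## Association statistics

The 2×2 carrier test is the uncorrected Pearson chi-square on 1 df; no Yates
correction and no multiple-testing correction by default (a Bonferroni flag
exists). Monomorphic tables (a zero margin) have an undefined statistic and
are flagged rather than forced to zero. Significance is `p < alpha`
(default 0.05). Sample size for two proportions uses the classical
pooled-null / unpooled-alternative normal approximation, two-sided, ceiling
per group. `empirical_power()` simulates binomial carrier tables and rejects
on the critical-value form `chi2 >= qchisq(1 - alpha, 1)` — equivalent to the
p-value rule everywhere except the degenerate `alpha = 1`, where it correctly
rejects every defined table; zero-margin tables count as non-rejections.

## Numerical conventions and reproducibility

* Coordinates are 1-based inclusive everywhere, including on-disk tables —
  the native convention of the R/Bioconductor sequence stack this package is
  built on. A cut at position `c` severs the bond between bases `c` and
  `c + 1`.
* All randomness flows from a single seed, fanned out per stage by
  `derive_seed()` (a fixed affine map mod 2³¹ − 1), so identical
  configuration + seed reproduces panels, cohorts, and reports bitwise, and
  stages are independently reproducible.
* Ties in probe ranking are broken deterministically (leftmost column);
  identity ranking breaks ties by element id, so input order never matters.
* Scores are computed as exact integer ratios (match counts divided once),
  which keeps rankings stable against floating-point accumulation order.

Problem sizes used by the shipped tests and acceptance script — chosen as
the package's standard validation scale: a 20-element, 12-locus demo panel
with a 25+25 cohort; three 18-locus randomized panels (54 loci) for the
digest-oracle equivalence; a 100+100 cohort at allele frequencies
{0.02, 0.1, 0.3, 0.7} for end-to-end recovery; 10,000 Monte-Carlo
replicates for size and power of the chi-square test.

## Known limitations

* The unblot is symbolic: band sizes only, no intensities, no densitometry,
  no partial digests, no methylation sensitivity.
* Only the probe-containing junction fragment is predicted per locus; the
  full digest engine exists but internal fragments are reported only when
  they actually light up (e.g. the tandem allele's second probe copy).
* Pairwise identity on user-supplied alignments assumes the rows are already
  aligned (or gapless and equal-length); no aligner is bundled, and manual
  alignment curation is out of scope.
* Real-genome fragment tables for published accessions require those
  sequences; the package validates the same arithmetic on synthetic twins
  instead.
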