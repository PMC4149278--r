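#' Simulate a diploid case-control cohort
#'
#' Draws two haplotypes per individual per locus independently (Hardy-
#' Weinberg equilibrium, no linkage between loci). The proviral ("pro")
#' allele is drawn with the configured per-haplotype frequency `f`
#' (group-specific when an enrichment pair is given); the remaining
#' probability `1 - f` is split equally among the locus's non-carrier alleles
#' (solo / pre). Where a repertoire includes "tandem", that state takes a
#' fixed 20% share of `f`, so the carrier probability stays `1 - (1 - f)^2`.
#'
#' @param panel An `erv_panel` from [make_reference_panel()].
#' @param n_cases,n_controls Group sizes (> 0).
#' @param freq Either a single numeric frequency applied to all loci and both
#'   groups, or a data.frame with columns `locus_id`, `f_case`, `f_control`
#'   covering every panel locus (explicit case/control pairs are how group
#'   enrichment is parameterized).
#' @param snp_rate Per-bp substitution rate applied later when genomes are
#'   realized; stored on the cohort.
#' @param seed Integer seed; identical panel + spec + seed reproduces the
#'   cohort exactly.
#' @return An object of class `erv_cohort`: list with `individuals`
#'   (data.frame: id, group), `genotypes` (long data.frame: id, group,
#'   locus_id, hap1, hap2), `carrier_truth` (data.frame of per-locus,
#'   per-group carrier counts — the simulation ledger), `freq`, `snp_rate`,
#'   `seed`.
#' @examples
#' panel <- make_reference_panel(n_elements = 4, n_loci = 2, seed = 1)
#' coh <- simulate_cohort(panel, 10, 10, freq = 0.3, seed = 2)
#' coh$carrier_truth
#' @export
simulate_cohort <- function(panel, n_cases, n_controls, freq,
                            snp_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "erv_panel"))
  if (n_cases <= 0 || n_controls <= 0) stop("group sizes must be > 0")
  loci <- panel$loci
  if (is.numeric(freq) && length(freq) == 1L) {
    freq <- data.frame(locus_id = loci$locus_id, f_case = freq,
                       f_control = freq, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("locus_id", "f_case", "f_control") %in% names(freq)))
  if (!setequal(freq$locus_id, loci$locus_id))
    stop("freq must cover exactly the panel's loci")
  if (any(freq$f_case < 0 | freq$f_case > 1 | freq$f_control < 0 | freq$f_control > 1))
    stop("allele frequencies must lie in [0, 1]")

  set.seed(seed)
  ids <- c(sprintf("case%03d", seq_len(n_cases)),
           sprintf("ctrl%03d", seq_len(n_controls)))
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  individuals <- data.frame(id = ids, group = group, stringsAsFactors = FALSE)

  geno <- vector("list", nrow(loci))
  for (j in seq_len(nrow(loci))) {
    rep_j <- strsplit(loci$repertoire[j], ",", fixed = TRUE)[[1L]]
    f <- ifelse(group == "case",
                freq$f_case[match(loci$locus_id[j], freq$locus_id)],
                freq$f_control[match(loci$locus_id[j], freq$locus_id)])
    haps <- vapply(seq_along(ids), function(i) {
      p <- allele_probs(rep_j, f[i])
      sample(names(p), 2L, replace = TRUE, prob = p)
    }, character(2L))
    geno[[j]] <- data.frame(
      id = ids, group = group, locus_id = loci$locus_id[j],
      hap1 = haps[1L, ], hap2 = haps[2L, ], stringsAsFactors = FALSE
    )
  }
  genotypes <- do.call(rbind, geno)
  rownames(genotypes) <- NULL

  carrier <- genotypes$hap1 %in% c("pro", "tandem") |
    genotypes$hap2 %in% c("pro", "tandem")
  truth <- stats::aggregate(carrier,
                            by = list(locus_id = genotypes$locus_id,
                                      group = genotypes$group),
                            FUN = sum)
  names(truth)[3] <- "carriers"

  structure(
    list(individuals = individuals, genotypes = genotypes,
         carrier_truth = truth[order(truth$locus_id, truth$group), ],
         freq = freq, snp_rate = snp_rate, seed = seed),
    class = "erv_cohort"
  )
}

#' @export
print.erv_cohort <- function(x, ...) {
  cat(sprintf("<erv_cohort: %d cases + %d controls, %d loci, snp_rate=%g>\n",
              sum(x$individuals$group == "case"),
              sum(x$individuals$group == "control"),
              length(unique(x$genotypes$locus_id)), x$snp_rate))
  invisible(x)
}

# Per-haplotype allele probabilities for one locus/one individual.
allele_probs <- function(repertoire, f) {
  carrier <- intersect(repertoire, c("pro", "tandem"))
  other <- setdiff(repertoire, carrier)
  p <- numeric(0)
  if ("pro" %in% carrier && "tandem" %in% carrier) {
    p <- c(pro = 0.8 * f, tandem = 0.2 * f)
  } else if ("pro" %in% carrier) {
    p <- c(pro = f)
  } else if ("tandem" %in% carrier) {
    p <- c(tandem = f)
  }
  if (length(other) > 0) {
    p <- c(p, stats::setNames(rep((1 - f) / length(other), length(other)), other))
  } else if (f < 1) {
    stop("repertoire has no non-carrier allele but f < 1")
  }
  # guard against tiny negative from floating arithmetic
  pmax(p, 0)
}

#' Expected Hardy-Weinberg carrier probability
#'
#' Probability that a diploid individual carries at least one proviral allele
#' given per-haplotype allele frequency `f`: `1 - (1 - f)^2`.
#'
#' @param f Proviral allele frequency in \[0, 1\].
#' @return Carrier probability.
#' @export
hw_carrier_prob <- function(f) 1 - (1 - f)^2

#' Realize the two haplotype sequences of one individual at every locus
#'
#' Composes, per locus and haplotype, the regional genomic sequence implied
#' by the allele state:
#' \itemize{
#'   \item `pre` — the host flank unchanged;
#'   \item `pro` — host-left + TSD + full element + TSD + host-right;
#'   \item `solo` — as `pro` with the element replaced by its 5'LTR;
#'   \item `tandem` — as `pro` with two element bodies sharing one central
#'     LTR (element minus its 3'LTR, then the full element).
#' }
#' The TSD is the `tsd` host bases immediately 3' of the insertion point,
#' duplicated on both sides of the insert. On `-` strand loci the insert is
#' reverse-complemented. Substitutions are applied afterwards at `snp_rate`
#' using the current RNG stream.
#'
#' @param individual_id Id present in `cohort$individuals`.
#' @param cohort An `erv_cohort`.
#' @param panel The `erv_panel` the cohort was simulated from.
#' @param flank Host flank (bp) on each side of the insertion point.
#' @return Named list (by locus_id) of character vectors `c(hap1, hap2)`.
#' @export
realize_genome <- function(individual_id, cohort, panel, flank = 8000) {
  stopifnot(inherits(cohort, "erv_cohort"), inherits(panel, "erv_panel"))
  g <- cohort$genotypes[cohort$genotypes$id == individual_id, ]
  if (nrow(g) == 0L) stop("unknown individual: ", individual_id)
  out <- lapply(seq_len(nrow(g)), function(k) {
    h1 <- realize_haplotype(panel, g$locus_id[k], g$hap1[k], flank)
    h2 <- realize_haplotype(panel, g$locus_id[k], g$hap2[k], flank)
    c(apply_snps(h1, cohort$snp_rate), apply_snps(h2, cohort$snp_rate))
  })
  names(out) <- g$locus_id
  out
}

#' Realize one haplotype sequence at one locus
#'
#' @inheritParams realize_genome
#' @param locus_id Panel locus id.
#' @param allele One of `pro`, `solo`, `tandem`, `pre`; must belong to the
#'   locus repertoire.
#' @return Character scalar, the regional haplotype sequence.
#' @export
realize_haplotype <- function(panel, locus_id, allele, flank = 8000) {
  lc <- panel$loci[panel$loci$locus_id == locus_id, ]
  if (nrow(lc) != 1L) stop("unknown locus: ", locus_id)
  repertoire <- strsplit(lc$repertoire, ",", fixed = TRUE)[[1L]]
  if (!allele %in% repertoire)
    stop(sprintf("allele '%s' not in repertoire of %s", allele, locus_id))

  host <- panel$host[[lc$contig]]
  ip <- lc$insertion_point
  tsd <- lc$tsd
  a <- max(1L, ip - flank + 1L)
  b <- min(nchar(host), ip + flank)
  if (allele == "pre") return(substr(host, a, b))

  el <- panel$elements[panel$elements$element_id == lc$element_id, ]
  eseq <- panel$element_seqs[[lc$element_id]]
  insert <- switch(allele,
    pro = eseq,
    solo = substr(eseq, el$ltr5_start, el$ltr5_end),
    tandem = paste0(substr(eseq, 1L, el$ltr3_start - 1L), eseq)
  )
  if (lc$strand == "-") insert <- revcomp(insert)

  left <- substr(host, a, ip)
  tsd_seq <- if (tsd > 0L) substr(host, ip + 1L, ip + tsd) else ""
  right <- substr(host, ip + tsd + 1L, b)
  paste0(left, tsd_seq, insert, tsd_seq, right)
}
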