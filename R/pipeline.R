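#' Default pipeline configuration
#'
#' Returns the demo run configuration: a 20-element panel with 12 polymorphic
#' loci, a 25 + 25 cohort at moderate proviral allele frequencies, BsrI
#' digest, 32-bp probe window, 2% band tolerance, 500-10,000 bp detectable
#' window, alpha 0.05. Any entry can be overridden via `...`.
#'
#' @param ... Named overrides of config entries.
#' @return Named list (class `erv_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    n_elements = 20L, n_loci = 12L, n_recent = 10L,
    element_length = 9472L, ltr_length = 968L,
    probe_offset = 49L, probe_length = 32L,
    flank = 8000L,
    repertoires = c("pro,solo,pre", "pro,pre",
                    "pro,solo,pre", "pro,solo,tandem,pre"),
    strands = c("+", "+", "-", "+"),
    tsd = 0L,
    n_cases = 25L, n_controls = 25L,
    freq = 0.3, snp_rate = 0,
    recent_k = 10L, max_ltr_distance = 2000L,
    max_mismatch = 2L, size_window = c(500, 10000),
    rel_tolerance = 0.02,
    size_tolerance = 50L, max_product = 4000L,
    alpha = 0.05,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "erv_config")
}

#' Run the full screen end-to-end
#'
#' Orchestrates every stage on synthetic data: panel generation, probe
#' selection from the identity-ranked element alignment, enzyme check,
#' junction-fragment prediction, cohort simulation, genome realization,
#' virtual unblot (digest, band collation, classification, per-cluster
#' counts), in silico PCR genotyping, and the case-control association scan
#' over both the PCR carrier tables and the band clusters. All randomness
#' flows from `config$seed`, fanned out per stage by [derive_seed()], so the
#' run is fully reproducible.
#'
#' @param config List from [default_config()].
#' @param enz Restriction [enzyme()] (default BsrI).
#' @return An object of class `erv_run_report`: list with `panel`, `cohort`,
#'   `probe` (the selected candidate row), `fragments` (predictions),
#'   `clusters` (classified cluster frequency table), `pcr_calls`,
#'   `locus_table` (per-locus join of predicted size, PCR carrier counts,
#'   matched band-cluster counts, chi-square results), `band_assoc`
#'   (association over all clusters) and `provenance`.
#' @export
run_pipeline <- function(config = default_config(), enz = default_enzymes()$BsrI) {
  panel <- make_reference_panel(
    n_elements = config$n_elements, n_loci = config$n_loci,
    n_recent = config$n_recent, element_length = config$element_length,
    ltr_length = config$ltr_length, probe_offset = config$probe_offset,
    probe_length = config$probe_length, flank = config$flank,
    repertoires = config$repertoires, strands = config$strands,
    tsd = config$tsd, enz = enz, seed = derive_seed(config$seed, 1L)
  )

  # probe design on the element family
  ranked <- rank_by_identity(panel$element_seqs, panel$elements$element_id[1])
  cand <- find_conserved_window(
    panel$element_seqs, panel$elements$element_id[1],
    ltr5_end = panel$elements$ltr5_end[1],
    recent_k = config$recent_k, L = config$probe_length,
    max_ltr_distance = config$max_ltr_distance
  )
  if (nrow(cand) == 0L) stop("stage probe_design failed: no conserved window")
  # the probe must sit 5' of the first internal cut of every locus element,
  # or its junction fragment is undefined
  first_cut <- min(vapply(unique(panel$loci$element_id), function(eid)
    min(find_sites(panel$element_seqs[[eid]], enz)), numeric(1L)))
  cand <- cand[cand$end <= first_cut, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("stage probe_design failed: no conserved window 5' of the first cut")
  probe <- cand$probe[1L]
  probe_region <- c(cand$start[1L], cand$end[1L])

  # enzyme must cut the element body but not the 5'LTR
  ok <- select_enzymes(panel$element_seqs[[1L]],
                       c(panel$elements$ltr5_start[1], panel$elements$ltr5_end[1]),
                       list(enz))
  if (length(ok) == 0L)
    stop("stage enzyme_selection failed: enzyme cuts the 5'LTR or not the body")

  fragments <- predict_all_fragments(panel, enz, probe_region = probe_region)

  cohort <- simulate_cohort(panel, config$n_cases, config$n_controls,
                            freq = config$freq, snp_rate = config$snp_rate,
                            seed = derive_seed(config$seed, 2L))

  # realize once, share between unblot and PCR
  set.seed(derive_seed(config$seed, 3L))
  regions_by_id <- lapply(cohort$individuals$id, realize_genome,
                          cohort = cohort, panel = panel, flank = config$flank)
  names(regions_by_id) <- cohort$individuals$id

  patterns <- lapply(cohort$individuals$id, function(id)
    digest_pattern(regions_by_id[[id]], enz, probe, id = id,
                   group = cohort$individuals$group[
                     match(id, cohort$individuals$id)],
                   max_mismatch = config$max_mismatch,
                   size_window = config$size_window))

  pcr_calls <- genotype_cohort(cohort, panel, regions_by_id = regions_by_id,
                               size_tolerance = config$size_tolerance,
                               max_product = config$max_product)
  carriers <- carrier_table(pcr_calls)

  collated <- collate_bands(patterns, rel_tolerance = config$rel_tolerance)
  classified <- classify_clusters(
    collated, fragments,
    pcr_carriers = pcr_calls[, c("id", "locus_id", "carrier")],
    rel_tolerance = config$rel_tolerance
  )
  cluster_freq <- cluster_frequencies(classified, cohort$individuals)

  pcr_assoc <- association_scan(carriers, alpha = config$alpha)
  band_assoc <- association_scan(cluster_freq, alpha = config$alpha)

  # per-locus join: prediction + PCR + matched band cluster
  locus_table <- merge(fragments[, c("locus_id", "size", "undetectable")],
                       pcr_assoc, by = "locus_id")
  band_cols <- cluster_freq[!is.na(cluster_freq$locus_id),
                            c("locus_id", "case_pos", "ctrl_pos")]
  names(band_cols) <- c("locus_id", "band_case_pos", "band_ctrl_pos")
  locus_table <- merge(locus_table, band_cols, by = "locus_id", all.x = TRUE)
  locus_table <- locus_table[order(locus_table$locus_id), ]
  rownames(locus_table) <- NULL

  structure(
    list(panel = panel, cohort = cohort,
         probe = cand[1L, ], ranked = ranked, fragments = fragments,
         patterns = patterns, clusters = cluster_freq, pcr_calls = pcr_calls,
         locus_table = locus_table, band_assoc = band_assoc,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(unclass(config)),
                           package_version = as.character(
                             utils::packageVersion("ervscreen")))),
    class = "erv_run_report"
  )
}

#' @export
print.erv_run_report <- function(x, ...) {
  cat(sprintf("<erv_run_report: %d loci, %d band clusters, seed %s>\n",
              nrow(x$locus_table), nrow(x$clusters), x$provenance$seed))
  print(x$locus_table[, c("locus_id", "size", "case_pos", "ctrl_pos",
                          "band_case_pos", "band_ctrl_pos", "chi2", "p")])
  invisible(x)
}

#' Write the joined run report to a directory
#'
#' Emits `locus_table.tsv`, `clusters.tsv`, `pcr_calls.tsv`,
#' `fragments.tsv` and `provenance.tsv`.
#'
#' @param report An `erv_run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "erv_run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$locus_table, file.path(dir, "locus_table.tsv"))
  write_tsv(report$clusters, file.path(dir, "clusters.tsv"))
  write_tsv(report$pcr_calls, file.path(dir, "pcr_calls.tsv"))
  write_tsv(report$fragments, file.path(dir, "fragments.tsv"))
  write_tsv(data.frame(seed = report$provenance$seed,
                       config_hash = report$provenance$config_hash,
                       package_version = report$provenance$package_version),
            file.path(dir, "provenance.tsv"))
  invisible(dir)
}
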