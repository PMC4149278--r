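#' In silico PCR over a template
#'
#' Finds every pair of a forward-primer match on the top strand and a
#' reverse-primer reverse-complement match downstream of it, and reports the
#' product sizes. Matching is ungapped with a perfectly matched 3' terminal
#' base and at most `max_mismatch` internal substitutions (default 0: perfect
#' match). The product size convention is 5' end of the forward match to 5'
#' end of the reverse site, inclusive — the length the amplicon would run at.
#'
#' @param template Template sequence (character scalar).
#' @param fwd,rev Primer sequences, 5'->3', >= 15 nt.
#' @param max_product Maximum product size reported (bp).
#' @param max_mismatch Internal mismatch tolerance per primer.
#' @return Integer vector of product sizes (possibly empty), sorted.
#' @export
insilico_pcr <- function(template, fwd, rev, max_product = 4000L,
                         max_mismatch = 0L) {
  stopifnot(nchar(fwd) >= 15L, nchar(rev) >= 15L)
  # amplification is orientation-symmetric: scan both template orientations
  sizes <- c(pcr_scan(template, fwd, rev, max_product, max_mismatch),
             pcr_scan(revcomp(template), fwd, rev, max_product, max_mismatch))
  sort(unique(sizes))
}

# One-orientation scan: forward primer on the top strand, reverse primer
# reverse-complement downstream of it.
pcr_scan <- function(template, fwd, rev, max_product, max_mismatch) {
  f_start <- primer_sites(template, fwd, max_mismatch)          # 5' ends
  r_site <- primer_sites(template, revcomp(rev), max_mismatch,
                         anchor = "first")                      # rc site starts
  if (length(f_start) == 0L || length(r_site) == 0L) return(integer(0))
  r_five <- r_site + nchar(rev) - 1L  # 5' end of the reverse primer site
  sizes <- integer(0)
  for (f in f_start) {
    ok <- r_site >= f & (r_five - f + 1L) <= max_product &
      (r_five - f + 1L) >= max(nchar(fwd), nchar(rev))
    sizes <- c(sizes, r_five[ok] - f + 1L)
  }
  sizes
}

# Match positions of a primer on the top strand. `anchor = "last"` requires
# the final pattern base (the primer 3' end) to match exactly; for a
# reverse-complemented reverse primer the 3' end is the first pattern base.
primer_sites <- function(template, pattern, max_mismatch, anchor = "last") {
  subject <- Biostrings::DNAString(template)
  if (nchar(pattern) > length(subject)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                max.mismatch = max_mismatch, with.indels = FALSE)
  if (length(m) == 0L) return(integer(0))
  st <- Biostrings::start(m)
  if (max_mismatch > 0L) {
    segs <- as.character(m)
    pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    keep <- vapply(segs, function(s) {
      sc <- strsplit(s, "", fixed = TRUE)[[1L]]
      idx <- if (anchor == "last") length(pc) else 1L
      sc[idx] == pc[idx]
    }, logical(1L))
    st <- st[keep]
  }
  st
}

#' Design a three-primer set for one locus
#'
#' Mirrors the locus-specific genotyping design: primer set I spans the
#' 5'LTR junction (forward in the upstream host flank, reverse in the
#' proviral leader just 3' of the 5'LTR) and detects the proviral allele;
#' primer set II reuses the forward primer with a reverse primer in the
#' downstream host flank, spanning the integration site, and distinguishes
#' the solo-LTR allele from the pre-integration (empty) site by product size
#' (they differ by one LTR plus TSD). Expected product sizes are computed
#' from the panel composition. Primers are taken in the element's reading
#' frame, so `-` strand loci get reverse-complemented host segments.
#'
#' @param panel An `erv_panel`.
#' @param locus_id Locus to design for.
#' @param primer_len Primer length (nt).
#' @param fwd_gap Gap (bp) between the forward primer 3' end and the
#'   insertion point.
#' @param leader_gap Gap (bp) between the 5'LTR end and the set-I reverse
#'   primer site.
#' @param down_gap Gap (bp) between the insertion point (after the TSD
#'   source) and the set-II reverse primer site.
#' @return An object of class `erv_primer_set`: list with `locus_id`,
#'   `forward`, `reverse_I`, `reverse_II`, `size_I`, `size_II_solo`,
#'   `size_II_pre`.
#' @export
design_primers <- function(panel, locus_id, primer_len = 20L, fwd_gap = 150L,
                           leader_gap = 80L, down_gap = 300L) {
  stopifnot(inherits(panel, "erv_panel"))
  lc <- panel$loci[panel$loci$locus_id == locus_id, ]
  if (nrow(lc) != 1L) stop("unknown locus: ", locus_id)
  el <- panel$elements[panel$elements$element_id == lc$element_id, ]
  eseq <- panel$element_seqs[[lc$element_id]]
  host <- panel$host[[lc$contig]]
  ip <- lc$insertion_point
  tsd <- lc$tsd
  ltr_len <- el$ltr5_end - el$ltr5_start + 1L

  # host segments flanking the insertion, in the element's reading frame
  up_seg <- function(dist, len) {   # ends `dist` bp 5' of the insertion point
    if (lc$strand == "+") substr(host, ip - dist - len + 1L, ip - dist)
    else revcomp(substr(host, ip + tsd + dist + 1L, ip + tsd + dist + len))
  }
  down_seg <- function(dist, len) { # starts `dist` bp 3' of the insertion point
    if (lc$strand == "+") substr(host, ip + tsd + dist + 1L, ip + tsd + dist + len)
    else revcomp(substr(host, ip - dist - len + 1L, ip - dist))
  }

  forward <- up_seg(fwd_gap, primer_len)
  leader_start <- el$ltr5_end + leader_gap + 1L
  reverse_I <- revcomp(substr(eseq, leader_start, leader_start + primer_len - 1L))
  reverse_II <- revcomp(down_seg(down_gap, primer_len))

  # product sizes: forward 5' end to reverse 5' end, inclusive
  size_I <- (fwd_gap + primer_len) + tsd + (leader_start + primer_len - 1L)
  size_II_pre <- (fwd_gap + primer_len) + tsd + (down_gap + primer_len)
  size_II_solo <- size_II_pre + ltr_len + tsd

  structure(list(locus_id = locus_id, forward = forward,
                 reverse_I = reverse_I, reverse_II = reverse_II,
                 size_I = size_I, size_II_solo = size_II_solo,
                 size_II_pre = size_II_pre),
            class = "erv_primer_set")
}

#' @export
print.erv_primer_set <- function(x, ...) {
  cat(sprintf("<primer set %s: I=%d bp, II=%d/%d bp (solo/pre)>\n",
              x$locus_id, x$size_I, x$size_II_solo, x$size_II_pre))
  invisible(x)
}

#' Call the diploid allele state at one locus by in silico PCR
#'
#' Runs both primer sets against each realized haplotype. A haplotype is
#' called `pro` when set I yields a product within `size_tolerance` of the
#' expected 5'LTR-junction size (tandem alleles amplify identically and are
#' called `pro`); otherwise set II classifies it `solo` or `pre` by the
#' nearer expected size. A haplotype matching neither is `noamp`. When a
#' single merged product set is supplied (haplotypes not separable), the call
#' falls back to `carrier-only` whenever set I amplifies but the set-II
#' evidence cannot resolve the second allele.
#'
#' @param haps Character vector of 1 (merged) or 2 (per-haplotype) realized
#'   regional sequences.
#' @param primers An `erv_primer_set` from [design_primers()].
#' @param size_tolerance Product-to-expected size tolerance (bp).
#' @param max_product Maximum amplifiable product (bp); proviral alleles
#'   exceed it for set II, which is what makes set II allele-discriminating.
#' @param max_mismatch Primer mismatch tolerance.
#' @return A one-row data.frame: `locus_id`, `call` (e.g. `"pro/pre"`,
#'   `"carrier-only"`, `"no-amplification"`), `carrier` (logical),
#'   `products` (comma-separated observed sizes).
#' @export
genotype_locus <- function(haps, primers, size_tolerance = 50L,
                           max_product = 4000L, max_mismatch = 0L) {
  stopifnot(inherits(primers, "erv_primer_set"), length(haps) %in% 1:2)
  prods <- lapply(haps, function(h) list(
    I = insilico_pcr(h, primers$forward, primers$reverse_I, max_product, max_mismatch),
    II = insilico_pcr(h, primers$forward, primers$reverse_II, max_product, max_mismatch)
  ))
  all_products <- sort(unique(unlist(prods)))

  near <- function(x, target) any(abs(x - target) <= size_tolerance)
  call_hap <- function(p) {
    if (near(p$I, primers$size_I)) return("pro")
    d_solo <- if (length(p$II)) min(abs(p$II - primers$size_II_solo)) else Inf
    d_pre <- if (length(p$II)) min(abs(p$II - primers$size_II_pre)) else Inf
    if (d_solo <= size_tolerance && d_solo < d_pre) return("solo")
    if (d_pre <= size_tolerance && d_pre < d_solo) return("pre")
    "noamp"
  }

  if (length(haps) == 2L) {
    calls <- vapply(prods, call_hap, character(1L))
    if (all(calls == "noamp")) {
      call <- "no-amplification"
    } else {
      ord <- c(pro = 1L, solo = 2L, pre = 3L, noamp = 4L)
      call <- paste(calls[order(ord[calls])], collapse = "/")
    }
  } else {
    p <- prods[[1L]]
    has_pro <- near(p$I, primers$size_I)
    has_solo <- near(p$II, primers$size_II_solo)
    has_pre <- near(p$II, primers$size_II_pre)
    alleles <- c("pro"[has_pro], "solo"[has_solo], "pre"[has_pre])
    call <- if (length(alleles) == 2L) paste(alleles, collapse = "/")
    else if (length(alleles) == 1L && !has_pro) paste(alleles, alleles, sep = "/")
    else if (has_pro) "carrier-only"
    else "no-amplification"
  }
  carrier <- grepl("pro", call, fixed = TRUE) || call == "carrier-only"
  data.frame(locus_id = primers$locus_id, call = call, carrier = carrier,
             products = paste(all_products, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Genotype a whole cohort by in silico PCR
#'
#' @param cohort An `erv_cohort`.
#' @param panel The matching `erv_panel`.
#' @param primer_sets Named list of `erv_primer_set` (one per locus); defaults
#'   to [design_primers()] on every panel locus.
#' @param regions_by_id Optional precomputed named list of
#'   [realize_genome()] outputs keyed by individual id (to share realized
#'   sequences with the digest stage).
#' @param flank Flank passed to [realize_genome()] when realizing here.
#' @inheritParams genotype_locus
#' @return data.frame of calls: `id`, `group`, `locus_id`, `call`, `carrier`,
#'   `products`.
#' @export
genotype_cohort <- function(cohort, panel, primer_sets = NULL,
                            regions_by_id = NULL, flank = 8000,
                            size_tolerance = 50L, max_product = 4000L,
                            max_mismatch = 0L) {
  stopifnot(inherits(cohort, "erv_cohort"), inherits(panel, "erv_panel"))
  if (is.null(primer_sets)) {
    primer_sets <- lapply(panel$loci$locus_id, design_primers, panel = panel)
    names(primer_sets) <- panel$loci$locus_id
  }
  out <- list()
  for (i in seq_len(nrow(cohort$individuals))) {
    id <- cohort$individuals$id[i]
    regions <- if (!is.null(regions_by_id)) regions_by_id[[id]]
    else realize_genome(id, cohort, panel, flank)
    for (locus in names(regions)) {
      call <- genotype_locus(regions[[locus]], primer_sets[[locus]],
                             size_tolerance, max_product, max_mismatch)
      call$id <- id
      call$group <- cohort$individuals$group[i]
      out[[length(out) + 1L]] <- call
    }
  }
  res <- do.call(rbind, out)
  res[, c("id", "group", "locus_id", "call", "carrier", "products")]
}

#' Per-locus carrier 2x2 counts
#'
#' Summarizes genotype calls into the per-locus case/control carrier table
#' that feeds the association scan.
#'
#' @param calls data.frame from [genotype_cohort()] (needs `id`, `group`,
#'   `locus_id`, `carrier`).
#' @return data.frame: `locus_id`, `case_pos`, `case_n`, `ctrl_pos`,
#'   `ctrl_n`, `case_freq`, `ctrl_freq`.
#' @export
carrier_table <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no genotype calls supplied")
  n_case <- length(unique(calls$id[calls$group == "case"]))
  n_ctrl <- length(unique(calls$id[calls$group == "control"]))
  out <- lapply(split(calls, calls$locus_id), function(d) {
    data.frame(locus_id = d$locus_id[1L],
               case_pos = sum(d$carrier & d$group == "case"),
               case_n = n_case,
               ctrl_pos = sum(d$carrier & d$group == "control"),
               ctrl_n = n_ctrl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$case_freq <- out$case_pos / out$case_n
  out$ctrl_freq <- out$ctrl_pos / out$ctrl_n
  out
}
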