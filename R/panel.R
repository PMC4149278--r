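#' Generate a synthetic reference panel
#'
#' Builds a host mini-genome plus a family of proviral element sequences with
#' a controlled gradient of nucleotide identity to a designated reference
#' element (the youngest integration), and a set of insertion loci with known
#' allele repertoires. This stands in for a mined genome-wide proviral set so
#' every downstream stage — probe design, virtual digest, unblot band
#' analysis, PCR genotyping — has exact ground truth.
#'
#' Structure of the generated data:
#' \itemize{
#'   \item Every element is `element_length` bp with identical-length LTRs at
#'     both ends; element 1 is the reference at 100% identity and the others
#'     carry `round(L * (1 - identity/100))` random substitutions.
#'   \item A probe window (default 32 bp, just 3' of the 5'LTR) is kept
#'     substitution-free in the `n_recent` highest-identity elements and
#'     deliberately diverged in the older ones, emulating a young-lineage
#'     diagnostic sequence.
#'   \item Recognition sites of `enz` are scrubbed from the 5'LTR and the
#'     pre-probe leader of every element, so the enzyme satisfies the
#'     body-but-not-5'LTR selection rule and the junction fragment contains
#'     the probe.
#'   \item Each locus sits on its own host contig with the insertion point at
#'     the centre. The host window upstream of the insertion (in the
#'     element's reading frame) is scrubbed and a single recognition site is
#'     planted at a per-locus distance drawn from a geometric ladder
#'     (`upstream_ladder`), giving a resolvable ladder of predicted junction
#'     fragment sizes like a real single-enzyme unblot.
#' }
#'
#' All coordinates are 1-based inclusive. Deterministic for a fixed `seed`.
#'
#' @param n_elements Number of proviral elements (>= 2), reference included.
#' @param identities Numeric vector of requested percent identities to the
#'   reference, one per element; element 1 must be 100. Values in \[0, 100\].
#' @param n_loci Number of polymorphic insertion loci.
#' @param n_recent Number of highest-identity elements treated as "recent"
#'   (probe window conserved).
#' @param element_length,ltr_length Element and LTR lengths (bp).
#' @param probe_offset Distance (bp) from the 5'LTR end to the probe window
#'   start.
#' @param probe_length Probe window length (bp).
#' @param flank Host flank retained on each side of an insertion point (bp);
#'   contigs are `2 * flank` bp.
#' @param upstream_ladder Numeric vector (recycled over loci) of distances
#'   (bp) from the insertion point to the planted nearest upstream host cut.
#' @param repertoires Character vector (recycled over loci) of comma-separated
#'   allele repertoires, subsets of `pro,solo,tandem,pre`.
#' @param strands Character vector (recycled) of locus strands, `+` or `-`.
#' @param tsd Integer vector (recycled) of target-site duplication lengths.
#' @param enz Restriction [enzyme()] the panel is conditioned on.
#' @param seed Integer seed.
#' @return An object of class `erv_panel`: a list with `host` (named
#'   character vector of contigs), `element_seqs` (named character vector),
#'   `elements` (data.frame: element_id, identity, ltr5_start, ltr5_end,
#'   ltr3_start, ltr3_end), `loci` (data.frame: locus_id, contig,
#'   insertion_point, strand, element_id, repertoire, tsd), `probe_region`
#'   (element coordinates of the conserved window) and `enzyme_name`.
#' @examples
#' panel <- make_reference_panel(n_elements = 5, n_loci = 3, seed = 1)
#' panel$loci
#' @export
make_reference_panel <- function(n_elements = 20,
                                 identities = NULL,
                                 n_loci = 12,
                                 n_recent = min(10L, n_elements),
                                 element_length = 9472,
                                 ltr_length = 968,
                                 probe_offset = 49,
                                 probe_length = 32,
                                 flank = 8000,
                                 upstream_ladder = round(800 * 1.18^(seq_len(n_loci) - 1)),
                                 repertoires = c("pro,solo,pre", "pro,pre",
                                                 "pro,solo,pre", "pro,solo,tandem,pre"),
                                 strands = c("+", "+", "-", "+"),
                                 tsd = 0L,
                                 enz = default_enzymes()$BsrI,
                                 seed = 1L) {
  if (n_elements < 2L) stop("configuration error: n_elements must be >= 2")
  if (is.null(identities)) {
    identities <- c(100, seq(99.5, 88, length.out = n_elements - 1L))
  }
  if (length(identities) != n_elements)
    stop("configuration error: identities must have one value per element")
  if (any(identities < 0 | identities > 100))
    stop("configuration error: identities must lie in [0, 100]")
  if (identities[1] != 100)
    stop("configuration error: element 1 is the reference and must be at 100")
  if (any(upstream_ladder <= 0) || max(upstream_ladder) > flank - 100)
    stop("configuration error: upstream_ladder must be positive and < flank")
  stopifnot(element_length > 2 * ltr_length + probe_offset + probe_length)

  set.seed(seed)
  L <- element_length
  ltr5 <- c(1L, as.integer(ltr_length))
  ltr3 <- c(as.integer(L - ltr_length + 1L), as.integer(L))
  probe_region <- as.integer(ltr_length + probe_offset + c(1L, probe_length))
  probe_region[2] <- probe_region[1] + probe_length - 1L

  # reference element: LTR + internal body + identical LTR, leader scrubbed
  ltr_seq <- random_dna(ltr_length)
  body <- random_dna(L - 2L * ltr_length)
  ref <- paste0(ltr_seq, body, ltr_seq)
  ref <- scrub_cuts(ref, enz, 1L, probe_region[2] - 1L)
  if (length(find_sites(ref, enz)) == 0L)
    stop("configuration error: element body carries no recognition site; ",
         "increase element_length")

  ids <- sprintf("elem%02d", seq_len(n_elements))
  ord <- order(identities, decreasing = TRUE)
  identities <- identities[ord]  # reference stays first (100)
  element_seqs <- character(n_elements)
  element_seqs[1] <- ref
  win <- probe_region[1]:probe_region[2]
  for (i in seq_len(n_elements)[-1]) {
    n_mut <- round(L * (1 - identities[i] / 100))
    if (i <= n_recent) {
      pos <- sample(setdiff(seq_len(L), win), n_mut)
    } else {
      # older elements: force divergence inside the probe window
      k <- min(length(win), max(4L, round(n_mut * probe_length / L)), n_mut)
      pos <- c(sample(win, k), sample(setdiff(seq_len(L), win), n_mut - k))
    }
    s <- substitute_bases(ref, pos)
    element_seqs[i] <- scrub_cuts(s, enz, 1L, probe_region[2] - 1L)
  }
  names(element_seqs) <- ids

  elements <- data.frame(
    element_id = ids,
    identity = identities,
    ltr5_start = ltr5[1], ltr5_end = ltr5[2],
    ltr3_start = ltr3[1], ltr3_end = ltr3[2],
    stringsAsFactors = FALSE
  )

  # loci: one contig each, insertion point centred, planted upstream cut
  n_loci <- as.integer(n_loci)
  locus_id <- sprintf("locus%02d", seq_len(n_loci))
  contig <- sprintf("ctg%02d", seq_len(n_loci))
  strands <- rep_len(strands, n_loci)
  repertoires <- rep_len(repertoires, n_loci)
  tsd <- rep_len(as.integer(tsd), n_loci)
  dists <- rep_len(as.integer(upstream_ladder), n_loci)
  elem_for_locus <- ids[rep_len(seq_len(n_recent), n_loci)]

  host <- character(n_loci)
  ip <- as.integer(flank)
  for (j in seq_len(n_loci)) {
    ctg <- random_dna(2L * flank)
    if (strands[j] == "+") {
      ctg <- scrub_cuts(ctg, enz, ip - dists[j], ip)
      ctg <- plant_cut(ctg, enz, ip - dists[j], ip - dists[j], ip)
    } else {
      ctg <- scrub_cuts(ctg, enz, ip, ip + dists[j])
      ctg <- plant_cut(ctg, enz, ip + dists[j], ip, ip + dists[j], strand = "-")
    }
    host[j] <- ctg
  }
  names(host) <- contig

  loci <- data.frame(
    locus_id = locus_id, contig = contig, insertion_point = ip,
    strand = strands, element_id = elem_for_locus,
    repertoire = repertoires, tsd = tsd,
    stringsAsFactors = FALSE
  )

  panel <- structure(
    list(host = host, element_seqs = element_seqs, elements = elements,
         loci = loci, probe_region = probe_region, enzyme_name = enz$name),
    class = "erv_panel"
  )
  validate_panel(panel)
  panel
}

#' @export
print.erv_panel <- function(x, ...) {
  cat(sprintf(
    "<erv_panel: %d elements (%.1f-%.1f%% identity), %d loci on %d contigs>\n",
    nrow(x$elements), min(x$elements$identity), max(x$elements$identity),
    nrow(x$loci), length(x$host)))
  invisible(x)
}

#' Validate reference-panel invariants
#'
#' Checks that every locus insertion point lies within its contig, every
#' element's LTR intervals are in range and non-overlapping, identities lie
#' in \[0, 100\], and repertoires are non-empty subsets of the allowed allele
#' states (with "pre" always constructible by definition).
#'
#' @param panel An `erv_panel`.
#' @return `panel`, invisibly; stops on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "erv_panel"))
  el <- panel$elements
  if (any(el$identity < 0 | el$identity > 100))
    stop("panel invariant violated: identity outside [0, 100]")
  lens <- nchar(panel$element_seqs[el$element_id])
  if (any(el$ltr5_start < 1 | el$ltr3_end > lens | el$ltr5_end >= el$ltr3_start))
    stop("panel invariant violated: LTR intervals out of range or overlapping")
  lc <- panel$loci
  if (any(!lc$contig %in% names(panel$host)))
    stop("panel invariant violated: locus contig missing from host genome")
  clen <- nchar(panel$host[lc$contig])
  if (any(lc$insertion_point < 1 | lc$insertion_point > clen))
    stop(sprintf("panel invariant violated: insertion point outside contig (%s)",
                 paste(lc$locus_id[lc$insertion_point < 1 | lc$insertion_point > clen],
                       collapse = ", ")))
  reps <- strsplit(lc$repertoire, ",", fixed = TRUE)
  ok <- vapply(reps, function(r) length(r) > 0 &&
                 all(r %in% c("pro", "solo", "tandem", "pre")), logical(1L))
  if (!all(ok))
    stop("panel invariant violated: bad allele repertoire")
  if (any(lc$tsd < 0)) stop("panel invariant violated: negative TSD")
  invisible(panel)
}

# All recognition occurrences of `enz` in `seq` with their resolved
# top-strand cut positions (cuts falling outside the sequence included).
site_occurrences <- function(seq, enz) {
  subject <- Biostrings::DNAString(seq)
  len <- nchar(enz$site)
  pat <- Biostrings::DNAString(enz$site)
  rcp <- Biostrings::reverseComplement(pat)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = FALSE))
  rev <- Biostrings::start(Biostrings::matchPattern(rcp, subject, fixed = FALSE))
  data.frame(
    start = c(fwd, rev), end = c(fwd, rev) + len - 1L,
    cut = c(fwd + len + enz$cut_offset - 1L, rev - enz$cut_offset - 1L),
    stringsAsFactors = FALSE
  )
}

# Mutate recognition occurrences whose CUT position falls in [from, to],
# until none remain. Occurrences lying exactly on the `protect` interval are
# kept; occurrences partially overlapping it are mutated outside it. Loops
# because a substitution can create a new occurrence.
scrub_cuts <- function(seq, enz, from, to, protect = NULL) {
  for (iter in 1:100) {
    occ <- site_occurrences(seq, enz)
    bad <- occ[occ$cut >= from & occ$cut <= to, , drop = FALSE]
    if (!is.null(protect)) {
      bad <- bad[!(bad$start == protect[1] & bad$end == protect[2]), , drop = FALSE]
    }
    if (nrow(bad) == 0L) return(seq)
    pos <- integer(0)
    for (i in seq_len(nrow(bad))) {
      cand <- bad$start[i]:bad$end[i]
      if (!is.null(protect)) cand <- setdiff(cand, protect[1]:protect[2])
      cand <- cand[cand >= 1L & cand <= nchar(seq)]
      if (length(cand) == 0L)
        stop("cannot scrub a recognition site inside the protected interval")
      pos <- c(pos, cand[ceiling(length(cand) / 2)])
    }
    seq <- substitute_bases(seq, unique(pos))
  }
  stop("site scrubbing did not converge")
}

# Plant one recognition site so that its cut lands exactly at `cut_pos`
# (top-strand coordinate), then scrub any other cut in [from, to] while
# protecting the planted site; verifies the planted cut is the only one left
# in the window.
plant_cut <- function(seq, enz, cut_pos, from, to, strand = "+") {
  len <- nchar(enz$site)
  site <- sample_concrete_site(enz$site)
  if (strand == "+") {
    start <- cut_pos - len - enz$cut_offset + 1L
    ins <- site
  } else {
    start <- cut_pos + enz$cut_offset + 1L
    ins <- revcomp(site)
  }
  stopifnot(start >= 1L, start + len - 1L <= nchar(seq))
  seq <- paste0(substr(seq, 1L, start - 1L), ins,
                substr(seq, start + len, nchar(seq)))
  seq <- scrub_cuts(seq, enz, from, to, protect = c(start, start + len - 1L))
  cuts <- find_sites(seq, enz)
  cuts <- cuts[cuts >= from & cuts <= to]
  if (!identical(cuts, as.integer(cut_pos)))
    stop("planting a recognition site failed to yield a unique cut")
  seq
}

# Resolve IUPAC codes in a recognition sequence to one concrete instance.
sample_concrete_site <- function(site) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(site, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    alts <- strsplit(iupac[[ch]], "", fixed = TRUE)[[1L]]
    sample(alts, 1L)
  }, character(1L)), collapse = "")
}
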