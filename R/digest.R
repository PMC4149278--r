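#' Split a sequence length into restriction fragments
#'
#' @param len Sequence length.
#' @param cuts Sorted cut positions from [find_sites()].
#' @return data.frame with `start`, `end`, `size` (1-based inclusive
#'   fragment intervals).
#' @keywords internal
fragments_from_cuts <- function(len, cuts) {
  b <- c(0L, as.integer(cuts), as.integer(len))
  data.frame(start = b[-length(b)] + 1L, end = b[-1L],
             size = diff(b), stringsAsFactors = FALSE)
}

#' Predict the probe-containing host-provirus junction fragment
#'
#' The junction fragment of an occupied locus runs from the nearest
#' restriction cut in host DNA 5' of the insertion (in the element's reading
#' frame) to the first cut within the element 3' of the probe; its size is
#' what the probe lights up on a blot. The prediction digests a
#' junction-local composite (upstream host within `horizon` + TSD + oriented
#' insert), which also captures recognition sites straddling the junction.
#' For `-` strand loci the computation runs on the reverse-complemented
#' composite.
#'
#' @param panel An `erv_panel`.
#' @param locus_id Locus to predict.
#' @param enz Restriction [enzyme()]; must cut the element outside its 5'LTR
#'   and not within it (see [select_enzymes()]).
#' @param probe_region Length-2 integer vector, probe interval in element
#'   coordinates (defaults to the panel's conserved window).
#' @param allele `"pro"` or `"tandem"` (both share the 5' junction fragment).
#' @param horizon Search horizon (bp) for the nearest upstream host cut;
#'   beyond it the fragment is reported as undetectably large rather than an
#'   error.
#' @return A one-row data.frame: `locus_id`, `allele`, `size` (bp; `NA` when
#'   undetectable), `upstream_cut` (host coordinate of the bounding host cut,
#'   `NA` when undetectable), `downstream_cut` (element coordinate),
#'   `contains_probe`, `undetectable`.
#' @export
predict_junction_fragment <- function(panel, locus_id, enz = default_enzymes()$BsrI,
                                      probe_region = panel$probe_region,
                                      allele = "pro", horizon = 20000L) {
  stopifnot(inherits(panel, "erv_panel"), allele %in% c("pro", "tandem"))
  lc <- panel$loci[panel$loci$locus_id == locus_id, ]
  if (nrow(lc) != 1L) stop("unknown locus: ", locus_id)
  el <- panel$elements[panel$elements$element_id == lc$element_id, ]
  eseq <- panel$element_seqs[[lc$element_id]]

  cuts_el <- find_sites(eseq, enz)
  if (length(cuts_el) == 0L)
    stop("contract violation: enzyme does not cut the element")
  if (any(cuts_el < probe_region[2]))
    stop("contract violation: probe lies 3' of the first internal cut")

  insert <- if (allele == "tandem")
    paste0(substr(eseq, 1L, el$ltr3_start - 1L), eseq) else eseq

  host <- panel$host[[lc$contig]]
  ip <- lc$insertion_point
  tsd <- lc$tsd
  tsd_seq <- if (tsd > 0L) substr(host, ip + 1L, ip + tsd) else ""
  if (lc$strand == "+") {
    host_up <- substr(host, max(1L, ip - horizon + 1L), ip)
  } else {
    seg <- substr(host, ip + tsd + 1L, min(nchar(host), ip + tsd + horizon))
    host_up <- revcomp(seg)
    tsd_seq <- if (tsd > 0L) revcomp(tsd_seq) else ""
    insert <- eseq  # element frame: read 5'->3' along the element
    if (allele == "tandem") insert <- paste0(substr(eseq, 1L, el$ltr3_start - 1L), eseq)
  }
  hh <- nchar(host_up)
  comp <- paste0(host_up, tsd_seq, insert)
  off <- hh + nchar(tsd_seq)
  ps <- off + probe_region[1]
  pe <- off + probe_region[2]

  cuts <- find_sites(comp, enz)
  up <- cuts[cuts < ps]
  down <- cuts[cuts >= pe]
  if (length(down) == 0L)
    stop("contract violation: no cut 3' of the probe in the composite")
  down <- min(down)

  if (length(up) == 0L) {
    return(data.frame(locus_id = locus_id, allele = allele, size = NA_real_,
                      upstream_cut = NA_integer_,
                      downstream_cut = down - off,
                      contains_probe = TRUE, undetectable = TRUE,
                      stringsAsFactors = FALSE))
  }
  up <- max(up)
  upstream_host <- if (up <= hh) {
    if (lc$strand == "+") ip - hh + up else ip + tsd + (hh - up) + 1L
  } else NA_integer_
  data.frame(locus_id = locus_id, allele = allele,
             size = as.numeric(down - up),
             upstream_cut = upstream_host,
             downstream_cut = down - off,
             contains_probe = TRUE, undetectable = FALSE,
             stringsAsFactors = FALSE)
}

#' Predict junction fragments for every panel locus
#'
#' @inheritParams predict_junction_fragment
#' @return data.frame, one row per locus (see [predict_junction_fragment()]).
#' @export
predict_all_fragments <- function(panel, enz, probe_region = panel$probe_region,
                                  horizon = 20000L) {
  out <- lapply(panel$loci$locus_id, function(id)
    predict_junction_fragment(panel, id, enz, probe_region, horizon = horizon))
  do.call(rbind, out)
}

#' Digest realized haplotypes into a band pattern
#'
#' Performs a full virtual digest of every realized regional sequence of one
#' individual, then emits a band for every fragment that contains a probe hit
#' (either strand, up to `max_mismatch` substitutions) and whose size lies in
#' the detectable window. Identical sizes — e.g. the two haplotypes of a
#' proviral homozygote — collapse to a single band, as on a gel lane read for
#' presence/absence.
#'
#' @param regions Named list of character vectors of realized sequences for
#'   one individual (as from [realize_genome()]).
#' @param enz Restriction [enzyme()].
#' @param probe Probe sequence.
#' @param id,group Individual label and group (`case` / `control`).
#' @param max_mismatch Probe mismatch tolerance.
#' @param size_window Length-2 numeric, detectable fragment size range (bp).
#' @return An object of class `erv_band_pattern`: list with `id`, `group`,
#'   `sizes` (distinct band sizes, sorted descending).
#' @export
digest_pattern <- function(regions, enz, probe, id = "ind", group = NA_character_,
                           max_mismatch = 2L, size_window = c(500, 10000)) {
  sizes <- integer(0)
  for (seqs in regions) {
    for (s in seqs) {
      cuts <- find_sites(s, enz)
      frs <- fragments_from_cuts(nchar(s), cuts)
      frs <- frs[frs$size >= size_window[1] & frs$size <= size_window[2], ,
                 drop = FALSE]
      if (nrow(frs) == 0L) next
      hits <- probe_hits(probe, stats::setNames(s, "region"), max_mismatch)
      if (nrow(hits) == 0L) next
      for (i in seq_len(nrow(frs))) {
        if (any(hits$start > frs$start[i] - 1L & hits$end <= frs$end[i]))
          sizes <- c(sizes, frs$size[i])
      }
    }
  }
  structure(list(id = id, group = group,
                 sizes = sort(unique(sizes), decreasing = TRUE)),
            class = "erv_band_pattern")
}

#' @export
print.erv_band_pattern <- function(x, ...) {
  cat(sprintf("<band pattern %s [%s]: %s>\n", x$id, x$group,
              if (length(x$sizes)) paste(x$sizes, collapse = ", ") else "empty"))
  invisible(x)
}
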