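#' Restriction enzyme records
#'
#' An enzyme is a name, an IUPAC recognition sequence, and a top-strand cut
#' offset in bp relative to the *end* of the recognition site: a match at
#' positions `p..p+len-1` cuts the top strand between `p+len-1+offset` and
#' `p+len+offset`. Offsets may be negative (cut inside or upstream of the
#' site) or positive (downstream cutters such as BsrI, ACTGG with offset 1).
#' For a recognition occurrence on the bottom strand the cut coordinate is
#' mirrored onto the top strand.
#'
#' @param name Enzyme name.
#' @param site Recognition sequence, IUPAC codes allowed, length >= 4.
#' @param cut_offset Integer offset as defined above.
#' @return An object of class `erv_enzyme`.
#' @examples
#' bsri <- enzyme("BsrI", "ACTGG", 1L)
#' find_sites("AAACTGGTTTT", bsri)
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition sequence must be at least 4 bp")
  structure(
    list(name = name, site = site, cut_offset = as.integer(cut_offset)),
    class = "erv_enzyme"
  )
}

#' @export
print.erv_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s, cut at site end %+d>\n", x$name, x$site, x$cut_offset))
  invisible(x)
}

#' The default enzyme table
#'
#' BsrI (the enzyme used for the genome-wide digest) plus a few common
#' enzymes used in tests. Equivalent to `read_enzyme_table()` on the shipped
#' `inst/extdata/enzymes.tsv`.
#'
#' @return A named list of [enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(
    BsrI    = enzyme("BsrI", "ACTGG", 1L),
    EcoRI   = enzyme("EcoRI", "GAATTC", -5L),
    BamHI   = enzyme("BamHI", "GGATCC", -5L),
    HindIII = enzyme("HindIII", "AAGCTT", -5L),
    DraI    = enzyme("DraI", "TTTAAA", -3L),
    MboI    = enzyme("MboI", "GATC", -4L)
  )
}

#' Find restriction cut positions in a sequence
#'
#' Recognition matches are located on both strands (IUPAC degeneracy
#' expanded); each occurrence is resolved to a single top-strand cut
#' coordinate. A cut at position `c` severs the bond between bases `c` and
#' `c+1`, so valid cuts satisfy `1 <= c <= nchar(seq) - 1`.
#'
#' @param seq Character scalar or `DNAString` to digest.
#' @param enz An [enzyme()].
#' @return Sorted, deduplicated integer vector of cut positions (possibly
#'   empty).
#' @export
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "erv_enzyme"))
  subject <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  n <- length(subject)
  len <- nchar(enz$site)
  off <- enz$cut_offset

  pat <- Biostrings::DNAString(enz$site)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = FALSE))
  cuts <- fwd + len + off - 1L

  rc <- Biostrings::reverseComplement(pat)
  rev <- Biostrings::start(Biostrings::matchPattern(rc, subject, fixed = FALSE))
  cuts <- c(cuts, rev - off - 1L)

  cuts <- cuts[cuts >= 1L & cuts <= n - 1L]
  sort(unique(as.integer(cuts)))
}

#' Select enzymes cutting the provirus body but not its 5'LTR
#'
#' Screens an enzyme table for enzymes predicted to cut at least once within
#' the proviral element outside the 5'LTR, and never within the 5'LTR — the
#' constraint that keeps the probe-containing junction fragment anchored at
#' the 5' host-provirus junction.
#'
#' @param element_seq Proviral element sequence (character).
#' @param ltr5 Integer length-2 vector, 1-based inclusive 5'LTR interval.
#' @param enzyme_db List of [enzyme()] objects.
#' @return The subset of `enzyme_db` passing the constraint (possibly empty).
#' @export
select_enzymes <- function(element_seq, ltr5, enzyme_db) {
  stopifnot(length(ltr5) == 2L, ltr5[1] >= 1L, ltr5[2] <= nchar(element_seq),
            ltr5[1] < ltr5[2])
  subject <- Biostrings::DNAString(element_seq)
  keep <- vapply(enzyme_db, function(enz) {
    cuts <- find_sites(subject, enz)
    # a cut at c severs LTR-internal bonds when ltr_start <= c < ltr_end
    in_ltr <- cuts >= ltr5[1] & cuts < ltr5[2]
    any(!in_ltr) && !any(in_ltr)
  }, logical(1L))
  enzyme_db[keep]
}
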