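#' Percent identity between two aligned rows
#'
#' Computed over shared non-gap columns: columns where either row has a gap
#' (`-`) are skipped; identity is 100 * matches / shared columns.
#'
#' @param a,b Equal-length aligned sequences (character scalars).
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  shared <- ca != "-" & cb != "-"
  if (!any(shared)) return(NA_real_)
  100 * sum(ca[shared] == cb[shared]) / sum(shared)
}

#' Rank aligned proviral elements by identity to a reference
#'
#' Sorts the rows of an alignment by decreasing nucleotide identity to a
#' designated reference element, the first step of probe selection: the most
#' recent germline integrations surface at the top.
#'
#' @param alignment Named character vector (or `DNAStringSet`) of equal-length
#'   aligned rows; gaps as `-`.
#' @param reference_id Name of the reference row.
#' @return data.frame with columns `element_id`, `identity`, in descending
#'   identity order (ties broken by element id, so the order is invariant
#'   under input shuffling); the reference is first at 100.
#' @export
rank_by_identity <- function(alignment, reference_id) {
  alignment <- as_aligned_rows(alignment)
  if (!reference_id %in% names(alignment))
    stop("reference element not found: ", reference_id)
  ref <- alignment[[reference_id]]
  idt <- vapply(alignment, percent_identity, numeric(1L), b = ref)
  out <- data.frame(element_id = names(alignment), identity = unname(idt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$element_id != reference_id, out$element_id), ]
  rownames(out) <- NULL
  out
}

#' Locate conserved candidate probe windows near the 5'LTR
#'
#' Scans every length-`L` window of an alignment lying strictly 3' of the
#' 5'LTR and within `max_ltr_distance` bp of its end, scoring each window by:
#' \itemize{
#'   \item `recent_score` — mean pairwise identity among the `recent_k`
#'     highest-identity rows over the window (in \[0, 1\]);
#'   \item `older_max_identity` — maximum identity of the recent-subset
#'     consensus window against any remaining (older) row;
#'   \item `distance` — bp between the 5'LTR end and the window start.
#' }
#' Candidates are ranked by recent conservation descending, older-subset
#' identity ascending, distance ascending, ties broken by leftmost column.
#' Gap characters never match. This is the probe-selection rule: highly
#' similar among recent integrations, distinct from older proviruses,
#' proximal to but outside the 5'LTR.
#'
#' @param alignment Named character vector of equal-length aligned rows,
#'   already ordered or orderable by [rank_by_identity()].
#' @param reference_id Reference row used to define the recent subset.
#' @param ltr5_end Alignment column of the last 5'LTR base.
#' @param recent_k Size of the recent subset (must be < number of rows).
#' @param L Window length (bp), >= 8.
#' @param max_ltr_distance Windows must end within this many bp 3' of the
#'   5'LTR end.
#' @return data.frame of candidates (`start`, `end`, `distance`,
#'   `recent_score`, `older_max_identity`, `probe` — the recent-subset
#'   consensus sequence), best first; zero rows if no window qualifies.
#' @export
find_conserved_window <- function(alignment, reference_id, ltr5_end,
                                  recent_k = 25L, L = 32L,
                                  max_ltr_distance = 2000L) {
  alignment <- as_aligned_rows(alignment)
  if (L < 8L) stop("window length must be >= 8")
  if (recent_k >= length(alignment))
    stop("recent_k must be smaller than the number of rows")

  ranked <- rank_by_identity(alignment, reference_id)
  recent_ids <- ranked$element_id[seq_len(recent_k)]
  older_ids <- setdiff(ranked$element_id, recent_ids)

  widths <- nchar(unlist(alignment))
  if (length(unique(widths)) != 1L)
    stop("alignment rows must all have the same length")
  ncol <- widths[[1L]]
  lo <- ltr5_end + 1L
  hi <- min(ncol, ltr5_end + max_ltr_distance) - L + 1L
  if (hi < lo) return(empty_candidates())
  starts <- lo:hi

  mat <- do.call(rbind, strsplit(toupper(unlist(alignment)), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  recent <- mat[recent_ids, , drop = FALSE]

  # column-wise count of matching recent pairs (gaps never match)
  k <- length(recent_ids)
  npairs <- k * (k - 1L) / 2L
  col_pair_matches <- numeric(ncol)
  for (b in DNA_BASES) {
    cnt <- colSums(recent == b)
    col_pair_matches <- col_pair_matches + cnt * (cnt - 1L) / 2L
  }
  csum <- c(0, cumsum(col_pair_matches))
  recent_score <- (csum[starts + L] - csum[starts]) / (L * npairs)

  # recent-subset consensus (majority base per column, gaps excluded)
  cons <- consensus_rows(recent)

  if (length(older_ids) > 0L) {
    older <- mat[older_ids, , drop = FALSE]
    match_older <- t(older) == cons & cons != "-"  # ncol x n_older
    mcs <- rbind(0, apply(match_older, 2L, cumsum))
    win_id <- (mcs[starts + L, , drop = FALSE] - mcs[starts, , drop = FALSE]) / L
    older_max <- apply(win_id, 1L, max)
  } else {
    older_max <- rep(0, length(starts))
  }

  distance <- starts - ltr5_end - 1L
  probe <- vapply(starts, function(s) paste(cons[s:(s + L - 1L)], collapse = ""),
                  character(1L))
  out <- data.frame(start = starts, end = starts + L - 1L, distance = distance,
                    recent_score = recent_score, older_max_identity = older_max,
                    probe = probe, stringsAsFactors = FALSE)
  out <- out[!grepl("-", out$probe, fixed = TRUE), , drop = FALSE]
  if (nrow(out) == 0L) return(empty_candidates())
  out <- out[order(-out$recent_score, out$older_max_identity,
                   out$distance, out$start), ]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(start = integer(0), end = integer(0), distance = integer(0),
             recent_score = numeric(0), older_max_identity = numeric(0),
             probe = character(0), stringsAsFactors = FALSE)
}

# Majority base per column over a character matrix; gap only when a column
# is all gaps.
consensus_rows <- function(mat) {
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    tb <- table(col)
    names(tb)[which.max(tb)]
  })
}

#' Find all hits of a probe in a genome under a mismatch tolerance
#'
#' Ungapped scan of both strands of every contig for windows within Hamming
#' distance `max_mismatch` of the probe (substitutions only — no indels). A
#' `-` strand hit means the reverse complement of the probe occurs at the
#' reported top-strand interval.
#'
#' @param probe Probe sequence (character, >= 8 nt).
#' @param genome Named character vector of contigs (or `DNAStringSet`).
#' @param max_mismatch Maximum number of substitutions (>= 0).
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `mismatches`; zero rows when nothing matches.
#' @export
probe_hits <- function(probe, genome, max_mismatch = 2L) {
  stopifnot(nchar(probe) >= 8L, max_mismatch >= 0L)
  genome <- as_aligned_rows(genome)
  pats <- list(`+` = probe, `-` = revcomp(probe))
  res <- list()
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    if (nchar(probe) > length(subject)) next
    for (strand in names(pats)) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(pats[[strand]]),
                                    subject, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      segs <- as.character(m)
      mism <- vapply(segs, hamming, integer(1L), b = pats[[strand]])
      res[[length(res) + 1L]] <- data.frame(
        contig = ctg, start = Biostrings::start(m), end = Biostrings::end(m),
        strand = strand, mismatches = as.integer(mism),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Coerce DNAStringSet / list / character vector to a named character vector.
as_aligned_rows <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.list(x)) {
    out <- unlist(x)
  } else {
    out <- x
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    names(out) <- sprintf("seq%03d", seq_along(out))
  stopifnot(length(unique(nchar(out))) >= 1L)
  as.list(out)
}
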