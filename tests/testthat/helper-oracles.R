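# Independent oracles used to cross-check the implementation. These are
# deliberately written with base-R string handling (regex scans, explicit
# loops) rather than the package's Biostrings-based routines.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# All start positions of a fixed pattern (overlaps allowed), via lookahead.
oracle_matches <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Top-strand cut positions of an enzyme with a fixed (non-degenerate)
# recognition sequence; mirrors the documented cut model.
oracle_cuts <- function(seq, site, offset) {
  len <- nchar(site)
  fwd <- oracle_matches(seq, site) + len + offset - 1L
  rev <- oracle_matches(seq, oracle_revcomp(site)) - offset - 1L
  cuts <- c(fwd, rev)
  sort(unique(cuts[cuts >= 1L & cuts <= nchar(seq) - 1L]))
}

# Digest a realized haplotype and return the size(s) of fragments containing
# the probe (matched by exact sequence on either strand).
oracle_probe_fragments <- function(seq, site, offset, probe) {
  cuts <- oracle_cuts(seq, site, offset)
  b <- c(0L, cuts, nchar(seq))
  hits <- c(oracle_matches(seq, probe), oracle_matches(seq, oracle_revcomp(probe)))
  sizes <- integer(0)
  for (h in hits) {
    lo <- h
    hi <- h + nchar(probe) - 1L
    for (i in seq_len(length(b) - 1L)) {
      if (lo > b[i] && hi <= b[i + 1L]) sizes <- c(sizes, b[i + 1L] - b[i])
    }
  }
  sort(unique(sizes))
}

# Brute-force percent identity over shared non-gap columns.
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n_shared <- 0L
  n_match <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] != "-" && cb[i] != "-") {
      n_shared <- n_shared + 1L
      if (ca[i] == cb[i]) n_match <- n_match + 1L
    }
  }
  100 * n_match / n_shared
}

# Exhaustive window enumeration under the declared probe scoring: recent
# mean pairwise identity (desc), older max identity vs recent consensus
# (asc), distance from the 5'LTR end (asc), leftmost start.
oracle_window_scan <- function(rows, reference_id, ltr5_end, recent_k, L,
                               max_ltr_distance) {
  ids <- names(rows)
  idt <- vapply(ids, function(i) oracle_identity(rows[[i]], rows[[reference_id]]),
                numeric(1L))
  ord <- ids[order(-idt, ids != reference_id, ids)]
  recent <- ord[seq_len(recent_k)]
  older <- setdiff(ord, recent)
  ncol <- nchar(rows[[1L]])
  out <- NULL
  for (s in seq_len(ncol)) {
    e <- s + L - 1L
    if (s <= ltr5_end || e > min(ncol, ltr5_end + max_ltr_distance)) next
    wins <- lapply(rows, function(r) strsplit(substr(r, s, e), "", fixed = TRUE)[[1L]])
    # mean pairwise identity in the recent subset; gaps never match.
    # integer match count over all pairs, divided once, so the score is the
    # same rational number the implementation computes
    tot <- 0L
    np <- 0L
    for (i in seq_len(recent_k - 1L)) {
      for (j in (i + 1L):recent_k) {
        a <- wins[[recent[i]]]
        b <- wins[[recent[j]]]
        tot <- tot + sum(a == b & a != "-")
        np <- np + 1L
      }
    }
    score <- tot / (np * L)
    cons <- character(L)
    for (k in seq_len(L)) {
      col <- vapply(recent, function(i) wins[[i]][k], character(1L))
      col <- col[col != "-"]
      cons[k] <- if (length(col) == 0L) "-" else names(which.max(table(col)))
    }
    if (any(cons == "-")) next
    omax <- 0
    for (o in older) omax <- max(omax, sum(wins[[o]] == cons) / L)
    if (length(older) == 0L) omax <- 0
    out <- rbind(out, data.frame(start = s, distance = s - ltr5_end - 1L,
                                 recent_score = score, older_max = omax,
                                 probe = paste(cons, collapse = ""),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(out)
  out[order(-out$recent_score, out$older_max, out$distance, out$start), ]
}

# Observed-vs-expected chi-square for a 2x2 table.
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# Small fixture panel shared by several tests (built once per test run).
fixture_panel <- function(n_loci = 4, seed = 42, ...) {
  make_reference_panel(n_elements = 8, n_loci = n_loci, n_recent = 4,
                       seed = seed, ...)
}
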