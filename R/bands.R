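#' Construct a band pattern from observed sizes
#'
#' Builds the same structure [digest_pattern()] emits, e.g. for band sizes
#' read off a real gel.
#'
#' @param id Individual label.
#' @param group Group label (`case` / `control`).
#' @param sizes Numeric band sizes (bp); deduplicated and sorted descending.
#' @return An `erv_band_pattern`.
#' @export
band_pattern <- function(id, group, sizes) {
  structure(list(id = id, group = group,
                 sizes = sort(unique(as.numeric(sizes)), decreasing = TRUE)),
            class = "erv_band_pattern")
}

#' Collate per-individual band patterns into cross-cohort clusters
#'
#' Pools all detected band sizes across lanes and clusters them by
#' single-linkage on log size: two bands link when their sizes differ by at
#' most `rel_tolerance` relatively (|log ratio| <= log(1 + rel_tolerance)).
#' In one dimension this is a cut of the sorted sizes at gaps exceeding the
#' tolerance. The cluster representative is the median member size. Every
#' input band belongs to exactly one cluster; an individual is counted at
#' most once per cluster. Clusters spanning more than twice the tolerance
#' (chaining) are flagged `wide`.
#'
#' @param patterns List of `erv_band_pattern` objects ([digest_pattern()]).
#' @param rel_tolerance Relative size tolerance, in (0, 0.2\]; default 0.02
#'   approximates agarose gel sizing precision.
#' @return An object of class `erv_band_clusters`: list with `clusters`
#'   (data.frame: cluster_id, representative, n_bands, n_individuals, wide)
#'   and `members` (data.frame: cluster_id, id, group, size).
#' @export
collate_bands <- function(patterns, rel_tolerance = 0.02) {
  stopifnot(rel_tolerance > 0, rel_tolerance <= 0.2)
  rows <- lapply(patterns, function(p) {
    if (length(p$sizes) == 0L) return(NULL)
    data.frame(id = p$id, group = p$group, size = as.numeric(p$sizes),
               stringsAsFactors = FALSE)
  })
  bands <- do.call(rbind, rows)
  if (is.null(bands) || nrow(bands) == 0L) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(0), representative = numeric(0),
                            n_bands = integer(0), n_individuals = integer(0),
                            wide = logical(0)),
      members = data.frame(cluster_id = integer(0), id = character(0),
                           group = character(0), size = numeric(0))),
      class = "erv_band_clusters"))
  }
  bands <- bands[order(bands$size), ]
  gap <- diff(log(bands$size)) > log(1 + rel_tolerance)
  bands$cluster_id <- cumsum(c(1L, as.integer(gap)))

  agg <- lapply(split(bands, bands$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1L],
               representative = stats::median(d$size),
               n_bands = nrow(d),
               n_individuals = length(unique(d$id)),
               wide = max(d$size) / min(d$size) > (1 + rel_tolerance)^2,
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, agg)
  rownames(clusters) <- rownames(bands) <- NULL
  structure(list(clusters = clusters,
                 members = bands[, c("cluster_id", "id", "group", "size")]),
            class = "erv_band_clusters")
}

#' @export
print.erv_band_clusters <- function(x, ...) {
  cat(sprintf("<band clusters: %d clusters from %d bands>\n",
              nrow(x$clusters), nrow(x$members)))
  invisible(x)
}

#' Classify band clusters against predictions and PCR calls
#'
#' A cluster is assigned to a known locus when its representative size
#' matches that locus's predicted junction-fragment size within the relative
#' tolerance *and*, when PCR calls are supplied, the set of individuals
#' showing the band equals the locus's PCR carrier set — the dual evidence
#' used to anchor bands to annotated proviruses. A size match with
#' discordant carriers, or a size matching two predictions, is `ambiguous`.
#' Anything else is `novel`: a candidate undescribed polymorphic insertion.
#'
#' @param collated An `erv_band_clusters` from [collate_bands()].
#' @param predictions data.frame with `locus_id` and `size` (bp) of predicted
#'   probe-containing fragments; rows with `NA` size are ignored.
#' @param pcr_carriers Optional data.frame with `id`, `locus_id`, `carrier`
#'   (logical) from PCR genotyping.
#' @param rel_tolerance Relative size tolerance.
#' @return `collated` with a `clusters$classification` column
#'   (`known` / `novel` / `ambiguous`) and `clusters$locus_id` (`NA` unless
#'   known).
#' @export
classify_clusters <- function(collated, predictions, pcr_carriers = NULL,
                              rel_tolerance = 0.02) {
  stopifnot(inherits(collated, "erv_band_clusters"))
  preds <- predictions[!is.na(predictions$size), , drop = FALSE]
  cl <- collated$clusters
  cl$classification <- "novel"
  cl$locus_id <- NA_character_
  for (i in seq_len(nrow(cl))) {
    hit <- abs(log(cl$representative[i] / preds$size)) <= log(1 + rel_tolerance)
    n_hit <- sum(hit)
    if (n_hit == 0L) next
    if (n_hit > 1L) { cl$classification[i] <- "ambiguous"; next }
    locus <- preds$locus_id[hit]
    if (!is.null(pcr_carriers)) {
      band_ids <- unique(collated$members$id[collated$members$cluster_id ==
                                               cl$cluster_id[i]])
      pcr_ids <- pcr_carriers$id[pcr_carriers$locus_id == locus &
                                   pcr_carriers$carrier]
      if (!setequal(band_ids, pcr_ids)) {
        cl$classification[i] <- "ambiguous"
        next
      }
    }
    cl$classification[i] <- "known"
    cl$locus_id[i] <- locus
  }
  collated$clusters <- cl
  collated
}

#' Per-cluster case-control presence counts
#'
#' Counts, per cluster and group, the individuals showing at least one member
#' band, and derives carrier frequencies — the 2x2 tables feeding the
#' association scan for bands.
#'
#' @param collated An `erv_band_clusters` (classified or not).
#' @param individuals data.frame with `id` and `group` for every cohort
#'   member (bands or not), so absences count.
#' @return data.frame: `cluster_id`, `representative`, `case_pos`, `case_n`,
#'   `ctrl_pos`, `ctrl_n`, `case_freq`, `ctrl_freq` (plus `classification` /
#'   `locus_id` when present).
#' @export
cluster_frequencies <- function(collated, individuals) {
  stopifnot(inherits(collated, "erv_band_clusters"),
            all(c("id", "group") %in% names(individuals)))
  n_case <- sum(individuals$group == "case")
  n_ctrl <- sum(individuals$group == "control")
  cl <- collated$clusters
  out <- lapply(seq_len(nrow(cl)), function(i) {
    mem <- collated$members[collated$members$cluster_id == cl$cluster_id[i], ]
    ids <- unique(mem$id)
    grp <- individuals$group[match(ids, individuals$id)]
    data.frame(cluster_id = cl$cluster_id[i],
               representative = cl$representative[i],
               case_pos = sum(grp == "case"), case_n = n_case,
               ctrl_pos = sum(grp == "control"), ctrl_n = n_ctrl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(out)
  out$case_freq <- out$case_pos / out$case_n
  out$ctrl_freq <- out$ctrl_pos / out$ctrl_n
  if (!is.null(cl$classification)) {
    out$classification <- cl$classification
    out$locus_id <- cl$locus_id
  }
  out
}
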