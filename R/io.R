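#' Read a FASTA file into a named character vector
#'
#' Sequences are normalized to uppercase; line wrapping and mixed case are
#' accepted. Backed by `Biostrings::readDNAStringSet`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a data.frame as tab-separated values
#'
#' Header row, no quoting, no row names — the package's universal tabular
#' dialect. Coordinates in all tables are 1-based inclusive.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with schema validation
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L)
      stop(sprintf("%s: missing required column(s): %s",
                   path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a locus table
#'
#' Columns: `locus_id`, `contig`, `insertion_point` (1-based), `strand`,
#' `element_id`, `repertoire` (comma-separated subset of pro,solo,tandem,pre),
#' `tsd`. When `host` is supplied, insertion points are validated against
#' contig bounds and offending loci are named.
#'
#' @param path File path.
#' @param host Optional named character vector of host contigs.
#' @return data.frame.
#' @export
read_locus_table <- function(path, host = NULL) {
  df <- read_tsv(path, required = c("locus_id", "contig", "insertion_point",
                                    "strand", "element_id", "repertoire", "tsd"))
  if (!is.null(host)) {
    bad <- !df$contig %in% names(host) |
      df$insertion_point < 1 | df$insertion_point > nchar(host[df$contig])
    if (any(bad))
      stop("locus table validation failed for: ",
           paste(df$locus_id[bad], collapse = ", "))
  }
  df
}

#' Read an enzyme table
#'
#' Columns: `name`, `site` (IUPAC), `cut_offset` (bp relative to recognition
#' end; see [enzyme()]). The shipped table is at
#' `system.file("extdata", "enzymes.tsv", package = "ervscreen")`.
#'
#' @param path File path.
#' @return Named list of [enzyme()] objects.
#' @export
read_enzyme_table <- function(path) {
  df <- read_tsv(path, required = c("name", "site", "cut_offset"))
  out <- lapply(seq_len(nrow(df)), function(i)
    enzyme(df$name[i], df$site[i], df$cut_offset[i]))
  stats::setNames(out, df$name)
}

#' Read a primer table
#'
#' Columns: `locus_id`, `forward`, `reverse_I`, `reverse_II`, `size_I`,
#' `size_II_solo`, `size_II_pre` — set I spans the 5'LTR junction, set II
#' spans the integration site with solo/pre dual expected sizes.
#'
#' @param path File path.
#' @return Named list of `erv_primer_set` objects.
#' @export
read_primer_table <- function(path) {
  df <- read_tsv(path, required = c("locus_id", "forward", "reverse_I",
                                    "reverse_II", "size_I", "size_II_solo",
                                    "size_II_pre"))
  bad <- df$size_II_solo <= df$size_II_pre
  if (any(bad))
    stop("primer table: size_II_solo must exceed size_II_pre for: ",
         paste(df$locus_id[bad], collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    structure(as.list(df[i, ]), class = "erv_primer_set"))
  stats::setNames(out, df$locus_id)
}

#' Serialize a reference panel to a directory
#'
#' Writes `host.fasta`, `elements.fasta`, `elements.tsv`, `loci.tsv` and
#' `panel.tsv` (probe region and enzyme name). Round-trips through
#' [read_panel()].
#'
#' @param panel An `erv_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "erv_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(panel$host, file.path(dir, "host.fasta"))
  write_fasta(panel$element_seqs, file.path(dir, "elements.fasta"))
  write_tsv(panel$elements, file.path(dir, "elements.tsv"))
  write_tsv(panel$loci, file.path(dir, "loci.tsv"))
  write_tsv(data.frame(probe_start = panel$probe_region[1],
                       probe_end = panel$probe_region[2],
                       enzyme_name = panel$enzyme_name),
            file.path(dir, "panel.tsv"))
  invisible(dir)
}

#' Read a reference panel from a directory written by [write_panel()]
#'
#' @param dir Directory path.
#' @return An `erv_panel`.
#' @export
read_panel <- function(dir) {
  host <- read_fasta(file.path(dir, "host.fasta"))
  element_seqs <- read_fasta(file.path(dir, "elements.fasta"))
  elements <- read_tsv(file.path(dir, "elements.tsv"),
                       required = c("element_id", "identity", "ltr5_start",
                                    "ltr5_end", "ltr3_start", "ltr3_end"))
  loci <- read_locus_table(file.path(dir, "loci.tsv"), host = host)
  meta <- read_tsv(file.path(dir, "panel.tsv"),
                   required = c("probe_start", "probe_end", "enzyme_name"))
  panel <- structure(
    list(host = host, element_seqs = element_seqs, elements = elements,
         loci = loci,
         probe_region = c(meta$probe_start[1], meta$probe_end[1]),
         enzyme_name = meta$enzyme_name[1]),
    class = "erv_panel"
  )
  validate_panel(panel)
  panel
}

#' Write a cohort's genotype matrix
#'
#' Long format: `id`, `group`, `locus_id`, `hap1`, `hap2`.
#'
#' @param cohort An `erv_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(cohort, path) {
  stopifnot(inherits(cohort, "erv_cohort"))
  write_tsv(cohort$genotypes, path)
}
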