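#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
#' @importFrom stats median pchisq qnorm rbinom runif
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; used by the synthetic panel generator for host
#' contigs and proviral element bodies.
#'
#' @param n Sequence length (bp).
#' @return A single uppercase character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param x Character scalar (A/C/G/T, IUPAC codes allowed).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Substitute bases at given positions
#'
#' Each listed position is replaced by a base drawn uniformly from the three
#' alternatives, so every substitution is a real change.
#'
#' @param seq Character scalar.
#' @param pos Integer vector of 1-based positions to mutate.
#' @return Mutated sequence.
#' @keywords internal
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Apply random substitutions at a per-bp rate
#'
#' @param seq Character scalar.
#' @param rate Per-bp substitution probability in \[0, 1\].
#' @return Mutated sequence (uses the current RNG stream).
#' @keywords internal
apply_snps <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  substitute_bases(seq, sample.int(n, k))
}

#' Hamming distance between equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Derive a stage seed from a top-level run seed
#'
#' All randomness in a pipeline run flows from one seed, fanned out per stage
#' so stages are independently reproducible. Kept within 32-bit integer range.
#'
#' @param seed Top-level integer seed.
#' @param stage Small non-negative integer stage index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 999983 * as.numeric(stage)) %% 2147483647)
}
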