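test_that("identity ranking matches brute-force pairwise scoring", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  row <- paste(rep("A", 100), collapse = "")
  row1 <- sub("A$", "C", row)
  expect_equal(percent_identity(row, row1), 99)
  # gapped columns are excluded from the shared denominator
  expect_equal(percent_identity("AC-T", "ACGT"), 100)

  set.seed(8)
  rows <- vapply(1:12, function(i) {
    n_mut <- sample(0:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    s
  }, character(1L))
  base <- rows[1]
  rows <- vapply(rows, function(s) {
    pos <- sample(200, sample(0:60, 1))
    chars <- strsplit(base, "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  }, character(1L))
  names(rows) <- sprintf("e%02d", seq_along(rows))
  rows["e01"] <- base

  ranked <- rank_by_identity(rows, "e01")
  expect_equal(ranked$element_id[1], "e01")
  expect_equal(ranked$identity[1], 100)
  oracle <- vapply(rows, oracle_identity, numeric(1), b = base)
  expect_equal(ranked$identity,
               unname(oracle[ranked$element_id]))
  expect_equal(ranked$identity, sort(ranked$identity, decreasing = TRUE))

  # order invariant under shuffling
  shuffled <- rows[sample(length(rows))]
  expect_equal(rank_by_identity(shuffled, "e01"), ranked)
})

test_that("ranking with an absent reference is a lookup error", {
  expect_error(rank_by_identity(c(a = "ACGT", b = "ACGA"), "zz"), "not found")
})

test_that("a window conserved in recent rows and diverged in older rows ranks first", {
  set.seed(5)
  ltr_end <- 40L
  L <- 10L
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  win <- 61:70
  recent <- lapply(1:4, function(i) {
    pos <- setdiff(sample(200, 30), c(win, 1:40))
    substitute <- strsplit(base, "")[[1]]
    for (p in pos) substitute[p] <- sample(setdiff(c("A", "C", "G", "T"), substitute[p]), 1)
    paste(substitute, collapse = "")
  })
  older <- lapply(1:3, function(i) {
    pos <- unique(c(win[c(2, 5, 8)], sample(200, 40)))
    substitute <- strsplit(base, "")[[1]]
    for (p in pos) substitute[p] <- sample(setdiff(c("A", "C", "G", "T"), substitute[p]), 1)
    paste(substitute, collapse = "")
  })
  rows <- c(base, recent, older)
  names(rows) <- sprintf("r%d", seq_along(rows))
  rows <- unlist(rows)

  cand <- find_conserved_window(rows, "r1", ltr5_end = ltr_end, recent_k = 5,
                                L = L, max_ltr_distance = 160)
  expect_gt(nrow(cand), 0)
  # the protected window is perfectly conserved in the recent subset; windows
  # overlapping it tie at score 1 and are ordered by the declared tie-breaks
  expect_equal(cand$recent_score[1], 1)
  expect_true(61L %in% cand$start[cand$recent_score == 1])
  # no candidate overlaps the 5'LTR and all lie within the distance cap
  expect_true(all(cand$start > ltr_end))
  expect_true(all(cand$end <= ltr_end + 160))
  expect_true(all(cand$distance == cand$start - ltr_end - 1L))

  # full ranking agrees with exhaustive enumeration
  oracle <- oracle_window_scan(as.list(rows), "r1", ltr_end, 5L, L, 160L)
  expect_equal(cand$start, oracle$start)
  expect_equal(cand$recent_score, oracle$recent_score, tolerance = 1e-12)
  expect_equal(cand$older_max_identity, oracle$older_max, tolerance = 1e-12)
  expect_equal(cand$probe[1], oracle$probe[1])
})

test_that("window scan returns an empty frame when nothing qualifies", {
  rows <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTTTTTTT")
  out <- find_conserved_window(rows, "a", ltr5_end = 8L, recent_k = 2, L = 8)
  expect_equal(nrow(out), 0)
})

test_that("probe hits recover planted copies up to the mismatch threshold", {
  set.seed(14)
  probe <- paste(sample(c("A", "C", "G", "T"), 32, replace = TRUE), collapse = "")
  genome <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")

  plant <- function(genome, seq, at) {
    paste0(substr(genome, 1, at - 1), seq, substr(genome, at + nchar(seq), nchar(genome)))
  }
  mutate_n <- function(seq, k) {
    chars <- strsplit(seq, "")[[1]]
    for (p in sample(nchar(seq), k))
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    paste(chars, collapse = "")
  }

  # ledger of planted copies: position, strand, substitutions
  ledger <- data.frame(at = seq(1000, 19000, by = 2000),
                       strand = rep(c("+", "-"), 5),
                       subs = c(0, 1, 2, 0, 2, 1, 0, 2, 1, 0))
  for (i in seq_len(nrow(ledger))) {
    copy <- mutate_n(probe, ledger$subs[i])
    if (ledger$strand[i] == "-") copy <- oracle_revcomp(copy)
    genome <- plant(genome, copy, ledger$at[i])
  }
  hits <- probe_hits(probe, c(chr = genome), max_mismatch = 2)
  found <- hits[hits$start %in% ledger$at, ]
  expect_equal(nrow(found), nrow(ledger))  # all 10 recovered
  found <- found[order(found$start), ]
  expect_equal(found$mismatches, ledger$subs)
  expect_equal(found$strand, ledger$strand)

  # a copy with 3 substitutions is not reported at max_mismatch = 2
  g3 <- plant(genome, mutate_n(probe, 3), 500)
  hits3 <- probe_hits(probe, c(chr = g3), max_mismatch = 2)
  expect_false(500 %in% hits3$start)
  expect_equal(nrow(probe_hits(probe, c(chr = substr(genome, 1, 10)), 2)), 0)
})

test_that("probe hits are strand-symmetric under genome reverse complement", {
  set.seed(15)
  probe <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  genome <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  genome <- paste0(substr(genome, 1, 999), probe, substr(genome, 1020, 5000))
  h1 <- probe_hits(probe, c(chr = genome), max_mismatch = 1)
  h2 <- probe_hits(probe, c(chr = oracle_revcomp(genome)), max_mismatch = 1)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$mismatches), sort(h2$mismatches))
  # positions mirror: start' = len - end + 1
  expect_setequal(nchar(genome) - h1$end + 1L, h2$start)
})
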