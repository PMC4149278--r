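# Hand-built miniature panel on homopolymer background: every cut position
# is placed explicitly, so fragment sizes are known by construction.
toy_panel <- function(D = 500L, internal_cut = 1200L, strand = "+",
                      host_len = 3000L, ip = 1500L, elem_len = 2000L,
                      tsd = 0L, plant_host_cut = TRUE) {
  put <- function(seq, piece, at)
    paste0(substr(seq, 1L, at - 1L), piece, substr(seq, at + nchar(piece), nchar(seq)))
  host <- strrep("A", host_len)
  if (plant_host_cut) {
    if (strand == "+") host <- put(host, "ACTGG", ip - D - 5L)   # cut at ip - D
    else host <- put(host, "CCAGT", ip + D + 2L)                 # cut at ip + D
  }
  elem <- strrep("A", elem_len)
  elem <- put(elem, strrep("C", 32L), 900L)                      # probe window
  elem <- put(elem, "ACTGG", internal_cut - 5L)                  # cut at internal_cut
  structure(list(
    host = c(ctg = host),
    element_seqs = c(elemX = elem),
    elements = data.frame(element_id = "elemX", identity = 100,
                          ltr5_start = 1L, ltr5_end = 100L,
                          ltr3_start = elem_len - 99L, ltr3_end = elem_len,
                          stringsAsFactors = FALSE),
    loci = data.frame(locus_id = "toy", contig = "ctg", insertion_point = ip,
                      strand = strand, element_id = "elemX",
                      repertoire = "pro,solo,tandem,pre", tsd = tsd,
                      stringsAsFactors = FALSE),
    probe_region = c(900L, 931L), enzyme_name = "BsrI"), class = "erv_panel")
}

bsri <- default_enzymes()$BsrI

test_that("cut positions follow the recognition + offset model on both strands", {
  seq200 <- strrep("T", 200)
  expect_identical(find_sites(seq200, bsri), integer(0))
  # top-strand ACTGG at 100..104, offset +1: cut between 105 and 106
  s <- paste0(strrep("T", 99), "ACTGG", strrep("T", 96))
  expect_identical(find_sites(s, bsri), 105L)
  expect_identical(oracle_cuts(s, "ACTGG", 1L), 105L)
  # bottom-strand site (CCAGT on top) mirrors the cut upstream
  s2 <- paste0(strrep("T", 99), "CCAGT", strrep("T", 96))
  expect_identical(find_sites(s2, bsri), 98L)
  expect_identical(oracle_cuts(s2, "ACTGG", 1L), 98L)
})

test_that("palindromic-site digestion mirrors under reverse complement", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  ecori <- default_enzymes()$EcoRI
  c1 <- find_sites(s, ecori)
  c2 <- find_sites(oracle_revcomp(s), ecori)
  expect_identical(sort(nchar(s) - c1), c2)
})

test_that("IUPAC degeneracy in recognition sequences is expanded", {
  hinfi <- enzyme("HinfI", "GANTC", -4L)  # G^ANTC, IUPAC-palindromic
  s <- paste0(strrep("T", 50), "GATTC", strrep("T", 20), "GACTC", strrep("T", 25))
  # each occurrence is seen on both strands: top cut G^ANTC plus the
  # bottom-strand cut mirrored 3 bp downstream
  expect_identical(find_sites(s, hinfi), c(51L, 54L, 76L, 79L))
})

test_that("enzyme selection keeps body cutters and rejects 5'LTR cutters", {
  put <- function(seq, piece, at)
    paste0(substr(seq, 1, at - 1), piece, substr(seq, at + nchar(piece), nchar(seq)))
  elem <- strrep("A", 300)
  ltr <- c(1L, 100L)
  body_cutter <- put(elem, "GAATTC", 150)   # EcoRI cut at 150 (body)
  ltr_cutter <- put(elem, "GAATTC", 40)     # EcoRI cut at 40 (inside LTR)
  both <- put(body_cutter, "GAATTC", 40)
  db <- default_enzymes()
  expect_named(select_enzymes(body_cutter, ltr, db["EcoRI"]), "EcoRI")
  expect_length(select_enzymes(ltr_cutter, ltr, db["EcoRI"]), 0)
  expect_length(select_enzymes(both, ltr, db["EcoRI"]), 0)
  expect_length(select_enzymes(elem, ltr, db["EcoRI"]), 0)  # no cut anywhere
  expect_length(select_enzymes(body_cutter, ltr, list()), 0)
})

test_that("junction fragment size is host distance plus first internal cut", {
  panel <- toy_panel(D = 500L, internal_cut = 1200L)
  fr <- predict_junction_fragment(panel, "toy", bsri)
  expect_equal(fr$size, 500 + 1200)
  expect_equal(fr$upstream_cut, 1000L)
  expect_equal(fr$downstream_cut, 1200L)
  expect_false(fr$undetectable)
  expect_true(fr$contains_probe)

  # degenerate boundary: host cut immediately adjacent to the insertion
  fr1 <- predict_junction_fragment(toy_panel(D = 1L), "toy")
  expect_equal(fr1$size, 1 + 1200)

  # minus-strand locus mirrors the plus-strand computation
  frm <- predict_junction_fragment(toy_panel(D = 500L, strand = "-"), "toy", bsri)
  expect_equal(frm$size, 500 + 1200)

  # TSD lengthens the host side by one duplicated copy
  frt <- predict_junction_fragment(toy_panel(D = 500L, tsd = 6L), "toy", bsri)
  expect_equal(frt$size, 500 + 6 + 1200)
})

test_that("missing host cut inside the horizon yields the undetectable sentinel", {
  panel <- toy_panel(plant_host_cut = FALSE)
  fr <- predict_junction_fragment(panel, "toy", bsri)
  expect_true(fr$undetectable)
  expect_true(is.na(fr$size))
})

test_that("a probe 3' of the first internal cut is a contract violation", {
  panel <- toy_panel(internal_cut = 800L)  # probe window is 900..931
  expect_error(predict_junction_fragment(panel, "toy", bsri),
               "contract violation")
})

test_that("prediction equals the full-composite digest oracle on random loci", {
  set.seed(77)
  panel <- make_reference_panel(
    n_elements = 6, n_loci = 10, n_recent = 3,
    upstream_ladder = sample(300:5000, 10),
    strands = sample(c("+", "-"), 10, replace = TRUE), seed = 19)
  probe_reg <- panel$probe_region
  for (j in seq_len(nrow(panel$loci))) {
    lc <- panel$loci[j, ]
    pred <- predict_junction_fragment(panel, lc$locus_id, bsri)
    probe_seq <- substr(panel$element_seqs[[lc$element_id]],
                        probe_reg[1], probe_reg[2])
    hap <- realize_haplotype(panel, lc$locus_id, "pro")
    sizes <- oracle_probe_fragments(hap, "ACTGG", 1L, probe_seq)
    expect_equal(pred$size, sizes, info = lc$locus_id)
    # the junction fragment's upstream boundary lies in host DNA
    expect_false(is.na(pred$upstream_cut))
  }
})

test_that("band patterns reflect allele content and gel collapse", {
  panel <- toy_panel()
  probe <- strrep("C", 32)
  pre2 <- list(toy = c(realize_haplotype(panel, "toy", "pre"),
                       realize_haplotype(panel, "toy", "pre")))
  expect_length(digest_pattern(pre2, bsri, probe)$sizes, 0)

  het <- list(toy = c(realize_haplotype(panel, "toy", "pro"),
                      realize_haplotype(panel, "toy", "pre")))
  bp <- digest_pattern(het, bsri, probe)
  expect_equal(bp$sizes, 1700)

  # homozygote: identical diploid sizes collapse to one band
  hom <- list(toy = c(realize_haplotype(panel, "toy", "pro"),
                      realize_haplotype(panel, "toy", "pro")))
  expect_equal(digest_pattern(hom, bsri, probe)$sizes, 1700)

  # solo haplotype never emits a band (probe absent)
  solo <- list(toy = c(realize_haplotype(panel, "toy", "solo"),
                       realize_haplotype(panel, "toy", "solo")))
  expect_length(digest_pattern(solo, bsri, probe)$sizes, 0)

  # out-of-window fragments are not reported
  expect_length(digest_pattern(het, bsri, probe, size_window = c(100, 1000))$sizes, 0)
})

test_that("a substitution destroying the host cut site grows the band", {
  panel <- toy_panel(D = 500L)
  probe <- strrep("C", 32)
  hap <- realize_haplotype(panel, "toy", "pro")
  # the planted host site sits 500 bp upstream of the junction; break it
  site_at <- regexpr("ACTGG", hap, fixed = TRUE)
  hap_mut <- paste0(substr(hap, 1, site_at + 1), "C",
                    substr(hap, site_at + 3, nchar(hap)))
  bp <- digest_pattern(list(toy = c(hap_mut, hap_mut)), bsri, probe)
  oracle <- oracle_probe_fragments(hap_mut, "ACTGG", 1L, probe)
  oracle <- oracle[oracle >= 500 & oracle <= 10000]
  expect_equal(bp$sizes, sort(oracle, decreasing = TRUE))
  expect_gt(bp$sizes[1], 1700)  # band grew past the destroyed site
})

test_that("minus-strand loci band at the same size as the plus construction", {
  probe <- strrep("C", 32)
  for (str in c("+", "-")) {
    panel <- toy_panel(D = 700L, strand = str)
    hap <- realize_haplotype(panel, "toy", "pro")
    bp <- digest_pattern(list(toy = c(hap, hap)), bsri, probe)
    expect_equal(bp$sizes, 700 + 1200, info = str)
  }
})
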