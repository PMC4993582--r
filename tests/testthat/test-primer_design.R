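# toy 60-nt CDS used throughout: 5x ATGAAACATGGC (no Ala codons, no stops)
toy_cds <- function() coding_sequence(strrep("ATGAAACATGGC", 5L), id = "toy60")

test_that("choose_mutant_codon picks minimal-mismatch codons", {
  expect_identical(choose_mutant_codon("AAA", "R"), list(codon = "AGA", mismatches = 1L))
  expect_identical(choose_mutant_codon("AAA", "K")$mismatches, 0L)
  expect_identical(choose_mutant_codon("CTG", "A"), list(codon = "GCG", mismatches = 2L))
  expect_error(choose_mutant_codon("AAA", "*"), "allow_stop")
  expect_identical(choose_mutant_codon("TAC", "*", allow_stop = TRUE)$codon, "TAA")
  expect_error(choose_mutant_codon("AAA", "B"), "invalid amino acid")
  expect_error(choose_mutant_codon("AA", "R"), "3 bases")
})

test_that("chosen codons are minimal over exhaustive enumeration", {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  for (seed in 1:40) {
    wt <- withr::with_seed(seed, sample(names(codon_lookup_oracle), 1))
    aa <- withr::with_seed(seed + 1000, sample(aas, 1))
    got <- choose_mutant_codon(wt, aa)
    expect_identical(translate_codon(got$codon), aa)
    expect_identical(got$mismatches, as.integer(brute_min_mismatch(wt, aa)))
  }
})

test_that("codon tie-breaks are deterministic by usage then lexicographic", {
  # CAT -> E: GAA/GAG both 2 mismatches; human usage prefers GAG (39.6 > 29.0)
  expect_identical(choose_mutant_codon("CAT", "E")$codon, "GAG")
  expect_identical(choose_mutant_codon("CAT", "E",
                                       tie_break = "lexicographic")$codon, "GAA")
  # equal-weight table falls back to lexicographic order
  flat <- codon_table(setNames(rep(1, 64), names(human_codon_usage())))
  expect_identical(choose_mutant_codon("CAT", "E", table = flat)$codon, "GAA")
})

test_that("design_primer_pair centres the mutant codon and annotates", {
  cds <- toy_cds()
  p <- design_primer_pair(cds, 6, "A", length = 29)
  expect_identical(unname(p$template_span), c(3L, 31L))
  expect_identical(substr(p$forward, 14, 16), p$mutant_codon)
  expect_identical(p$reverse, reverse_complement(p$forward))
  expect_identical(nchar(p$forward), 29L)
  # both flanks equal the template
  expect_identical(substr(p$forward, 1, 13), substr(cds$bases, 3, 15))
  expect_identical(substr(p$forward, 17, 29), substr(cds$bases, 19, 31))
  expect_equal(p$tm, tm_quikchange(p$gc_percent, 29, p$mismatches))
})

test_that("design_primer_pair enforces its preconditions", {
  cds <- toy_cds()
  err <- expect_error(design_primer_pair(cds, 2, "A", length = 29),
                      "flank out of range")
  expect_match(conditionMessage(err), "6..15") # first/last designable residue
  expect_error(design_primer_pair(cds, 6, "A", length = 28), "odd integer")
  expect_error(design_primer_pair(cds, 6, "A", length = 13), "odd integer")
  expect_error(design_primer_pair(cds, 6, "K"), "no mutation introduced")
  expect_no_error(design_primer_pair(cds, 6, "K", allow_silent = TRUE))
  expect_warning(design_primer_pair(cds, 8, "A", length = 41), "40 nt")
})

test_that("designed pairs satisfy the full invariants on random CDSs", {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  for (seed in 1:15) {
    cds <- random_cds(40, seed)
    res <- withr::with_seed(seed, sample(6:35, 1))
    aa <- withr::with_seed(seed, sample(setdiff(aas, translate_residue(cds, res)), 1))
    p <- design_primer_pair(cds, res, aa)
    expect_identical(p$reverse, reverse_complement(p$forward))
    expect_identical(substr(p$forward, 14, 16), p$mutant_codon)
    expect_identical(translate_codon(p$mutant_codon), aa)
    expect_identical(p$mismatches, as.integer(brute_min_mismatch(p$wt_codon, aa)))
    # whole-CDS translation changes exactly the targeted residue
    mutated <- cds$bases
    substr(mutated, 3 * (res - 1) + 1, 3 * res) <- p$mutant_codon
    wt_prot <- strsplit(translate_cds_oracle(cds$bases), "")[[1]]
    mut_prot <- strsplit(translate_cds_oracle(mutated), "")[[1]]
    changed <- which(wt_prot != mut_prot)
    expect_identical(changed, res)
    expect_identical(mut_prot[res], aa)
  }
})

test_that("ala scans cover the remaining sequence in 3-base steps", {
  cds <- toy_cds()
  pairs <- suppressMessages(design_ala_scan(cds, 3, length = 29))
  expect_length(pairs, 10)
  expect_identical(vapply(pairs, `[[`, integer(1), "residue_index"), 6:15)
  starts <- vapply(pairs, function(p) p$template_span[["start"]], integer(1))
  expect_identical(diff(starts), rep(3L, 9))
  expect_true(all(vapply(pairs, `[[`, character(1), "target_aa") == "A"))
})

test_that("out-of-frame starts advance and Ala codons are skipped with notices", {
  cds <- toy_cds()
  expect_message(pairs <- design_ala_scan(cds, 4, length = 29),
                 "out of frame; advanced to 6")
  expect_identical(vapply(pairs, `[[`, integer(1), "residue_index"), 7:15)
  # put an Ala codon at position 8
  b <- toy_cds()$bases
  substr(b, 22, 24) <- "GCT"
  cds_ala <- coding_sequence(b, "toyAla")
  expect_message(pairs <- design_ala_scan(cds_ala, 3, length = 29),
                 "codon 8 already encodes Ala")
  expect_length(pairs, 9)
  expect_false(8L %in% vapply(pairs, `[[`, integer(1), "residue_index"))
  # nothing designable -> warning, empty list
  tiny <- coding_sequence("ATGAAACATGGC", "tiny")
  expect_warning(out <- suppressMessages(design_ala_scan(tiny, 1)),
                 "empty primer list")
  expect_length(out, 0)
})

test_that("multisite sets share the window and skip the wild type", {
  cds <- toy_cds() # residue 7 codon CAT (His)
  expect_identical(cds_codon(cds, 7), "CAT")
  set <- design_multisite_set(cds, 7, c("R", "Y", "L", "P"))
  expect_length(set, 4)
  expect_true(all(vapply(set, `[[`, integer(1), "mismatches") == 1L))
  spans <- unique(lapply(set, `[[`, "template_span"))
  expect_length(spans, 1)
  expect_message(set2 <- design_multisite_set(cds, 7, c("H", "R")),
                 "equals the wild-type residue")
  expect_length(set2, 1)
  expect_message(none <- design_multisite_set(cds, 7, "H"), "skipped")
  expect_length(none, 0)
  # duplicates removed
  expect_length(design_multisite_set(cds, 7, c("R", "R", "Y")), 2)
})

test_that("19-target multisite sets carry mismatch classes 1..3", {
  cds <- random_cds(40, 99)
  res <- 20L
  wt <- translate_residue(cds, res)
  targets <- setdiff(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*"), wt)
  set <- design_multisite_set(cds, res, targets)
  expect_length(set, 19)
  mm <- vapply(set, `[[`, integer(1), "mismatches")
  expect_true(all(mm %in% 1:3))
})

test_that("tm_quikchange reproduces the convention and is monotone", {
  expect_equal(tm_quikchange(52, 29, 1), 76.09586, tolerance = 1e-6)
  expect_equal(tm_quikchange(34, 29, 2), 65.26759, tolerance = 1e-6)
  expect_equal(round_half_degree(tm_quikchange(24, 29, 1)), 64.5)
  expect_error(tm_quikchange(52, 0, 1), "positive")
  expect_error(tm_quikchange(101, 29, 1), "\\[0, 100\\]")
  gc <- seq(0, 100, by = 5)
  expect_true(all(diff(tm_quikchange(gc, 29, 1)) > 0))       # increasing in GC
  expect_true(all(diff(tm_quikchange(50, 29, 0:3)) < 0))     # decreasing in mm
  lens <- seq(15, 45, by = 2)
  expect_true(all(diff(tm_quikchange(50, lens, 1)) > 0))     # increasing in N
})

test_that("restriction_site_diff reports gains and losses on both strands", {
  wt <- "AAATCTTGAAAAGATCTAAA" # has BglII AGATCT at 12
  mut <- "AAATCTAGAAAAGATTTAAA" # gains XbaI TCTAGA at 4, loses BglII
  d <- restriction_site_diff(wt, mut)
  expect_identical(d$gained, list(XbaI = 4L))
  expect_identical(d$lost, list(BglII = 12L))
  same <- restriction_site_diff(wt, wt)
  expect_length(same$gained, 0)
  expect_length(same$lost, 0)
  expect_error(restriction_site_diff("AAA", "AAAA"), "equal length")
  # non-palindromic site found via the opposite strand
  enz <- c(Fake = "GGGAA") # revcomp TTCCC
  d2 <- restriction_site_diff("AAAAAAA", "ATTCCCA", enzymes = enz)
  expect_identical(d2$gained, list(Fake = 2L))
  expect_error(restriction_site_diff("AAA", "AAA", enzymes = "TCTAGA"), "named")
})

test_that("primer sheets round-trip through TSV", {
  cds <- toy_cds()
  pairs <- suppressMessages(design_ala_scan(cds, 3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_primer_sheet(pairs, tsv, seed = 11)
  hdr <- readLines(tsv, n = 3)
  expect_match(hdr[1], "onetubeSDM")
  expect_match(hdr[3], "seed: 11")
  back <- read_primer_sheet(tsv)
  expect_equal(back, pairs)
})
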