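# Hand-crafted hit tables isolate the pairing logic from discovery.

mk_hit <- function(end_type, start, end, up, down, strand = "+",
                   contig = "c1", family = "fam") {
  data.frame(family = family, end_type = end_type, contig = contig,
             start = start, end = end, strand = strand, identity = 1,
             coverage = 1, full_start = start, full_end = end,
             up_flank = up, down_flank = down, edge_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("a crafted insert with duplicated TSD pairs with that TSD", {
  hits <- rbind(
    mk_hit("five_prime", 1001, 1060, up = "AAAAAAAAAAAAAAACATTG",
           down = "GGGGGGGGGGGGGGGGGGGG"),
    mk_hit("three_prime", 2001, 2060, up = "CCCCCCCCCCCCCCCCCCCC",
           down = "CATTGTTTTTTTTTTTTTTT"))
  cp <- pair_inserts(hits, "DNA", tsd_len = 5)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$structure, "full")
  expect_equal(cp$tsd_seq, "CATTG")
  expect_equal(cp$start, 1001L)
  expect_equal(cp$end, 2060L)
})

test_that("adjacent inserts with distinct TSDs never cross-pair", {
  hits <- rbind(
    mk_hit("five_prime", 1000, 1059, up = "AAAAAAAAAAAAAAAGTTAC",
           down = "NNNNNNNNNNNNNNNNNNNN"),
    mk_hit("three_prime", 2000, 2059, up = "NNNNNNNNNNNNNNNNNNNN",
           down = "GTTACAAAAAAAAAAAAAAA"),
    mk_hit("five_prime", 3000, 3059, up = "AAAAAAAAAAAAAAATCGGA",
           down = "NNNNNNNNNNNNNNNNNNNN"),
    mk_hit("three_prime", 4000, 4059, up = "NNNNNNNNNNNNNNNNNNNN",
           down = "TCGGAAAAAAAAAAAAAAAA"))
  cp <- pair_inserts(hits, "DNA", tsd_len = 5)
  paired <- cp[cp$structure == "full", ]
  expect_equal(nrow(paired), 2L)
  expect_setequal(paired$tsd_seq, c("GTTAC", "TCGGA"))
  expect_equal(paired$three_start, paired$five_start + 1000L)
})

test_that("solo LTRs are recognized by their own flank duplication", {
  hits <- rbind(
    mk_hit("ltr", 500, 649, up = "AAAAAAAAAAAAAAAGCGCA",
           down = "GCGCATTTTTTTTTTTTTTT"),
    mk_hit("ltr", 5000, 5149, up = "AAAAAAAAAAAAAAATTTAA",
           down = "CCCCCTTTTTTTTTTTTTTT"))
  cp <- pair_inserts(hits, "LTR", tsd_len = 5, max_span = 2000)
  expect_equal(cp$structure[cp$start == 500], "soloLTR")
  expect_equal(cp$tsd_seq[cp$start == 500], "GCGCA")
  expect_equal(cp$structure[cp$start == 5000], "unpaired")
})

test_that("LTR pairs within max_span become FLEs, beyond it do not", {
  fle_hits <- rbind(
    mk_hit("ltr", 1000, 1149, up = "AAAAAAAAAAAAAAACCGGT",
           down = "NNNNNNNNNNNNNNNNNNNN"),
    mk_hit("ltr", 6000, 6149, up = "NNNNNNNNNNNNNNNNNNNN",
           down = "CCGGTAAAAAAAAAAAAAAA"))
  cp <- pair_inserts(fle_hits, "LTR", tsd_len = 5, max_span = 15000)
  expect_equal(cp$structure, "FLE")
  cp2 <- pair_inserts(fle_hits, "LTR", tsd_len = 5, max_span = 3000)
  expect_false(any(cp2$structure == "FLE"))
})

test_that("minus-strand pairing follows element orientation", {
  # on the - strand the element-5' hit lies genomically downstream
  hits <- rbind(
    mk_hit("three_prime", 1000, 1059, strand = "-",
           up = "NNNNNNNNNNNNNNNNNNNN", down = "CAGTACCCCCCCCCCCCCCC"),
    mk_hit("five_prime", 2000, 2059, strand = "-",
           up = "AAAAAAAAAAAAAACAGTAC", down = "NNNNNNNNNNNNNNNNNNNN"))
  cp <- pair_inserts(hits, "nonLTR", tsd_len = 6)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$structure, "full")
  expect_equal(cp$tsd_seq, "CAGTAC")
  expect_equal(cp$five_start, 2000L)
  expect_equal(cp$three_start, 1000L)
})

test_that("intra-element LTR identity arithmetic is exact", {
  ltr <- paste(rep("A", 143), collapse = "")
  expect_equal(intra_ltr_identity(ltr, ltr), 100.0)
  one_off <- paste0(substring(ltr, 1, 142), "T")
  expect_equal(intra_ltr_identity(ltr, one_off), 99.3)
  expect_warning(intra_ltr_identity("AAAA", "AAA"), "prefix")
})

test_that("TSD length inference finds the modal duplicated k-mer", {
  up <- paste0(strrep("A", 15), "GCTGA")
  down <- paste0("GCTGA", strrep("T", 15))
  inf <- infer_tsd_len(rep(up, 10), rep(down, 10))
  expect_equal(inf$inferred_len, 5L)
  expect_true(all(inf$tsd_seqs == "GCTGA"))

  # no shared prefix/suffix: TSD-absent
  inf2 <- infer_tsd_len(c(strrep("A", 20)), c(strrep("T", 20)))
  expect_true(is.na(inf2$per_insert[1]))

  # under 3 candidates the family length stays undefined
  inf3 <- infer_tsd_len(rep(up, 2), rep(down, 2))
  expect_true(is.na(inf3$inferred_len))
  expect_equal(inf3$per_insert, c(5L, 5L))
})

test_that("TSD inference is order-independent and idempotent", {
  set.seed(60)
  ups <- replicate(12, paste0(
    paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = ""),
    "CATGG"))
  downs <- paste0("CATGG", strrep("C", 15))
  perm <- sample(12)
  a <- infer_tsd_len(ups, rep(downs, 12))
  b <- infer_tsd_len(ups[perm], rep(downs, 12)[perm])
  expect_equal(a$inferred_len, b$inferred_len)
  expect_equal(a$per_insert[perm], b$per_insert)
})

test_that("TSD composition frequencies are proper and GC is correct", {
  comp <- tsd_composition(c("TA", "TA", "TA"))
  expect_equal(unname(comp$freq[1, "T"]), 1)
  expect_equal(unname(comp$freq[2, "A"]), 1)
  expect_equal(unname(comp$gc_by_position), c(0, 0))
  expect_equal(comp$n_sites, 3L)
  expect_true(all(abs(rowSums(comp$freq) - 1) < 1e-9))
  expect_error(tsd_composition(c("TA", "TAA")), "mixed")
})

test_that("GC_ends planting enriches G/C at TSD positions 1 and 5", {
  fam <- te_family("f", "LTR", terminus_len = 60, internal_len = 40,
                   tsd_len = 5, target_pref = "GC_ends",
                   history = burst_history(0, 200), solo_rate = 0)
  sim <- simulate_family(fam, rng_seed = 61)
  pl <- plant_genome(900000, 0.5, list(sim), rng_seed = 62, min_gap = 4)
  comp <- tsd_composition(pl$truth$tsd)
  # weight w per G/C at ends: expected GC = w g /(w g + (1-g)) with g = 0.5
  w <- 1.8
  expected <- w * 0.5 / (w * 0.5 + 0.5)
  se <- 3 * sqrt(expected * (1 - expected) / comp$n_sites)
  expect_lt(abs(comp$gc_by_position[1] - expected), se)
  expect_lt(abs(comp$gc_by_position[5] - expected), se)
  expect_gt(comp$gc_by_position[1], comp$gc_by_position[3])
  expect_gt(comp$gc_by_position[5], comp$gc_by_position[3])
})
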