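test_that("a zero-age burst yields copies identical to the consensus", {
  fam <- te_family("f", "DNA", terminus_len = 50, internal_len = 100,
                   history = burst_history(0, 10))
  sim <- simulate_family(fam, rng_seed = 1)
  expect_equal(nrow(sim$copies), 10L)
  expect_true(all(sim$copies$seq == sim$consensus$full))
  nd <- nucleotide_diversity(as_alignment(sim$copies$seq))
  expect_equal(nd$pi, 0)
  expect_equal(nd$S, 0L)
})

test_that("intra-element LTR divergence matches the clock expectation", {
  # both LTRs identical at insertion, then mutating independently with
  # p(t) = 1 - exp(-mu t): expected pairwise mismatch ~ 2p(1-p) + (2/3)p^2
  mu <- 0.01; t <- 5; L <- 400L
  fam <- te_family("f", "LTR", terminus_len = L, internal_len = 50,
                   history = burst_history(t, 60), mu = mu)
  sim <- simulate_family(fam, rng_seed = 11)
  div <- mapply(function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x != y)
  }, sim$copies$five_seq, sim$copies$three_seq)
  p <- 1 - exp(-mu * t)
  expected <- 2 * p * (1 - p) + (2 / 3) * p^2
  se <- sqrt(expected * (1 - expected) / (L * length(div)))
  expect_lt(abs(mean(div) - expected), 4 * se)
  # and approximately 2*mu*t for small mu*t
  expect_lt(abs(mean(div) - 2 * mu * t), 0.02)
})

test_that("truncation probability boundaries hold exactly", {
  base <- list(name = "f", te_class = "nonLTR", terminus_len = 60,
               internal_len = 200, history = burst_history(1, 20))
  all_trunc <- simulate_family(do.call(te_family, c(base, trunc_prob = 1)),
                               rng_seed = 2)
  expect_true(all(all_trunc$copies$structure == "truncated"))
  none <- simulate_family(do.call(te_family, c(base, trunc_prob = 0)),
                          rng_seed = 2)
  expect_true(all(none$copies$structure == "full"))
})

test_that("solo fraction converges to 1 - exp(-rho t)", {
  rho <- 0.3; t <- 4
  fam <- te_family("f", "LTR", terminus_len = 60, internal_len = 60,
                   history = burst_history(t, 1000), solo_rate = rho)
  sim <- simulate_family(fam, rng_seed = 3)
  p <- 1 - exp(-rho * t)
  frac <- mean(sim$copies$structure == "soloLTR")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("a single recent burst is dominated by singleton variants", {
  fam <- te_family("f", "DNA", terminus_len = 300, internal_len = 0,
                   history = burst_history(1, 30), mu = 0.02)
  sim <- simulate_family(fam, rng_seed = 4)
  m <- do.call(rbind, strsplit(substr(sim$copies$seq, 1, 300), ""))
  singletons <- 0L; intermediates <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) < 2) next
    minor <- sum(tab) - max(tab)
    if (minor == 1) singletons <- singletons + 1L
    else intermediates <- intermediates + 1L
  }
  expect_gte(singletons, intermediates)
})

test_that("simulation is deterministic under a fixed seed", {
  fam <- te_family("f", "LTR", terminus_len = 50, internal_len = 100,
                   history = burst_history(2, 8), solo_rate = 0.2)
  a <- simulate_family(fam, rng_seed = 99)
  b <- simulate_family(fam, rng_seed = 99)
  expect_identical(a$copies, b$copies)
  g1 <- plant_genome(50000, 0.5, list(a), rng_seed = 7)
  g2 <- plant_genome(50000, 0.5, list(b), rng_seed = 7)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$truth, g2$truth)
})

test_that("planted truth intervals slice back to the copy sequences", {
  fams <- list(
    simulate_family(te_family("ltr", "LTR", terminus_len = 60,
                              internal_len = 150, tsd_len = 5,
                              history = burst_history(1, 6),
                              solo_rate = 0.3), rng_seed = 5),
    simulate_family(te_family("dna", "DNA", terminus_len = 40,
                              internal_len = 120, tsd_len = 2,
                              target_pref = "TA",
                              history = burst_history(2, 6)), rng_seed = 6))
  pl <- plant_genome(80000, 0.5, fams, rng_seed = 8)
  g <- pl$genome$seq
  all_copies <- rbind(fams[[1]]$copies, fams[[2]]$copies)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    planted <- substring(g, tr$start, tr$end)
    if (tr$strand == "-") planted <- revcomp(planted)
    expect_identical(planted,
                     all_copies$seq[all_copies$copy_id == tr$copy_id])
  }
})

test_that("TSDs duplicate the target exactly, and TA preference is absolute", {
  fams <- list(
    simulate_family(te_family("dna", "DNA", terminus_len = 40,
                              internal_len = 80, tsd_len = 2,
                              target_pref = "TA",
                              history = burst_history(0, 10)), rng_seed = 9))
  pl <- plant_genome(60000, 0.5, fams, rng_seed = 10)
  g <- pl$genome$seq
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    expect_identical(tr$tsd, "TA")
    left <- substring(g, tr$start - 2, tr$start - 1)
    right <- substring(g, tr$end + 1, tr$end + 2)
    expect_identical(left, "TA")
    expect_identical(right, "TA")
  }
})

test_that("tsd_len 0 plants without duplication", {
  fams <- list(
    simulate_family(te_family("x", "DNA", terminus_len = 30,
                              internal_len = 50, tsd_len = 0,
                              history = burst_history(0, 5)), rng_seed = 12))
  pl <- plant_genome(30000, 0.5, fams, rng_seed = 13)
  expect_true(all(pl$truth$tsd == ""))
})

test_that("read simulation respects zero means and fixed seeds", {
  fam0 <- te_family("silent", "DNA", terminus_len = 40, internal_len = 200,
                    history = burst_history(1, 5),
                    stage_means = c(0, 0, 0))
  fam1 <- te_family("loud", "DNA", terminus_len = 40, internal_len = 200,
                    history = burst_history(1, 5),
                    stage_means = c(50, 50, 50))
  sims <- list(simulate_family(fam0, 1), simulate_family(fam1, 2))
  rd <- simulate_reads(sims, read_len = 40, error_rate = 0.01, rng_seed = 3)
  tc <- rd$truth_counts
  expect_true(all(tc$count[tc$family == "silent"] == 0))
  expect_false(any(grepl("^silent", unlist(lapply(rd$reads, `[[`, "id")))))
  rd2 <- simulate_reads(sims, read_len = 40, error_rate = 0.01,
                        rng_seed = 3)
  expect_identical(rd$reads, rd2$reads)
})

test_that("near-Poisson counts concentrate around the mean", {
  fam <- te_family("f", "DNA", terminus_len = 40, internal_len = 400,
                   history = burst_history(0, 3),
                   stage_means = c(1000, 1000, 1000), dispersion = 1e6)
  sim <- simulate_family(fam, 1)
  rd <- simulate_reads(list(sim), read_len = 40, error_rate = 0,
                       rng_seed = 21)
  expect_true(all(abs(rd$truth_counts$count - 1000) <= 3 * sqrt(1000) + 5))
})
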