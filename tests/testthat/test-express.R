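make_counts <- function(vals) {
  # vals: named list family -> 3x3 matrix (stages x replicates)
  stages <- c("adherent", "floating", "aggregate")
  do.call(rbind, lapply(names(vals), function(f) {
    m <- vals[[f]]
    data.frame(family = f,
               stage = rep(stages, 3),
               replicate = rep(1:3, each = 3),
               count = as.vector(m))
  }))
}

test_that("reads assign to the unique matching family; ties drop", {
  set.seed(90)
  consA <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  consB <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  read <- substring(consA, 101, 160)
  r <- map_reads(read, c(A = consA, B = consB))
  expect_equal(unname(r$counts["A"]), 1L)
  expect_equal(unname(r$counts["B"]), 0L)

  # reverse-complemented reads map identically (strand symmetry)
  r2 <- map_reads(revcomp(read), c(A = consA, B = consB))
  expect_equal(r2$counts, r$counts)

  # a read present in both consensi ties and is dropped
  shared <- substring(consA, 201, 260)
  consB2 <- paste0(substring(consB, 1, 250), shared,
                   substring(consB, 311))
  r3 <- map_reads(shared, c(A = consA, B = consB2))
  expect_equal(sum(r3$counts), 0L)
  expect_equal(r3$n_tied, 1L)
  expect_error(map_reads(read, character(0)), "empty")
})

test_that("mapped counts recover simulated truth within 2%", {
  fams <- list(
    simulate_family(te_family("fA", "DNA", terminus_len = 100,
                              internal_len = 700,
                              history = burst_history(1, 8),
                              stage_means = c(400, 400, 400)), 91),
    simulate_family(te_family("fB", "DNA", terminus_len = 100,
                              internal_len = 700,
                              history = burst_history(1, 8),
                              stage_means = c(300, 300, 300)), 92))
  rd <- simulate_reads(fams, read_len = 60, error_rate = 0.01,
                       rng_seed = 93)
  consensi <- vapply(fams, function(f) f$consensus$full, character(1))
  names(consensi) <- c("fA", "fB")
  truth <- aggregate(count ~ family, rd$truth_counts, sum)
  mapped <- stats::setNames(c(0L, 0L), c("fA", "fB"))
  for (key in names(rd$reads)) {
    mr <- map_reads(rd$reads[[key]], consensi, k = 10,
                    min_identity = 0.8, min_cov = 0.8)
    mapped <- mapped + mr$counts
  }
  for (f in truth$family) {
    tc <- truth$count[truth$family == f]
    expect_lt(abs(mapped[[f]] - tc) / tc, 0.02)
  }
})

test_that("normalization scales to the global maximum and preserves rank", {
  single <- make_counts(list(
    f1 = matrix(c(9, 0, 0, 0, 0, 0, 0, 0, 0), 3),
    f2 = matrix(0, 3, 3)))
  # all-zero rows are fine as long as one cell is positive
  m <- normalize_matrix(expression_table(single))
  expect_equal(unname(m$normalized["f1", "adherent"]), 1)
  expect_equal(sum(m$normalized), 1)

  uniform <- make_counts(list(f1 = matrix(5, 3, 3), f2 = matrix(5, 3, 3)))
  mu <- normalize_matrix(expression_table(uniform))
  expect_true(all(mu$normalized == 1))

  set.seed(94)
  vals <- matrix(rpois(9, 50), 3)
  base <- normalize_matrix(expression_table(make_counts(list(f = vals))))
  doubled <- normalize_matrix(
    expression_table(make_counts(list(f = vals * 2))))
  expect_equal(doubled$normalized, base$normalized)
  expect_equal(order(base$log_normalized), order(base$cell))

  expect_error(normalize_matrix(
    expression_table(make_counts(list(f = matrix(0, 3, 3))))), "zero")
})

test_that("equal stage profiles are never called significant", {
  et <- expression_table(make_counts(list(
    f = matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3, byrow = FALSE))))
  # each stage sees replicates (1,2,3): equal means, F = 0
  res <- stage_tests(et)
  expect_false(res$significant)
  expect_true(is.na(res$elevated_stage))

  # constant table: F undefined, reported not significant
  flat <- expression_table(make_counts(list(f = matrix(7, 3, 3))))
  expect_false(stage_tests(flat)$significant)
})

test_that("ANOVA F and p match the hand-computed decomposition", {
  groups <- list(adherent = c(100, 110, 90), floating = c(10, 12, 8),
                 aggregate = c(11, 9, 10))
  m <- do.call(rbind, groups)   # stages x replicates
  et <- expression_table(make_counts(list(f = m)))
  res <- stage_tests(et)
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) 3 * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova_F, f_oracle, tolerance = 1e-12)
  expect_equal(res$anova_p, stats::pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$elevated_stage, "adherent")
})

test_that("identical top-two stages produce no elevated call", {
  et <- expression_table(make_counts(list(
    f = rbind(c(50, 60, 70), c(50, 60, 70), c(1, 2, 3)))))
  res <- stage_tests(et)
  if (res$significant) {
    expect_equal(res$t_stat, 0)
    expect_true(is.na(res$elevated_stage))
  }
})

test_that("activity correlation reproduces exact ranks and signs", {
  expect_equal(activity_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(activity_correlation(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_error(activity_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(activity_correlation(c(1, 2), c(1, 2)), "3 families")
})
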