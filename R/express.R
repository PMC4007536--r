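# Expression quantification of stage/replicate read sets against family
# consensus sequences, max-normalized heatmap matrices, per-family ANOVA
# with a top-two-stage t-test, and the reads-vs-identical-copies correlation.

#' Map reads to family consensus sequences
#'
#' Each read is assigned to the family with the best seeded ungapped
#' identity (both strands) at or above \code{min_identity} covering at
#' least \code{min_cov} of the read; reads tying between families are
#' dropped, unmapped reads are uncounted.
#'
#' @param reads Data frame with a \code{seq} column (or character vector).
#' @param consensi Named character vector of family consensus sequences.
#' @param k Seed length in bp (smaller k is more sensitive to diverged
#'   copies at modest extra cost).
#' @param min_identity Minimum identity for an assignment.
#' @param min_cov Minimum fraction of the read aligned.
#' @param seed_stride Spacing between seed offsets within a read.
#' @return List with \code{counts} (named integer vector per family),
#'   \code{n_mapped}, \code{n_tied}, \code{n_unmapped}.
#' @export
map_reads <- function(reads, consensi, k = 12, min_identity = 0.85,
                      min_cov = 0.90, seed_stride = 1L) {
  if (length(consensi) == 0L) stop("empty consensus set")
  if (is.data.frame(reads)) reads <- reads$seq
  fams <- names(consensi)
  counts <- stats::setNames(integer(length(fams)), fams)
  if (length(reads) == 0L)
    return(list(counts = counts, n_mapped = 0L, n_tied = 0L,
                n_unmapped = 0L))
  idx <- kmer_index(consensi, k)
  nr <- length(reads)
  all_q <- c(toupper(reads), revcomp(toupper(reads)))
  cand <- seed_candidates(idx, all_q, stride_by = seed_stride)
  best_id <- rep(-1, nr)
  best_fam <- rep(NA_integer_, nr)
  tied <- rep(FALSE, nr)
  if (nrow(cand) > 0L) {
    qchars <- vector("list", 2L * nr)
    for (i in seq_len(nrow(cand))) {
      qi <- cand$query[i]
      ri <- if (qi > nr) qi - nr else qi
      if (is.null(qchars[[qi]]))
        qchars[[qi]] <- strsplit(all_q[qi], "", fixed = TRUE)[[1]]
      sc <- score_diagonal(qchars[[qi]], idx$chars[[cand$subject[i]]],
                           cand$qstart[i])
      if (is.null(sc)) next
      if (sc$identity < min_identity || sc$coverage < min_cov) next
      if (sc$identity > best_id[ri] + 1e-12) {
        best_id[ri] <- sc$identity
        best_fam[ri] <- cand$subject[i]
        tied[ri] <- FALSE
      } else if (abs(sc$identity - best_id[ri]) <= 1e-12 &&
                 !identical(best_fam[ri], cand$subject[i])) {
        tied[ri] <- TRUE
      }
    }
  }
  mapped <- which(best_id >= 0 & !tied)
  tab <- table(factor(idx$seq_names[best_fam[mapped]], levels = fams))
  counts[] <- as.integer(tab)
  list(counts = counts, n_mapped = length(mapped),
       n_tied = sum(tied & best_id >= 0),
       n_unmapped = nr - length(mapped) - sum(tied & best_id >= 0))
}

#' Build an expression table from long-format counts
#'
#' @param df Data frame with columns family, stage, replicate, count.
#' @param stages Stage order.
#' @return An \code{expression_table}: list with \code{counts} (3-d array
#'   family x stage x replicate) and \code{stages}.
#' @export
expression_table <- function(df,
                             stages = c("adherent", "floating",
                                        "aggregate")) {
  fams <- unique(df$family)
  reps <- sort(unique(df$replicate))
  arr <- array(0L, dim = c(length(fams), length(stages), length(reps)),
               dimnames = list(fams, stages, reps))
  for (i in seq_len(nrow(df)))
    arr[df$family[i], df$stage[i], as.character(df$replicate[i])] <-
      as.integer(df$count[i])
  structure(list(counts = arr, stages = stages),
            class = "expression_table")
}

#' Max-normalized expression matrices
#'
#' Per family x stage cell = sum over replicates. \code{normalized} divides
#' by the global maximum cell; \code{log_normalized} rescales
#' log10(cell + 1) so its minimum is 0 and maximum 1.
#'
#' @param et An \code{\link{expression_table}}.
#' @return List with \code{cell} (raw sums), \code{normalized} and
#'   \code{log_normalized} matrices (family x stage).
#' @export
normalize_matrix <- function(et) {
  stopifnot(inherits(et, "expression_table"))
  cell <- apply(et$counts, c(1, 2), sum)
  if (all(cell == 0)) stop("all-zero expression table")
  norm <- cell / max(cell)
  lg <- log10(cell + 1)
  rng <- range(lg)
  logn <- if (rng[2] > rng[1]) (lg - rng[1]) / (rng[2] - rng[1])
          else lg * 0
  list(cell = cell, normalized = norm, log_normalized = logn)
}

#' Stage-specificity tests per family
#'
#' One-way ANOVA across the three stages (3 replicates each); for families
#' significant at \code{alpha}, an unpaired pooled-variance t-test between
#' the two stages with the highest combined expression decides whether one
#' stage is significantly elevated.
#'
#' @param et An \code{\link{expression_table}} (3 stages x 3 replicates).
#' @param alpha Significance level for both tests.
#' @return Data frame per family: anova_F, anova_p, significant,
#'   top_stage_1, top_stage_2, t_stat, t_p, elevated_stage.
#' @export
stage_tests <- function(et, alpha = 0.05) {
  stopifnot(inherits(et, "expression_table"))
  arr <- et$counts
  fams <- dimnames(arr)[[1]]
  res <- lapply(fams, function(f) {
    y <- as.numeric(arr[f, , ])              # stage-major: s1 r1..r3 order
    g <- factor(rep(et$stages, times = dim(arr)[3]), levels = et$stages)
    out <- data.frame(family = f, anova_F = NA_real_, anova_p = NA_real_,
                      significant = FALSE, top_stage_1 = NA_character_,
                      top_stage_2 = NA_character_, t_stat = NA_real_,
                      t_p = NA_real_, elevated_stage = NA_character_,
                      stringsAsFactors = FALSE)
    if (stats::var(y) == 0) return(out)      # F undefined: not significant
    fit <- stats::anova(stats::lm(y ~ g))
    out$anova_F <- fit$`F value`[1]
    out$anova_p <- fit$`Pr(>F)`[1]
    out$significant <- is.finite(out$anova_p) && out$anova_p < alpha
    if (!out$significant) return(out)
    tot <- tapply(y, g, sum)
    top <- names(sort(tot, decreasing = TRUE))[1:2]
    out$top_stage_1 <- top[1]; out$top_stage_2 <- top[2]
    y1 <- y[g == top[1]]; y2 <- y[g == top[2]]
    if (stats::var(y1) == 0 && stats::var(y2) == 0) {
      out$t_stat <- 0; out$t_p <- 1
      return(out)
    }
    tt <- stats::t.test(y1, y2, var.equal = TRUE)
    out$t_stat <- unname(tt$statistic)
    out$t_p <- tt$p.value
    if (out$t_p < alpha)
      out$elevated_stage <- if (mean(y1) >= mean(y2)) top[1] else top[2]
    out
  })
  do.call(rbind, res)
}

#' Correlation between expression and identical-copy counts
#'
#' Pearson product-moment correlation between per-family read counts and
#' identical-paralogous-copy counts, on untransformed values.
#'
#' @param reads_per_family,identical_copies Numeric vectors, same order.
#' @return List with \code{r} and \code{n}.
#' @export
activity_correlation <- function(reads_per_family, identical_copies) {
  stopifnot(length(reads_per_family) == length(identical_copies))
  if (length(reads_per_family) < 3L) stop("need at least 3 families")
  if (stats::var(reads_per_family) == 0 || stats::var(identical_copies) == 0)
    stop("zero variance in input vector")
  list(r = stats::cor(reads_per_family, identical_copies),
       n = length(reads_per_family))
}
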