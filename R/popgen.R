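# Per-family diversity and activity statistics: segregating sites, pi,
# Tajima's D with beta-approximation significance, identical-copy counts and
# FLE/solo partitioned diversity.
#
# Gap handling follows the complete-deletion convention by default: every
# alignment column containing a gap or N is removed before any statistic is
# computed, so pi, k and S always refer to the same site set. An alignment
# whose every column is gapped yields an "insufficient sites" condition
# rather than a number (reported n/a downstream).

insufficient_sites <- function(msg = "insufficient usable sites") {
  stop(structure(class = c("te_insufficient_sites", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Usable alignment columns under a gap-handling policy
#'
#' @param aln A \code{\link{as_alignment}} matrix (rows = sequences).
#' @param policy \code{"complete_deletion"} removes every column containing
#'   a gap or N; \code{"pairwise_deletion"} returns per-pair column sets.
#' @return For complete deletion, an integer vector of column indices. For
#'   pairwise deletion, a list with \code{pairs} (2-column index matrix) and
#'   \code{sites} (list of usable-column vectors, one per pair).
#' @export
usable_sites <- function(aln,
                         policy = c("complete_deletion",
                                    "pairwise_deletion")) {
  policy <- match.arg(policy)
  aln <- as_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  valid <- aln == "A" | aln == "C" | aln == "G" | aln == "T"
  if (policy == "complete_deletion") {
    cols <- which(colSums(valid) == nrow(aln))
    if (length(cols) == 0L) insufficient_sites()
    return(cols)
  }
  pr <- t(utils::combn(nrow(aln), 2L))
  sites <- lapply(seq_len(nrow(pr)), function(i)
    which(valid[pr[i, 1L], ] & valid[pr[i, 2L], ]))
  list(pairs = pr, sites = sites)
}

#' Nucleotide diversity of a copy alignment
#'
#' Average pairwise difference statistics over the usable site set:
#' \code{k} is the mean per-pair difference count, \code{pi} the per-site
#' diversity, \code{S} the number of segregating (usable, polymorphic)
#' columns.
#'
#' @inheritParams usable_sites
#' @return List with \code{pi}, \code{k}, \code{S}, \code{n}, \code{L_used}.
#' @export
nucleotide_diversity <- function(aln,
                                 policy = c("complete_deletion",
                                            "pairwise_deletion")) {
  policy <- match.arg(policy)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  if (policy == "complete_deletion") {
    cols <- usable_sites(aln, "complete_deletion")
    sub <- aln[, cols, drop = FALSE]
    pr <- t(utils::combn(n, 2L))
    diffs <- vapply(seq_len(nrow(pr)), function(i)
      sum(sub[pr[i, 1L], ] != sub[pr[i, 2L], ]), numeric(1))
    k <- mean(diffs)
    S <- sum(vapply(seq_len(ncol(sub)), function(j)
      length(unique(sub[, j])) > 1L, logical(1)))
    list(pi = k / length(cols), k = k, S = S, n = n, L_used = length(cols))
  } else {
    us <- usable_sites(aln, "pairwise_deletion")
    per_pair <- vapply(seq_len(nrow(us$pairs)), function(i) {
      s <- us$sites[[i]]
      if (length(s) == 0L) return(c(NA_real_, NA_real_))
      d <- sum(aln[us$pairs[i, 1L], s] != aln[us$pairs[i, 2L], s])
      c(d, d / length(s))
    }, numeric(2))
    if (all(is.na(per_pair[1, ]))) insufficient_sites()
    valid <- aln == "A" | aln == "C" | aln == "G" | aln == "T"
    S <- sum(vapply(seq_len(ncol(aln)), function(j) {
      b <- aln[valid[, j], j]
      length(unique(b)) > 1L
    }, logical(1)))
    list(pi = mean(per_pair[2, ], na.rm = TRUE),
         k = mean(per_pair[1, ], na.rm = TRUE), S = S, n = n,
         L_used = NA_integer_)
  }
}

#' Tajima's D with beta-approximation significance
#'
#' Computes the standard Tajima test statistic from the mean pairwise
#' difference count k and the number of segregating sites S under complete
#' deletion, together with all intermediates and a two-tailed p-value from
#' the scaled-beta approximation to the null distribution of D.
#'
#' @inheritParams usable_sites
#' @param family Optional family label carried into the summary.
#' @param partition Partition label (\code{all}, \code{FLE} or \code{solo}).
#' @return A one-row \code{data.frame} (PopGen summary): family, partition,
#'   n, L_used, S, k, pi, a1, a2, b1, b2, c1, c2, e1, e2, D, p_two_tailed,
#'   sig_code. D is NA (not 0) when S = 0 or n < 4.
#' @export
tajimas_d <- function(aln, policy = "complete_deletion",
                      family = NA_character_, partition = "all") {
  if (!identical(policy, "complete_deletion"))
    stop("Tajima's D is defined here under complete deletion only")
  nd <- nucleotide_diversity(aln, "complete_deletion")
  n <- nd$n; S <- nd$S; k <- nd$k
  ints <- tajima_intermediates(n)
  D <- NA_real_; p <- NA_real_; sig <- NA_character_
  if (n >= 4L && S >= 1L) {
    varD <- ints$e1 * S + ints$e2 * S * (S - 1)
    D <- (k - S / ints$a1) / sqrt(varD)
    p <- tajima_beta_p(D, n, ints)
    sig <- sig_code(p)
  }
  data.frame(family = family, partition = partition, n = n,
             L_used = nd$L_used, S = S, k = k, pi = nd$pi,
             a1 = ints$a1, a2 = ints$a2, b1 = ints$b1, b2 = ints$b2,
             c1 = ints$c1, c2 = ints$c2, e1 = ints$e1, e2 = ints$e2,
             D = D, p_two_tailed = p, sig_code = sig,
             stringsAsFactors = FALSE)
}

# a1..e2 for sample size n
tajima_intermediates <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Two-tailed p for D under the scaled beta approximation. D is assumed to
# range over [Dmin, Dmax] (all-singleton vs balanced-intermediate extremes)
# with mean 0 and variance 1; the beta shapes follow from those moments.
# Falls back to a normal approximation when the variance constraint cannot
# be met (very small n).
tajima_beta_p <- function(D, n, ints = tajima_intermediates(n)) {
  dmin <- (2 / n - 1 / ints$a1) / sqrt(ints$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / ints$a1) / sqrt(ints$e2)
  s <- -(1 + dmin * dmax)
  if (!is.finite(s) || s <= 0) return(2 * stats::pnorm(-abs(D)))
  shape_p <- -dmin * s / (dmax - dmin)
  shape_q <- dmax * s / (dmax - dmin)
  x <- (D - dmin) / (dmax - dmin)
  x <- min(max(x, 0), 1)
  P <- stats::pbeta(x, shape_p, shape_q)
  min(1, 2 * min(P, 1 - P))
}

sig_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Count of identical paralogous copies
#'
#' The number of sequences belonging to any exact-identity group of size at
#' least 2, compared after uppercase normalization. Sequences are expected
#' in canonical (discovery) strand orientation, so reverse-complement pairs
#' have already been reconciled upstream.
#'
#' @param seqs Character vector of copy sequences.
#' @return Integer count (0 when all copies are unique).
#' @export
identical_copy_count <- function(seqs) {
  if (length(seqs) == 0L) return(0L)
  tab <- table(toupper(seqs))
  sum(tab[tab >= 2L])
}

#' Diversity partitioned by element structure
#'
#' One PopGen summary row per partition (all copies, FLE-derived LTRs,
#' solo LTRs), using one LTR per insert. Tajima's D is computed on the
#' all-copies partition only; partitions with fewer than 2 sequences are
#' reported empty.
#'
#' @param seqs Equal-length, one-per-insert LTR sequences.
#' @param structure Per-insert structure labels (\code{FLE} / \code{soloLTR}).
#' @param family Optional family label.
#' @param policy Gap policy for pi.
#' @return Data frame with rows \code{all}, \code{FLE}, \code{solo}.
#' @export
partitioned_diversity <- function(seqs, structure, family = NA_character_,
                                  policy = "complete_deletion") {
  stopifnot(length(seqs) == length(structure))
  parts <- list(all = seq_along(seqs),
                FLE = which(structure == "FLE"),
                solo = which(structure == "soloLTR"))
  rows <- lapply(names(parts), function(pn) {
    idx <- parts[[pn]]
    if (length(idx) < 2L)
      return(empty_popgen_row(family, pn, n = length(idx)))
    if (pn == "all")
      return(tryCatch(tajimas_d(as_alignment(seqs[idx]), family = family,
                                partition = pn),
                      te_insufficient_sites = function(e)
                        empty_popgen_row(family, pn, n = length(idx))))
    r <- tryCatch({
      nd <- nucleotide_diversity(as_alignment(seqs[idx]), policy)
      row <- empty_popgen_row(family, pn, n = nd$n)
      row$L_used <- nd$L_used; row$S <- nd$S; row$k <- nd$k
      row$pi <- nd$pi
      row
    }, te_insufficient_sites = function(e)
      empty_popgen_row(family, pn, n = length(idx)))
    r
  })
  do.call(rbind, rows)
}

empty_popgen_row <- function(family, partition, n = NA_integer_) {
  data.frame(family = family, partition = partition, n = n,
             L_used = NA_integer_, S = NA_integer_, k = NA_real_,
             pi = NA_real_, a1 = NA_real_, a2 = NA_real_, b1 = NA_real_,
             b2 = NA_real_, c1 = NA_real_, c2 = NA_real_, e1 = NA_real_,
             e2 = NA_real_, D = NA_real_, p_two_tailed = NA_real_,
             sig_code = NA_character_, stringsAsFactors = FALSE)
}
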