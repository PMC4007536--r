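# Copy-age profiling: JC69 distances, neighbor-joining copy trees, terminal
# branch lengths and the >= 0.05 substitutions/site old-insert rule.

#' Jukes-Cantor (JC69) distance between two sequences
#'
#' d = -(3/4) ln(1 - (4/3) p) over sites where both sequences carry an
#' unambiguous base. Saturated pairs (p >= 0.75) are flagged and capped.
#'
#' @param a,b Equal-length DNA strings (gaps/N excluded pairwise).
#' @param cap Distance assigned to saturated pairs.
#' @return List with \code{d}, \code{p}, \code{sites}, \code{saturated}.
#' @export
jc69_distance <- function(a, b, cap = 3.0) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(x) == length(y))
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("zero usable sites")
  p <- sum(x[ok] != y[ok]) / sum(ok)
  if (p >= 0.75)
    return(list(d = cap, p = p, sites = sum(ok), saturated = TRUE))
  list(d = -0.75 * log(1 - 4 * p / 3), p = p, sites = sum(ok),
       saturated = FALSE)
}

#' JC69 distance matrix for a set of copies
#'
#' @param seqs Equal-length sequences (named, or ids supplied).
#' @param ids Copy identifiers.
#' @param cap Saturation cap in substitutions/site.
#' @return Symmetric distance matrix with a \code{saturated} attribute
#'   (logical matrix of flagged pairs).
#' @export
jc69_matrix <- function(seqs, ids = names(seqs), cap = 3.0) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("copy", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    r <- jc69_distance(seqs[i], seqs[j], cap = cap)
    d[i, j] <- d[j, i] <- r$d
    sat[i, j] <- sat[j, i] <- r$saturated
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree of element copies
#'
#' Classic Saitou-Nei neighbor joining on a JC69 distance matrix. Negative
#' branch-length estimates are clamped to zero with the deficit transferred
#' to the sibling branch, preserving path lengths through the parent.
#'
#' @param d Symmetric distance matrix (ids as dimnames).
#' @return An \code{ape} \code{phylo} tree with branch lengths in
#'   substitutions/site.
#' @export
copy_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 copies")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == parent)
    sib <- setdiff(sib, e)
    tr$edge.length[e] <- 0
    if (length(sib) > 0L)
      tr$edge.length[sib[1L]] <- max(0, tr$edge.length[sib[1L]] + deficit)
  }
  tr
}

#' Terminal branch length of every leaf
#'
#' @param tree A \code{phylo} tree.
#' @return Named numeric vector (leaf -> subtending branch length).
#' @export
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  e <- match(seq_len(ntip), tree$edge[, 2L])
  stats::setNames(tree$edge.length[e], tree$tip.label)
}

#' Copy-age profile from terminal branch lengths
#'
#' Flags copies whose terminal branch length meets the old-insert threshold
#' (0.05 substitutions/site by default) and summarises the family's length
#' distribution as a five-number box summary with 1.5 x IQR whiskers.
#'
#' @param x A \code{phylo} tree or a named numeric vector of terminal
#'   branch lengths.
#' @param threshold Old-insert threshold in substitutions/site.
#' @return List with \code{per_copy} (copy_id, terminal_len, old) and
#'   \code{summary} (median, q1, q3, whisker_lo, whisker_hi, outliers,
#'   n, n_old, old_fraction).
#' @export
age_profile <- function(x, threshold = 0.05) {
  lens <- if (inherits(x, "phylo")) terminal_branch_lengths(x) else x
  if (length(lens) < 2L) stop("need at least 2 copies")
  per <- data.frame(copy_id = names(lens), terminal_len = as.numeric(lens),
                    old = as.numeric(lens) >= threshold,
                    stringsAsFactors = FALSE)
  q <- stats::quantile(per$terminal_len, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- per$terminal_len >= lo & per$terminal_len <= hi
  list(per_copy = per,
       summary = list(median = q[2], q1 = q[1], q3 = q[3],
                      whisker_lo = if (any(inside))
                        min(per$terminal_len[inside]) else NA_real_,
                      whisker_hi = if (any(inside))
                        max(per$terminal_len[inside]) else NA_real_,
                      outliers = per$copy_id[!inside],
                      n = nrow(per), n_old = sum(per$old),
                      old_fraction = mean(per$old)))
}
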