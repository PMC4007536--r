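# Terminus discovery: seeded ungapped scanning of genome sequence with
# family terminus queries, on both strands, with flank extraction.

#' Scan a genome for family-terminus matches
#'
#' Finds candidate matches of family terminus sequences (LTRs, ITRs, UTR
#' termini) in genome contigs by exact k-mer seeding followed by ungapped
#' +1/-1 extension along the seed diagonal. Both strands are searched;
#' reverse-complement matches are reported on the \code{-} strand with
#' flanks re-oriented to the hit strand. Overlapping hits of the same query
#' are merged keeping the higher identity (ties: leftmost).
#'
#' @param genome Data frame of contigs from \code{\link{read_fasta}}.
#' @param queries Data frame with columns \code{family}, \code{end_type}
#'   (\code{five_prime}, \code{three_prime} or \code{ltr}) and \code{seq}.
#'   Queries longer than 300 bp are truncated with a warning.
#' @param seed_len Exact seed length in bp (>= 8).
#' @param min_identity Minimum identity over the reported segment.
#' @param min_cov Minimum fraction of the query covered by the segment.
#' @param flank_len Flank length extracted on each side.
#' @return Data frame of hits: family, end_type, contig, start, end (1-based
#'   inclusive), strand, identity, coverage, full_start/full_end (the whole
#'   query projected onto the contig), up_flank, down_flank, edge_flag.
#' @export
scan_genome <- function(genome, queries, seed_len = 12, min_identity = 0.80,
                        min_cov = 0.50, flank_len = 20) {
  stopifnot(seed_len >= 8)
  if (nrow(queries) == 0L) stop("empty query set")
  qs <- toupper(queries$seq)
  too_long <- nchar(qs) > 300L
  if (any(too_long)) {
    warning(sum(too_long), " query sequence(s) longer than 300 bp truncated")
    qs[too_long] <- substring(qs[too_long], 1L, 300L)
  }
  gseqs <- stats::setNames(toupper(genome$seq), genome$id)
  idx <- kmer_index(gseqs, seed_len)

  # forward queries then their reverse complements, in one batch
  all_q <- c(qs, revcomp(qs))
  strand_of <- rep(c("+", "-"), each = length(qs))
  qrow_of <- rep(seq_len(nrow(queries)), 2L)
  cand <- seed_candidates(idx, all_q, stride_by = 1L)
  hits <- list()
  if (nrow(cand) > 0L) {
    qchars_cache <- lapply(all_q, function(x) strsplit(x, "", fixed = TRUE)[[1]])
    for (i in seq_len(nrow(cand))) {
      qi <- cand$query[i]; si <- cand$subject[i]
      sc <- score_diagonal(qchars_cache[[qi]], idx$chars[[si]],
                           cand$qstart[i])
      if (is.null(sc)) next
      if (sc$identity < min_identity || sc$coverage < min_cov) next
      qlen <- nchar(all_q[qi])
      hits[[length(hits) + 1L]] <- data.frame(
        qrow = qrow_of[qi], contig = idx$seq_names[si],
        start = sc$sstart, end = sc$send, strand = strand_of[qi],
        identity = sc$identity, coverage = sc$coverage,
        full_start = max(1L, cand$qstart[i]),
        full_end = min(idx$seq_lens[si], cand$qstart[i] + qlen - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(family = character(0), end_type = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      full_start = integer(0), full_end = integer(0))
    return(extract_flanks(genome, out, flank_len))
  }
  h <- do.call(rbind, hits)

  # merge overlapping same-query hits: keep higher identity, ties leftmost
  keep <- logical(nrow(h))
  for (qr in unique(h$qrow)) {
    rows <- which(h$qrow == qr)
    for (ctg in unique(h$contig[rows])) {
      rr <- rows[h$contig[rows] == ctg]
      ord <- rr[order(-h$identity[rr], h$start[rr])]
      acc <- integer(0)
      for (i in ord) {
        ov <- any(h$start[i] <= h$end[acc] & h$end[i] >= h$start[acc])
        if (!ov) { keep[i] <- TRUE; acc <- c(acc, i) }
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  out <- data.frame(family = queries$family[h$qrow],
                    end_type = queries$end_type[h$qrow],
                    contig = h$contig, start = h$start, end = h$end,
                    strand = h$strand, identity = h$identity,
                    coverage = h$coverage, full_start = h$full_start,
                    full_end = h$full_end, stringsAsFactors = FALSE)
  out <- out[order(out$family, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  extract_flanks(genome, out, flank_len)
}

#' Extract flanking sequence for terminus hits
#'
#' \code{up_flank} is the \code{flank_len} bases 5' of the hit in the hit's
#' strand orientation, \code{down_flank} the bases 3' of it. Flanks anchor
#' at the full query projection (\code{full_start}/\code{full_end}) when
#' available, so that a terminal mismatch trimmed from the scored segment
#' does not shift the flank window into the element and mask the TSD.
#' Flanks that run off a contig edge are shortened and flagged.
#'
#' @param genome Data frame of contigs.
#' @param hits Hit data frame with contig, start, end, strand columns.
#' @param flank_len Flank length in bp.
#' @return \code{hits} with \code{up_flank}, \code{down_flank} and
#'   \code{edge_flag} columns.
#' @export
extract_flanks <- function(genome, hits, flank_len = 20) {
  gs <- stats::setNames(toupper(genome$seq), genome$id)
  glen <- stats::setNames(nchar(gs), genome$id)
  n <- nrow(hits)
  anchor_s <- if (!is.null(hits$full_start)) hits$full_start else hits$start
  anchor_e <- if (!is.null(hits$full_end)) hits$full_end else hits$end
  up <- character(n); down <- character(n); edge <- logical(n)
  for (i in seq_len(n)) {
    g <- gs[[hits$contig[i]]]
    L <- glen[[hits$contig[i]]]
    left <- substring(g, max(1L, anchor_s[i] - flank_len),
                      anchor_s[i] - 1L)
    right <- substring(g, anchor_e[i] + 1L,
                       min(L, anchor_e[i] + flank_len))
    if (hits$strand[i] == "+") {
      up[i] <- left; down[i] <- right
    } else {
      up[i] <- revcomp(right); down[i] <- revcomp(left)
    }
    edge[i] <- nchar(left) < flank_len || nchar(right) < flank_len
  }
  hits$up_flank <- up
  hits$down_flank <- down
  hits$edge_flag <- edge
  hits
}
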