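# Insert assembly: pair terminus hits into individual element copies using
# TSD + flank evidence, classify FLE vs solo LTR, and profile TSDs.

#' Pair terminus hits into individual element copies
#'
#' For non-LTR and DNA families a \code{five_prime} hit pairs with the
#' nearest downstream \code{three_prime} hit on the same contig and strand
#' within \code{max_span}, iff the \code{tsd_len} bases ending the 5' hit's
#' up-flank equal the \code{tsd_len} bases starting the 3' hit's down-flank
#' (the target-site duplication). For LTR families two \code{ltr} hits pair
#' by the same rule into an FLE; a lone \code{ltr} hit whose own up-flank
#' tail equals its down-flank head is a solo LTR. Hits are consumed greedily
#' in element orientation; hits that pair with nothing are emitted with
#' structure \code{unpaired}.
#'
#' @param hits Hit data frame for one family (from \code{\link{scan_genome}}).
#' @param te_class \code{"LTR"}, \code{"nonLTR"} or \code{"DNA"}.
#' @param tsd_len TSD length in bp; 0 requests proximity-only pairing, which
#'   is flagged low-confidence.
#' @param max_span Maximum span in bp between outer terminus bounds.
#' @param tsd_mismatch Number of mismatches tolerated in the TSD comparison
#'   (default 0, exact).
#' @return Data frame of element copies: copy_id, family, structure, contig,
#'   strand, start, end, five_start/five_end, three_start/three_end,
#'   tsd_seq, span, low_confidence.
#' @export
pair_inserts <- function(hits, te_class = c("LTR", "nonLTR", "DNA"),
                         tsd_len = 5, max_span = 15000, tsd_mismatch = 0) {
  te_class <- match.arg(te_class)
  fam <- if (nrow(hits)) hits$family[1] else NA_character_
  low_conf <- tsd_len == 0
  out <- list()
  emit <- function(structure, h1, h2 = NULL, tsd = NA_character_) {
    s <- min(h1$start, if (is.null(h2)) h1$start else h2$start)
    e <- max(h1$end, if (is.null(h2)) h1$end else h2$end)
    # h1 is always the element-5' hit (hits are consumed in element
    # orientation, which reverses genomic order on the - strand)
    f5 <- h1; f3 <- h2
    fs <- function(h, col, alt) if (!is.null(h[[col]])) h[[col]] else h[[alt]]
    out[[length(out) + 1L]] <<- data.frame(
      copy_id = NA_character_, family = fam, structure = structure,
      contig = h1$contig, strand = h1$strand, start = s, end = e,
      five_start = f5$start, five_end = f5$end,
      five_full_start = fs(f5, "full_start", "start"),
      five_full_end = fs(f5, "full_end", "end"),
      three_start = if (is.null(f3)) NA_integer_ else f3$start,
      three_end = if (is.null(f3)) NA_integer_ else f3$end,
      three_full_start = if (is.null(f3)) NA_integer_ else
        fs(f3, "full_start", "start"),
      three_full_end = if (is.null(f3)) NA_integer_ else
        fs(f3, "full_end", "end"),
      tsd_seq = tsd, span = e - s + 1L, low_confidence = low_conf,
      stringsAsFactors = FALSE)
  }
  tsd_match <- function(up, down) {
    if (tsd_len == 0) return(list(ok = TRUE, tsd = ""))
    a <- substring(up, nchar(up) - tsd_len + 1L)
    b <- substring(down, 1L, tsd_len)
    if (nchar(a) < tsd_len || nchar(b) < tsd_len)
      return(list(ok = FALSE, tsd = NA_character_))
    mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    list(ok = mm <= tsd_mismatch, tsd = a)
  }

  for (ctg in unique(hits$contig)) for (std in c("+", "-")) {
    rows <- which(hits$contig == ctg & hits$strand == std)
    if (length(rows) == 0L) next
    # element orientation: ascending on +, descending on -
    rows <- rows[order(hits$start[rows],
                       decreasing = identical(std, "-"))]
    used <- rep(FALSE, length(rows))
    for (a in seq_along(rows)) {
      if (used[a]) next
      h1 <- hits[rows[a], ]
      used[a] <- TRUE
      first_type <- if (te_class == "LTR") "ltr" else "five_prime"
      second_type <- if (te_class == "LTR") "ltr" else "three_prime"
      paired <- FALSE
      if (h1$end_type == first_type) {
        # nearest downstream (in element orientation) candidate partner
        b <- a + 1L
        while (b <= length(rows) && used[b]) b <- b + 1L
        if (b <= length(rows)) {
          h2 <- hits[rows[b], ]
          span <- max(h1$end, h2$end) - min(h1$start, h2$start) + 1L
          if (h2$end_type == second_type && span <= max_span) {
            tm <- tsd_match(h1$up_flank, h2$down_flank)
            if (tm$ok) {
              emit(if (te_class == "LTR") "FLE" else "full", h1, h2, tm$tsd)
              used[b] <- TRUE
              paired <- TRUE
            }
          }
        }
      }
      if (!paired && te_class == "LTR" && h1$end_type == "ltr" &&
          tsd_len > 0) {
        tm <- tsd_match(h1$up_flank, h1$down_flank)
        if (tm$ok) {
          emit("soloLTR", h1, NULL, tm$tsd)
          paired <- TRUE
        }
      }
      if (!paired) emit("unpaired", h1, NULL)
    }
  }
  if (length(out) == 0L)
    return(data.frame(copy_id = character(0), family = character(0),
                      structure = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), five_start = integer(0),
                      five_end = integer(0), five_full_start = integer(0),
                      five_full_end = integer(0), three_start = integer(0),
                      three_end = integer(0), three_full_start = integer(0),
                      three_full_end = integer(0), tsd_seq = character(0),
                      span = integer(0), low_confidence = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  res$copy_id <- sprintf("%s_i%03d", fam, seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Intra-element LTR identity
#'
#' Percent identity between the 5' and 3' LTR of one full-length element;
#' identical at insertion, the two LTRs diverge with copy age, so identity
#' near 100 marks a recent insert.
#'
#' @param ltr5,ltr3 The two LTR sequences. Unequal lengths are compared over
#'   the shared prefix with a warning.
#' @return Percent identity, rounded to one decimal.
#' @export
intra_ltr_identity <- function(ltr5, ltr3) {
  a <- strsplit(toupper(ltr5), "")[[1]]
  b <- strsplit(toupper(ltr3), "")[[1]]
  if (length(a) != length(b)) {
    warning("LTR lengths differ; comparing shared prefix")
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]; b <- b[seq_len(n)]
  }
  if (length(a) == 0L) stop("empty LTR sequence")
  round(100 * sum(a == b) / length(a), 1)
}

#' Infer a family's TSD length from paired flanks
#'
#' For each insert, the longest k in \code{scan_range} such that the last k
#' bases of the up-flank equal the first k bases of the down-flank; the
#' family length is the modal per-insert value (ties: smallest).
#'
#' @param up_flanks,down_flanks Character vectors (one element per insert).
#' @param scan_range Candidate TSD lengths.
#' @return List with \code{inferred_len} (NA when fewer than 3 inserts carry
#'   a duplication), \code{per_insert} lengths (NA = TSD-absent) and
#'   \code{tsd_seqs}.
#' @export
infer_tsd_len <- function(up_flanks, down_flanks, scan_range = 2:12) {
  stopifnot(length(up_flanks) == length(down_flanks))
  per <- rep(NA_integer_, length(up_flanks))
  seqs <- rep(NA_character_, length(up_flanks))
  for (i in seq_along(up_flanks)) {
    up <- toupper(up_flanks[i]); down <- toupper(down_flanks[i])
    best <- NA_integer_
    for (k in sort(scan_range)) {
      if (nchar(up) < k || nchar(down) < k) break
      a <- substring(up, nchar(up) - k + 1L)
      if (a == substring(down, 1L, k)) best <- k
    }
    per[i] <- best
    if (!is.na(best)) seqs[i] <- substring(up, nchar(up) - best + 1L)
  }
  found <- per[!is.na(per)]
  inferred <- NA_integer_
  if (length(found) >= 3L) {
    tab <- table(found)
    inferred <- as.integer(names(tab)[which.max(tab)])
  }
  list(inferred_len = inferred, per_insert = per, tsd_seqs = seqs)
}

#' Positional base composition of a family's TSDs
#'
#' @param tsds Character vector of equal-length TSD sequences.
#' @return List with \code{freq} (positions x A,C,G,T frequency matrix,
#'   rows summing to 1), \code{gc_by_position} and \code{n_sites}.
#' @export
tsd_composition <- function(tsds) {
  tsds <- toupper(tsds[!is.na(tsds) & nzchar(tsds)])
  if (length(tsds) == 0L) stop("no TSD sequences")
  lens <- nchar(tsds)
  if (length(unique(lens)) != 1L)
    stop("TSDs have mixed lengths: ", paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(tsds, "", fixed = TRUE))
  L <- ncol(m)
  freq <- t(vapply(seq_len(L), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / sum(tab)
  }, numeric(4)))
  colnames(freq) <- c("A", "C", "G", "T")
  rownames(freq) <- seq_len(L)
  list(freq = freq, gc_by_position = freq[, "C"] + freq[, "G"],
       n_sites = length(tsds))
}
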