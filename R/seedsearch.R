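# Seeded ungapped search engine.
#
# Shared by genome terminus scanning (discover) and read-to-consensus mapping
# (express). Exact k-mer seeds anchor candidate diagonals; each diagonal is
# then scored ungapped (+1 match / -1 mismatch) and the maximal-scoring
# segment is taken as the hit. No indels are modelled.

# k-mer index over a set of subject sequences.
# Returns the subject metadata plus, per distinct k-mer, the positions at
# which it occurs, encoded as (subject_idx - 1) * stride + position.
kmer_index <- function(seqs, k) {
  stopifnot(k >= 4, length(seqs) >= 1)
  lens <- nchar(seqs)
  stride <- max(lens) + 1L
  enc <- integer(0)
  kms <- character(0)
  pieces_enc <- vector("list", length(seqs))
  pieces_km <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    n <- lens[i]
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    pieces_km[[i]] <- substring(seqs[i], starts, starts + k - 1L)
    pieces_enc[[i]] <- (i - 1L) * stride + starts
  }
  kms <- unlist(pieces_km, use.names = FALSE)
  enc <- unlist(pieces_enc, use.names = FALSE)
  keep <- !grepl("N", kms, fixed = TRUE)
  tab <- split(enc[keep], kms[keep])
  list(k = k, stride = stride, tab = tab, keys = names(tab),
       seq_names = names(seqs), seq_lens = lens,
       chars = lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
}

# Batched candidate diagonals for a set of query strings against an index.
# seed_starts: list (per query) of 1-based seed offsets; NULL = every offset.
# Returns data.frame(query, subject, qstart) where qstart is the (possibly
# out-of-range) subject coordinate aligned with query position 1.
seed_candidates <- function(index, queries, stride_by = 1L) {
  k <- index$k
  qlens <- nchar(queries)
  qk <- vector("list", length(queries))
  qoff <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    n <- qlens[i]
    if (n < k) next
    offs <- unique(c(seq(1L, n - k + 1L, by = stride_by), n - k + 1L))
    qk[[i]] <- substring(queries[i], offs, offs + k - 1L)
    qoff[[i]] <- offs
  }
  kms <- unlist(qk, use.names = FALSE)
  if (length(kms) == 0L)
    return(data.frame(query = integer(0), subject = integer(0),
                      qstart = integer(0)))
  qidx <- rep(seq_along(queries), lengths(qk))
  offs <- unlist(qoff, use.names = FALSE)
  m <- match(kms, index$keys)
  hit <- !is.na(m)
  if (!any(hit))
    return(data.frame(query = integer(0), subject = integer(0),
                      qstart = integer(0)))
  hits_enc <- index$tab[m[hit]]
  nrep <- lengths(hits_enc)
  enc <- unlist(hits_enc, use.names = FALSE)
  subj <- (enc - 1L) %/% index$stride + 1L
  spos <- enc - (subj - 1L) * index$stride
  out <- data.frame(query = rep(qidx[hit], nrep),
                    subject = subj,
                    qstart = spos - rep(offs[hit], nrep) + 1L)
  unique(out)
}

# Maximal-scoring (+1/-1) segment of a logical match vector (Kadane).
# Returns c(start, end, matches) or NULL when every position mismatches.
best_segment <- function(match) {
  s <- ifelse(match, 1L, -1L)
  cs <- cumsum(s)
  prev <- c(0L, cs[-length(cs)])
  lo <- cummin(prev)
  gain <- cs - lo
  j <- which.max(gain)
  if (gain[j] <= 0L) return(NULL)
  i <- which(prev[seq_len(j)] == lo[j])[1L]
  c(i, j, sum(match[i:j]))
}

# Score one candidate diagonal: align query chars against subject chars at
# qstart, clip to the subject, and extract the maximal-scoring segment.
# Returns NULL or list(sstart, send, identity, coverage, matches).
score_diagonal <- function(qchars, schars, qstart) {
  qlen <- length(qchars)
  slen <- length(schars)
  q_lo <- max(1L, 1L - qstart + 1L)
  q_hi <- min(qlen, slen - qstart + 1L)
  if (q_hi - q_lo + 1L < 1L) return(NULL)
  qs <- qchars[q_lo:q_hi]
  ss <- schars[(qstart + q_lo - 1L):(qstart + q_hi - 1L)]
  mt <- qs == ss & qs != "N" & ss != "N"
  seg <- best_segment(mt)
  if (is.null(seg)) return(NULL)
  len <- seg[2L] - seg[1L] + 1L
  list(sstart = qstart + q_lo - 1L + seg[1L] - 1L,
       send = qstart + q_lo - 1L + seg[2L] - 1L,
       identity = seg[3L] / len,
       coverage = len / qlen,
       matches = seg[3L])
}
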