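# Independent oracles used across tests. These deliberately re-derive every
# quantity from first principles (naive double loops, direct formula
# evaluation) and never call the package's own computation paths.

# brute-force pi/k/S under complete deletion: all pairs x all columns
oracle_pi_k_s <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  if (ncol(m) == 0) return(NULL)
  total <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  S <- 0L
  for (c in seq_len(ncol(m))) if (length(unique(m[, c])) > 1) S <- S + 1L
  list(k = total / np, pi = (total / np) / ncol(m), S = S, n = n,
       L = ncol(m))
}

# direct evaluation of the Tajima test statistic from n, S, k
oracle_tajima_d <- function(n, S, k) {
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# random alignment: descendants of one ancestor with iid substitutions, a
# sprinkle of gaps when gapped = TRUE
random_alignment_rows <- function(n, L, sub_p = 0.1, gapped = FALSE) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    x <- anc
    hit <- runif(L) < sub_p
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    if (gapped) {
      g <- runif(L) < 0.05
      x[g] <- "-"
    }
    paste(x, collapse = "")
  }, character(1))
  rows
}

# all-pairs path lengths on a phylo tree (naive; independent of ape's
# cophenetic): sums edge lengths along the unique leaf-to-leaf paths
oracle_path_lengths <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nodes)
    d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(d[u])) {
          d[u] <- d[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    d
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) out[i, ] <- dist_from(i)[seq_len(n)]
  out
}

# best ungapped full-query window by exhaustive sliding-window identity
oracle_best_window <- function(genome, query) {
  g <- strsplit(genome, "")[[1]]
  q <- strsplit(query, "")[[1]]
  L <- length(g); k <- length(q)
  best <- c(identity = -1, start = NA)
  for (s in 1:(L - k + 1)) {
    id <- mean(g[s:(s + k - 1)] == q)
    if (id > best["identity"]) best <- c(identity = id, start = s)
  }
  best
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}
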