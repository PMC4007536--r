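# Synthetic TE family generator.
#
# Copies are i.i.d. descendants of a (sub)family founder under a
# Jukes-Cantor-style clock: a copy of age t carries independent per-site
# substitutions with probability p(t) = 1 - exp(-mu * t), each to one of the
# three alternative bases uniformly. LTR copies duplicate the founder LTR at
# insertion and the two LTRs then mutate independently; ectopic recombination
# converts an FLE of age t to a solo LTR with probability 1 - exp(-rho * t)
# (the 5' LTR is retained by convention). Non-LTR copies are 5'-truncated
# with probability q at a uniform breakpoint. Age units are arbitrary: only
# mu * t products matter.

#' Describe one transposable-element family for simulation
#'
#' @param name Family name.
#' @param te_class One of \code{"LTR"}, \code{"nonLTR"}, \code{"DNA"}.
#' @param terminus_len Length in bp of the analyzed terminus (the LTR for LTR
#'   retrotransposons; the 5' ITR / 3' UTR otherwise).
#' @param internal_len Length in bp of the internal region.
#' @param tsd_len Target-site duplication length in bp (0 = none).
#' @param target_pref Insertion-site preference: \code{"none"} (uniform),
#'   \code{"TA"} (only at TA dinucleotides), or \code{"GC_ends"} (sites
#'   weighted towards G/C at positions 1 and 5 of the target k-mer).
#' @param history Insertion history from \code{\link{burst_history}} or
#'   \code{\link{constant_history}}.
#' @param subfamily_split_age Age at which two founder lineages diverged;
#'   0 keeps a single lineage.
#' @param mu Substitution rate per site per time unit.
#' @param solo_rate Per-time ectopic-recombination rate converting FLEs to
#'   solo LTRs (LTR class only).
#' @param trunc_prob Probability of 5' truncation (non-LTR class only).
#' @param loss_rate Per-time removal rate of intact (non-solo) copies.
#' @param stage_means Mean read counts for the three life-cycle stages
#'   (adherent, floating, aggregate).
#' @param dispersion Negative-binomial size parameter for read counts.
#' @return A \code{te_family} model object.
#' @export
te_family <- function(name, te_class = c("LTR", "nonLTR", "DNA"),
                      terminus_len = 150, internal_len = 1000, tsd_len = 5,
                      target_pref = c("none", "TA", "GC_ends"),
                      history = burst_history(1, 10),
                      subfamily_split_age = 0, mu = 0.01,
                      solo_rate = 0, trunc_prob = 0, loss_rate = 0,
                      stage_means = c(100, 100, 100), dispersion = 10) {
  te_class <- match.arg(te_class)
  target_pref <- match.arg(target_pref)
  stopifnot(mu > 0, trunc_prob >= 0, trunc_prob <= 1,
            tsd_len >= 0, terminus_len >= 1, internal_len >= 0,
            subfamily_split_age >= 0, length(stage_means) == 3,
            all(stage_means >= 0), dispersion > 0)
  structure(list(name = name, te_class = te_class,
                 terminus_len = as.integer(terminus_len),
                 internal_len = as.integer(internal_len),
                 tsd_len = as.integer(tsd_len), target_pref = target_pref,
                 history = history,
                 subfamily_split_age = subfamily_split_age, mu = mu,
                 solo_rate = solo_rate, trunc_prob = trunc_prob,
                 loss_rate = loss_rate, stage_means = as.numeric(stage_means),
                 dispersion = dispersion),
            class = "te_family")
}

#' @rdname te_family
#' @param ages,counts Burst ages (time units) and copy counts per burst.
#' @export
burst_history <- function(ages, counts) {
  stopifnot(length(ages) == length(counts), all(ages >= 0), all(counts >= 0))
  list(type = "burst", ages = ages, counts = as.integer(counts))
}

#' @rdname te_family
#' @param rate Insertions per time unit.
#' @param horizon Time horizon over which insertions accrue.
#' @export
constant_history <- function(rate, horizon) {
  stopifnot(rate > 0, horizon > 0)
  list(type = "constant", rate = rate, horizon = horizon)
}

# p(t) = 1 - exp(-mu t): per-site substitution probability for age t
p_subst <- function(mu, t) 1 - exp(-mu * t)

random_seq <- function(n, gc = 0.5) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# substitute each site independently with probability p, uniform over the
# three alternative bases
mutate_chars <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) == 0L) return(chars)
  alts <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"), 3,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  pick <- sample.int(3L, length(hit), replace = TRUE)
  chars[hit] <- alts[cbind(pick, match(chars[hit], colnames(alts)))]
  chars
}

#' Simulate the copies of one TE family
#'
#' Draws insertion ages from the family history, evolves each copy from its
#' (sub)family founder under the clock model, applies solo-LTR conversion,
#' 5' truncation and copy loss, and returns the surviving copies with a
#' per-copy truth table.
#'
#' @param model A \code{\link{te_family}} model.
#' @param rng_seed Integer seed; the call is fully deterministic given it.
#' @return A list with elements \code{model}, \code{consensus} (list with
#'   \code{five}, \code{internal}, \code{three}, \code{full} sequences),
#'   \code{copies} (data frame: copy_id, structure, age, subfamily, seq,
#'   five_seq, three_seq) and \code{truth} (per-copy truth records, genome
#'   intervals unset until planting).
#' @export
simulate_family <- function(model, rng_seed) {
  stopifnot(inherits(model, "te_family"))
  set.seed(rng_seed)
  tl <- model$terminus_len
  il <- model$internal_len
  five0 <- random_seq(tl)
  internal0 <- random_seq(il)
  three0 <- if (model$te_class == "LTR") five0 else random_seq(tl)

  h <- model$history
  ages <- switch(h$type,
    burst = rep(h$ages, h$counts),
    constant = {
      n <- stats::rpois(1L, h$rate * h$horizon)
      stats::runif(n, 0, h$horizon)
    })
  if (length(ages) == 0L) stop("zero copies requested for family ", model$name)

  # two founder lineages when a subfamily split is modelled; the second
  # founder diverged from the first subfamily_split_age time units ago
  split <- model$subfamily_split_age
  founders <- list(list(five = five0, internal = internal0, three = three0))
  sub <- rep(1L, length(ages))
  if (split > 0) {
    pd <- p_subst(model$mu, split)
    f2 <- list(five = mutate_chars(five0, pd),
               internal = mutate_chars(internal0, pd),
               three = if (model$te_class == "LTR") NULL
                       else mutate_chars(three0, pd))
    if (model$te_class == "LTR") f2$three <- f2$five
    founders[[2L]] <- f2
    sub <- sample(c(1L, 2L), length(ages), replace = TRUE)
  }

  # intact-copy loss: survival exp(-loss_rate * t); solo LTRs are exempt
  # (they are near-neutral relics), which lets old cohorts become
  # solo-enriched as in real LTR family demography
  is_solo <- rep(FALSE, length(ages))
  if (model$te_class == "LTR" && model$solo_rate > 0)
    is_solo <- stats::runif(length(ages)) < (1 - exp(-model$solo_rate * ages))
  surv <- rep(TRUE, length(ages))
  if (model$loss_rate > 0) {
    pl <- exp(-model$loss_rate * ages)
    keep <- stats::runif(length(ages)) < pl
    surv <- is_solo | keep
  }

  ids <- sprintf("%s_c%03d", model$name, seq_along(ages))
  n <- length(ages)
  seqs <- character(n); five_s <- character(n); three_s <- character(n)
  struct <- character(n)
  for (i in seq_len(n)) {
    f <- founders[[sub[i]]]
    p <- p_subst(model$mu, ages[i])
    if (model$te_class == "LTR") {
      l5 <- mutate_chars(f$five, p)
      l3 <- mutate_chars(f$five, p)    # both LTRs identical at insertion
      if (is_solo[i]) {
        struct[i] <- "soloLTR"
        seqs[i] <- paste(l5, collapse = "")
        five_s[i] <- seqs[i]; three_s[i] <- NA_character_
      } else {
        struct[i] <- "FLE"
        body <- mutate_chars(f$internal, p)
        seqs[i] <- paste(c(l5, body, l3), collapse = "")
        five_s[i] <- paste(l5, collapse = "")
        three_s[i] <- paste(l3, collapse = "")
      }
    } else {
      el <- mutate_chars(c(f$five, f$internal, f$three), p)
      trunc <- model$te_class == "nonLTR" &&
        stats::runif(1) < model$trunc_prob
      if (trunc) {
        bp <- sample.int(length(el) - 1L, 1L)   # keep the 3' suffix
        el <- el[(bp + 1L):length(el)]
        struct[i] <- "truncated"
        five_s[i] <- NA_character_
      } else {
        struct[i] <- "full"
        five_s[i] <- paste(el[seq_len(tl)], collapse = "")
      }
      seqs[i] <- paste(el, collapse = "")
      three_s[i] <- substring(seqs[i], nchar(seqs[i]) - tl + 1L)
    }
  }
  copies <- data.frame(copy_id = ids, family = model$name, structure = struct,
                       age = ages, subfamily = sub, seq = seqs,
                       five_seq = five_s, three_seq = three_s,
                       stringsAsFactors = FALSE)[surv, , drop = FALSE]
  rownames(copies) <- NULL
  truth <- copies[, c("copy_id", "family", "structure", "age")]
  truth$contig <- NA_character_; truth$start <- NA_integer_
  truth$end <- NA_integer_; truth$strand <- NA_character_
  truth$tsd <- NA_character_
  list(model = model,
       consensus = list(five = paste(five0, collapse = ""),
                        internal = paste(internal0, collapse = ""),
                        three = paste(three0, collapse = ""),
                        full = paste(c(five0, internal0, three0),
                                     collapse = "")),
       copies = copies, truth = truth)
}

#' Plant simulated TE copies into a random background genome
#'
#' Each copy is inserted at a site drawn according to its family's target
#' preference; the \code{tsd_len} target bases are duplicated so the insert
#' is flanked by identical TSDs. Placements never overlap.
#'
#' @param background_len Background genome length in bp.
#' @param background_gc Background GC fraction.
#' @param families List of \code{\link{simulate_family}} results.
#' @param rng_seed Integer seed.
#' @param contig Contig name for the planted genome.
#' @param min_gap Minimum background separation between insertion points.
#' @param gc_weight Sampling-weight multiplier per G/C at target positions 1
#'   and 5 under the \code{GC_ends} preference.
#' @return List with \code{genome} (data frame id/seq) and \code{truth}
#'   (per-copy intervals, TSDs, strands and terminus coordinates).
#' @export
plant_genome <- function(background_len, background_gc, families, rng_seed,
                         contig = "chr1", min_gap = 50L, gc_weight = 1.8) {
  set.seed(rng_seed)
  bg <- random_seq(background_len, background_gc)
  all_copies <- do.call(rbind, lapply(families, function(f) {
    cp <- f$copies
    cp$tsd_len <- f$model$tsd_len
    cp$target_pref <- f$model$target_pref
    cp$terminus_len <- f$model$terminus_len
    cp$te_class <- f$model$te_class
    cp
  }))
  n <- nrow(all_copies)
  margin <- 200L
  lo <- margin; hi <- background_len - margin

  # pick non-overlapping insertion points per target preference; rejection
  # sampling against the sorted set of accepted points keeps this O(n log n)
  pts <- integer(n)
  taken <- integer(0)
  bg2 <- paste(bg, collapse = "")
  ta_sites <- which(bg[-length(bg)] == "T" & bg[-1L] == "A")
  ta_sites <- ta_sites[ta_sites >= lo & ta_sites <= hi]
  gc_cum <- NULL
  if (any(all_copies$target_pref == "GC_ends")) {
    g1 <- bg[lo:hi] %in% c("G", "C")
    g5 <- bg[(lo + 4L):(hi + 4L)] %in% c("G", "C")
    gc_cum <- cumsum(gc_weight^(g1 + g5))
  }
  clear_of <- function(p) {
    if (length(taken) == 0L) return(TRUE)
    j <- findInterval(p, taken)
    (j == 0L || p - taken[j] >= min_gap) &&
      (j == length(taken) || taken[j + 1L] - p >= min_gap)
  }
  for (i in seq_len(n)) {
    pref <- all_copies$target_pref[i]
    placed <- FALSE
    for (try in seq_len(2000L)) {
      p <- if (pref == "TA") {
        if (length(ta_sites) == 0L) break
        ta_sites[sample.int(length(ta_sites), 1L)]
      } else if (pref == "GC_ends") {
        u <- stats::runif(1, 0, gc_cum[length(gc_cum)])
        lo + findInterval(u, gc_cum)
      } else {
        lo + sample.int(hi - lo + 1L, 1L) - 1L
      }
      if (clear_of(p)) {
        pts[i] <- p
        taken <- sort(c(taken, p))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("insufficient placement sites (preference ", pref, ")")
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)

  ord <- order(pts)
  pieces <- character(2L * n + 1L)
  truth <- all_copies[ord, c("copy_id", "family", "structure", "age")]
  truth$contig <- contig
  truth$start <- NA_integer_; truth$end <- NA_integer_
  truth$strand <- strands[ord]
  truth$tsd <- NA_character_
  truth$five_start <- NA_integer_; truth$five_end <- NA_integer_
  truth$three_start <- NA_integer_; truth$three_end <- NA_integer_
  off <- 0L
  prev <- 1L
  for (j in seq_len(n)) {
    i <- ord[j]
    p <- pts[i]
    tsd <- all_copies$tsd_len[i]
    el <- all_copies$seq[i]
    if (truth$strand[j] == "-") el <- revcomp(el)
    pieces[2L * j - 1L] <- substring(bg2, prev, p + tsd - 1L)
    pieces[2L * j] <- el
    start <- p + tsd + off
    end <- start + nchar(el) - 1L
    truth$start[j] <- start; truth$end[j] <- end
    truth$tsd[j] <- if (tsd > 0L) substring(bg2, p, p + tsd - 1L) else ""
    tl <- all_copies$terminus_len[i]
    st <- all_copies$structure[i]
    has5 <- st %in% c("FLE", "full", "soloLTR")
    has3 <- st %in% c("FLE", "full", "truncated")
    if (truth$strand[j] == "+") {
      if (has5) { truth$five_start[j] <- start
                  truth$five_end[j] <- start + tl - 1L }
      if (has3) { truth$three_start[j] <- end - tl + 1L
                  truth$three_end[j] <- end }
    } else {
      if (has5) { truth$five_start[j] <- end - tl + 1L
                  truth$five_end[j] <- end }
      if (has3) { truth$three_start[j] <- start
                  truth$three_end[j] <- start + tl - 1L }
    }
    off <- off + nchar(el) + tsd
    prev <- p
  }
  pieces[2L * n + 1L] <- substring(bg2, prev, background_len)
  genome <- data.frame(id = contig, description = "",
                       seq = paste(pieces, collapse = ""),
                       stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Simulate stage-structured RNA-seq read sets
#'
#' Per family, stage and replicate, a read count is drawn from a negative
#' binomial with the family's stage mean and dispersion; reads are sampled
#' uniformly along uniformly chosen copies on either strand, with independent
#' substitution errors.
#'
#' @param families List of \code{\link{simulate_family}} results.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param rng_seed Integer seed.
#' @param stages Stage names.
#' @param replicates Replicates per stage.
#' @param out_dir Optional directory; when given, reads are written as
#'   \code{<stage>_<rep>.fa} FASTA files.
#' @return List with \code{reads} (named list of read data frames, one per
#'   stage/replicate) and \code{truth_counts} (family x stage x replicate).
#' @export
simulate_reads <- function(families, read_len = 60, error_rate = 0.01,
                           rng_seed = 1,
                           stages = c("adherent", "floating", "aggregate"),
                           replicates = 3, out_dir = NULL) {
  set.seed(rng_seed)
  read_len <- as.integer(read_len)
  sets <- list()
  truth <- data.frame()
  for (s in seq_along(stages)) for (r in seq_len(replicates)) {
    recs <- list()
    for (f in families) {
      mu <- f$model$stage_means[s]
      cnt <- if (mu <= 0) 0L else
        stats::rnbinom(1L, mu = mu, size = f$model$dispersion)
      truth <- rbind(truth, data.frame(family = f$model$name,
                                       stage = stages[s], replicate = r,
                                       count = cnt))
      if (cnt == 0L) next
      lens <- nchar(f$copies$seq)
      elig <- which(lens >= read_len)
      if (length(elig) == 0L)
        stop("read_len exceeds every copy of family ", f$model$name)
      ci <- elig[sample.int(length(elig), cnt, replace = TRUE)]
      pos <- floor(stats::runif(cnt) * (lens[ci] - read_len + 1L)) + 1L
      rd <- substring(f$copies$seq[ci], pos, pos + read_len - 1L)
      flip <- stats::runif(cnt) < 0.5
      rd[flip] <- revcomp(rd[flip])
      if (error_rate > 0) {
        rd <- vapply(rd, function(x) {
          ch <- strsplit(x, "", fixed = TRUE)[[1]]
          paste(mutate_chars(ch, error_rate), collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      recs[[f$model$name]] <- data.frame(
        id = sprintf("%s|%s|%d|%d", f$model$name, stages[s], r,
                     seq_len(cnt)),
        description = "", seq = rd, stringsAsFactors = FALSE)
    }
    key <- sprintf("%s_%d", stages[s], r)
    sets[[key]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(id = character(0), description = character(0),
                 seq = character(0))
    rownames(sets[[key]]) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(sets[[key]], file.path(out_dir, paste0(key, ".fa")))
    }
  }
  list(reads = sets, truth_counts = truth)
}
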