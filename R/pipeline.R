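# End-to-end orchestration: simulate -> discover -> assemble -> popgen ->
# age -> express, with a Tables-1-3-shaped per-family summary.

#' Demo run configuration
#'
#' Three synthetic families exercising the regimes the analysis is designed
#' to distinguish: a recent-burst LTR retrotransposon (negative Tajima's D,
#' mixed FLE/solo), a two-subfamily non-LTR retrotransposon (positive D,
#' 5'-truncated copies) and a constant-rate DNA transposon with a TA target
#' site.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A run-configuration list for \code{\link{run_all}}.
#' @export
demo_config <- function(seed = 42, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    background_len = 200000L,
    background_gc = 0.54,
    read_len = 60L,
    error_rate = 0.01,
    seed_len = 12L, min_identity = 0.80, min_cov = 0.50, flank_len = 20L,
    max_span = 15000L, tsd_scan = 2:12, age_threshold = 0.05, alpha = 0.05,
    map_k = 10L, map_min_identity = 0.80, map_min_cov = 0.80,
    families = list(
      te_family("CvLTR1", "LTR", terminus_len = 150, internal_len = 1500,
                tsd_len = 5, target_pref = "GC_ends",
                history = burst_history(1.0, 20), mu = 0.01,
                solo_rate = 0.35,
                stage_means = c(1500, 250, 80), dispersion = 8),
      te_family("CvLINE1", "nonLTR", terminus_len = 200,
                internal_len = 1200, tsd_len = 9, target_pref = "none",
                history = burst_history(0.25, 18),
                subfamily_split_age = 8, mu = 0.01, trunc_prob = 0.2,
                stage_means = c(250, 250, 450), dispersion = 8),
      te_family("CvDNA1", "DNA", terminus_len = 100, internal_len = 800,
                tsd_len = 2, target_pref = "TA",
                history = constant_history(3, 5), mu = 0.01,
                stage_means = c(60, 600, 150), dispersion = 8)))
}

#' Read a run configuration from a YAML file
#'
#' Every field of \code{\link{demo_config}} has a YAML twin; family entries
#' are passed to \code{\link{te_family}} (with \code{history} given as
#' \code{type: burst, ages: [...], counts: [...]} or
#' \code{type: constant, rate: r, horizon: T}).
#'
#' @param path YAML file path.
#' @return A run-configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$families <- lapply(cfg$families, function(f) {
    h <- f$history
    f$history <- if (identical(h$type, "constant"))
      constant_history(h$rate, h$horizon)
    else burst_history(unlist(h$ages), unlist(h$counts))
    do.call(te_family, f)
  })
  cfg
}

slice_seq <- function(genome_seq, start, end, strand) {
  s <- substring(genome_seq, start, end)
  if (strand == "-") revcomp(s) else s
}

# family terminus queries for scan_genome, per the analyzed ends:
# LTR -> the LTR; nonLTR/DNA -> both termini
family_queries <- function(sims) {
  do.call(rbind, lapply(sims, function(f) {
    m <- f$model
    if (m$te_class == "LTR")
      data.frame(family = m$name, end_type = "ltr",
                 seq = f$consensus$five, stringsAsFactors = FALSE)
    else
      data.frame(family = m$name,
                 end_type = c("five_prime", "three_prime"),
                 seq = c(f$consensus$five, f$consensus$three),
                 stringsAsFactors = FALSE)
  }))
}

# one analysis sequence per recovered copy, sliced at the full query
# projection so all sequences of a family are equal length:
# LTR -> one LTR per insert (5' of FLE, the lone LTR of a solo);
# nonLTR -> the 3' terminus (full and truncated copies);
# DNA -> the 5' ITR of paired copies.
analysis_seqs <- function(genome_seq, copies, hits, te_class) {
  if (te_class == "LTR") {
    rows <- copies[copies$structure %in% c("FLE", "soloLTR"), , drop = FALSE]
    if (nrow(rows) == 0L) return(stats::setNames(character(0), character(0)))
    seqs <- mapply(slice_seq, rows$five_full_start, rows$five_full_end,
                   rows$strand, MoreArgs = list(genome_seq = genome_seq))
    return(stats::setNames(as.character(seqs), rows$copy_id))
  }
  if (te_class == "nonLTR") {
    # near-complete termini only: a partially truncated 3' end would drag
    # flanking DNA into the alignment and flood it with spurious singletons
    h <- hits[hits$end_type == "three_prime" & hits$coverage >= 0.9, ,
              drop = FALSE]
    if (nrow(h) == 0L) return(stats::setNames(character(0), character(0)))
    seqs <- mapply(slice_seq, h$full_start, h$full_end, h$strand,
                   MoreArgs = list(genome_seq = genome_seq))
    return(stats::setNames(as.character(seqs),
                           sprintf("%s_t%03d", h$family[1], seq_len(nrow(h)))))
  }
  rows <- copies[copies$structure == "full", , drop = FALSE]
  if (nrow(rows) == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- mapply(slice_seq, rows$five_full_start, rows$five_full_end,
                 rows$strand, MoreArgs = list(genome_seq = genome_seq))
  stats::setNames(as.character(seqs), rows$copy_id)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates the configured families, plants them in a background genome,
#' simulates stage-structured reads, then runs terminus discovery, TSD-based
#' insert assembly, diversity statistics, copy-age profiling and expression
#' analysis, writing all module tables (and Newick copy trees) when an
#' output directory is configured.
#'
#' @param config Run configuration from \code{\link{demo_config}} or
#'   \code{\link{read_run_config}}.
#' @return Invisibly, a list with every intermediate and the per-family
#'   \code{summary} table.
#' @export
run_all <- function(config = demo_config()) {
  cfg <- config
  seed <- cfg$seed
  te_log("INFO", "run_all start, seed=", seed)

  sims <- lapply(seq_along(cfg$families), function(i)
    simulate_family(cfg$families[[i]], rng_seed = seed + i))
  names(sims) <- vapply(sims, function(f) f$model$name, character(1))
  planted <- plant_genome(cfg$background_len, cfg$background_gc, sims,
                          rng_seed = seed + 100L)
  reads <- simulate_reads(sims, read_len = cfg$read_len,
                          error_rate = cfg$error_rate,
                          rng_seed = seed + 200L)

  queries <- family_queries(sims)
  hits <- scan_genome(planted$genome, queries, seed_len = cfg$seed_len,
                      min_identity = cfg$min_identity,
                      min_cov = cfg$min_cov, flank_len = cfg$flank_len)

  gseq <- planted$genome$seq[1]
  copies_list <- list(); tsd_list <- list(); stats_list <- list()
  ages_list <- list(); trees <- list(); tsd_info <- list()
  ltr_ident <- list()
  for (f in sims) {
    m <- f$model
    fh <- hits[hits$family == m$name, , drop = FALSE]
    # provisional proximity pairing feeds TSD-length inference, which then
    # drives the definitive TSD-checked pairing
    prov <- suppressWarnings(
      pair_inserts(fh, m$te_class, tsd_len = 0, max_span = cfg$max_span))
    cand_up <- character(0); cand_down <- character(0)
    pp <- prov[prov$structure %in% c("FLE", "full"), , drop = FALSE]
    if (nrow(pp) > 0L) {
      for (i in seq_len(nrow(pp))) {
        el5 <- fh[fh$start == pp$five_start[i] &
                    fh$end == pp$five_end[i], ][1, ]
        el3 <- fh[fh$start == pp$three_start[i] &
                    fh$end == pp$three_end[i], ][1, ]
        cand_up <- c(cand_up, el5$up_flank)
        cand_down <- c(cand_down, el3$down_flank)
      }
    }
    lone <- prov[prov$structure == "unpaired", , drop = FALSE]
    if (m$te_class == "LTR" && nrow(lone) > 0L) {
      for (i in seq_len(nrow(lone))) {
        h <- fh[fh$start == lone$five_start[i], ][1, ]
        cand_up <- c(cand_up, h$up_flank)
        cand_down <- c(cand_down, h$down_flank)
      }
    }
    inf <- infer_tsd_len(cand_up, cand_down, scan_range = cfg$tsd_scan)
    tsd_use <- if (!is.na(inf$inferred_len)) inf$inferred_len else m$tsd_len
    cp <- pair_inserts(fh, m$te_class, tsd_len = tsd_use,
                       max_span = cfg$max_span)
    copies_list[[m$name]] <- cp
    tsd_info[[m$name]] <- data.frame(family = m$name,
                                     inferred_tsd_len = inf$inferred_len,
                                     model_tsd_len = m$tsd_len)
    tsds <- cp$tsd_seq[!is.na(cp$tsd_seq) & nzchar(cp$tsd_seq)]
    if (length(tsds) >= 1L && length(unique(nchar(tsds))) == 1L) {
      comp <- tsd_composition(tsds)
      tsd_list[[m$name]] <- data.frame(family = m$name,
                                       position = seq_len(nrow(comp$freq)),
                                       comp$freq,
                                       GC = comp$gc_by_position,
                                       n_sites = comp$n_sites)
    }
    if (m$te_class == "LTR") {
      fle <- cp[cp$structure == "FLE", , drop = FALSE]
      if (nrow(fle) > 0L)
        ltr_ident[[m$name]] <- vapply(seq_len(nrow(fle)), function(i) {
          l5 <- slice_seq(gseq, fle$five_full_start[i], fle$five_full_end[i],
                          fle$strand[i])
          l3 <- slice_seq(gseq, fle$three_full_start[i],
                          fle$three_full_end[i], fle$strand[i])
          intra_ltr_identity(l5, l3)
        }, numeric(1))
    }

    seqs <- analysis_seqs(gseq, cp, fh, m$te_class)
    st <- if (length(seqs) >= 2L) {
      row <- tryCatch(tajimas_d(as_alignment(seqs), family = m$name),
                      te_insufficient_sites = function(e)
                        empty_popgen_row(m$name, "all", n = length(seqs)))
      row$identical_copies <- identical_copy_count(seqs)
      if (m$te_class == "LTR") {
        structs <- copies_list[[m$name]]$structure[
          copies_list[[m$name]]$structure %in% c("FLE", "soloLTR")]
        part <- partitioned_diversity(seqs, structs, family = m$name)
        part$identical_copies <- NA_integer_
        rbind(row, part[part$partition != "all", ])
      } else row
    } else empty_popgen_row(m$name, "all", n = length(seqs))
    stats_list[[m$name]] <- st

    if (length(seqs) >= 3L) {
      dm <- jc69_matrix(seqs)
      tr <- copy_tree(dm)
      trees[[m$name]] <- tr
      ap <- age_profile(tr, threshold = cfg$age_threshold)
      ages_list[[m$name]] <- cbind(family = m$name, ap$per_copy)
    }
  }
  copies <- do.call(rbind, copies_list); rownames(copies) <- NULL
  stats <- do.call(rbind, stats_list); rownames(stats) <- NULL
  ages <- if (length(ages_list)) do.call(rbind, ages_list) else NULL
  if (!is.null(ages)) rownames(ages) <- NULL

  consensi <- vapply(sims, function(f) f$consensus$full, character(1))
  counts_long <- data.frame()
  for (key in names(reads$reads)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    mr <- map_reads(reads$reads[[key]], consensi, k = cfg$map_k,
                    min_identity = cfg$map_min_identity,
                    min_cov = cfg$map_min_cov)
    counts_long <- rbind(counts_long,
                         data.frame(family = names(mr$counts),
                                    stage = parts[1],
                                    replicate = as.integer(parts[2]),
                                    count = as.integer(mr$counts)))
  }
  et <- expression_table(counts_long)
  mats <- normalize_matrix(et)
  tests <- stage_tests(et, alpha = cfg$alpha)

  fam_reads <- rowSums(mats$cell)
  ident <- stats$identical_copies[stats$partition == "all"]
  names(ident) <- stats$family[stats$partition == "all"]
  corr <- tryCatch(
    activity_correlation(fam_reads[names(ident)], as.numeric(ident)),
    error = function(e) list(r = NA_real_, n = length(ident)))

  summary <- do.call(rbind, lapply(sims, function(f) {
    m <- f$model
    cp <- copies_list[[m$name]]
    st <- stats_list[[m$name]]
    all_row <- st[st$partition == "all", ][1, ]
    li <- ltr_ident[[m$name]]
    data.frame(
      family = m$name, class = m$te_class,
      n_copies = sum(cp$structure %in% c("FLE", "soloLTR", "full")),
      n_fle = sum(cp$structure == "FLE"),
      n_solo = sum(cp$structure == "soloLTR"),
      n_unpaired = sum(cp$structure == "unpaired"),
      rnaseq_reads = unname(fam_reads[m$name]),
      identical_copies = all_row$identical_copies,
      ltr_id_min = if (length(li)) min(li) else NA_real_,
      ltr_id_max = if (length(li)) max(li) else NA_real_,
      pi_total = all_row$pi,
      pi_fle = if (m$te_class == "LTR")
        st$pi[st$partition == "FLE"][1] else NA_real_,
      pi_solo = if (m$te_class == "LTR")
        st$pi[st$partition == "solo"][1] else NA_real_,
      tajimas_d = all_row$D, sig_code = all_row$sig_code,
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  res <- list(config = cfg, sims = sims, genome = planted$genome,
              truth = planted$truth, read_truth = reads$truth_counts,
              hits = hits, copies = copies,
              tsd_inference = do.call(rbind, tsd_info),
              tsd_profile = if (length(tsd_list))
                do.call(rbind, tsd_list) else NULL,
              ltr_identity = ltr_ident, stats = stats, ages = ages,
              trees = trees, expression = et, matrices = mats,
              stage_tests = tests, correlation = corr, summary = summary)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(summary, file.path(cfg$out_dir, "summary.tsv"))
    write_tsv(copies, file.path(cfg$out_dir, "copies.tsv"))
    write_tsv(stats, file.path(cfg$out_dir, "stats.tsv"))
    if (!is.null(ages)) write_tsv(ages, file.path(cfg$out_dir, "ages.tsv"))
    if (!is.null(res$tsd_profile))
      write_tsv(res$tsd_profile, file.path(cfg$out_dir, "tsd_profile.tsv"))
    write_tsv(counts_long, file.path(cfg$out_dir, "expression.tsv"))
    write_tsv(tests, file.path(cfg$out_dir, "expression_tests.tsv"))
    write_tsv(planted$truth, file.path(cfg$out_dir, "truth_copies.tsv"))
    write_tsv(reads$truth_counts,
              file.path(cfg$out_dir, "truth_counts.tsv"))
    tdir <- file.path(cfg$out_dir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(trees))
      ape::write.tree(trees[[nm]], file.path(tdir, paste0(nm, ".nwk")))
    cfg_echo <- cfg
    cfg_echo$families <- lapply(cfg$families, unclass)
    yaml::write_yaml(cfg_echo, file.path(cfg$out_dir, "config.yaml"))
  }
  te_log("INFO", "run_all done: ", nrow(summary), " families, ",
         nrow(copies), " reconstructed copies")
  invisible(res)
}

#' Analyze pre-aligned per-family copy alignments
#'
#' Stats-only mode: runs the diversity statistics and copy-age profiling on
#' aligned FASTA files (one alignment per family), skipping simulation,
#' discovery and expression stages.
#'
#' @param paths Character vector of aligned-FASTA paths (names used as
#'   family labels; defaults to file base names).
#' @param age_threshold Old-insert threshold in substitutions/site.
#' @return List with \code{stats} (one PopGen summary row per family),
#'   \code{ages} (per-copy terminal branch table) and \code{trees}.
#' @export
analyze_alignments <- function(paths, age_threshold = 0.05) {
  fams <- names(paths)
  if (is.null(fams)) fams <- sub("\\.[^.]*$", "", basename(paths))
  stats_list <- list(); ages_list <- list(); trees <- list()
  for (i in seq_along(paths)) {
    aln <- read_alignment(paths[i])
    seqs <- apply(unclass(aln), 1L, paste, collapse = "")
    row <- tryCatch(tajimas_d(aln, family = fams[i]),
                    te_insufficient_sites = function(e)
                      empty_popgen_row(fams[i], "all", n = nrow(aln)))
    row$identical_copies <- identical_copy_count(seqs)
    stats_list[[fams[i]]] <- row
    if (nrow(aln) >= 3L) {
      tr <- copy_tree(jc69_matrix(seqs, ids = rownames(aln)))
      trees[[fams[i]]] <- tr
      ap <- age_profile(tr, threshold = age_threshold)
      ages_list[[fams[i]]] <- cbind(family = fams[i], ap$per_copy)
    }
  }
  list(stats = do.call(rbind, stats_list),
       ages = if (length(ages_list)) do.call(rbind, ages_list) else NULL,
       trees = trees)
}
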