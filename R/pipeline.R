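# End-to-end synthetic demonstration: simulate -> sites -> enrichment ->
# motif -> model -> methylation -> correction, with deterministic seeded
# outputs and a provenance record.

#' Pipeline run configuration
#'
#' Defaults are the protocol constants of the analysis: 51-bp model window,
#' 19-bp motif window, 500 000-site subsample, 20 000 sites + 20 000 controls,
#' 10-fold CV, FDR < 0.001, scan q < 0.001, k = 19, 70/30 split.
#'
#' @param window model window (bp).
#' @param motif_window PWM window (bp).
#' @param subsample_n paired-fragment subsample size.
#' @param n_train sites (and controls) for the classifier.
#' @param folds CV folds (>= 2).
#' @param fdr enrichment FDR threshold.
#' @param q_threshold motif-scan q threshold.
#' @param k bias-model context width.
#' @param split cross-sample training fraction.
#' @param seed master seed.
#' @param sim a `tn5_sim_config` describing the synthetic input.
#' @param model_blocks feature blocks for the demo model stage.
#' @return a `tn5_run_config` list.
#' @export
run_config <- function(window = 51L, motif_window = 19L,
                       subsample_n = 500000L, n_train = 20000L,
                       folds = 10L, fdr = 0.001, q_threshold = 0.001,
                       k = 19L, split = 0.7, seed = 1L,
                       sim = NULL, model_blocks = c("motif")) {
  if (folds < 2) stop("folds must be >= 2")
  stopifnot(window %% 2 == 1, motif_window %% 2 == 1, k %% 2 == 1,
            split > 0, split < 1)
  structure(list(window = as.integer(window),
                 motif_window = as.integer(motif_window),
                 subsample_n = as.integer(subsample_n),
                 n_train = as.integer(n_train), folds = as.integer(folds),
                 fdr = fdr, q_threshold = q_threshold, k = as.integer(k),
                 split = split, seed = as.integer(seed), sim = sim,
                 model_blocks = model_blocks),
            class = "tn5_run_config")
}

#' Demo configuration: 2-Mb genome, 100 000 insertions
#'
#' The desk-scale demonstration: a planted Tn5-like PWM plus a mild
#' dinucleotide term and a positive methylation effect on a 2-Mb AT-rich
#' genome (80% AT, the low-complexity regime in which 9-bp sequence contexts
#' recur often enough for the context-dependent methylation procedure, as in
#' the most AT-rich genomes Tn5 has been profiled on). Embedded consensus
#' motif instances give the genome scan a realistic motif density. The bias
#' model uses k = 7 (a full 19-bp context on a 2-Mb genome makes nearly every
#' context unique).
#'
#' @param seed master seed.
#' @return a `tn5_run_config`.
#' @export
run_demo_config <- function(seed = 1L) {
  dinuc <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  dinuc["C", "G"] <- 0.4
  dinuc["T", "A"] <- 0.3
  dinuc <- dinuc - mean(dinuc)
  sim <- sim_config(genome_length = 2000000L,
                    base_composition = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4),
                    planted_pwm = default_planted_pwm(),
                    motif_weight = 0.6, dinuc_weights = dinuc,
                    methylation_effect = 1.0, n_insertions = 100000L,
                    n_planted_motifs = 25000L, seed = seed)
  run_config(seed = seed, sim = sim, k = 7L, n_train = 10000L,
             model_blocks = c("motif"))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes all stages in dependency order on a simulated dataset and writes
#' deterministic text artifacts (FASTA, BED, bedGraph, TSV) plus a provenance
#' record to `outdir`. Reruns with the same config are byte-identical.
#'
#' @param config a `tn5_run_config` with a non-NULL `sim`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "tn5_run_config"))
  if (is.null(config$sim)) stop("config$sim is required: run the 'simulate' stage config first (see run_demo_config())")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  ## stage: simulate
  genome <- simulate_genome(config$sim)
  meth <- simulate_methylation(genome, config$sim)
  ins <- simulate_insertions(genome, config$sim, methylation = meth$condA)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$seq),
    file.path(outdir, "genome.fa"))
  write_insertion_track(ins$sites, file.path(outdir, "sites.bed"), "bed")
  write_truth(ins$truth, file.path(outdir, "truth.tsv"))
  fragments <- sites_to_fragments(ins$sites, genome, seed = config$seed)
  write_fragments_bed(fragments, file.path(outdir, "fragments.bed"))
  for (cond in names(meth))
    write_bedgraph(meth[[cond]],
                   file.path(outdir, paste0("meth_", cond, ".bedGraph")))
  res$genome <- genome
  res$sites <- ins$sites
  res$truth <- ins$truth

  ## stage: sites (fragments -> shifted sites; QC)
  shifted <- shift_fragments(fragments)
  res$fragment_sizes <- fragment_size_distribution(fragments)
  write.table(res$fragment_sizes, file.path(outdir, "fragment_sizes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: enrichment (features = GC-content quartiles of 1-kb tiles; the
  ## planted CG/motif preference enriches GC-rich tiles)
  L <- genome$contig_lengths[[1]]
  ctg <- names(genome$seq)[1]
  tile <- 1000L
  starts <- seq(0L, L - tile, by = tile)
  gc <- vapply(starts, function(s) {
    w <- substr(genome$seq[[ctg]], s + 1L, s + tile)
    lengths(regmatches(w, gregexpr("[GC]", w))) / tile
  }, numeric(1))
  classes <- paste0("GC_q", cut(gc, quantile(gc, 0:4 / 4),
                                include.lowest = TRUE, labels = FALSE))
  features <- lapply(split(starts, classes), function(st) {
    data.frame(contig = ctg, start = st, end = st + tile)
  })
  res$enrichment <- feature_enrichment(features, merge_site_strands(res$sites),
                                       genome, fdr = config$fdr)
  write_enrichment_tsv(res$enrichment, file.path(outdir, "enrichment.tsv"))

  ## stage: motif
  paired <- paired_fragment_sites(fragments)
  paired_sub <- subsample_sites(paired, min(config$subsample_n, nrow(paired)),
                                seed = config$seed)
  pwm <- build_pwm(paired_sub, genome, window = config$motif_window)
  write_pwm_meme(pwm, file.path(outdir, "tn5_motif.meme"))
  core <- build_pwm(paired_sub, genome,
                    window = config$sim$planted_pwm$width %||% 9L)
  hits <- scan_pwm(core, genome, q_threshold = config$q_threshold)
  usage <- usage_summary(merge_site_strands(res$sites), hits)
  res$pwm <- pwm
  res$hits <- hits
  res$usage <- usage
  write.table(data.frame(metric = names(usage),
                         value = as.numeric(usage)),
              file.path(outdir, "motif_usage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## stage: model
  n_tr <- min(config$n_train, nrow(res$sites))
  tr_sites <- subsample_sites(res$sites, n_tr, seed = config$seed + 1L)
  tr_sites$count <- 1L
  controls <- sample_control_sites(genome, n_tr, width = config$window,
                                   seed = config$seed, exclude = res$sites)
  pwm51 <- build_pwm(tr_sites, genome, window = config$window)
  table51 <- synthetic_shape_table()
  sets <- list()
  for (b in config$model_blocks) {
    sets[[b]] <- list(blocks = b, pwm = pwm51, table = table51)
  }
  sets[["shuffled_seqs"]] <- list(blocks = config$model_blocks[1],
                                  pwm = pwm51, table = table51,
                                  shuffle_sequences = TRUE)
  res$model <- compare_vector_sets(tr_sites, controls, genome, sets,
                                   window = config$window,
                                   folds = config$folds, seed = config$seed)
  write.table(res$model, file.path(outdir, "model_accuracy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: methylation (two conditions share the same insertion process here)
  bins <- tile_and_annotate(genome, meth,
                            list(condA = res$sites, condB = res$sites))
  bins <- classify_groups(bins)
  prof <- ninemer_profile(bins)
  res$ninemer <- prof
  write.table(head(prof[order(prof$ninemer, prof$group), ], 20000),
              file.path(outdir, "ninemer_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res$levels <- stratify_levels(bins, "condA")
  write.table(res$levels, file.path(outdir, "methylation_levels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: correction
  model <- build_bias_model(res$sites, genome, k = config$k)
  corrected <- correct_signal(res$sites, model, genome)
  write_bias_model(model, file.path(outdir, "bias_scales.tsv"))
  write_bedgraph(corrected, file.path(outdir, "corrected.bedGraph"))
  res$bias_model <- model
  res$corrected <- corrected

  ## provenance
  prov <- c(
    sprintf("tn5prefer_version\t%s", as.character(packageVersion("tn5prefer"))),
    sprintf("seed\t%d", config$seed),
    sprintf("window\t%d", config$window),
    sprintf("motif_window\t%d", config$motif_window),
    sprintf("subsample_n\t%d", config$subsample_n),
    sprintf("n_train\t%d", config$n_train),
    sprintf("folds\t%d", config$folds),
    sprintf("fdr\t%g", config$fdr),
    sprintf("q_threshold\t%g", config$q_threshold),
    sprintf("k\t%d", config$k),
    sprintf("split\t%g", config$split),
    sprintf("genome_length\t%d", config$sim$genome_length),
    sprintf("n_insertions\t%d", config$sim$n_insertions)
  )
  writeLines(prov, file.path(outdir, "provenance.tsv"))
  invisible(res)
}
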