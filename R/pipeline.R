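#' Run the full downstream pipeline on a synthetic bundle
#'
#' Executes the stages in dependency order -- simulate, signal processing,
#' consensus peaks, overlap enrichment, profiles/GC, expression
#' integration, motif statistics, chromatin features -- writing each
#' stage's tables under `out_dir` and returning (and writing) a run
#' manifest with the config snapshot, seeds, per-stage timings and output
#' file digests. Reruns with the same seed produce byte-identical outputs.
#'
#' @param config `NULL`, a JSON file path, or a list with optional
#'   `simulation` and `analysis` elements overriding
#'   [simulation_config()] / [analysis_config()] fields.
#' @param out_dir Output directory.
#' @param seed Master seed; overrides any seed in `config`.
#' @param stages Character vector of stages to run (dependencies must have
#'   run into the same `out_dir` before, or be listed).
#' @return The manifest, invisibly; also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         stages = c("simulate", "signal", "peaks", "enrich",
                                    "profiles", "expression", "motifs",
                                    "features")) {
  all_stages <- c("simulate", "signal", "peaks", "enrich", "profiles",
                  "expression", "motifs", "features")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.character(config)) config <- jsonlite::read_json(config)
  sim_cfg <- do.call(simulation_config,
                     c(config$simulation %||% list()))
  ana_cfg <- do.call(analysis_config, c(config$analysis %||% list()))
  if (!is.null(seed)) {
    sim_cfg$rng_seed <- as.integer(seed)
    ana_cfg$rng_seed <- as.integer(seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(tool = "peakscape",
                   version = as.character(utils::packageVersion("peakscape")),
                   seed = sim_cfg$rng_seed,
                   simulation_config = unclass(sim_cfg),
                   analysis_config = unclass(ana_cfg),
                   stages = list())
  for (st in all_stages[all_stages %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    outs <- switch(st,
      simulate = stage_simulate(state, sim_cfg, out_dir),
      signal = stage_signal(state, out_dir),
      peaks = stage_peaks(state, ana_cfg, out_dir),
      enrich = stage_enrich(state, ana_cfg, out_dir),
      profiles = stage_profiles(state, ana_cfg, out_dir),
      expression = stage_expression(state, ana_cfg, out_dir),
      motifs = stage_motifs(state, ana_cfg, out_dir),
      features = stage_features(state, ana_cfg, out_dir))
    manifest$stages[[st]] <- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = as.list(tools::md5sum(unlist(outs))))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- stage implementations -------------------------------------------------

provider <- c(bundle = "simulate", signal = "signal", peaks = "peaks",
              enrichment = "enrich", gc = "profiles",
              expression_results = "expression", motifs = "motifs",
              features = "features")

need <- function(state, what, stage) {
  if (!exists(what, state))
    stop("stage '", stage, "' requires outputs of stage '",
         provider[[what]], "'; run or include it first")
  get(what, state)
}

stage_simulate <- function(state, sim_cfg, out_dir) {
  b <- simulate_bundle(sim_cfg, out_dir = file.path(out_dir, "sim"))
  # an "active histone mark" track: enrichment at all active promoters,
  # independent of which of them condensin actually binds
  genes <- b$annotations$genes[b$annotations$active[b$annotations$genes$name]]
  tssp <- tss_positions(genes)
  mark_truth <- peak_set(
    clamp_to_genome(GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(genes),
      IRanges::IRanges(tssp - 400L, tssp + 400L)), b$genome),
    summit_score = rep(4, sum(b$annotations$active)))
  mark_truth$height <- mark_truth$summit_score
  mcfg <- b$config; mcfg$n_subunits <- 1L; mcfg$n_replicates <- 2L
  b$mark <- generate_binding_tracks(mcfg, b$genome, mark_truth,
                                    seed = sim_cfg$rng_seed + 101L)
  assign("bundle", b, state)
  unlist(b$paths[names(b$paths) != "dir"], use.names = FALSE)
}

# per replicate: median-normalize chip and input, subtract; then average
# replicates per subunit; the complex-level track is the subunit mean
process_complex_tracks <- function(tr) {
  input_norm <- lapply(tr$input, median_normalize)
  input_mean <- merge_replicates(input_norm)
  sub_tracks <- lapply(tr$chip, function(reps)
    merge_replicates(lapply(reps, function(t)
      subtract_input(median_normalize(t), input_mean))))
  list(subunits = sub_tracks,
       complex = merge_replicates(unname(sub_tracks)),
       input = input_mean)
}

stage_signal <- function(state, out_dir) {
  b <- need(state, "bundle", "signal")
  sig <- lapply(b$tracks, process_complex_tracks)
  sig$mark <- process_complex_tracks(b$mark)
  assign("signal", sig, state)
  d <- file.path(out_dir, "signal")
  dir.create(d, showWarnings = FALSE)
  paths <- character()
  for (cx in names(sig))
    paths <- c(paths, write_track(sig[[cx]]$complex,
                                  file.path(d, paste0(cx, ".bedGraph"))))
  paths
}

stage_peaks <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "peaks")
  sig <- need(state, "signal", "peaks")
  d <- file.path(out_dir, "peaks")
  dir.create(d, showWarnings = FALSE)
  peaks <- list()
  for (cx in names(b$tracks)) {
    sp <- if (cx == "condensin_II") b$subunit_peaks
          else generate_subunit_peaks(b$config, b$genome, b$truth[[cx]],
                                      seed = b$config$rng_seed + 17L)
    filtered <- lapply(sp, function(s)
      majority_replicate_filter(s$combined, s$replicates))
    cons <- consensus_k_of_n(filtered, k = ana_cfg$consensus_k,
                             genome = b$genome)
    # fragment-scale smoothing: per-base count noise otherwise seeds
    # spurious sub-peaks in the valley scan
    smoothed <- smooth_track(sig[[cx]]$complex)
    summ <- call_summits(cons, smoothed)
    final <- split_peaks(summ, smoothed,
                         min_height = summit_median_height(summ),
                         separation_float = ana_cfg$separation_float)
    peaks[[cx]] <- final
  }
  assign("peaks", peaks, state)
  vapply(names(peaks), function(cx)
    write_intervals(peaks[[cx]], file.path(d, paste0(cx, ".bed"))), "")
}

annotation_regions <- function(b, ana_cfg) {
  ann <- b$annotations$annotations
  genes <- ann[ann$class == "gene"]
  list(promoters = derive_promoters(genes, b$genome, ana_cfg$promoter_len),
       gene_bodies = GenomicRanges::granges(genes),
       three_prime = derive_3prime(genes, b$genome, ana_cfg$promoter_len),
       tRNA = GenomicRanges::granges(ann[ann$class == "tRNA"]),
       ncRNA_short = derive_promoters(ann[ann$class == "ncRNA_short"],
                                      b$genome, ana_cfg$promoter_len),
       ncRNA_long = derive_promoters(ann[ann$class == "ncRNA_long"],
                                     b$genome, ana_cfg$promoter_len))
}

stage_enrich <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "enrich")
  peaks <- need(state, "peaks", "enrich")
  d <- file.path(out_dir, "enrich")
  dir.create(d, showWarnings = FALSE)
  regions <- annotation_regions(b, ana_cfg)
  rows <- list()
  for (cx in names(peaks))
    for (rg in names(regions)) {
      res <- permutation_test(peaks[[cx]], regions[[rg]], b$genome, ana_cfg,
                              keep_null = FALSE)
      rows[[paste(cx, rg)]] <- data.frame(
        complex = cx, annotation = rg, observed_pct = 100 *
          res$observed_fraction, null_pct = 100 * res$null_mean,
        fold = res$fold_enrichment, p_value = res$p_value,
        direction = res$direction)
    }
  enr <- do.call(rbind, rows)
  rownames(enr) <- NULL
  f1 <- file.path(d, "annotation_enrichment.tsv")
  utils::write.table(enr, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  tft <- tf_overlap_table(peaks$condensin_II, b$tf$tf_sets, b$genome,
                          ana_cfg, hot_regions = b$tf$hot_regions)
  f2 <- file.path(d, "tf_overlap.tsv")
  utils::write.table(tft, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  assign("enrichment", list(annotations = enr, tf = tft), state)
  c(f1, f2)
}

stage_profiles <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "profiles")
  sig <- need(state, "signal", "profiles")
  peaks <- need(state, "peaks", "profiles")
  d <- file.path(out_dir, "profiles")
  dir.create(d, showWarnings = FALSE)
  paths <- character()
  for (cx in names(peaks)) {
    pm <- anchored_matrix(sig[[cx]]$complex, peaks[[cx]],
                          ana_cfg$heatmap_flank, ana_cfg$heatmap_bin)
    pm <- order_by_summit_score(pm, peaks[[cx]])
    paths <- c(paths, write_profile_matrix(
      pm, file.path(d, paste0("summit_matrix_", cx, ".tsv"))))
  }
  tssp <- tss_profile(sig$condensin_II$complex, b$annotations$genes,
                      expression_medians(b$expression),
                      flank = ana_cfg$heatmap_flank,
                      bin = ana_cfg$heatmap_bin)
  f <- file.path(d, "tss_profile.tsv")
  utils::write.table(tssp, f, sep = "\t", quote = FALSE, row.names = FALSE)
  gcp <- gc_summit_profile(b$sequences, b$genome, peaks$condensin_II,
                           flank = ana_cfg$heatmap_flank,
                           bin = ana_cfg$heatmap_bin,
                           gc_window = ana_cfg$gc_window,
                           seed = ana_cfg$rng_seed)
  f2 <- file.path(d, "gc_summit_profile.tsv")
  utils::write.table(
    rbind(cbind(set = "summit", gcp$summit),
          cbind(set = "control", gcp$control)),
    f2, sep = "\t", quote = FALSE, row.names = FALSE)
  assign("gc", gcp$gc, state)
  c(paths, f, f2)
}

stage_expression <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "expression")
  sig <- need(state, "signal", "expression")
  peaks <- need(state, "peaks", "expression")
  d <- file.path(out_dir, "expression")
  dir.create(d, showWarnings = FALSE)
  ps <- promoter_signal(sig$condensin_II$complex, b$annotations$genes,
                        b$genome, upstream = ana_cfg$promoter_signal_len)
  med <- expression_medians(b$expression)
  rho <- binding_expression_correlation(ps, med)
  rho_x <- tryCatch(
    binding_expression_correlation(ps, med, b$annotations$genes,
                                   b$genome, scope = "X"),
    error = function(e) NA_real_)   # tiny simulations: too few X genes
  bound <- classify_bound_genes(b$annotations$genes, peaks$condensin_II,
                                b$genome, window = ana_cfg$promoter_len)
  tab <- de_binding_table(b$de_table, bound)
  f1 <- file.path(d, "promoter_signal.tsv")
  utils::write.table(
    data.frame(gene = names(ps), promoter_signal = ps,
               expression = med[names(ps)],
               bound = bound[names(ps)]),
    f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(d, "summary.json")
  jsonlite::write_json(list(
    spearman_rho_genome = rho, spearman_rho_X = rho_x,
    n_bound_genes = sum(bound),
    de_counts = as.data.frame.matrix(tab$counts),
    de_row_percent = as.data.frame.matrix(tab$row_percent)),
    f2, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  assign("expression_results",
         list(rho = rho, rho_x = rho_x, bound = bound, de = tab), state)
  c(f1, f2)
}

stage_motifs <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "motifs")
  peaks <- need(state, "peaks", "motifs")
  sig <- need(state, "signal", "motifs")
  d <- file.path(out_dir, "motifs")
  dir.create(d, showWarnings = FALSE)
  pwm <- pwm_from_consensus(b$config$motif_ii)
  hits <- scan_pwm(pwm, b$sequences, b$genome)
  win <- summit_windows(peaks$condensin_II, b$genome,
                        ana_cfg$summit_window)
  frac <- motif_bound_fraction(hits, win)
  # 2 kb windows enriched for the active mark: top decile by median signal
  fm <- window_feature_matrix(list(mark = sig$mark$complex), b$genome,
                              window = 2000L)
  thr <- stats::quantile(fm$features[, "mark"], 0.9)
  mark_windows <- fm$windows[fm$features[, "mark"] >= thr]
  ctx <- context_conditioned_fraction(hits, win, mark_windows)
  clus <- clustering_effect(hits, win, b$genome, window = 1000L)
  f1 <- file.path(d, "motif_hits.bed")
  write_intervals(hits, f1)
  f2 <- file.path(d, "motif_stats.json")
  jsonlite::write_json(list(
    n_hits = length(hits), bound_fraction = frac,
    bound_fraction_in_marked = ctx$fraction_in_marked,
    clustering_fold = clus$fold), f2, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  assign("motifs", list(hits = hits, bound_fraction = frac, context = ctx,
                        clustering = clus), state)
  c(f1, f2)
}

stage_features <- function(state, ana_cfg, out_dir) {
  b <- need(state, "bundle", "features")
  sig <- need(state, "signal", "features")
  peaks <- need(state, "peaks", "features")
  motifs <- need(state, "motifs", "features")
  d <- file.path(out_dir, "features")
  dir.create(d, showWarnings = FALSE)
  # correlation/clustering of all subunit-level tracks (1 kb windows)
  tracks <- list()
  for (cx in names(b$tracks))
    for (su in names(sig[[cx]]$subunits))
      tracks[[paste(cx, su, sep = ".")]] <- sig[[cx]]$subunits[[su]]
  tracks$mark <- sig$mark$complex
  fm <- window_feature_matrix(tracks, b$genome,
                              window = ana_cfg$corr_window)
  co <- correlation_heatmap_order(fm)
  f1 <- file.path(d, "correlation_matrix.tsv")
  utils::write.table(round(co$cor[co$order, co$order], 6), f1, sep = "\t",
                     quote = FALSE)
  # bound/unbound classification in 250 bp windows
  lw <- label_windows(b$genome, peaks$condensin_II,
                      window = ana_cfg$ml_window)
  gc <- if (exists("gc", state)) get("gc", state)
        else gc_track(b$sequences, b$genome, ana_cfg$gc_window)
  fml <- window_feature_matrix(
    list(mark = sig$mark$complex, idc = sig$condensin_I_IDC$complex,
         input = sig$condensin_II$input, gc = gc),
    b$genome, window = ana_cfg$ml_window)
  feat <- cbind(fml$features,
                motif = GenomicRanges::countOverlaps(fml$windows,
                                                     motifs$hits))
  imp <- permutation_importance(feat, lw$bound, seed = ana_cfg$rng_seed)
  f2 <- file.path(d, "feature_importance.tsv")
  utils::write.table(imp, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  assign("features", list(cor = co, importance = imp), state)
  c(f1, f2)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--seed N] [--config FILE]`,
#' `run --out DIR [--seed N] [--config FILE] [--stages a,b,...]`,
#' `enrich --peaks BED --annotation BED --sizes FILE [--n N] [--seed N]`,
#' `validate --sizes FILE [files...]`,
#' `signal <normalize|subtract|merge|zscore> --sizes FILE --out TRACK
#' [--peaks BED] [tracks...]` (provenance written as a JSON sidecar), and
#' `peaks <consensus|summits|split> --sizes FILE --out BED [--k K]
#' [--track TRACK] [--separation F] [beds...]`. Intended to be called from
#' an `Rscript -e 'peakscape::peakscape_cli()'` wrapper.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status (0 on success), invisibly.
#' @export
peakscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: peakscape <simulate|run|enrich|validate> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- parse_cli_opts(args[-1L])
  seed <- as.integer(opt$seed %||% 1L)
  switch(cmd,
    simulate = {
      cfg <- if (!is.null(opt$config))
        do.call(simulation_config,
                jsonlite::read_json(opt$config)$simulation %||% list())
      else simulation_config()
      cfg$rng_seed <- seed
      simulate_bundle(cfg, out_dir = opt$out %||% "peakscape_sim")
      message("bundle written to ", opt$out %||% "peakscape_sim")
    },
    run = {
      stages <- if (!is.null(opt$stages))
        strsplit(opt$stages, ",")[[1L]]
      else c("simulate", "signal", "peaks", "enrich", "profiles",
             "expression", "motifs", "features")
      run_pipeline(opt$config, out_dir = opt$out %||% "peakscape_run",
                   seed = seed, stages = stages)
      message("pipeline complete; manifest in ",
              file.path(opt$out %||% "peakscape_run", "manifest.json"))
    },
    enrich = {
      genome <- read_chrom_sizes(opt$sizes)
      peaks <- read_intervals(opt$peaks, genome, "BED")
      ann <- read_intervals(opt$annotation, genome, "BED")
      cfg <- analysis_config(n_permutations = as.integer(opt$n %||% 10000L),
                             rng_seed = seed)
      print(permutation_test(peaks, ann, genome, cfg))
    },
    validate = {
      genome <- read_chrom_sizes(opt$sizes)
      for (f in opt$positional) {
        read_intervals(f, genome)
        message(f, ": OK")
      }
    },
    signal = {
      # signal <normalize|subtract|merge|zscore> --sizes F --out F [inputs]
      genome <- read_chrom_sizes(opt$sizes)
      sub <- opt$positional[1L]
      ins <- opt$positional[-1L]
      out <- switch(sub,
        normalize = median_normalize(read_track(ins[1L], genome)),
        subtract = subtract_input(
          median_normalize(read_track(ins[1L], genome)),
          median_normalize(read_track(ins[2L], genome))),
        merge = merge_replicates(lapply(ins, function(f) {
          t <- read_track(f, genome); t$state <- "input_subtracted"; t
        })),
        zscore = {
          t <- read_track(ins[1L], genome)
          t$state <- "input_subtracted"
          pk <- if (!is.null(opt$peaks))
            read_intervals(opt$peaks, genome, "BED")
          zscore_standardize(t, pk)
        },
        stop("unknown signal subcommand: ", sub))
      write_track(out, opt$out)
      jsonlite::write_json(out$provenance, paste0(opt$out, ".prov.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      message("written ", opt$out)
    },
    peaks = {
      # peaks <consensus|summits|split> --sizes F --out F [options] [beds]
      genome <- read_chrom_sizes(opt$sizes)
      sub <- opt$positional[1L]
      ins <- opt$positional[-1L]
      out <- switch(sub,
        consensus = consensus_k_of_n(
          lapply(ins, read_intervals, genome = genome, format = "BED"),
          k = as.integer(opt$k %||% 2L), genome = genome),
        summits = call_summits(
          read_intervals(ins[1L], genome, "BED"),
          read_track(opt$track, genome)),
        split = {
          trk <- read_track(opt$track, genome)
          trk$state <- "input_subtracted"
          pk <- call_summits(read_intervals(ins[1L], genome, "BED"), trk)
          split_peaks(pk, trk,
                      min_height = summit_median_height(pk),
                      separation_float =
                        as.numeric(opt$separation %||% 0.85))
        },
        stop("unknown peaks subcommand: ", sub))
      write_intervals(out, opt$out)
      message("written ", opt$out)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opt[[substring(a, 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opt$positional <- c(opt$positional, a)
      i <- i + 1L
    }
  }
  opt
}
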