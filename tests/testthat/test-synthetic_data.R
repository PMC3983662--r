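small_cfg <- function(seed = 1, ...) {
  simulation_config(n_chroms = 3, chrom_length = 50000, n_genes = 18,
                    n_trnas = 4, n_ncrnas = 6, rng_seed = seed, ...)
}

test_that("config invariants are enforced", {
  expect_error(simulation_config(chrom_length = 1000,
                                 peak_width_mean = 400), "10x")
  expect_s3_class(simulation_config(), "SimulationConfig")
  gm <- sim_genome_model(simulation_config())
  expect_identical(gm$x_chrom, "chrX")
  expect_identical(gm$excluded_chroms, "chrM")
  expect_equal(length(chrom_names(gm)), 7)  # 5 autosomes + X + chrM
})

test_that("the generator is deterministic under a fixed seed", {
  b1 <- simulate_bundle(small_cfg(5))
  b2 <- simulate_bundle(small_cfg(5))
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(as.data.frame(b1$truth$condensin_II),
                   as.data.frame(b2$truth$condensin_II))
  expect_identical(b1$tracks$condensin_II$chip$subunit1$rep1$values,
                   b2$tracks$condensin_II$chip$subunit1$rep1$values)
  expect_identical(b1$expression$median, b2$expression$median)
  b3 <- simulate_bundle(small_cfg(6))
  expect_false(identical(b1$sequences, b3$sequences))
})

test_that("genome sequence has the configured GC, elevated at summits", {
  cfg <- small_cfg(7, gc_background = 0.5, gc_at_peaks = 0.7)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 7)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 8)
  seqs <- generate_genome(cfg, gm, list(condensin_II = tp), seed = 9)
  b <- strsplit(seqs[["chrI"]], "")[[1]]
  n <- length(b)
  gc <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n) + 0.02)  # summits shift it up
  # recompute GC in +/-7 bp windows at summits vs far flanks
  gt <- gc_track(seqs, gm, 15)
  on_I <- tp[as.character(seqnames(tp)) == "chrI"]
  at_summit <- mean(gt$values$chrI[on_I$summit])
  expect_gt(at_summit, 0.6)
  far <- setdiff(seq_len(n), unlist(lapply(on_I$summit, function(s)
    max(1, s - 300):min(n, s + 300))))
  expect_lt(abs(mean(gt$values$chrI[far]) - 0.5), 0.02)
})

test_that("x_bias concentrates the X-specific complex on the X", {
  cfg <- small_cfg(10)   # default x_bias = 160
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 10)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_I_IDC", seed = 11)
  expect_gt(mean(as.character(seqnames(tp)) == "chrX"), 0.9)
  # and the non-biased complex is spread across chromosomes
  tp2 <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 11)
  expect_lt(mean(as.character(seqnames(tp2)) == "chrX"), 0.7)
})

test_that("zero enrichment makes ChIP statistically indistinguishable from input", {
  cfg <- small_cfg(12, enrichment_height = 0)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 12)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 13)
  tr <- generate_binding_tracks(cfg, gm, tp, seed = 14)
  chip <- tr$chip$subunit1$rep1$values$chrI
  inp <- tr$input$rep1$values$chrI
  expect_gt(suppressWarnings(ks.test(chip, inp))$p.value, 0.01)
  expect_equal(mean(chip), mean(inp), tolerance = 0.02)
})

test_that("planted peaks are recoverable from the tracks", {
  cfg <- small_cfg(15, enrichment_height = 8)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 15)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 16)
  tr <- generate_binding_tracks(cfg, gm, tp, seed = 17)
  enr <- subtract_input(median_normalize(tr$chip$subunit1$rep1),
                        merge_replicates(lapply(tr$input,
                                                median_normalize)))
  at_summits <- vapply(seq_along(tp), function(i)
    enr$values[[as.character(seqnames(tp))[i]]][tp$summit[i]], 0)
  bg <- median(unlist(enr$values))
  expect_gt(min(at_summits), 1)     # every summit well above background
  expect_lt(abs(bg), 0.2)
})

test_that("bound fraction of active genes matches the configured rate", {
  hits <- vapply(1:6, function(s) {
    cfg <- simulation_config(n_chroms = 4, chrom_length = 120000,
                             n_genes = 60, frac_active_promoters_bound = 0.2,
                             rng_seed = s)
    gm <- sim_genome_model(cfg)
    ann <- generate_annotations(cfg, gm, seed = s)
    tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = s + 50)
    active_genes <- names(ann$active)[ann$active]
    mean(active_genes %in% tp$gene)
  }, 0)
  expect_equal(mean(hits), 0.2, tolerance = 0.05)
})

test_that("expression coupling: null, shift, and copula rho recovery", {
  cfg <- simulation_config(n_chroms = 4, chrom_length = 150000,
                           n_genes = 80, expr_active_shift = 0,
                           expr_bound_shift = 0, rng_seed = 20)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 20)
  genes <- ann$genes$name
  covar <- setNames(runif(length(genes)), genes)
  # no coupling -> |rho| small
  et0 <- generate_expression(cfg, ann, seed = 21)
  rho0 <- cor(covar, expression_medians(et0)[genes], method = "spearman")
  expect_lt(abs(rho0), 0.15)
  # positive shift -> bound genes higher
  cfg2 <- cfg; cfg2$expr_bound_shift <- 2
  bound <- setNames(runif(length(genes)) < 0.3, genes)
  et1 <- generate_expression(cfg2, ann, bound_genes = bound, seed = 22)
  med1 <- expression_medians(et1)
  expect_gt(median(med1[names(bound)[bound]]),
            median(med1[names(bound)[!bound]]))
  # copula mode: planted rho 0.3 recovered within +/-0.05 over 10 seeds
  rhos <- vapply(1:10, function(s) {
    et <- generate_expression(cfg, ann, rho_target = 0.3,
                              covariate = covar, seed = 30 + s)
    cor(covar, expression_medians(et)[genes], method = "spearman")
  }, 0)
  expect_lt(abs(mean(rhos) - 0.3), 0.05)
})

test_that("TF sets overlap the truth at the configured rates", {
  cfg <- small_cfg(25)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 25)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 26)
  tf <- generate_tf_sets(cfg, gm, tp, tf_rates = c(hi = 0.6, none = 0),
                         n_sites = 100, seed = 27)
  ov_hi <- overlap_fraction(tf$tf_sets$hi, tp)$fraction
  expect_lt(abs(ov_hi - 0.6), 3 * sqrt(0.6 * 0.4 / 100) + 0.05)
  ov_none <- overlap_fraction(tf$tf_sets$none, tp)$fraction
  expect_lt(ov_none, 0.2)    # random placement: near-chance overlap
  # identical seed -> identical sets
  tf2 <- generate_tf_sets(cfg, gm, tp, tf_rates = c(hi = 0.6, none = 0),
                          n_sites = 100, seed = 27)
  expect_identical(as.data.frame(tf$tf_sets$hi),
                   as.data.frame(tf2$tf_sets$hi))
})

test_that("every emitted file re-parses through the package readers", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(small_cfg(30), out_dir = dir)
  gm <- read_chrom_sizes(file.path(dir, "chrom.sizes"), x_chrom = "chrX",
                         excluded_chroms = "chrM")
  expect_identical(gm$chrom_lengths, b$genome$chrom_lengths)
  ann <- read_intervals(file.path(dir, "annotations.gff3"), gm, "GFF")
  expect_equal(length(ann), length(b$annotations$annotations))
  tp <- read_intervals(file.path(dir, "truth_condensin_II.bed"), gm, "BED")
  expect_equal(start(tp), start(b$truth$condensin_II))
  expect_equal(tp$summit, b$truth$condensin_II$summit)
  wig <- file.path(dir, "chip_condensin_I_IDC_subunit1_rep1.wig")
  tr <- read_track(wig, gm)
  expect_equal(tr$values$chrI,
               b$tracks$condensin_I_IDC$chip$subunit1$rep1$values$chrI)
  et <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(expression_medians(et), expression_medians(b$expression))
  tfbed <- read_intervals(file.path(dir, "tf_TF_A.bed"), gm, "BED")
  expect_equal(length(tfbed), length(b$tf$tf_sets$TF_A))
})
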