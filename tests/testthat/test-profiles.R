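test_that("anchored_matrix bins per-anchor signal, strand-aware", {
  gm <- genome_model(c(chrI = 5000))
  # constant track -> all cells equal the constant
  ct <- constant_track(gm, 3.5, state = "input_subtracted")
  anchors <- GRanges("chrI", IRanges(c(1000, 2500), width = 1),
                     strand = c("+", "-"), seqinfo = as_seqinfo(gm))
  pm <- anchored_matrix(ct, anchors, flank = 500, bin = 50)
  expect_equal(dim(pm$matrix), c(2, 20))
  expect_true(all(pm$matrix == 3.5))
  expect_equal(pm$offsets[1], -500)
  # delta spike lands in the center bin only (and is mirrored on -)
  v <- rep(0, 5000); v[1010] <- 100   # offset +10 from the + anchor
  tr <- coverage_track(list(chrI = v), gm, state = "input_subtracted")
  pm2 <- anchored_matrix(tr, anchors[1], flank = 500, bin = 50,
                         stat = "mean")
  hitcol <- which(pm2$matrix[1, ] > 0)
  expect_equal(pm2$offsets[hitcol], 0)  # bin [0, 50)
  v2 <- rep(0, 5000); v2[2490] <- 100  # 10 bp 5-prime of the - anchor
  tr2 <- coverage_track(list(chrI = v2), gm, state = "input_subtracted")
  pm3 <- anchored_matrix(tr2, anchors[2], flank = 500, bin = 50,
                         stat = "mean")
  expect_equal(pm3$offsets[which(pm3$matrix[1, ] > 0)], 0)
  # per-bin median oracle on a random track
  set.seed(31)
  v3 <- runif(5000)
  tr3 <- coverage_track(list(chrI = v3), gm, state = "input_subtracted")
  pm4 <- anchored_matrix(tr3, anchors[1], flank = 200, bin = 25)
  for (b in seq_len(16)) {
    at <- (1000 - 200 + (b - 1) * 25):(1000 - 200 + b * 25 - 1)
    expect_equal(pm4$matrix[1, b], median(v3[at]))
  }
  # off-chromosome bases excluded as missing
  edge <- GRanges("chrI", IRanges(10, width = 1), strand = "+")
  pm5 <- anchored_matrix(tr3, edge, flank = 500, bin = 50)
  expect_true(all(is.na(pm5$matrix[1, 1:9])))
  expect_false(anyNA(pm5$matrix[1, 11:20]))
})

test_that("translation equivariance of anchored_matrix", {
  set.seed(32)
  gm <- genome_model(c(chrI = 3000))
  v <- runif(3000)
  shift <- 137
  v_shift <- c(rep(0, shift), v)[1:3000]
  a1 <- GRanges("chrI", IRanges(1500, width = 1), strand = "+")
  a2 <- GRanges("chrI", IRanges(1500 + shift, width = 1), strand = "+")
  t1 <- coverage_track(list(chrI = v), gm, state = "raw")
  t2 <- coverage_track(list(chrI = v_shift), gm, state = "raw")
  expect_equal(anchored_matrix(t1, a1, 400, 50)$matrix,
               anchored_matrix(t2, a2, 400, 50)$matrix)
})

test_that("order_by_summit_score sorts rows strongest-first", {
  gm <- toy_genome()
  pk <- peak_set(df_to_gr(data.frame(chrom = "chrI",
                                     start = c(100, 300, 500),
                                     end = c(200, 400, 600)), gm),
                 summit = c(150, 350, 550), summit_score = c(2, 9, 5))
  pm <- list(matrix = matrix(1:9, 3, 3), offsets = c(-50, 0, 50), bin = 50,
             flank = 75, stat = "median", row_order = 1:3)
  class(pm) <- "ProfileMatrix"
  out <- order_by_summit_score(pm, pk)
  expect_equal(out$row_order, c(2, 3, 1))
  expect_equal(out$matrix[1, ], c(2, 5, 8))
  # already sorted input unchanged; reversed input reversed
  pk_sorted <- pk[order(-pk$summit_score)]
  expect_equal(order_by_summit_score(pm, pk_sorted)$row_order, 1:3)
  # ties broken by (chrom, start)
  pk$summit_score <- c(5, 5, 5)
  expect_equal(order_by_summit_score(pm, pk)$row_order, 1:3)
})

test_that("tss_profile separates expression classes with planted signal", {
  set.seed(33)
  gm <- genome_model(c(chrI = 100000))
  starts <- seq(2000, 96000, by = 2000)
  genes <- GRanges("chrI", IRanges(starts, width = 1000), strand = "+",
                   seqinfo = as_seqinfo(gm))
  genes$name <- sprintf("g%02d", seq_along(genes))
  expr <- setNames(rlnorm(length(genes), 2, 1), genes$name)
  top <- names(sort(expr, decreasing = TRUE))[1:12]
  v <- rnorm(100000, 0, 0.1)
  for (g in top) {   # promoter enrichment only at top-quartile genes
    s <- starts[match(g, genes$name)]
    v[(s - 300):(s + 100)] <- v[(s - 300):(s + 100)] + 5
  }
  tr <- coverage_track(list(chrI = v), gm, state = "input_subtracted")
  prof <- tss_profile(tr, genes, expr, flank = 750, bin = 50)
  near <- prof$offset >= -250 & prof$offset < 100  # inside planted window
  hi <- prof[prof$class == "expressed" & near, ]
  lo <- prof[prof$class == "not_expressed" & near, ]
  expect_true(all(hi$mean > lo$mean + 1))
  # identical rows -> zero-width band
  ct <- constant_track(gm, 2, state = "input_subtracted")
  prof2 <- tss_profile(ct, genes, expr, flank = 500, bin = 50)
  expect_true(all(prof2$hi - prof2$lo < 1e-12))
  # shuffled labels -> curves indistinguishable
  expr_shuf <- setNames(sample(expr), names(expr))
  prof3 <- tss_profile(tr, genes, expr_shuf, flank = 750, bin = 50)
  m_hi <- mean(prof3$mean[prof3$class == "expressed" & near])
  m_lo <- mean(prof3$mean[prof3$class == "not_expressed" & near])
  expect_lt(abs(m_hi - m_lo), 2.5)
  # bootstrap band available and finite
  prof4 <- tss_profile(tr, genes, expr, flank = 500, bin = 50,
                       band = "bootstrap", n_boot = 50, seed = 2)
  expect_identical(attr(prof4, "band"), "bootstrap")
  expect_false(anyNA(prof4$lo))
})

test_that("gc_track matches exact values and the window-count oracle", {
  gm <- genome_model(c(chrI = 40))
  allg <- paste(rep("G", 40), collapse = "")
  expect_true(all(gc_track(list(chrI = allg), gm)$values$chrI == 1))
  alla <- paste(rep("A", 40), collapse = "")
  expect_true(all(gc_track(list(chrI = alla), gm)$values$chrI == 0))
  # alternating ACGT: every 15 bp interior window holds 0.5 GC close
  alt <- paste(rep("ACGT", 10), collapse = "")
  gt <- gc_track(list(chrI = alt), gm)$values$chrI
  interior <- gt[8:33]
  expect_true(all(abs(interior - 0.5) <= 0.5 / 15 + 1e-9))
  expect_equal(mean(interior), 0.5, tolerance = 0.01)
  # random sequence: brute-force oracle incl. truncated ends
  set.seed(34)
  sq <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  gm2 <- genome_model(c(chrI = 200))
  expect_equal(gc_track(list(chrI = sq), gm2)$values$chrI,
               oracle_gc(sq, 15))
  # non-ACGT counts as non-GC and is tallied
  sqn <- paste(c(rep("G", 10), "N", rep("G", 9)), collapse = "")
  gm3 <- genome_model(c(chrI = 20))
  gtn <- gc_track(list(chrI = sqn), gm3)
  expect_lt(gtn$values$chrI[11], 1)
  expect_equal(gtn$provenance[[1]]$n_nonacgt, 1)
  expect_error(gc_track(list(chrI = sq), gm2, window = 14), "odd")
})

test_that("gc_summit_profile recovers planted GC elevation over control", {
  cfg <- simulation_config(n_chroms = 3, chrom_length = 40000,
                           n_genes = 12, gc_background = 0.35,
                           gc_at_peaks = 0.7, rng_seed = 41)
  gm <- sim_genome_model(cfg)
  ann <- generate_annotations(cfg, gm, seed = 41)
  tp <- generate_true_peaks(cfg, gm, ann, "condensin_II", seed = 42)
  seqs <- generate_genome(cfg, gm, list(condensin_II = tp), seed = 43)
  prof <- gc_summit_profile(seqs, gm, tp, flank = 750, bin = 50,
                            n_random = 500, seed = 44)
  center <- abs(prof$summit$offset) <= 50
  flank_bins <- abs(prof$summit$offset) >= 600
  expect_gt(mean(prof$summit$mean_gc[center]),
            mean(prof$control$mean_gc[center]) + 0.1)
  # flanks at background; control flat near background everywhere
  expect_equal(mean(prof$summit$mean_gc[flank_bins]), 0.35,
               tolerance = 0.03)
  expect_equal(mean(prof$control$mean_gc), 0.35, tolerance = 0.03)
  # fixed seed -> identical control
  prof2 <- gc_summit_profile(seqs, gm, tp, flank = 750, bin = 50,
                             n_random = 500, seed = 44)
  expect_identical(prof$control, prof2$control)
})
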