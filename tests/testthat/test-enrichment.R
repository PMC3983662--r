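test_that("summit windows are +/-200 bp, clamped at chromosome ends", {
  gm <- toy_genome()
  pk <- peak_set(df_to_gr(data.frame(chrom = "chrI",
                                     start = c(40, 900, 9900),
                                     end = c(60, 1100, 9990)), gm),
                 summit = c(50, 1000, 9950))
  w <- summit_windows(pk, gm, 200)
  expect_equal(start(w), c(1, 800, 9750))    # left clamp on the first
  expect_equal(end(w), c(250, 1200, 10000))  # right clamp on the last
  expect_equal(width(w)[2], 401)
  expect_error(summit_windows(df_to_gr(data.frame(
    chrom = "chrI", start = 1, end = 10), gm), gm), "summit")
})

test_that("overlap_fraction counts both directions and matches the oracle", {
  set.seed(21)
  gm <- toy_genome()
  a <- random_intervals(gm, 60)
  b <- random_intervals(gm, 30)
  ov <- overlap_fraction(df_to_gr(a, gm), df_to_gr(b, gm))
  expect_equal(ov$fraction, mean(oracle_hit_flags(a, b, gm)))
  expect_equal(ov$rev_fraction, mean(oracle_hit_flags(b, a, gm)))
  # annotation = whole genome -> 1; disjoint -> 0
  whole <- df_to_gr(data.frame(chrom = chrom_names(gm), start = 1,
                               end = 10000), gm)
  expect_equal(overlap_fraction(df_to_gr(a, gm), whole)$fraction, 1)
  far <- GRanges("chrII", IRanges(1, 1))
  aI <- df_to_gr(a[a$chrom == "chrI", ], gm)
  expect_equal(overlap_fraction(aI, far)$fraction, 0)
  expect_error(overlap_fraction(GRanges(), whole), "empty")
})

test_that("the fast hit index agrees with interval_hits on random data", {
  set.seed(22)
  gm <- toy_genome()
  for (mo in c(1L, 40L)) {
    a <- random_intervals(gm, 80, 10, 300)
    b <- random_intervals(gm, 25, 10, 500)
    idx <- peakscape:::prepare_annotation_index(df_to_gr(b, gm), mo)
    fast <- peakscape:::fast_hit_flags(a$chrom, a$start, a$end, idx)
    # reference: merged annotation via the GRanges route
    ref <- interval_hits(df_to_gr(a, gm),
                         merge_intervals(df_to_gr(b, gm)), mo)$a_hit
    expect_identical(fast, ref)
  }
})

test_that("shuffle preserves lengths, respects exclusions, is seeded", {
  gm <- genome_model(c(chrI = 10000, chrII = 20000, chrM = 3000),
                     excluded_chroms = "chrM")
  pk <- peak_set(df_to_gr(data.frame(chrom = "chrI",
                                     start = seq(1, 9001, by = 500),
                                     end = seq(1, 9001, by = 500) + 99),
                          gm))
  s1 <- shuffle_peaks(pk, gm, seed = 3)
  s2 <- shuffle_peaks(pk, gm, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_setequal(width(s1), 100)
  expect_false("chrM" %in% as.character(seqnames(s1)))
  # placement proportional to chromosome length over many shuffles
  counts <- c(chrI = 0, chrII = 0)
  set.seed(99)
  for (i in 1:400) {
    s <- shuffle_peaks(pk[1:5], gm)
    tab <- table(factor(as.character(seqnames(s)),
                        levels = c("chrI", "chrII")))
    counts <- counts + as.integer(tab)
  }
  p <- chisq.test(counts, p = c(1, 2) / 3)$p.value
  expect_gt(p, 0.01)
  # peak longer than every chromosome
  giant <- peak_set(GRanges("chrI", IRanges(1, 10000)))
  expect_error(shuffle_peaks(peak_set(GRanges("chrII",
                                              IRanges(1, 25000))), gm))
})

test_that("permutation null mean matches exact enumeration on a tiny genome", {
  gm <- genome_model(c(c1 = 100, c2 = 100))
  pk <- peak_set(GRanges("c1", IRanges(1, 10),
                         seqinfo = as_seqinfo(gm)))   # one 10 bp peak
  ann <- GRanges("c1", IRanges(41, 60), seqinfo = as_seqinfo(gm))  # 20 bp
  # ORACLE: enumerate every placement (chrom x start), uniform over both
  hits <- 0L; total <- 0L
  for (ch in c("c1", "c2")) for (s in 1:91) {
    total <- total + 1L
    if (ch == "c1" && s <= 60 && s + 9 >= 41) hits <- hits + 1L
  }
  exact <- hits / total
  res <- permutation_test(pk, ann, gm,
                          analysis_config(n_permutations = 20000,
                                          rng_seed = 5),
                          use_summit_windows = FALSE)
  mc_err <- 3 * sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$null_mean - exact), mc_err)
})

test_that("p-value convention reproduces the 0.0002 floor and fold", {
  gm <- genome_model(c(c1 = 50000, c2 = 50000))
  # all peaks inside the annotation: observed fraction 1, tiny null
  ann <- GRanges("c1", IRanges(1001, 6000), seqinfo = as_seqinfo(gm))
  pk <- peak_set(GRanges("c1", IRanges(seq(1100, 5600, by = 250),
                                       width = 100),
                         seqinfo = as_seqinfo(gm)))
  cfg <- analysis_config(n_permutations = 10000, rng_seed = 11)
  res <- permutation_test(pk, ann, gm, cfg, use_summit_windows = FALSE)
  expect_equal(res$observed_fraction, 1)
  expect_equal(res$p_value, 0.0002)
  expect_identical(res$direction, "enriched")
  expect_equal(permutation_p_floor(10000), 0.0002)
  # annotation = whole genome -> fold 1, not significant
  whole <- df_to_gr(data.frame(chrom = c("c1", "c2"), start = 1,
                               end = 50000), gm)
  res2 <- permutation_test(pk, whole, gm, cfg, use_summit_windows = FALSE)
  expect_equal(res2$fold_enrichment, 1)
  expect_identical(res2$direction, "ns")
  expect_equal(res2$p_value, 1)
})

test_that("observed overlap is invariant to N; null mean converges", {
  set.seed(23)
  gm <- toy_genome()
  pk <- peak_set(df_to_gr(random_intervals(gm, 40, 50, 200), gm))
  ann <- df_to_gr(random_intervals(gm, 15, 200, 1000), gm)
  r1 <- permutation_test(pk, ann, gm,
                         analysis_config(n_permutations = 200,
                                         rng_seed = 1),
                         use_summit_windows = FALSE)
  r2 <- permutation_test(pk, ann, gm,
                         analysis_config(n_permutations = 4000,
                                         rng_seed = 2),
                         use_summit_windows = FALSE)
  expect_identical(r1$observed_count, r2$observed_count)
  # sd of the null-mean estimate shrinks ~ 1/sqrt(N): both should be close
  expect_lt(abs(r1$null_mean - r2$null_mean),
            5 * r2$null_sd / sqrt(200) + 5 * r2$null_sd / sqrt(4000))
})

test_that("tf_overlap_table ranks by fold and masks HOT regions", {
  set.seed(24)
  gm <- toy_genome()
  pk <- peak_set(df_to_gr(data.frame(
    chrom = rep(c("chrI", "chrII"), each = 10),
    start = rep(seq(500, 9500, by = 1000), 2),
    end = rep(seq(500, 9500, by = 1000), 2) + 200), gm))
  cfg <- analysis_config(n_permutations = 300, summit_window = 100,
                         rng_seed = 9)
  # TF identical to the peaks: 100% overlap, top fold
  tf_same <- GenomicRanges::granges(pk)
  tf_rand <- df_to_gr(random_intervals(gm, 20, 100, 300), gm)
  tab <- tf_overlap_table(pk, list(same = tf_same, rand = tf_rand), gm, cfg)
  expect_identical(tab$tf[1], "same")
  expect_equal(tab$pct_peaks_hit[tab$tf == "same"], 100)
  expect_gt(tab$fold[tab$tf == "same"], 1)
  # HOT masking removes exactly the flagged peaks
  hot <- GRanges("chrI", IRanges(1, 10000))
  tab2 <- tf_overlap_table(pk, list(same = tf_same), gm, cfg,
                           hot_regions = hot)
  expect_equal(attr(tab2, "n_peaks_masked"), 10)
  # empty TF set after masking is flagged ns
  tf_onlyI <- df_to_gr(data.frame(chrom = "chrI", start = 100, end = 300),
                       gm)
  tab3 <- tf_overlap_table(pk, list(gone = tf_onlyI), gm, cfg,
                           hot_regions = hot)
  expect_identical(tab3$direction, "ns")
  expect_equal(tab3$n_tf_sites, 0L)
})

test_that("peak count vs covered length regression behaves", {
  gm <- genome_model(c(a = 10000, b = 10000, c = 10000, d = 10000,
                       chrX = 10000), x_chrom = "chrX")
  # peaks proportional to mark-covered length -> R^2 = 1
  marks <- list(
    m1 = df_to_gr(data.frame(chrom = c("a", "b", "c", "d"), start = 1,
                             end = c(1000, 2000, 3000, 4000)), gm))
  pk <- do.call(rbind, lapply(seq_along(c("a", "b", "c", "d")), function(i)
    data.frame(chrom = c("a", "b", "c", "d")[i],
               start = seq(10, 5000, length.out = i * 2),
               end = seq(10, 5000, length.out = i * 2) + 5)))
  fit <- suppressWarnings(peaks_vs_marked_length(df_to_gr(pk, gm), marks, gm))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 2 / 1000, tolerance = 1e-9)
  # constant counts -> slope 0
  pk2 <- df_to_gr(data.frame(chrom = c("a", "b", "c", "d"),
                             start = 100, end = 200), gm)
  fit2 <- suppressWarnings(peaks_vs_marked_length(pk2, marks, gm))
  expect_equal(fit2$slope, 0, tolerance = 1e-9)
  expect_error(peaks_vs_marked_length(pk2, marks, gm, chroms = c("a", "b")),
               ">= 3")
  # covered length uses the merged union of the sets
  marks2 <- list(m1 = marks$m1, m2 = marks$m1)  # duplicate set
  fit3 <- suppressWarnings(peaks_vs_marked_length(df_to_gr(pk, gm), marks2, gm))
  expect_equal(fit3$slope, fit$slope, tolerance = 1e-9)
})
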