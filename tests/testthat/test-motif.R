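# exhaustive ORACLE: score every window on both strands by direct lookup
oracle_scan <- function(pwm, seq_chr, threshold) {
  b <- strsplit(seq_chr, "")[[1]]
  w <- pwm$width
  lo <- log2(pwm$probs / pwm$background)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (i in seq_len(length(b) - w + 1)) {
    win <- b[i:(i + w - 1)]
    if (!all(win %in% c("A", "C", "G", "T"))) next
    fwd <- sum(vapply(seq_len(w), function(j) lo[win[j], j], 0))
    rev_win <- rev(unname(rc[win]))
    rev_s <- sum(vapply(seq_len(w), function(j) lo[rev_win[j], j], 0))
    if (fwd >= threshold)
      hits[[length(hits) + 1]] <- c(i, fwd, 1)
    if (rev_s >= threshold)
      hits[[length(hits) + 1]] <- c(i, rev_s, -1)
  }
  do.call(rbind, hits)
}

test_that("pwm construction validates and reports consensus", {
  pwm <- pwm_from_consensus("ACGTACGT", strength = 0.9)
  expect_equal(colSums(pwm$probs), rep(1, 8))
  expect_equal(pwm$width, 8)
  expect_error(pwm_from_consensus("ACGN"), "ACGT")
  expect_error(pwm_model(matrix(1, 4, 3,
                                dimnames = list(c("A", "C", "G", "T"),
                                                NULL))), "width")
  seqs <- c("ACGT", "ACGA", "ACGT")
  pwm2 <- pwm_from_sequences(seqs)
  expect_gt(pwm2$probs["T", 4], pwm2$probs["A", 4])
  expect_equal(colSums(pwm2$probs), rep(1, 4))
})

test_that("scan_pwm finds a planted consensus and respects the threshold", {
  gm <- genome_model(c(chrI = 300))
  set.seed(71)
  base <- sample(c("A", "T"), 300, TRUE)   # AT background: no GC hits
  base[101:110] <- strsplit("AGGGGCGCGC", "")[[1]]
  sq <- paste(base, collapse = "")
  pwm <- pwm_from_consensus("AGGGGCGCGC", strength = 0.9)
  hits <- scan_pwm(pwm, list(chrI = sq), gm,
                   threshold = 0.9 * max_logodds(pwm), chroms = "chrI")
  expect_equal(length(hits), 1)
  expect_equal(start(hits), 101)
  expect_identical(as.character(strand(hits)), "+")
  # +Inf threshold -> no hits; short sequence -> empty
  expect_length(scan_pwm(pwm, list(chrI = sq), gm, threshold = Inf,
                         chroms = "chrI"), 0)
  gm5 <- genome_model(c(chrI = 5))
  expect_length(scan_pwm(pwm, list(chrI = "ACGTA"), gm5, chroms = "chrI"),
                0)
})

test_that("scan_pwm matches the exhaustive oracle on random sequence", {
  set.seed(72)
  gm <- genome_model(c(chrI = 2000))
  sq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  pwm <- pwm_from_consensus("GCGCGC", strength = 0.7)
  thr <- 0.5 * max_logodds(pwm)
  hits <- scan_pwm(pwm, list(chrI = sq), gm, threshold = thr,
                   chroms = "chrI")
  want <- oracle_scan(pwm, sq, thr)
  expect_equal(length(hits), nrow(want))
  got <- data.frame(start = start(hits),
                    strand = ifelse(as.character(strand(hits)) == "+",
                                    1, -1))
  got <- got[order(got$start, got$strand), ]
  wnt <- data.frame(start = want[, 1], strand = want[, 3])
  wnt <- wnt[order(wnt$start, wnt$strand), ]
  expect_equal(got$start, wnt$start)
  expect_equal(got$strand, wnt$strand)
  expect_equal(sort(hits$score), sort(want[, 2]), tolerance = 1e-9)
})

test_that("scan_pwm hit set is strand-symmetric", {
  set.seed(73)
  gm <- genome_model(c(chrI = 1500))
  sq_v <- sample(c("A", "C", "G", "T"), 1500, TRUE)
  sq <- paste(sq_v, collapse = "")
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  sq_rc <- paste(rev(unname(rc[sq_v])), collapse = "")
  pwm <- pwm_from_consensus("AGGCGC", strength = 0.8)
  thr <- 0.6 * max_logodds(pwm)
  h1 <- scan_pwm(pwm, list(chrI = sq), gm, threshold = thr, chroms = "chrI")
  h2 <- scan_pwm(pwm, list(chrI = sq_rc), gm, threshold = thr,
                 chroms = "chrI")
  # mirrored positions: start' = L - end + 1, strands swapped
  expect_equal(sort(1500 - end(h1) + 1), sort(start(h2)))
  expect_equal(length(h1), length(h2))
  expect_equal(sum(strand(h1) == "+"), sum(strand(h2) == "-"))
})

test_that("motif bound fraction and context conditioning recover truth", {
  gm <- genome_model(c(chrI = 1000000))
  set.seed(74)
  # 2000 planted motif positions; 500 inside "marked" windows
  pos <- sort(sample(seq(1000, 999000, by = 450), 2000))
  hits <- GRanges("chrI", IRanges(pos, width = 10),
                  seqinfo = as_seqinfo(gm))
  marked_idx <- 1:500
  mark_windows <- reduce(GRanges("chrI",
                                 IRanges(pos[marked_idx] - 995,
                                         pos[marked_idx] + 1005)))
  # bind 29% of marked, 5% of unmarked -> ~11% overall
  bound_idx <- c(sample(marked_idx, 145), sample(501:2000, 75))
  peaks <- GRanges("chrI", IRanges(pos[bound_idx] - 50,
                                   pos[bound_idx] + 50))
  frac <- motif_bound_fraction(hits, peaks)
  expect_equal(frac, 220 / 2000, tolerance = 1e-9)
  ctx <- context_conditioned_fraction(hits, peaks, mark_windows)
  expect_equal(ctx$fraction_all, 0.11, tolerance = 1e-9)
  # conditioned fraction can pick up unbound-marked neighbours by window
  # overlap; require it near the planted 29%
  expect_equal(ctx$fraction_in_marked, 0.29, tolerance = 0.05)
  # degenerate cases
  expect_equal(motif_bound_fraction(hits,
                                    GRanges("chrI", IRanges(1, 1000000))),
               1)
  expect_equal(motif_bound_fraction(hits[1:10],
                                    GRanges("chrI", IRanges(999990, 999999))),
               0)
  expect_error(motif_bound_fraction(GRanges(), peaks), "no motif hits")
})

test_that("clustering_effect recovers the planted fold", {
  gm <- genome_model(c(chrI = 5000000))
  set.seed(75)
  tiles_n <- 5000
  # windows 1..5000 of 1 kb; plant exactly 1 motif in 2000, 2+ in 1000
  single_w <- sample(tiles_n, 3000)
  multi_w <- single_w[2001:3000]; single_w <- single_w[1:2000]
  mpos <- c((single_w - 1) * 1000 + 500,
            (multi_w - 1) * 1000 + 300, (multi_w - 1) * 1000 + 700)
  hits <- GRanges("chrI", IRanges(sort(mpos), width = 10),
                  seqinfo = as_seqinfo(gm))
  # bind multi-windows at 0.5, single at 0.2 -> fold 2.5
  bound_w <- c(single_w[runif(2000) < 0.2], multi_w[runif(1000) < 0.5])
  peaks <- GRanges("chrI", IRanges((bound_w - 1) * 1000 + 450, width = 100))
  res <- clustering_effect(hits, peaks, gm, window = 1000)
  expect_equal(res$n_single, 2000)
  expect_equal(res$n_multi, 1000)
  expect_equal(res$fold, 2.5, tolerance = 0.2 * 2.5)
  # binding independent of motif count -> fold ~ 1
  bound_all <- sample(tiles_n, 1500)
  peaks2 <- GRanges("chrI", IRanges((bound_all - 1) * 1000 + 450,
                                    width = 100))
  res2 <- clustering_effect(hits, peaks2, gm, window = 1000)
  expect_equal(res2$fold, 1, tolerance = 0.25)
  # peaks only at multi-motif windows -> fold >> 1
  peaks3 <- GRanges("chrI", IRanges((multi_w - 1) * 1000 + 450,
                                    width = 100))
  res3 <- clustering_effect(hits, peaks3, gm, window = 1000)
  expect_gt(res3$fold, 10)
  expect_error(clustering_effect(hits[0], peaks, gm), "single-motif")
})

test_that("PWM matrix files round-trip", {
  pwm <- pwm_from_consensus("AGGGGCGCGC", strength = 0.88,
                            background = c(A = 0.32, C = 0.18, G = 0.18,
                                           T = 0.32))
  f <- withr::local_tempfile(fileext = ".pwm")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$probs, pwm$probs, tolerance = 1e-5)
  expect_equal(back$background, pwm$background, tolerance = 1e-5)
  expect_equal(max_logodds(back), max_logodds(pwm), tolerance = 1e-4)
})
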