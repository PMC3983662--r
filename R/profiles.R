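#' Signal matrix anchored at a set of genomic positions
#'
#' For each anchor (a TSS or a peak summit) the per-base signal in
#' `[-flank, +flank)` is summarized in consecutive bins (median by default,
#' per the 50 bp-window convention). Minus-strand anchors are reversed so
#' columns always read 5' to 3'. Bases falling off a chromosome end are
#' treated as missing and excluded from their bin's summary (a bin with no
#' bases is `NA`).
#'
#' @param track A `CoverageTrack`.
#' @param anchors `GRanges` of anchor points (width 1 or with a `summit`
#'   column, which takes precedence); strand used for orientation.
#' @param flank Bases on each side of the anchor (750 gives a 1.5 kb
#'   window).
#' @param bin Bin width in bp; must divide `2 * flank`.
#' @param stat `"median"` or `"mean"` per bin.
#' @return A `ProfileMatrix`: list with `matrix` (anchors x bins), `offsets`
#'   (bin start offsets relative to the anchor), `bin`, `flank`, `stat`,
#'   `row_order`.
#' @export
anchored_matrix <- function(track, anchors, flank = 750L, bin = 50L,
                            stat = c("median", "mean")) {
  stat <- match.arg(stat)
  flank <- as.integer(flank); bin <- as.integer(bin)
  if ((2L * flank) %% bin != 0L) stop("bin must divide 2*flank")
  n_bins <- 2L * flank %/% bin
  pos <- if (!is.null(anchors$summit)) anchors$summit
         else GenomicRanges::start(anchors)
  ch <- as.character(GenomeInfoDb::seqnames(anchors))
  neg <- as.character(GenomicRanges::strand(anchors)) == "-"
  fun <- if (stat == "median") function(x) stats::median(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  mat <- matrix(NA_real_, length(anchors), n_bins)
  for (i in seq_along(anchors)) {
    L <- length(track$values[[ch[i]]])
    at <- (pos[i] - flank):(pos[i] + flank - 1L)
    v <- rep(NA_real_, 2L * flank)
    ok <- at >= 1L & at <= L
    v[ok] <- track$values[[ch[i]]][at[ok]]
    if (neg[i]) v <- rev(v)
    mat[i, ] <- suppressWarnings(
      vapply(seq_len(n_bins),
             function(b) fun(v[((b - 1L) * bin + 1L):(b * bin)]), 0))
  }
  mat[is.nan(mat)] <- NA_real_
  structure(list(matrix = mat, offsets = seq(-flank, flank - bin, by = bin),
                 bin = bin, flank = flank, stat = stat,
                 row_order = seq_along(anchors)),
            class = "ProfileMatrix")
}

#' Order profile rows by summit score, strongest on top
#'
#' @param pm A `ProfileMatrix` with one row per peak.
#' @param peaks The `GRanges` (with `summit_score`) the rows came from, in
#'   the same order.
#' @return The `ProfileMatrix` with rows sorted by decreasing summit score
#'   (ties broken by chromosome then start).
#' @export
order_by_summit_score <- function(pm, peaks) {
  if (nrow(pm$matrix) != length(peaks))
    stop("one row per peak required")
  o <- order(-peaks$summit_score,
             as.character(GenomeInfoDb::seqnames(peaks)),
             GenomicRanges::start(peaks))
  pm$matrix <- pm$matrix[o, , drop = FALSE]
  pm$row_order <- o
  pm
}

#' Write a profile matrix as TSV (header row = bin offsets)
#' @param pm A `ProfileMatrix`.
#' @param path Output path.
#' @export
write_profile_matrix <- function(pm, path) {
  m <- pm$matrix
  colnames(m) <- pm$offsets
  utils::write.table(format(m, digits = 8, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' TSS metagene profile by expression class
#'
#' Genes are split into expression classes (by default the top and bottom
#' quartiles -- expressed vs not expressed) and the mean signal per bin is
#' plotted with a 95% confidence band. The band is the normal approximation
#' `mean +/- 1.96 * sd / sqrt(n)` across genes by default; a bootstrap
#' percentile band is available.
#'
#' @param track A `CoverageTrack`.
#' @param genes Stranded `GRanges` with a `name` column.
#' @param expression Named numeric vector of expression values (FPKM-like),
#'   names matching `genes$name`.
#' @param flank,bin Window geometry (defaults: 750 bp each side, 50 bp
#'   bins).
#' @param classes Named list of quantile ranges defining the classes.
#' @param band `"normal"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `band = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return data.frame: class, offset, mean, lo, hi, n_genes; attribute
#'   `band` records the method. Classes with fewer than 2 genes get `NA`
#'   bands.
#' @export
tss_profile <- function(track, genes, expression, flank = 750L, bin = 50L,
                        classes = list(expressed = c(0.75, 1),
                                       not_expressed = c(0, 0.25)),
                        band = c("normal", "bootstrap"), n_boot = 200L,
                        seed = 1L) {
  band <- match.arg(band)
  expr <- expression[genes$name]
  if (anyNA(expr)) {
    keep <- !is.na(expr)
    genes <- genes[keep]; expr <- expr[keep]
  }
  q <- rank(expr, ties.method = "average") / length(expr)
  pm <- anchored_matrix(track, anchor_points(genes, tss_positions(genes)),
                        flank, bin, stat = "mean")
  out <- list()
  for (cl in names(classes)) {
    rng <- classes[[cl]]
    rows <- which(q > rng[1L] & q <= rng[2L] |
                    (rng[1L] == 0 & q == 0))
    sub <- pm$matrix[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    if (length(rows) < 2L) {
      lo <- hi <- rep(NA_real_, ncol(sub))
    } else if (band == "normal") {
      se <- apply(sub, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1L))
      lo <- mu - 1.96 * se; hi <- mu + 1.96 * se
    } else {
      bq <- with_seed(seed, {
        reps <- replicate(n_boot, {
          colMeans(sub[sample(nrow(sub), replace = TRUE), , drop = FALSE],
                   na.rm = TRUE)
        })
        apply(reps, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
      })
      lo <- bq[1L, ]; hi <- bq[2L, ]
    }
    out[[cl]] <- data.frame(class = cl, offset = pm$offsets, mean = mu,
                            lo = lo, hi = hi, n_genes = length(rows))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "band") <- band
  res
}

# Internal: width-1 anchor GRanges at the given positions, keeping strand.
anchor_points <- function(gr, pos) {
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::IRanges(pos, width = 1L),
                                strand = GenomicRanges::strand(gr))
  out
}

#' Per-base GC content with a centered sliding window
#'
#' Each base is assigned the GC fraction of the window of `window` bases
#' centered on it (the mid position of the window); windows are truncated at
#' chromosome ends. Non-ACGT characters count as non-GC (their total is
#' reported in the provenance).
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`,
#'   one sequence per chromosome of `genome`.
#' @param genome A `GenomeModel`.
#' @param window Odd window size in bp (default 15).
#' @return A `CoverageTrack` of GC fractions in `[0, 1]`.
#' @export
gc_track <- function(sequences, genome, window = 15L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  half <- window %/% 2L
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  n_nonacgt <- 0L
  vals <- lapply(chrom_names(genome), function(ch) {
    s <- sequences[[ch]]
    if (is.null(s)) stop("no sequence for chromosome ", ch)
    b <- strsplit(toupper(s), "")[[1L]]
    L <- length(b)
    if (L != genome$chrom_lengths[[ch]])
      stop("sequence length mismatch on ", ch)
    n_nonacgt <<- n_nonacgt + sum(!b %in% c("A", "C", "G", "T"))
    isgc <- as.numeric(b %in% c("G", "C"))
    cs <- c(0, cumsum(isgc))
    i <- seq_len(L)
    lo <- pmax(i - half, 1L); hi <- pmin(i + half, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  names(vals) <- chrom_names(genome)
  coverage_track(vals, genome,
                 provenance = list(list(op = "gc_track", window = window,
                                        n_nonacgt = n_nonacgt)))
}

#' Mean GC profile across peak summits, with a random-coordinate control
#'
#' The sliding-window GC track is averaged in bins across the summits, and
#' the same computation is repeated over `n_random` uniformly drawn genomic
#' positions (1,500 by convention) as the control curve.
#'
#' @param sequences Sequences as in [gc_track()] (or a precomputed GC
#'   `CoverageTrack`).
#' @param genome A `GenomeModel`.
#' @param summits `GRanges` with a `summit` column, or width-1 anchors.
#' @param flank,bin Window geometry.
#' @param gc_window Sliding-window size for [gc_track()].
#' @param n_random Number of random control positions.
#' @param seed Seed for the control draw.
#' @return List: `summit` and `control` data.frames (offset, mean_gc, n),
#'   plus the `gc` track used.
#' @export
gc_summit_profile <- function(sequences, genome, summits, flank = 750L,
                              bin = 50L, gc_window = 15L, n_random = 1500L,
                              seed = 1L) {
  gc <- if (methods::is(sequences, "CoverageTrack")) sequences
        else gc_track(sequences, genome, gc_window)
  pm <- anchored_matrix(gc, summits, flank, bin, stat = "mean")
  ctrl_anchors <- with_seed(seed, {
    chroms <- analysis_chroms(genome)
    L <- genome$chrom_lengths[chroms]
    ch <- sample(chroms, n_random, replace = TRUE, prob = L)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      1L + as.integer(floor(stats::runif(n_random) * L[ch])), width = 1L))
  })
  pmc <- anchored_matrix(gc, ctrl_anchors, flank, bin, stat = "mean")
  summarize <- function(p) data.frame(
    offset = p$offsets, mean_gc = colMeans(p$matrix, na.rm = TRUE),
    n = colSums(!is.na(p$matrix)))
  list(summit = summarize(pm), control = summarize(pmc), gc = gc)
}
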