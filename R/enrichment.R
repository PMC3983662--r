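#' Windows around peak summits for overlap statistics
#'
#' The region +/- `halfwidth` bp around each summit (total `2*halfwidth + 1`
#' bases), clamped to chromosome bounds, is the unit used to ask which
#' annotations a peak overlaps.
#'
#' @param peaks `GRanges` with a `summit` column ([peak_set()]).
#' @param genome A `GenomeModel`.
#' @param halfwidth Half-width in bp (default 200).
#' @return `GRanges` of summit windows (one per peak, same order).
#' @export
summit_windows <- function(peaks, genome, halfwidth = 200L) {
  if (is.null(peaks$summit)) stop("peaks carry no summit column")
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(peaks),
    IRanges::IRanges(pmax(1L, peaks$summit - as.integer(halfwidth)),
                     pmin(as.integer(genome$chrom_lengths[
                       as.character(GenomeInfoDb::seqnames(peaks))]),
                       peaks$summit + as.integer(halfwidth))))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(peaks)
  gr
}

#' Fraction of peaks overlapping an annotation (and the reverse)
#'
#' @param peak_windows `GRanges` of peak (summit) windows.
#' @param annotation `GRanges` of annotation intervals.
#' @param min_overlap Minimum shared bases.
#' @return List: `fraction`/`count` of peak windows hit, `rev_fraction`/
#'   `rev_count` of annotation records hit, and the set sizes.
#' @export
overlap_fraction <- function(peak_windows, annotation, min_overlap = 1L) {
  if (length(peak_windows) == 0L) stop("empty peak set")
  h <- interval_hits(peak_windows, annotation, min_overlap)
  list(fraction = h$n_a_hit / length(peak_windows), count = h$n_a_hit,
       n_peaks = length(peak_windows),
       rev_fraction = if (length(annotation))
         h$n_b_hit / length(annotation) else NA_real_,
       rev_count = h$n_b_hit, n_annotation = length(annotation))
}

# Internal: run code with a temporary RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Internal: per-chromosome index of merged annotation intervals adjusted for
# a minimum-overlap threshold, for O(log n) hit tests via findInterval.
prepare_annotation_index <- function(annotation, min_overlap = 1L) {
  ann <- merge_intervals(annotation)
  ann <- ann[GenomicRanges::width(ann) >= min_overlap]
  m <- as.integer(min_overlap)
  by_chrom <- split(ann, as.character(GenomeInfoDb::seqnames(ann)))
  idx <- lapply(by_chrom, function(g)
    list(bs = GenomicRanges::start(g) + m - 1L,
         be = GenomicRanges::end(g) - m + 1L))
  list(index = idx, min_overlap = m)
}

# Internal: logical hit flags for query intervals against an index. Merged
# annotation intervals are disjoint and sorted, so the candidate with the
# largest start <= query end decides the hit.
fast_hit_flags <- function(chrom, start, end, ann_index) {
  hit <- logical(length(start))
  wide <- (end - start + 1L) >= ann_index$min_overlap
  for (ch in unique(chrom)) {
    ix <- ann_index$index[[ch]]
    sel <- which(chrom == ch & wide)
    if (is.null(ix) || !length(sel)) next
    j <- findInterval(end[sel], ix$bs)
    hit[sel] <- j >= 1L & ix$be[pmax(j, 1L)] >= start[sel]
  }
  hit
}

#' Randomly re-place peaks across the genome, preserving lengths
#'
#' Each peak keeps its length and is dropped uniformly at random onto the
#' non-excluded genome: a chromosome is chosen with probability proportional
#' to its placeable length (`L - w + 1`), the start uniformly within it.
#' Shuffled peaks may overlap one another; summits are reset to interval
#' midpoints.
#'
#' @param peaks `GRanges` to shuffle.
#' @param genome A `GenomeModel`; excluded chromosomes are never placement
#'   targets.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param within_chromosome If `TRUE`, each peak is re-placed on its own
#'   chromosome (for X-restricted analyses).
#' @return A shuffled [peak_set()].
#' @export
shuffle_peaks <- function(peaks, genome, seed = NULL,
                          within_chromosome = FALSE) {
  w <- GenomicRanges::width(peaks)
  sh <- with_seed(seed,
    shuffle_engine(w, genome, n_perms = 1L,
                   chrom_fixed = if (within_chromosome)
                     as.character(GenomeInfoDb::seqnames(peaks)) else NULL))
  gr <- GenomicRanges::GRanges(sh$chrom, IRanges::IRanges(sh$start,
                                                          width = w))
  peak_set(gr)
}

# Internal shuffle engine: vectorized placement of n_perms copies of a
# length profile. Returns parallel vectors of length n_perms * n_peaks
# (peak-major order within each permutation).
shuffle_engine <- function(widths, genome, n_perms, chrom_fixed = NULL) {
  chroms <- analysis_chroms(genome)
  L <- genome$chrom_lengths[chroms]
  n <- length(widths)
  chrom <- character(n * n_perms)
  start <- integer(n * n_perms)
  for (i in seq_len(n)) {
    place <- pmax(L - widths[i] + 1, 0)
    at <- seq(i, by = n, length.out = n_perms)
    if (!is.null(chrom_fixed)) {
      if (place[[chrom_fixed[i]]] <= 0)
        stop("peak ", i, " longer than its chromosome")
      ch <- rep(chrom_fixed[i], n_perms)
    } else {
      if (all(place == 0)) stop("peak ", i, " longer than every chromosome")
      ch <- if (length(chroms) == 1L) rep(chroms, n_perms)
            else sample(chroms, n_perms, replace = TRUE, prob = place)
    }
    chrom[at] <- ch
    start[at] <- 1L + as.integer(floor(stats::runif(n_perms) * place[ch]))
  }
  list(chrom = chrom, start = start)
}

#' Permutation test for overlap enrichment
#'
#' The observed overlap fraction of the peak (summit) windows with an
#' annotation is compared with the fractions obtained after randomly
#' re-placing the same windows across the genome `n_permutations` times
#' (10,000 by convention). Fold enrichment is the observed fraction over the
#' mean null fraction, and the two-sided empirical p-value is
#' `p = 2 (r + 1) / (N + 1)` with `r` the number of null overlaps at least
#' as extreme as the observed one in the observed direction, capped at 1 and
#' reported to four decimals -- so with N = 10,000 the attainable floor is
#' 0.0002.
#'
#' @param peaks `GRanges` of peaks; if they carry summits and
#'   `use_summit_windows` is `TRUE` the +/-`config$summit_window` windows
#'   are tested, otherwise the intervals themselves.
#' @param annotation `GRanges` of annotation intervals.
#' @param genome A `GenomeModel`.
#' @param config An [analysis_config()] (`n_permutations`, `summit_window`,
#'   `min_overlap`, `rng_seed`).
#' @param use_summit_windows Test summit windows instead of raw intervals.
#' @param within_chromosome Restrict the null to per-chromosome re-placement.
#' @param keep_null Keep the full null vector (default) or only its summary.
#' @return A `PermutationResult`.
#' @export
permutation_test <- function(peaks, annotation, genome,
                             config = analysis_config(),
                             use_summit_windows = TRUE,
                             within_chromosome = FALSE,
                             keep_null = TRUE) {
  windows <- if (use_summit_windows && !is.null(peaks$summit))
    summit_windows(peaks, genome, config$summit_window) else peaks
  n_peaks <- length(windows)
  if (n_peaks == 0L) stop("empty peak set")
  obs <- overlap_fraction(windows, annotation, config$min_overlap)
  idx <- prepare_annotation_index(annotation, config$min_overlap)
  w <- GenomicRanges::width(windows)
  N <- config$n_permutations
  null_counts <- with_seed(config$rng_seed, {
    sh <- shuffle_engine(w, genome, N,
                         chrom_fixed = if (within_chromosome)
                           rep(as.character(GenomeInfoDb::seqnames(windows)),
                               1L) else NULL)
    hits <- fast_hit_flags(sh$chrom, sh$start,
                           sh$start + rep(w, times = N) - 1L, idx)
    as.integer(colSums(matrix(hits, nrow = n_peaks)))
  })
  null_frac <- null_counts / n_peaks
  mean_null <- mean(null_frac)
  fold <- if (mean_null > 0) obs$fraction / mean_null
          else if (obs$fraction > 0) Inf else NA_real_
  upper <- obs$count >= mean(null_counts)
  r <- if (upper) sum(null_counts >= obs$count)
       else sum(null_counts <= obs$count)
  p <- min(1, 2 * (r + 1) / (N + 1))
  direction <- if (p > 0.05 || is.na(fold)) "ns"
               else if (fold > 1) "enriched" else "depleted"
  structure(list(
    observed_count = obs$count, observed_fraction = obs$fraction,
    n_peaks = n_peaks,
    null_mean = mean_null, null_sd = stats::sd(null_frac),
    null_min = min(null_frac), null_max = max(null_frac),
    null_fractions = if (keep_null) null_frac else NULL,
    fold_enrichment = fold,
    p_value = round(p, 4), p_value_raw = p,
    direction = direction, n_permutations = N,
    rng_seed = config$rng_seed,
    within_chromosome = within_chromosome),
    class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "Permutation overlap test (N = %d, seed = %d)\n", x$n_permutations,
    x$rng_seed))
  cat(sprintf("  observed: %d/%d peaks (%.1f%%); null mean %.1f%%\n",
              x$observed_count, x$n_peaks, 100 * x$observed_fraction,
              100 * x$null_mean))
  cat(sprintf("  fold enrichment %.2f, p = %.4f (%s)\n",
              x$fold_enrichment, x$p_value, x$direction))
  invisible(x)
}

#' Smallest reportable p-value of the permutation test
#' @param n_permutations Number of shuffles.
#' @return `2 / (N + 1)` rounded to four decimals (0.0002 for N = 10,000).
#' @export
permutation_p_floor <- function(n_permutations) {
  round(2 / (n_permutations + 1), 4)
}

#' Overlap enrichment against a panel of transcription-factor peak sets
#'
#' Runs [permutation_test()] for each TF set and tabulates fold enrichment,
#' p-value and both overlap percentages, sorted by fold. When HOT (high
#' occupancy target) regions are supplied, peaks and TF sites intersecting
#' any HOT region are removed before testing so promiscuous loci do not
#' drive the ranking.
#'
#' @param condensin_peaks `GRanges` with summits.
#' @param tf_sets Named list of `GRanges`.
#' @param genome A `GenomeModel`.
#' @param config An [analysis_config()].
#' @param hot_regions Optional `GRanges` of HOT regions.
#' @return data.frame: tf, n_tf_sites, fold, p_value, pct_peaks_hit,
#'   pct_tf_hit, direction; attribute `n_peaks_masked`.
#' @export
tf_overlap_table <- function(condensin_peaks, tf_sets, genome,
                             config = analysis_config(),
                             hot_regions = NULL) {
  if (!length(tf_sets)) stop("need at least one TF set")
  peaks <- condensin_peaks
  masked <- 0L
  if (!is.null(hot_regions) && length(hot_regions)) {
    hit <- interval_hits(peaks, hot_regions)$a_hit
    masked <- sum(hit)
    peaks <- peaks[!hit]
  }
  rows <- lapply(names(tf_sets), function(nm) {
    tf <- tf_sets[[nm]]
    if (!is.null(hot_regions) && length(hot_regions))
      tf <- tf[!interval_hits(tf, hot_regions)$a_hit]
    if (length(tf) == 0L || length(peaks) == 0L)
      return(data.frame(tf = nm, n_tf_sites = 0L, fold = NA_real_,
                        p_value = NA_real_, pct_peaks_hit = NA_real_,
                        pct_tf_hit = NA_real_, direction = "ns"))
    res <- permutation_test(peaks, tf, genome, config, keep_null = FALSE)
    win <- summit_windows(peaks, genome, config$summit_window)
    ov <- overlap_fraction(win, tf, config$min_overlap)
    data.frame(tf = nm, n_tf_sites = length(tf), fold = res$fold_enrichment,
               p_value = res$p_value, pct_peaks_hit = 100 * ov$fraction,
               pct_tf_hit = 100 * ov$rev_fraction, direction = res$direction)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold), ]
  rownames(out) <- NULL
  attr(out, "n_peaks_masked") <- masked
  out
}

#' Peak count per chromosome against mark-covered chromosome length
#'
#' Regresses the number of peaks per chromosome on the number of bases of
#' that chromosome covered by a set of (histone) mark peak sets -- the
#' merged union of the supplied sets. Used to ask whether binding-site
#' number tracks active-chromatin territory rather than raw chromosome
#' length (which can also be tested by passing `NULL` marks).
#'
#' @param peaks `GRanges` of peaks.
#' @param mark_peak_sets List of `GRanges` (merged-union defines covered
#'   bases), or `NULL` to regress on chromosome length itself.
#' @param genome A `GenomeModel`.
#' @param chroms Chromosomes entering the fit (default: autosomes, >= 3
#'   required).
#' @return List: slope, intercept, r_squared, and the per-chromosome
#'   data.frame.
#' @export
peaks_vs_marked_length <- function(peaks, mark_peak_sets, genome,
                                   chroms = NULL) {
  if (is.null(chroms)) chroms <- analysis_chroms(genome, "autosome")
  if (length(chroms) < 3L) stop("need >= 3 chromosomes for the fit")
  counts <- table(factor(as.character(GenomeInfoDb::seqnames(peaks)),
                         levels = chroms))
  covered <- if (is.null(mark_peak_sets)) {
    genome$chrom_lengths[chroms]
  } else {
    u <- merge_intervals(do.call(c, unname(lapply(mark_peak_sets,
                                                  GenomicRanges::granges))))
    vapply(chroms, function(ch)
      sum(GenomicRanges::width(
        u[as.character(GenomeInfoDb::seqnames(u)) == ch])), 0)
  }
  df <- data.frame(chrom = chroms, n_peaks = as.integer(counts),
                   covered_bp = as.numeric(covered))
  fit <- stats::lm(n_peaks ~ covered_bp, data = df)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       data = df)
}
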