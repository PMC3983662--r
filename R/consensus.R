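#' Keep combined peaks supported by a strict majority of replicates
#'
#' A peak called on reads pooled across replicates is retained only if it
#' overlaps (>= 1 bp) a peak in more than half of the individual replicate
#' sets. Ties at exactly half are excluded, so with two replicates both must
#' support the peak.
#'
#' @param combined `GRanges` of peaks called on the combined reads.
#' @param replicates List of `GRanges`, one peak set per replicate.
#' @return The supported subset of `combined`, with a `n_replicates_support`
#'   column.
#' @export
majority_replicate_filter <- function(combined, replicates) {
  if (length(replicates) == 0L) stop("need at least one replicate set")
  support <- Reduce(`+`, lapply(replicates, function(r)
    as.integer(interval_hits(combined, r)$a_hit)))
  combined$n_replicates_support <- support
  combined[support > length(replicates) / 2]
}

#' Bases covered by at least k of n peak sets
#'
#' The complex-level consensus: maximal runs of bases covered by peaks from
#' at least `k` of the `n` subunit peak sets, returned as merged intervals.
#' `k = 1` is the plain union; output is monotone decreasing in `k`.
#'
#' @param peaksets List of n `GRanges`.
#' @param k Minimum number of covering sets.
#' @param genome Optional `GenomeModel` fixing the coordinate universe
#'   (otherwise inferred from the sets' seqinfo / maximal coordinates).
#' @return `GRanges` of consensus intervals (unstranded, non-overlapping).
#' @export
consensus_k_of_n <- function(peaksets, k, genome = NULL) {
  n <- length(peaksets)
  if (k < 1L || k > n) stop("need 1 <= k <= number of peak sets")
  si <- if (!is.null(genome)) as_seqinfo(genome) else {
    # harmonized universe: union of levels, max observed end per level
    lev <- Reduce(union, lapply(peaksets, function(p)
      as.character(unique(GenomeInfoDb::seqnames(p)))))
    len <- vapply(lev, function(ch) max(unlist(lapply(peaksets, function(p) {
      e <- GenomicRanges::end(p)[as.character(
        GenomeInfoDb::seqnames(p)) == ch]
      if (length(e)) max(e) else 0L
    }))), 0)
    GenomeInfoDb::Seqinfo(lev, as.integer(len))
  }
  covs <- lapply(peaksets, function(p) {
    p <- merge_intervals(p)
    GenomeInfoDb::seqlevels(p) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(p) <- si
    GenomicRanges::coverage(p)
  })
  total <- Reduce(`+`, covs)
  out <- GenomicRanges::GRanges(IRanges::slice(total, lower = k,
                                               rangesOnly = TRUE),
                                seqinfo = si)
  sort_intervals(out)
}

#' Call summits: the base of maximal enrichment within each interval
#'
#' Ties are broken to the leftmost maximal base for determinism (an interval
#' of all-equal signal therefore gets its first base).
#'
#' @param intervals `GRanges` to summit.
#' @param track An enrichment `CoverageTrack` covering them.
#' @return A [peak_set()] with `summit` and `summit_score` filled in.
#' @export
call_summits <- function(intervals, track) {
  vals <- track_region_values(track, intervals)
  off <- vapply(vals, which.max, 0L)
  score <- vapply(seq_along(vals), function(i) vals[[i]][off[i]], 0)
  peak_set(intervals, summit = GenomicRanges::start(intervals) + off - 1L,
           summit_score = score)
}

#' Median summit height of a peak set
#'
#' The conventional minimum height for peak splitting: the median enrichment
#' over all summits of the data set.
#'
#' @param peaks A `GRanges` with `summit_score`.
#' @return A scalar.
#' @export
summit_median_height <- function(peaks) {
  stats::median(peaks$summit_score)
}

# Internal: positions (1-based, within v) of local maxima. A run of equal
# values is a maximum iff both flanking runs (or boundaries) are lower;
# plateaus contribute their leftmost base.
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1L], -Inf)
  starts[r$values > prev & r$values > nxt]
}

#' Split multi-summit peaks at sufficiently deep valleys
#'
#' Long peaks spanning several binding events are split so each event gets
#' its own summit. Within each peak, local maxima with height >=
#' `min_height` are found (conventionally `min_height` is the median summit
#' height of the data set, see [summit_median_height()]). Walking the
#' retained maxima left to right, the signal minimum between the current
#' sub-peak's maximum and the next retained maximum is a cut point iff the
#' valley value is below `separation_float` times the lower of the two
#' flanking maxima; otherwise the two maxima are merged into one sub-peak.
#' Peaks with fewer than two retained maxima are returned unsplit. Sub-peaks
#' partition the parent peak exactly (no bases gained or lost).
#'
#' @param peaks `GRanges` of peaks (any `summit` columns are recomputed).
#' @param track Enrichment `CoverageTrack`.
#' @param min_height Minimum height for a local maximum to seed a sub-peak.
#' @param separation_float Valley threshold fraction in (0, 1); default
#'   0.85.
#' @return A [peak_set()] of sub-peaks with a `parent` index column.
#' @export
split_peaks <- function(peaks, track, min_height,
                        separation_float = 0.85) {
  if (min_height <= 0) stop("min_height must be > 0")
  if (separation_float <= 0 || separation_float >= 1)
    stop("separation_float must lie in (0, 1)")
  vals <- track_region_values(track, peaks)
  ch <- as.character(GenomeInfoDb::seqnames(peaks))
  pstart <- GenomicRanges::start(peaks)
  out <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    v <- vals[[i]]
    cuts <- split_points(v, min_height, separation_float)
    bounds <- c(0L, cuts, length(v))   # sub-peak i spans (bounds[i], bounds[i+1]]
    n_sub <- length(bounds) - 1L
    s <- pstart[i] + utils::head(bounds, -1L)
    e <- pstart[i] + utils::tail(bounds, -1L) - 1L
    out[[i]] <- data.frame(chrom = ch[i], start = s, end = e, parent = i)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$parent <- df$parent
  si <- tryCatch(GenomeInfoDb::seqinfo(peaks), error = function(e) NULL)
  if (!is.null(si)) suppressWarnings({
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  })
  call_summits(gr, track)
}

# Internal: 0-based cut offsets within a peak's value vector.
split_points <- function(v, min_height, separation_float) {
  mx <- local_maxima(v)
  mx <- mx[v[mx] >= min_height]
  if (length(mx) < 2L) return(integer())
  cuts <- integer()
  cur_max <- mx[1L]               # position of current sub-peak's max
  for (j in 2:length(mx)) {
    nxt <- mx[j]
    seg <- v[cur_max:nxt]
    valley_rel <- which.min(seg)  # leftmost deepest valley
    valley_val <- seg[valley_rel]
    if (valley_val < separation_float * min(v[cur_max], v[nxt])) {
      # cut after the valley base: left sub-peak keeps the valley
      cuts <- c(cuts, cur_max + valley_rel - 1L)
      cur_max <- nxt
    } else if (v[nxt] > v[cur_max]) {
      cur_max <- nxt              # merged; track the taller summit
    }
  }
  cuts
}
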