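#' Normalize a track to its genome-wide median coverage
#'
#' Every base is divided by the genome-wide median of per-base coverage,
#' computed over all bases of the non-excluded chromosomes (the mitochondrial
#' chromosome is the usual exclusion). Division (rather than subtraction)
#' makes tracks from different sequencing depths comparable, so the later
#' input subtraction is meaningful. The median is computed over all bases,
#' zeros included; a zero median (degenerate, very sparse track) is an error.
#'
#' @param track A raw `CoverageTrack`.
#' @param chroms Optional subset of chromosomes over which to compute the
#'   median (default: all non-excluded chromosomes of the track's genome).
#' @return A `CoverageTrack` in state `median_normalized`; the divisor is
#'   recorded in the provenance.
#' @export
median_normalize <- function(track, chroms = NULL) {
  if (track$state != "raw")
    stop("median_normalize expects a raw track, got ", track$state)
  if (is.null(chroms)) chroms <- analysis_chroms(track$genome)
  med <- stats::median(track_concat(track, chroms))
  if (med == 0)
    stop("genome-wide median coverage is 0; track too sparse to normalize")
  track$values <- lapply(track$values, function(v) v / med)
  track$state <- "median_normalized"
  add_provenance(track, "median_normalize", median = med,
                 chroms = paste(chroms, collapse = ","))
}

#' Subtract matching input coverage from a ChIP track
#'
#' Per-base difference of two median-normalized tracks on the same genome.
#' Negative values are retained (not clipped): downstream statistics use
#' medians and means that are robust to them.
#'
#' @param chip_norm,input_norm Median-normalized `CoverageTrack`s.
#' @return A `CoverageTrack` in state `input_subtracted`.
#' @export
subtract_input <- function(chip_norm, input_norm) {
  for (t in list(chip_norm, input_norm))
    if (t$state != "median_normalized")
      stop("both tracks must be median_normalized, got ", t$state)
  if (!identical(chip_norm$genome$chrom_lengths,
                 input_norm$genome$chrom_lengths))
    stop("tracks are on different genomes")
  chip_norm$values <- Map(`-`, chip_norm$values, input_norm$values)
  chip_norm$state <- "input_subtracted"
  add_provenance(chip_norm, "subtract_input",
                 negatives_kept = sum(vapply(chip_norm$values,
                                             function(v) sum(v < 0), 0)))
}

#' Merge replicate tracks by per-base averaging
#'
#' @param tracks Non-empty list of `CoverageTrack`s in the same state on the
#'   same genome.
#' @return The per-base arithmetic mean track.
#' @export
merge_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks to merge")
  st <- unique(vapply(tracks, function(t) t$state, ""))
  if (length(st) != 1L)
    stop("tracks in mixed states: ", paste(st, collapse = ", "))
  out <- tracks[[1L]]
  for (ch in names(out$values)) {
    acc <- out$values[[ch]]
    for (t in tracks[-1L]) {
      if (!identical(t$genome$chrom_lengths, out$genome$chrom_lengths))
        stop("tracks are on different genomes")
      acc <- acc + t$values[[ch]]
    }
    out$values[[ch]] <- acc / length(tracks)
  }
  add_provenance(out, "merge_replicates", n = length(tracks))
}

#' Z-score standardization against the non-peak background
#'
#' Transforms every base to `(x - mu_bg) / sd_bg`, with the background mean
#' and standard deviation computed over all bases *not* covered by
#' `peak_regions` (the presumed background). This puts wild-type and mutant
#' tracks on a common scale before ratio comparisons.
#'
#' @param track An input-subtracted (or median-normalized) `CoverageTrack`.
#' @param peak_regions `GRanges` of regions excluded from the background
#'   (may be empty, giving an ordinary genome-wide z-score).
#' @return A `CoverageTrack` in state `zscored`.
#' @export
zscore_standardize <- function(track, peak_regions = NULL) {
  chroms <- analysis_chroms(track$genome)
  mask <- lapply(track$genome$chrom_lengths[chroms],
                 function(L) rep(TRUE, L))
  if (!is.null(peak_regions) && length(peak_regions)) {
    validate_on_genome(peak_regions, track$genome, "peak_regions")
    pr <- merge_intervals(peak_regions)
    ch <- as.character(GenomeInfoDb::seqnames(pr))
    s <- GenomicRanges::start(pr); e <- GenomicRanges::end(pr)
    for (i in seq_along(pr))
      if (ch[i] %in% chroms) mask[[ch[i]]][s[i]:e[i]] <- FALSE
  }
  bg <- unlist(Map(function(v, m) v[m], track$values[chroms], mask),
               use.names = FALSE)
  mu <- mean(bg)
  sd_bg <- stats::sd(bg)
  if (!is.finite(sd_bg) || sd_bg == 0)
    stop("background standard deviation is 0; cannot z-score")
  track$values <- lapply(track$values, function(v) (v - mu) / sd_bg)
  track$state <- "zscored"
  add_provenance(track, "zscore_standardize", mean = mu, sd = sd_bg,
                 n_background = length(bg))
}

#' Median-normalize the X chromosome and autosomes separately
#'
#' For samples where X-linked coverage is systematically shifted relative to
#' autosomes (e.g. dosage-compensation mutants with half the X reads), the
#' median divisor is computed separately for the X and for the autosomes and
#' the two normalized parts are recombined.
#'
#' @param track A raw `CoverageTrack` whose genome has `x_chrom` set.
#' @return A `median_normalized` `CoverageTrack`.
#' @export
split_process <- function(track) {
  genome <- track$genome
  if (is.null(genome$x_chrom))
    stop("genome has no X chromosome; use median_normalize")
  xc <- analysis_chroms(genome, "X")
  ac <- analysis_chroms(genome, "autosome")
  med_x <- stats::median(track_concat(track, xc))
  med_a <- stats::median(track_concat(track, ac))
  if (med_x == 0 || med_a == 0)
    stop("zero median in one compartment; track too sparse")
  for (ch in names(track$values)) {
    div <- if (ch %in% xc) med_x else med_a
    track$values[[ch]] <- track$values[[ch]] / div
  }
  track$state <- "median_normalized"
  add_provenance(track, "split_process", median_X = med_x,
                 median_autosome = med_a)
}

#' Running-mean smoothing of a track
#'
#' Centered running mean over `bandwidth` bases (odd; truncated at
#' chromosome ends). Per-base count noise produces spurious local maxima
#' inside peaks; smoothing at roughly the fragment scale (default 51 bp)
#' before summit calling and peak splitting restores one-summit-per-event
#' behavior. Fragment-pileup tracks from upstream peak callers are already
#' smooth at this scale.
#'
#' @param track A `CoverageTrack` (any state).
#' @param bandwidth Odd window size in bases.
#' @return The smoothed track (same state), with a provenance entry.
#' @export
smooth_track <- function(track, bandwidth = 51L) {
  bandwidth <- as.integer(bandwidth)
  if (bandwidth %% 2L == 0L) stop("bandwidth must be odd")
  half <- bandwidth %/% 2L
  track$values <- lapply(track$values, function(v) {
    L <- length(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(L)
    lo <- pmax(i - half, 1L); hi <- pmin(i + half, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  add_provenance(track, "smooth_track", bandwidth = bandwidth)
}

#' Mutant / wild-type enrichment ratios within regions
#'
#' For each region the ratio of mean enrichment (mutant over wild type) is
#' computed from two z-scored tracks; ratios are summarized per region class
#' (e.g. autosomal peaks vs X peaks with low or high recruiter occupancy).
#' Regions whose wild-type mean is not positive make the ratio meaningless
#' and are excluded (their count is reported).
#'
#' @param mutant,wildtype Z-scored `CoverageTrack`s on the same genome.
#' @param regions `GRanges` of regions (typically binding peaks).
#' @param classes Character vector of class labels, one per region
#'   (default: one class `"all"`).
#' @return A list with `ratios` (per-region data.frame: class, ratio,
#'   mean_mutant, mean_wildtype, excluded flag), `summary` (per-class
#'   quartiles of the ratio) and `n_excluded`.
#' @export
ratio_in_regions <- function(mutant, wildtype, regions, classes = NULL) {
  for (t in list(mutant, wildtype))
    if (t$state != "zscored")
      stop("ratio_in_regions expects z-scored tracks")
  if (is.null(classes)) classes <- rep("all", length(regions))
  stopifnot(length(classes) == length(regions))
  mm <- vapply(track_region_values(mutant, regions), mean, 0)
  mw <- vapply(track_region_values(wildtype, regions), mean, 0)
  excluded <- mw <= 0
  ratio <- ifelse(excluded, NA_real_, mm / mw)
  df <- data.frame(class = classes, ratio = ratio, mean_mutant = mm,
                   mean_wildtype = mw, excluded = excluded)
  ok <- df[!df$excluded, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok$ratio, ok$class), function(r)
    data.frame(n = length(r), q1 = stats::quantile(r, 0.25, names = FALSE),
               median = stats::median(r),
               q3 = stats::quantile(r, 0.75, names = FALSE))))
  summ$class <- rownames(summ); rownames(summ) <- NULL
  list(ratios = df, summary = summ[, c("class", "n", "q1", "median", "q3")],
       n_excluded = sum(excluded))
}
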