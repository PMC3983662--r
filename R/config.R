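#' Analysis configuration
#'
#' Collects the numeric parameters used across the pipeline. Defaults follow
#' the conventions of condensin ChIP-seq analysis in *C. elegans*:
#' 10,000-shuffle permutation null, +/-200 bp summit windows for overlap,
#' 1 kb promoters and 3' regions, 500 bp promoter-signal windows, 15 bp GC
#' sliding window, 1.5 kb summit heat-map windows in 50 bp bins, 1 kb
#' correlation windows, 250 bp classification windows, a 0.85 separation
#' float for peak splitting, and a 2-of-3 subunit consensus.
#'
#' @param n_permutations Number of random shuffles for permutation tests.
#' @param summit_window Half-width (bp) of the window around peak summits
#'   used for overlap statistics.
#' @param promoter_len Promoter / 3' region length (bp) for annotation
#'   overlap.
#' @param promoter_signal_len Upstream window (bp) for promoter signal
#'   vs expression analyses.
#' @param gc_window Sliding window (bp, odd) for per-base GC content.
#' @param heatmap_flank Flank (bp) on each side of an anchor for profile
#'   matrices (750 gives a 1.5 kb window).
#' @param heatmap_bin Bin size (bp) within profile windows.
#' @param corr_window Window (bp) for track correlation matrices.
#' @param ml_window Window (bp) for bound/unbound classification.
#' @param separation_float Valley-depth fraction for peak splitting,
#'   in (0, 1).
#' @param consensus_k Minimum number of subunit peak sets that must cover a
#'   base for it to enter the complex-level consensus.
#' @param min_overlap Minimum shared bases for two intervals to count as
#'   overlapping.
#' @param ncrna_cutoff Length cutoff (bp) separating short from long
#'   non-coding RNAs.
#' @param rng_seed Integer seed recorded with results.
#' @return A list of class `AnalysisConfig`.
#' @export
analysis_config <- function(n_permutations = 10000L,
                            summit_window = 200L,
                            promoter_len = 1000L,
                            promoter_signal_len = 500L,
                            gc_window = 15L,
                            heatmap_flank = 750L,
                            heatmap_bin = 50L,
                            corr_window = 1000L,
                            ml_window = 250L,
                            separation_float = 0.85,
                            consensus_k = 2L,
                            min_overlap = 1L,
                            ncrna_cutoff = 200L,
                            rng_seed = 1L) {
  cfg <- list(n_permutations = as.integer(n_permutations),
              summit_window = as.integer(summit_window),
              promoter_len = as.integer(promoter_len),
              promoter_signal_len = as.integer(promoter_signal_len),
              gc_window = as.integer(gc_window),
              heatmap_flank = as.integer(heatmap_flank),
              heatmap_bin = as.integer(heatmap_bin),
              corr_window = as.integer(corr_window),
              ml_window = as.integer(ml_window),
              separation_float = separation_float,
              consensus_k = as.integer(consensus_k),
              min_overlap = as.integer(min_overlap),
              ncrna_cutoff = as.integer(ncrna_cutoff),
              rng_seed = as.integer(rng_seed))
  winders <- c("summit_window", "promoter_len", "promoter_signal_len",
               "gc_window", "heatmap_flank", "heatmap_bin", "corr_window",
               "ml_window", "ncrna_cutoff")
  if (any(unlist(cfg[winders]) <= 0)) stop("all windows must be > 0")
  if (cfg$gc_window %% 2L == 0L) stop("gc_window must be odd")
  if (cfg$separation_float <= 0 || cfg$separation_float >= 1)
    stop("separation_float must lie in (0, 1)")
  if (cfg$n_permutations < 1L) stop("n_permutations must be >= 1")
  if (cfg$min_overlap < 1L) stop("min_overlap must be >= 1")
  class(cfg) <- "AnalysisConfig"
  cfg
}
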