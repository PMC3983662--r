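#' Window-level feature matrix from coverage tracks
#'
#' Tiles the genome into contiguous windows (1 kb for correlation analyses,
#' 250 bp for classification) and records the median per-base signal of
#' every track in every window. Motif presence or other per-window vectors
#' can be bound on afterwards.
#'
#' @param tracks Named list of `CoverageTrack`s on the same genome.
#' @param genome A `GenomeModel`.
#' @param window Window size in bp (last partial window per chromosome is
#'   kept).
#' @param chroms Chromosomes to tile (default non-excluded).
#' @return A `FeatureMatrix`: list with `windows` (`GRanges`), `features`
#'   (windows x tracks matrix of medians), `window_size`.
#' @export
window_feature_matrix <- function(tracks, genome, window = 1000L,
                                  chroms = NULL) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list")
  tiles <- tile_genome_windows(genome, window, chroms)
  chrom_order <- unique(as.character(GenomeInfoDb::seqnames(tiles)))
  feat <- vapply(tracks, function(t) {
    unlist(lapply(chrom_order, function(ch) {
      v <- t$values[[ch]]
      wi <- (seq_along(v) - 1L) %/% as.integer(window)
      vapply(split(v, factor(wi, levels = unique(wi))), stats::median, 0,
             USE.NAMES = FALSE)
    }), use.names = FALSE)
  }, numeric(length(tiles)))
  structure(list(windows = tiles, features = feat,
                 window_size = as.integer(window)),
            class = "FeatureMatrix")
}

#' Pearson correlation matrix with hierarchical leaf order
#'
#' Pairwise Pearson correlation of the feature columns over windows,
#' clustered on the distance `1 - r` (average linkage by default, the
#' unstated-convention default; exposed). Tracks simulated from the same
#' underlying binding truth should cluster together.
#'
#' @param x A `FeatureMatrix` or plain numeric matrix (columns = tracks).
#' @param linkage Linkage method for [stats::hclust()].
#' @return List: `cor` (correlation matrix), `order` (leaf order),
#'   `labels_ordered`, `hclust`.
#' @export
correlation_heatmap_order <- function(x, linkage = "average") {
  m <- if (methods::is(x, "FeatureMatrix")) x$features else as.matrix(x)
  if (ncol(m) < 2L) stop("need >= 2 feature columns")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant feature column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  list(cor = r, order = hc$order, labels_ordered = colnames(m)[hc$order],
       hclust = hc)
}

#' Label genomic windows as bound / unbound
#'
#' @param genome A `GenomeModel`.
#' @param peaks `GRanges` of consensus peaks.
#' @param window Window size in bp (250 by convention for classification).
#' @param chroms Chromosomes to tile.
#' @return List: `windows` (`GRanges`), `bound` (logical per window).
#' @export
label_windows <- function(genome, peaks, window = 250L, chroms = NULL) {
  tiles <- tile_genome_windows(genome, window, chroms)
  list(windows = tiles, bound = interval_hits(tiles, peaks)$a_hit)
}

#' Logistic-regression classifier contract
#'
#' The default fit/predict pair for [permutation_importance()]. Any list
#' with a `fit(x, y)` returning a model and a `predict(model, x)` returning
#' predicted logical labels satisfies the contract -- a random forest (the
#' classical choice, an ensemble of 10,000 trees) plugs in the same way
#' when such a library is available.
#'
#' @return A classifier contract list.
#' @export
classifier_logistic <- function() {
  list(
    name = "logistic_regression",
    fit = function(x, y) {
      df <- data.frame(x)
      df$.y <- as.numeric(y)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    predict = function(model, x) {
      suppressWarnings(
        stats::predict(model, newdata = data.frame(x),
                       type = "response")) > 0.5
    })
}

#' Permutation feature importance (mean decrease in accuracy)
#'
#' Fits the classifier on a stratified train split and measures, on the
#' held-out windows, how much accuracy drops when each feature's values are
#' permuted -- the mean decrease in accuracy, averaged over `n_repeats`
#' permutations. Features are ranked by it, most discriminative first.
#' (The out-of-bag variant used with bagged ensembles is a drop-in
#' alternative; held-out is the package default.)
#'
#' @param features Numeric matrix (windows x named features).
#' @param labels Logical (or two-level) vector of window labels.
#' @param classifier A contract from [classifier_logistic()] or compatible.
#' @param n_repeats Permutations per feature.
#' @param train_frac Fraction of windows in the stratified training split.
#' @param seed Integer seed (split and permutations).
#' @return data.frame (feature, mean_decrease, sd, rank), ordered by rank;
#'   attributes `baseline_accuracy` and `seed`.
#' @export
permutation_importance <- function(features, labels,
                                   classifier = classifier_logistic(),
                                   n_repeats = 10L, train_frac = 0.7,
                                   seed = 1L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%d", seq_len(ncol(features)))
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  with_seed(seed, {
    # stratified split: preserve class balance in train and test
    idx_pos <- sample(which(y)); idx_neg <- sample(which(!y))
    tr <- c(idx_pos[seq_len(floor(train_frac * length(idx_pos)))],
            idx_neg[seq_len(floor(train_frac * length(idx_neg)))])
    te <- setdiff(seq_along(y), tr)
    model <- classifier$fit(features[tr, , drop = FALSE], y[tr])
    baseline <- mean(classifier$predict(
      model, features[te, , drop = FALSE]) == y[te])
    dec <- matrix(NA_real_, n_repeats, ncol(features))
    for (j in seq_len(ncol(features))) {
      for (r in seq_len(n_repeats)) {
        xp <- features[te, , drop = FALSE]
        xp[, j] <- xp[sample(length(te)), j]
        dec[r, j] <- baseline - mean(classifier$predict(model, xp) == y[te])
      }
    }
    out <- data.frame(feature = colnames(features),
                      mean_decrease = colMeans(dec),
                      sd = apply(dec, 2L, stats::sd))
    out <- out[order(-out$mean_decrease), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "baseline_accuracy") <- baseline
    attr(out, "seed") <- seed
    out
  })
}
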