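#' Position weight matrices
#'
#' A PWM is a 4 x width matrix of per-position base probabilities (rows
#' A, C, G, T) with background base frequencies; scanning scores a window by
#' its log2 odds `sum(log2(p_j(base) / bg(base)))`.
#'
#' @param probs 4 x width numeric matrix, rows named A, C, G, T, columns
#'   summing to 1.
#' @param background Named numeric vector of background base frequencies
#'   (default uniform).
#' @return An object of class `pwm_model`.
#' @export
pwm_model <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25,
                                            T = 0.25)) {
  probs <- as.matrix(probs)
  if (!identical(rownames(probs), c("A", "C", "G", "T")))
    stop("probs rows must be named A, C, G, T")
  if (ncol(probs) < 4L) stop("motif width must be >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop("columns must sum to 1 (apply a pseudocount first)")
  background <- background[c("A", "C", "G", "T")] / sum(background)
  structure(list(probs = probs, background = background,
                 width = ncol(probs)), class = "pwm_model")
}

#' @rdname pwm_model
#' @param consensus Consensus string (e.g. a GCGC-core motif such as
#'   `"AGGGGCGCGC"`); IUPAC codes are not supported, only ACGT.
#' @param strength Probability mass on the consensus base at each position.
#' @export
pwm_from_consensus <- function(consensus,
                               strength = 0.85,
                               background = c(A = 0.25, C = 0.25, G = 0.25,
                                              T = 0.25)) {
  b <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(b %in% c("A", "C", "G", "T"))) stop("consensus must be ACGT only")
  probs <- matrix((1 - strength) / 3, 4L, length(b),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) probs[b[j], j] <- strength
  pwm_model(probs, background)
}

#' @rdname pwm_model
#' @param sequences Character vector of equal-length hit sequences.
#' @param pseudocount Added per base per position before normalizing
#'   (default 0.25).
#' @export
pwm_from_sequences <- function(sequences, pseudocount = 0.25,
                               background = c(A = 0.25, C = 0.25, G = 0.25,
                                              T = 0.25)) {
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  counts <- apply(m, 2L, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))))
  probs <- sweep(counts + pseudocount, 2L, colSums(counts) +
                   4 * pseudocount, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  pwm_model(probs, background)
}

#' Read / write a PWM as a simple tab-delimited matrix
#'
#' Four rows labeled A, C, G, T; one column per motif position; values are
#' base probabilities. A comment line `# background: a c g t` carries the
#' background frequencies.
#'
#' @param path File path.
#' @return `read_pwm` returns a `pwm_model`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^# background:", lines, value = TRUE)
  if (length(bgl))
    bg <- stats::setNames(as.numeric(strsplit(sub("^# background:\\s*", "",
                                                  bgl[1L]), "\\s+")[[1L]]),
                          c("A", "C", "G", "T"))
  m <- utils::read.table(text = lines[!startsWith(lines, "#")],
                         row.names = 1)
  probs <- as.matrix(m)
  colnames(probs) <- NULL
  pwm_model(probs[c("A", "C", "G", "T"), , drop = FALSE], bg)
}

#' @rdname read_pwm
#' @param pwm A `pwm_model` to write.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# background:",
                   paste(sprintf("%.6g", pwm$background), collapse = " ")),
             con)
  utils::write.table(format(pwm$probs, digits = 6), con, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pwm_model <- function(x, ...) {
  cons <- paste(rownames(x$probs)[apply(x$probs, 2L, which.max)],
                collapse = "")
  cat(sprintf("pwm_model: width %d, consensus %s, max log-odds %.2f\n",
              x$width, cons, max_logodds(x)))
  invisible(x)
}

# Internal: log2-odds matrix with a 5th row for non-ACGT bases (-Inf).
logodds_matrix <- function(pwm) {
  lom <- log2(pwm$probs / pwm$background)
  rbind(lom, N = rep(-Inf, ncol(lom)))
}

#' Maximal attainable log-odds score of a PWM
#' @param pwm A `pwm_model`.
#' @export
max_logodds <- function(pwm) sum(apply(log2(pwm$probs / pwm$background),
                                       2L, max))

# Internal: reverse complement of a PWM.
revcomp_pwm <- function(pwm) {
  probs <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)),
                     drop = FALSE]
  rownames(probs) <- c("A", "C", "G", "T")
  pwm_model(probs, pwm$background)
}

#' Scan a genome for PWM hits on both strands
#'
#' Every position (either strand) whose log2-odds score reaches the
#' threshold is reported; overlapping hits are retained. The default
#' threshold is 80% of the maximal attainable log-odds score.
#'
#' @param pwm A `pwm_model`.
#' @param sequences Named character vector / `DNAStringSet` per chromosome.
#' @param genome A `GenomeModel`.
#' @param threshold Log2-odds threshold (default `0.8 * max_logodds(pwm)`).
#' @param chroms Chromosomes to scan (default: non-excluded).
#' @return `GRanges` of hits with `score` (log-odds) and strand; minus
#'   strand means the motif matches the reverse complement at that locus.
#' @export
scan_pwm <- function(pwm, sequences, genome, threshold = NULL,
                     chroms = NULL) {
  if (is.null(threshold)) threshold <- 0.8 * max_logodds(pwm)
  if (is.null(chroms)) chroms <- analysis_chroms(genome)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  fwd <- logodds_matrix(pwm)
  rev_ <- logodds_matrix(revcomp_pwm(pwm))
  w <- pwm$width
  res <- list()
  for (ch in chroms) {
    code <- match(strsplit(toupper(sequences[[ch]]), "")[[1L]],
                  c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L
    L <- length(code)
    if (L < w) next
    n_pos <- L - w + 1L
    sf <- numeric(n_pos); sr <- numeric(n_pos)
    for (j in seq_len(w)) {
      cj <- code[j:(j + n_pos - 1L)]
      sf <- sf + fwd[cbind(cj, j)]
      sr <- sr + rev_[cbind(cj, j)]
    }
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sf else sr
      at <- which(sc >= threshold)
      if (length(at))
        res[[paste0(ch, strand)]] <- data.frame(
          chrom = ch, start = at, score = sc[at], strand = strand)
    }
  }
  if (!length(res))
    return(GenomicRanges::GRanges(seqinfo = as_seqinfo(genome)))
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = w),
                               strand = df$strand, score = df$score,
                               seqinfo = as_seqinfo(genome))
  sort_intervals(gr)
}

#' Fraction of motif hits bound by the complex
#'
#' @param motif_hits `GRanges` of motif occurrences.
#' @param peaks `GRanges` of binding peaks (or summit windows).
#' @param min_overlap Minimum shared bases.
#' @return Fraction of hits intersecting any peak.
#' @export
motif_bound_fraction <- function(motif_hits, peaks, min_overlap = 1L) {
  if (length(motif_hits) == 0L) stop("no motif hits")
  mean(interval_hits(motif_hits, peaks, min_overlap)$a_hit)
}

#' Bound fraction of motifs conditioned on chromatin context
#'
#' Restricts [motif_bound_fraction()] to motif hits lying inside windows
#' flagged as enriched for an (active) chromatin mark, reported alongside
#' the unconditioned fraction -- the comparison asking whether open
#' chromatin context raises the usage of a motif (e.g. from 11% to 29%).
#'
#' @param motif_hits `GRanges` of motif occurrences.
#' @param peaks `GRanges` of binding peaks.
#' @param mark_windows `GRanges` of mark-enriched windows (e.g. 2 kb).
#' @return List: `fraction_in_marked`, `fraction_all`, `n_hits_in_marked`,
#'   `n_hits`. `fraction_in_marked` is `NA` (flagged) if no hit falls in a
#'   marked window.
#' @export
context_conditioned_fraction <- function(motif_hits, peaks, mark_windows) {
  inside <- interval_hits(motif_hits, mark_windows)$a_hit
  all_frac <- motif_bound_fraction(motif_hits, peaks)
  list(fraction_in_marked = if (any(inside))
         motif_bound_fraction(motif_hits[inside], peaks) else NA_real_,
       fraction_all = all_frac,
       n_hits_in_marked = sum(inside), n_hits = length(motif_hits))
}

#' Tile the genome into contiguous fixed-size windows
#'
#' @param genome A `GenomeModel`.
#' @param window Window size in bp; the last (partial) window of each
#'   chromosome is kept.
#' @param chroms Chromosomes to tile (default non-excluded).
#' @return `GRanges` of windows in genome order.
#' @export
tile_genome_windows <- function(genome, window, chroms = NULL) {
  if (is.null(chroms)) chroms <- analysis_chroms(genome)
  sl <- genome$chrom_lengths[chroms]
  gr <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(window),
                                  cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqlevels(gr) <- chrom_names(genome)
  GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  gr
}

#' Motif clustering effect on binding
#'
#' Tiles the genome into non-overlapping windows (1 kb by convention),
#' assigns each motif hit to the window containing its midpoint, and
#' compares the probability of being bound (window intersects a peak)
#' between windows with more than one motif and windows with exactly one.
#'
#' @param motif_hits `GRanges` of motif occurrences.
#' @param peaks `GRanges` of binding peaks.
#' @param genome A `GenomeModel`.
#' @param window Window size in bp.
#' @return List: `fold` = P(bound | >=2 motifs) / P(bound | exactly 1),
#'   the two probabilities, and window counts.
#' @export
clustering_effect <- function(motif_hits, peaks, genome, window = 1000L) {
  tiles <- tile_genome_windows(genome, window)
  mid <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(motif_hits),
    IRanges::IRanges(GenomicRanges::start(motif_hits) +
                       GenomicRanges::width(motif_hits) %/% 2L, width = 1L))
  n_motifs <- GenomicRanges::countOverlaps(tiles, mid, ignore.strand = TRUE)
  bound <- interval_hits(tiles, peaks)$a_hit
  single <- n_motifs == 1L
  multi <- n_motifs >= 2L
  if (!any(single)) stop("no single-motif windows; fold undefined")
  p1 <- mean(bound[single])
  p2 <- if (any(multi)) mean(bound[multi]) else NA_real_
  list(fold = p2 / p1, p_bound_multi = p2, p_bound_single = p1,
       n_single = sum(single), n_multi = sum(multi),
       n_windows = length(tiles))
}
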