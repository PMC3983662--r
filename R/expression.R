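#' Expression tables
#'
#' An expression table holds per-gene replicate FPKM-like values and their
#' median (the per-gene summary used throughout). `read_expression_table` /
#' `write_expression_table` use a plain TSV with columns `gene`,
#' `rep1..repN`, `median`.
#'
#' @param gene Character vector of gene ids.
#' @param reps Numeric matrix, one row per gene, one column per replicate.
#' @return data.frame of class `ExpressionTable` with the median column
#'   recomputed from the replicates.
#' @export
expression_table <- function(gene, reps) {
  reps <- as.matrix(reps)
  stopifnot(length(gene) == nrow(reps))
  df <- data.frame(gene = as.character(gene), reps)
  names(df)[-1L] <- sprintf("rep%d", seq_len(ncol(reps)))
  df$median <- apply(reps, 1L, stats::median)
  class(df) <- c("ExpressionTable", "data.frame")
  df
}

#' @rdname expression_table
#' @param path File path.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  reps <- as.matrix(df[grep("^rep", names(df))])
  expression_table(df$gene, reps)
}

#' @rdname expression_table
#' @param x An `ExpressionTable`.
#' @export
write_expression_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median expression as a named vector
#' @param x An `ExpressionTable`.
#' @export
expression_medians <- function(x) stats::setNames(x$median, x$gene)

#' Median enrichment in the promoter window of each gene
#'
#' The median of per-base enrichment over the strand-aware window `upstream`
#' bp upstream of the TSS (500 bp by convention for binding-vs-expression
#' analyses). Genes whose window falls entirely off the chromosome are
#' skipped.
#'
#' @param track A `CoverageTrack`.
#' @param genes Stranded `GRanges` with a `name` column.
#' @param genome A `GenomeModel`.
#' @param upstream Window length in bp.
#' @return Named numeric vector (gene -> median enrichment).
#' @export
promoter_signal <- function(track, genes, genome, upstream = 500L) {
  prom <- derive_promoters(GenomicRanges::granges(genes, use.mcols = FALSE),
                           genome, upstream)
  vals <- track_region_values(track, prom)
  med <- vapply(vals, stats::median, 0)
  nm <- if (!is.null(genes$name)) genes$name else as.character(seq_along(genes))
  stats::setNames(med, nm[prom$source_idx])
}

#' Spearman correlation between promoter binding and expression
#'
#' @param prom_signal Named numeric vector from [promoter_signal()].
#' @param expression Named numeric vector of expression values.
#' @param genes Optional `GRanges` (with `name`) used to restrict scope.
#' @param genome Needed when `scope != "genome"`.
#' @param scope `"genome"`, `"X"` or `"autosome"`.
#' @return Spearman's rho over the genes present in both vectors.
#' @export
binding_expression_correlation <- function(prom_signal, expression,
                                           genes = NULL, genome = NULL,
                                           scope = c("genome", "X",
                                                     "autosome")) {
  scope <- match.arg(scope)
  common <- intersect(names(prom_signal), names(expression))
  if (scope != "genome") {
    if (is.null(genes) || is.null(genome))
      stop("genes and genome required for scoped correlation")
    keep <- genes$name[as.character(GenomeInfoDb::seqnames(genes)) %in%
                         analysis_chroms(genome, scope)]
    common <- intersect(common, keep)
  }
  if (length(common) < 10L) stop("need >= 10 genes in scope")
  x <- prom_signal[common]; y <- expression[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector; correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Flag genes with a binding site near the TSS
#'
#' A gene is bound iff any peak summit window overlaps the window of
#' `window` bp around its TSS (symmetric by default; `upstream_only = TRUE`
#' restricts to the upstream side).
#'
#' @param genes Stranded `GRanges` with `name`.
#' @param peaks `GRanges` with summits.
#' @param genome A `GenomeModel`.
#' @param window Distance cutoff in bp (default 1 kb).
#' @param summit_halfwidth Half-width of the peak summit window (0 uses the
#'   bare summit position).
#' @param upstream_only Use only the upstream side of the TSS.
#' @return Named logical vector (gene -> bound).
#' @export
classify_bound_genes <- function(genes, peaks, genome, window = 1000L,
                                 summit_halfwidth = 0L,
                                 upstream_only = FALSE) {
  pos <- tss_positions(genes)
  neg <- as.character(GenomicRanges::strand(genes)) == "-"
  lo <- pos - window
  hi <- pos + window
  if (upstream_only) {
    hi[!neg] <- pos[!neg]
    lo[neg] <- pos[neg]
  }
  tssw <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                 IRanges::IRanges(pmax(1L, lo), hi))
  tssw <- clamp_to_genome(tssw, genome)
  pw <- if (summit_halfwidth > 0L)
    summit_windows(peaks, genome, summit_halfwidth)
  else if (!is.null(peaks$summit))
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                           IRanges::IRanges(peaks$summit, width = 1L))
  else peaks
  hit <- interval_hits(tssw, pw)$a_hit
  nm <- if (!is.null(genes$name)) genes$name else as.character(seq_along(genes))
  stats::setNames(hit, nm)
}

#' Differential expression by binding contingency table
#'
#' Cross-tabulates differentially expressed genes by binding status and
#' direction of change, with row percentages -- the summary asking whether
#' the direct effect of binding is repressive (bound DE genes mostly up on
#' loss of the complex) or activating.
#'
#' @param de_genes data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`, or a numeric `lfc` whose sign is used).
#' @param bound_flags Named logical vector from [classify_bound_genes()].
#' @return List: `counts` (2x2 matrix bound/unbound x up/down),
#'   `row_percent`, `n_de`.
#' @export
de_binding_table <- function(de_genes, bound_flags) {
  if (nrow(de_genes) == 0L) stop("empty DE gene list")
  dir <- if (!is.null(de_genes$direction)) as.character(de_genes$direction)
         else if (!is.null(de_genes$lfc))
           ifelse(de_genes$lfc > 0, "up", "down")
         else stop("need a direction or lfc column")
  bound <- bound_flags[de_genes$gene]
  bound[is.na(bound)] <- FALSE
  counts <- table(factor(ifelse(bound, "bound", "unbound"),
                         levels = c("bound", "unbound")),
                  factor(dir, levels = c("up", "down")))
  row_percent <- 100 * prop.table(counts, margin = 1L)
  list(counts = unclass(counts), row_percent = unclass(row_percent),
       n_de = nrow(de_genes))
}
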