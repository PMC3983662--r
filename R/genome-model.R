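#' Genome model: the coordinate universe for all analyses
#'
#' A `GenomeModel` records chromosome names and lengths, which chromosome is
#' the X (needed for X/autosome split processing and X-restricted statistics),
#' and which chromosomes are excluded from genome-wide statistics (typically
#' the mitochondrial chromosome).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param x_chrom Name of the X chromosome, or `NULL` if not applicable.
#' @param excluded_chroms Character vector of chromosomes dropped from
#'   genome-wide statistics (e.g. `"chrM"`). Must be a subset of the names of
#'   `chrom_lengths`.
#' @return An object of class `GenomeModel`.
#' @examples
#' gm <- genome_model(c(chrI = 1e5, chrX = 1e5, chrM = 15000),
#'                    x_chrom = "chrX", excluded_chroms = "chrM")
#' analysis_chroms(gm)
#' @export
genome_model <- function(chrom_lengths, x_chrom = NULL,
                         excluded_chroms = character()) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a fully named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be finite and > 0")
  nm <- names(chrom_lengths)
  if (!is.null(x_chrom) && !x_chrom %in% nm)
    stop("x_chrom '", x_chrom, "' not among chromosome names")
  if (!all(excluded_chroms %in% nm))
    stop("excluded_chroms must be a subset of chromosome names")
  structure(
    list(chrom_lengths = round(as.numeric(chrom_lengths)) |>
           stats::setNames(nm),
         x_chrom = x_chrom,
         excluded_chroms = as.character(excluded_chroms)),
    class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosomes, %.1f Mb total\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  if (!is.null(x$x_chrom)) cat("  X chromosome:", x$x_chrom, "\n")
  if (length(x$excluded_chroms))
    cat("  excluded:", paste(x$excluded_chroms, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genome_model
#' @param genome A `GenomeModel`.
#' @export
chrom_names <- function(genome) names(genome$chrom_lengths)

#' Chromosomes that enter genome-wide statistics
#'
#' Non-excluded chromosome names, optionally restricted to the X or to
#' autosomes.
#'
#' @param genome A `GenomeModel`.
#' @param scope One of `"genome"` (all non-excluded), `"X"`, `"autosome"`.
#' @return Character vector of chromosome names.
#' @export
analysis_chroms <- function(genome, scope = c("genome", "X", "autosome")) {
  scope <- match.arg(scope)
  nm <- setdiff(chrom_names(genome), genome$excluded_chroms)
  switch(scope,
    genome = nm,
    X = intersect(nm, genome$x_chrom),
    autosome = setdiff(nm, genome$x_chrom))
}

#' Convert a GenomeModel to a Seqinfo
#'
#' @param genome A `GenomeModel`.
#' @return A [GenomeInfoDb::Seqinfo] used to annotate `GRanges` produced by
#'   the package, so out-of-bounds ranges are caught by the Bioconductor
#'   machinery.
#' @export
as_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = chrom_names(genome),
                        seqlengths = as.integer(genome$chrom_lengths))
}

#' Read / write a two-column chromosome-sizes table
#'
#' The standard `chrom.sizes` format: chromosome name, TAB, length.
#'
#' @param path File path.
#' @param x_chrom,excluded_chroms Passed to [genome_model()].
#' @return `read_chrom_sizes` returns a `GenomeModel`.
#' @export
read_chrom_sizes <- function(path, x_chrom = NULL,
                             excluded_chroms = character()) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_model(stats::setNames(df$length, df$chrom), x_chrom = x_chrom,
               excluded_chroms = excluded_chroms)
}

#' @rdname read_chrom_sizes
#' @param genome A `GenomeModel` to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = chrom_names(genome),
               length = format(genome$chrom_lengths, scientific = FALSE,
                               trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: check that a GRanges lives on the genome (names + bounds).
validate_on_genome <- function(gr, genome, what = "ranges") {
  bad <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                 chrom_names(genome))
  if (length(bad))
    stop(what, " on chromosomes absent from the GenomeModel: ",
         paste(bad, collapse = ", "))
  len <- genome$chrom_lengths[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(GenomicRanges::start(gr) < 1) || any(GenomicRanges::end(gr) > len))
    stop(what, " extend beyond chromosome bounds")
  invisible(TRUE)
}
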