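#' Peak sets: intervals with summits
#'
#' Peaks are plain `GRanges` carrying two required metadata columns:
#' `summit` (absolute 1-based position of the base with maximal enrichment)
#' and `summit_score` (the enrichment value there). `peak_set()` builds and
#' validates one; most peak-consuming functions accept any `GRanges` with
#' these columns.
#'
#' @param gr A `GRanges`.
#' @param summit Absolute summit positions (default: interval midpoints).
#' @param summit_score Numeric score at each summit (default `NA`).
#' @return A validated `GRanges` with `summit` and `summit_score` columns.
#' @export
peak_set <- function(gr, summit = NULL, summit_score = NULL) {
  if (is.null(summit))
    summit <- GenomicRanges::start(gr) +
      (GenomicRanges::width(gr) - 1L) %/% 2L
  if (is.null(summit_score)) summit_score <- rep(NA_real_, length(gr))
  if (any(summit < GenomicRanges::start(gr)) ||
      any(summit > GenomicRanges::end(gr)))
    stop("summits must lie within their peaks")
  gr$summit <- as.integer(summit)
  gr$summit_score <- as.numeric(summit_score)
  sort_intervals(gr)
}

# Internal: deterministic (chrom, start) order with lexicographic chromosomes.
sort_intervals <- function(gr) {
  o <- order(as.character(GenomeInfoDb::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Read intervals from BED or GFF3
#'
#' BED is natively 0-based half-open and GFF3 1-based closed; both are
#' converted by \pkg{rtracklayer} to the package-internal `GRanges`
#' convention. Records on chromosomes absent from the `GenomeModel` are a
#' validation error. For BED files whose name column carries a
#' `";summit=<offset>"` tag (written by [write_intervals()] for peak sets)
#' the summit is decoded back to an absolute position.
#'
#' @param path File path.
#' @param genome A `GenomeModel`.
#' @param format `"auto"` (by extension), `"BED"` or `"GFF"`.
#' @return A `GRanges` with seqinfo from `genome`.
#' @export
read_intervals <- function(path, genome, format = c("auto", "BED", "GFF")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3", "gtf")) "GFF" else "BED"
  }
  gr <- switch(format,
    BED = rtracklayer::import(path, format = "bed"),
    GFF = rtracklayer::import(path, format = "gff3"))
  validate_on_genome(gr, genome, basename(path))
  GenomeInfoDb::seqlevels(gr) <- chrom_names(genome)
  GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  if (format == "BED" && !is.null(gr$name) &&
      any(grepl(";summit=", gr$name, fixed = TRUE))) {
    off <- suppressWarnings(
      as.integer(sub("^.*;summit=(\\d+).*$", "\\1", gr$name)))
    gr$summit <- GenomicRanges::start(gr) + off
    gr$summit_score <- if (!is.null(gr$score)) as.numeric(gr$score)
                       else rep(NA_real_, length(gr))
    gr$name <- sub(";summit=\\d+", "", gr$name)
  }
  sort_intervals(gr)
}

#' Write intervals as BED
#'
#' Emits BED3 or BED6; when the ranges carry `summit`/`summit_score`
#' columns, the 0-based summit offset is appended to the name as
#' `";summit=<offset>"` and the summit score becomes the BED score, so peak
#' sets round-trip bit-exactly through [read_intervals()].
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_intervals <- function(gr, path) {
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  n <- length(gr)
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("iv%d", seq_len(n))
  has_summit <- !is.null(gr$summit)
  if (has_summit)
    nm <- sprintf("%s;summit=%d", nm, gr$summit - GenomicRanges::start(gr))
  score <- if (has_summit && !is.null(gr$summit_score)) gr$summit_score
           else if (!is.null(gr$score)) as.numeric(gr$score)
           else rep(0, n)
  score[!is.finite(score)] <- 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%s", chrom, start0, end, nm,
                   score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Flag and pair overlapping intervals
#'
#' Strand-blind overlap with a minimum-shared-bases threshold; the workhorse
#' behind every overlap statistic in the package.
#'
#' @param a,b `GRanges` on the same genome.
#' @param min_overlap Minimum number of shared bases (>= 1).
#' @return A list with `pairs` (data.frame of index pairs), logical vectors
#'   `a_hit`, `b_hit`, and counts `n_a_hit`, `n_b_hit`.
#' @export
interval_hits <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  ov <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  a_hit <- rep(FALSE, length(a)); a_hit[S4Vectors::queryHits(ov)] <- TRUE
  b_hit <- rep(FALSE, length(b)); b_hit[S4Vectors::subjectHits(ov)] <- TRUE
  list(pairs = data.frame(a = S4Vectors::queryHits(ov),
                          b = S4Vectors::subjectHits(ov)),
       a_hit = a_hit, b_hit = b_hit,
       n_a_hit = sum(a_hit), n_b_hit = sum(b_hit))
}

#' Annotation sets: stranded gene-like records with a class label
#'
#' Assigns the record class used by the overlap analyses: `gene`, `tRNA`,
#' and non-coding RNAs split into `ncRNA_short` / `ncRNA_long` at a length
#' cutoff (200 bp by default).
#'
#' @param gr Stranded `GRanges`; a `type` metadata column (values `gene`,
#'   `tRNA`, `ncRNA`, or already-final classes) drives the labeling, with
#'   everything unlabeled treated as `gene`.
#' @param ncrna_cutoff Length (bp) at or below which an ncRNA is short.
#' @return The `GRanges` with a `class` column.
#' @export
as_annotation_set <- function(gr, ncrna_cutoff = 200L) {
  type <- if (!is.null(gr$class)) as.character(gr$class)
          else if (!is.null(gr$type)) as.character(gr$type)
          else rep("gene", length(gr))
  type[type %in% c("protein_coding_gene", "mRNA", "coding")] <- "gene"
  is_nc <- type == "ncRNA"
  type[is_nc & GenomicRanges::width(gr) <= ncrna_cutoff] <- "ncRNA_short"
  type[is_nc & GenomicRanges::width(gr) > ncrna_cutoff] <- "ncRNA_long"
  ok <- c("gene", "tRNA", "ncRNA_short", "ncRNA_long")
  if (!all(type %in% ok))
    stop("unknown annotation classes: ",
         paste(setdiff(unique(type), ok), collapse = ", "))
  gr$class <- type
  gr
}

#' Collapse transcript-level records to one record per gene
#'
#' For genes with multiple transcripts the gene coordinates are the outmost
#' coordinates of all its transcripts.
#'
#' @param gr Transcript-level `GRanges` with a `gene_id` (or `Parent`/`name`)
#'   column.
#' @return One range per gene, named by gene id.
#' @export
collapse_transcripts <- function(gr) {
  id <- if (!is.null(gr$gene_id)) as.character(gr$gene_id)
        else if (!is.null(gr$Parent)) as.character(gr$Parent)
        else if (!is.null(gr$name)) as.character(gr$name)
        else stop("need a gene_id, Parent or name column")
  first <- function(x) x[1L]
  ch <- tapply(as.character(GenomeInfoDb::seqnames(gr)), id, first)
  if (any(tapply(as.character(GenomeInfoDb::seqnames(gr)), id,
                 function(x) length(unique(x))) > 1L))
    stop("transcripts of one gene on multiple chromosomes")
  out <- GenomicRanges::GRanges(
    as.character(ch),
    IRanges::IRanges(as.integer(tapply(GenomicRanges::start(gr), id, min)),
                     as.integer(tapply(GenomicRanges::end(gr), id, max))),
    strand = as.character(tapply(as.character(GenomicRanges::strand(gr)),
                                 id, first)),
    seqinfo = GenomeInfoDb::seqinfo(gr))
  out$name <- names(ch)
  sort_intervals(out)
}

#' TSS / TES anchor positions
#'
#' TSS is the 5' end of the record (start on `+`, end on `-`); TES the 3'
#' end. Unstranded records are treated as `+`.
#'
#' @param gr Stranded `GRanges`.
#' @return Integer vector of positions (1-based).
#' @export
tss_positions <- function(gr) {
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  ifelse(neg, GenomicRanges::end(gr), GenomicRanges::start(gr))
}

#' @rdname tss_positions
#' @export
tes_positions <- function(gr) {
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  ifelse(neg, GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# Internal: clamp ranges to chromosome bounds, dropping emptied ones.
clamp_to_genome <- function(gr, genome) {
  len <- genome$chrom_lengths[as.character(GenomeInfoDb::seqnames(gr))]
  s <- pmax(GenomicRanges::start(gr), 1L)
  e <- pmin(GenomicRanges::end(gr), as.integer(len))
  keep <- s <= e
  gr <- gr[keep]
  GenomicRanges::ranges(gr) <- IRanges::IRanges(s[keep], e[keep])
  gr
}

#' Derive promoter and 3' regions from stranded annotations
#'
#' Coding genes and tRNAs get the classical 1 kb upstream promoter
#' (`[TSS-L, TSS)`) and 1 kb downstream 3' region (`(TES, TES+L]`),
#' strand-aware. Non-coding RNA records instead get a window of total length
#' `L` centered on the TSS (promoters) or TES (3' regions), following the
#' convention of taking "1 kb around" the ends of ncRNAs. Regions are
#' truncated at chromosome boundaries.
#'
#' @param ann Stranded annotation `GRanges` (a `class` column switches the
#'   ncRNA convention; absent means all records are treated as genes).
#' @param genome A `GenomeModel` (for boundary truncation).
#' @param len Region length L in bp.
#' @return A `GRanges` of regions, carrying the source record index as
#'   `source_idx`.
#' @export
derive_promoters <- function(ann, genome, len = 1000L) {
  derive_end_regions(ann, genome, len, anchor = "tss", side = "upstream")
}

#' @rdname derive_promoters
#' @export
derive_3prime <- function(ann, genome, len = 1000L) {
  derive_end_regions(ann, genome, len, anchor = "tes", side = "downstream")
}

derive_end_regions <- function(ann, genome, len, anchor, side) {
  pos <- if (anchor == "tss") tss_positions(ann) else tes_positions(ann)
  neg <- as.character(GenomicRanges::strand(ann)) == "-"
  is_nc <- if (!is.null(ann$class)) grepl("^ncRNA", ann$class)
           else rep(FALSE, length(ann))
  # upstream promoter [pos-L, pos-1]; downstream 3' [pos+1, pos+L]; the
  # strand mirror swaps the two; ncRNAs get a centered window of length L.
  before <- xor(side == "upstream", neg)
  s <- ifelse(before, pos - len, pos + 1L)
  e <- ifelse(before, pos - 1L, pos + len)
  half <- len %/% 2L
  s[is_nc] <- pos[is_nc] - half
  e[is_nc] <- pos[is_nc] + (len - half - 1L)
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(ann),
    IRanges::IRanges(pmax(1L, as.integer(s)), as.integer(e)),
    strand = GenomicRanges::strand(ann))
  out$source_idx <- seq_along(ann)
  if (!is.null(ann$name)) out$name <- ann$name
  clamp_to_genome(out, genome)
}

#' Merge overlapping / book-ended intervals
#'
#' @param gr A `GRanges`.
#' @return Strand-blind reduced ranges.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}
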