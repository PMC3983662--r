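#' Per-base coverage / enrichment tracks
#'
#' A `CoverageTrack` holds one numeric value per base per chromosome together
#' with its `GenomeModel` and a normalization state. State moves along
#' `raw -> median_normalized -> input_subtracted -> zscored`; every operation
#' appends a provenance entry with its parameters so a processed track is
#' self-describing.
#'
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length equal to the chromosome length.
#' @param genome A [genome_model()].
#' @param state Normalization state string.
#' @param provenance List of provenance records (internal use).
#' @return A `CoverageTrack`.
#' @export
coverage_track <- function(values, genome,
                           state = c("raw", "median_normalized",
                                     "input_subtracted", "zscored"),
                           provenance = list()) {
  state <- match.arg(state)
  if (!setequal(names(values), chrom_names(genome)))
    stop("values must name exactly the genome's chromosomes")
  values <- values[chrom_names(genome)]
  for (ch in names(values)) {
    v <- values[[ch]]
    if (length(v) != genome$chrom_lengths[[ch]])
      stop("track length on ", ch, " (", length(v),
           ") does not match chromosome length (",
           genome$chrom_lengths[[ch]], ")")
    if (!all(is.finite(v)))
      stop("non-finite track values on ", ch)
  }
  structure(list(values = values, genome = genome, state = state,
                 provenance = provenance),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack [%s]: %d chromosomes, %.1f Mb\n", x$state,
              length(x$values), sum(lengths(x$values)) / 1e6))
  for (p in x$provenance)
    cat("  -", p$op,
        if (length(p) > 1L)
          paste0("(", paste(names(p)[-1], unlist(p[-1]), sep = "=",
                            collapse = ", "), ")"), "\n")
  invisible(x)
}

# Internal: append a provenance record.
add_provenance <- function(track, op, ...) {
  track$provenance <- c(track$provenance, list(c(list(op = op), list(...))))
  track
}

#' Constant-valued track (mainly for tests and controls)
#' @param genome A `GenomeModel`.
#' @param value The constant.
#' @param state Normalization state to stamp.
#' @export
constant_track <- function(genome, value = 0, state = "raw") {
  coverage_track(lapply(genome$chrom_lengths, function(L) rep(value, L)),
                 genome, state = state)
}

#' Extract per-base values under a set of ranges
#'
#' @param track A `CoverageTrack`.
#' @param gr A `GRanges` on the track's genome.
#' @return A list of numeric vectors, one per range, 5'->3' in genome
#'   orientation (no strand flipping).
#' @export
track_region_values <- function(track, gr) {
  validate_on_genome(gr, track$genome, "query ranges")
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  lapply(seq_along(gr), function(i) track$values[[ch[i]]][s[i]:e[i]])
}

# Internal: concatenated values over the given chromosomes.
track_concat <- function(track, chroms = NULL) {
  if (is.null(chroms)) chroms <- chrom_names(track$genome)
  unlist(track$values[chroms], use.names = FALSE)
}

#' Read a coverage track (bedGraph or wiggle)
#'
#' Both bedGraph and fixedStep/variableStep wiggle dialects are accepted
#' (parsed by \pkg{rtracklayer}); positions the file does not specify are
#' filled with 0. Records beyond a chromosome end, or on chromosomes the
#' `GenomeModel` does not know, are an error.
#'
#' @param path File path.
#' @param genome A `GenomeModel` supplying chromosome lengths.
#' @param format `"auto"` (by extension), `"bedGraph"` or `"wiggle"`.
#' @return A raw-state `CoverageTrack`.
#' @export
read_track <- function(path, genome, format = c("auto", "bedGraph", "wiggle")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("wig", "wiggle")) "wiggle" else "bedGraph"
  }
  gr <- switch(format,
    bedGraph = rtracklayer::import(path, format = "bedGraph"),
    wiggle = rtracklayer::import(path, format = "wig"))
  validate_on_genome(gr, genome, "track records")
  GenomeInfoDb::seqlevels(gr) <- chrom_names(genome)
  GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  vals <- lapply(chrom_names(genome), function(ch) as.numeric(cov[[ch]]))
  names(vals) <- chrom_names(genome)
  coverage_track(vals, genome,
                 provenance = list(list(op = "read_track", path = path,
                                        format = format)))
}

#' Write a coverage track as bedGraph or fixedStep wiggle
#'
#' Zero-valued runs are omitted in bedGraph (the read-side fill rule restores
#' them); the wiggle writer emits every base. `write_track` then `read_track`
#' is the identity on the value arrays.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param format `"bedGraph"` or `"wiggle"`.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wiggle")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chrom_names(track$genome)) {
    v <- track$values[[ch]]
    if (format == "bedGraph") {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths  # 0-based
      keep <- r$values != 0
      if (any(keep)) {
        vk <- r$values[keep]
        u <- unique(vk)  # format each distinct value once
        writeLines(paste0(ch, "\t", starts[keep], "\t", ends[keep], "\t",
                          sprintf("%.10g", u)[match(vk, u)]), con)
      }
    } else {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ch), con)
      vi <- as.integer(v)
      if (isTRUE(all(v == vi))) {  # fast path for count tracks
        writeLines(as.character(vi), con)
      } else {
        u <- unique(v)
        writeLines(sprintf("%.10g", u)[match(v, u)], con)
      }
    }
  }
  invisible(path)
}
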