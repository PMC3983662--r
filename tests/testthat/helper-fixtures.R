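# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use per-base logical/numeric vectors instead of interval arithmetic so they
# share no code path with the implementation under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_genome <- function(lengths = c(chrI = 10000, chrII = 10000,
                                   chrX = 10000),
                       x_chrom = "chrX", excluded = character()) {
  genome_model(lengths, x_chrom = x_chrom, excluded_chroms = excluded)
}

# random intervals as a data.frame (chrom, start, end; 1-based closed)
random_intervals <- function(genome, n, min_w = 5L, max_w = 400L) {
  chroms <- chrom_names(genome)
  ch <- sample(chroms, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  L <- genome$chrom_lengths[ch]
  s <- 1L + floor(runif(n) * (L - w))
  data.frame(chrom = ch, start = as.integer(s),
             end = as.integer(s + w - 1L))
}

df_to_gr <- function(df, genome) {
  GRanges(df$chrom, IRanges(df$start, df$end),
          seqinfo = as_seqinfo(genome))
}

# per-base occupancy vector per chromosome
base_mask <- function(df, genome) {
  m <- lapply(genome$chrom_lengths, function(L) logical(L))
  for (i in seq_len(nrow(df)))
    m[[df$chrom[i]]][df$start[i]:df$end[i]] <- TRUE
  m
}

# ORACLE: does interval i of `a` share >= min_overlap bases with any b?
oracle_hit_flags <- function(a_df, b_df, genome, min_overlap = 1L) {
  vapply(seq_len(nrow(a_df)), function(i) {
    ach <- a_df$chrom[i]
    span <- a_df$start[i]:a_df$end[i]
    any(vapply(which(b_df$chrom == ach), function(j)
      sum(span >= b_df$start[j] & span <= b_df$end[j]) >= min_overlap,
      TRUE))
  }, TRUE)
}

# ORACLE: bases covered by >= k of the sets, as a per-chrom count vector
oracle_consensus_mask <- function(dfs, genome, k) {
  counts <- lapply(genome$chrom_lengths, function(L) integer(L))
  for (df in dfs) {
    m <- base_mask(df, genome)
    for (ch in names(counts)) counts[[ch]] <- counts[[ch]] + m[[ch]]
  }
  lapply(counts, function(x) x >= k)
}

gr_to_mask <- function(gr, genome) {
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr))
  base_mask(df, genome)
}

# ORACLE: sliding-window GC at each base by direct per-window counting
oracle_gc <- function(seq_chr, window) {
  b <- strsplit(seq_chr, "")[[1]]
  half <- window %/% 2
  L <- length(b)
  vapply(seq_len(L), function(i) {
    at <- max(1, i - half):min(L, i + half)
    mean(b[at] %in% c("G", "C"))
  }, 0)
}

# random coverage track with values rounded so text round-trips are exact
random_track <- function(genome, digits = 4, state = "raw") {
  coverage_track(lapply(genome$chrom_lengths, function(L)
    round(rexp(L, 1 / 10), digits)), genome, state = state)
}

# track with given per-chromosome value vectors
track_from <- function(genome, values, state = "raw") {
  coverage_track(values[chrom_names(genome)], genome, state = state)
}

# small single-chromosome genome + explicit signal vector, for peak tests
signal_fixture <- function(v, chrom = "chrI") {
  g <- genome_model(setNames(length(v), chrom))
  list(genome = g,
       track = coverage_track(setNames(list(as.numeric(v)), chrom), g,
                              state = "input_subtracted"))
}

# ORACLE: independent sequential valley-scan for peak splitting; returns the
# number of sub-peaks for one value vector (enumerates candidate maxima via
# a direct neighborhood test, then walks valleys)
oracle_subpeak_count <- function(v, min_height, sep) {
  n <- length(v)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) v[i - 1] else -Inf
    right <- if (i < n) v[i + 1] else -Inf
    # leftmost base of a plateau that is higher than both flanking values
    if (v[i] < left || v[i] < right) return(FALSE)
    if (i > 1 && v[i] == left) return(FALSE)
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    (i == 1 || v[i] > v[i - 1]) && (j == n || v[j + 1] < v[i])
  }, TRUE)
  mx <- which(is_max & v >= min_height)
  if (length(mx) < 2) return(1L)
  count <- 1L
  cur <- mx[1]
  for (m in mx[-1]) {
    valley <- min(v[cur:m])
    if (valley < sep * min(v[cur], v[m])) {
      count <- count + 1L
      cur <- m
    } else if (v[m] > v[cur]) cur <- m
  }
  count
}
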