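#' Simulation configuration for the synthetic data generator
#'
#' Describes a miniature genome with the statistical structure the pipeline
#' assumes: several equally sized autosomes plus an X and a small excluded
#' mitochondrial chromosome; genes, tRNAs and short/long ncRNAs; two
#' condensin-like complexes whose true binding sites sit at a fraction of
#' active promoters, at tRNAs and at intergenic enhancer sites, with the
#' X-specific complex concentrated on the X; per-subunit replicate coverage
#' tracks (Poisson background plus Gaussian enrichment bumps); GC elevation
#' and a planted sequence motif at summits; and log-normal expression
#' coupled to promoter binding.
#'
#' Defaults emulate the shape of *C. elegans* embryo condensin data at desk
#' scale: 5 autosomes + X of 200 kb (1/100 of the real ~100 Mb genome),
#' ~10x background coverage, 400 bp peaks at ~5-fold enrichment, 36%
#' background GC, and an X-placement odds multiplier that reproduces the
#' observed ~97% X-specificity of the dosage-compensation complex.
#'
#' @param n_chroms Number of chromosomes (last one is the X).
#' @param chrom_length Length of each chromosome in bp.
#' @param mito_length Length of the excluded mitochondrial chromosome
#'   (0 = none).
#' @param n_genes,n_trnas,n_ncrnas Annotation counts per chromosome.
#' @param n_enhancers Intergenic enhancer candidate sites per chromosome.
#' @param frac_active Fraction of genes latently active (top expression
#'   quartile by construction).
#' @param frac_active_promoters_bound Probability that an active promoter
#'   carries a true peak.
#' @param frac_trnas_bound,frac_enhancers_bound Binding rates of the other
#'   candidate classes.
#' @param x_bias Odds multiplier for placing X-specific-complex peaks on
#'   the X (160 gives ~97% X-placement with 5 autosomes).
#' @param peak_width_mean,peak_width_sd Peak width distribution (bp).
#' @param enrichment_height Mean fold enrichment of peaks over background.
#' @param height_sdlog Log-sd of per-peak heights.
#' @param background_rate Mean background coverage per base.
#' @param gc_background,gc_at_peaks Genome GC fraction and the elevated GC
#'   within +/-100 bp of summits.
#' @param motif_idc,motif_ii Consensus motifs planted at summits of the two
#'   complexes (GCGC core; the X-specific one extended by AGGG).
#' @param motif_plant_prob Probability a summit gets its motif planted.
#' @param n_subunits Non-SMC subunits per complex (tracks per complex).
#' @param n_replicates Replicates per subunit track.
#' @param replicate_noise SD of the multiplicative per-peak replicate noise.
#' @param replicate_dropout Probability a true peak is missing from one
#'   replicate's peak list (exercises the majority filter).
#' @param expr_meanlog,expr_sdlog Log-normal expression baseline.
#' @param expr_active_shift,expr_bound_shift Additive log-expression shifts
#'   for active and promoter-bound genes.
#' @param expr_rep_sd Log-sd of replicate-to-replicate expression noise.
#' @param n_expr_reps Expression replicates.
#' @param rng_seed Master seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_chroms = 6L, chrom_length = 200000L,
                              mito_length = 10000L,
                              n_genes = 50L, n_trnas = 8L, n_ncrnas = 12L,
                              n_enhancers = 10L,
                              frac_active = 0.25,
                              frac_active_promoters_bound = 0.2,
                              frac_trnas_bound = 0.3,
                              frac_enhancers_bound = 0.5,
                              x_bias = 160,
                              peak_width_mean = 400, peak_width_sd = 80,
                              enrichment_height = 5, height_sdlog = 0.4,
                              background_rate = 10,
                              gc_background = 0.36, gc_at_peaks = 0.55,
                              motif_idc = "AGGGGCGCGC",
                              motif_ii = "TAGCGCGCGA",
                              motif_plant_prob = 0.7,
                              n_subunits = 3L, n_replicates = 3L,
                              replicate_noise = 0.3,
                              replicate_dropout = 0,
                              expr_meanlog = 1.5, expr_sdlog = 1.2,
                              expr_active_shift = 3,
                              expr_bound_shift = 0.5,
                              expr_rep_sd = 0.1,
                              n_expr_reps = 5L,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$chrom_length < 10 * cfg$peak_width_mean)
    stop("chrom_length must be >= 10x the mean peak width")
  stopifnot(cfg$frac_active_promoters_bound >= 0,
            cfg$frac_active_promoters_bound <= 1,
            cfg$gc_background > 0, cfg$gc_background < 1,
            cfg$enrichment_height >= 0, cfg$background_rate > 0,
            cfg$n_chroms >= 2L)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' GenomeModel implied by a SimulationConfig
#'
#' Chromosomes `chrI..chrN` with the last one flagged as `chrX`, plus an
#' excluded `chrM` when `mito_length > 0`.
#'
#' @param config A [simulation_config()].
#' @export
sim_genome_model <- function(config) {
  n <- config$n_chroms
  nm <- c(paste0("chr", utils::as.roman(seq_len(n - 1L))), "chrX")
  len <- rep(config$chrom_length, n)
  excl <- character()
  if (config$mito_length > 0) {
    nm <- c(nm, "chrM"); len <- c(len, config$mito_length)
    excl <- "chrM"
  }
  genome_model(stats::setNames(len, nm), x_chrom = "chrX",
               excluded_chroms = excl)
}

#' Generate annotations: genes, tRNAs, ncRNAs, enhancer candidates
#'
#' Genes are laid down sequentially with log-normal lengths and
#' exponential-ish gaps; tRNAs (~75 bp), ncRNAs (half short, half long
#' around the 200 bp class cutoff) and point-like intergenic enhancer
#' candidates are dropped into the remaining space. A latent activity rank
#' marks the `frac_active` top genes; expression later follows it.
#'
#' @param config A [simulation_config()].
#' @param genome The matching [sim_genome_model()].
#' @param seed Integer seed (default from config).
#' @return List: `annotations` (classed `GRanges` incl. genes, tRNAs,
#'   ncRNAs), `genes`, `active` (named logical), `enhancers` (point
#'   `GRanges`).
#' @export
generate_annotations <- function(config, genome, seed = config$rng_seed) {
  with_seed(seed, {
    chroms <- analysis_chroms(genome)
    recs <- list(); enh <- list()
    gid <- 0L
    for (ch in chroms) {
      L <- genome$chrom_lengths[[ch]]
      pos <- 1500L
      for (i in seq_len(config$n_genes)) {
        len <- round(min(max(stats::rlnorm(1, log(1500), 0.5), 300), 8000))
        gap <- round(stats::rexp(1, 1 / 1200)) + 400L
        if (pos + len + 2000L > L) break
        gid <- gid + 1L
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = pos + len - 1L,
          strand = sample(c("+", "-"), 1L), class = "gene",
          name = sprintf("gene%04d", gid))
        pos <- pos + len + gap
      }
      gene_iv <- do.call(rbind, recs)
      gene_iv <- gene_iv[gene_iv$chrom == ch & gene_iv$class == "gene", ]
      in_gene <- function(p)
        any(p >= gene_iv$start - 200 & p <= gene_iv$end + 200)
      drop_nongene <- function(n, width_fun, class, prefix) {
        out <- list()
        for (i in seq_len(n)) {
          w <- width_fun()
          for (try in 1:25) {
            s <- sample.int(L - w - 1L, 1L)
            if (!in_gene(s) && !in_gene(s + w - 1L)) break
          }
          out[[i]] <- data.frame(
            chrom = ch, start = s, end = s + w - 1L,
            strand = sample(c("+", "-"), 1L), class = class,
            name = sprintf("%s_%s_%02d", prefix, ch, i))
        }
        do.call(rbind, out)
      }
      recs[[length(recs) + 1L]] <-
        drop_nongene(config$n_trnas, function() 75L, "tRNA", "trna")
      recs[[length(recs) + 1L]] <- drop_nongene(
        config$n_ncrnas,
        function() if (stats::runif(1) < 0.5)
          sample(60:200, 1L) else sample(201:2000, 1L),
        "ncRNA", "ncrna")
      enh[[ch]] <- drop_nongene(config$n_enhancers, function() 1L,
                                "gene", "enh")  # class placeholder
    }
    df <- do.call(rbind, recs)
    ann <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start, df$end),
                                  strand = df$strand,
                                  seqinfo = as_seqinfo(genome))
    ann$class <- df$class; ann$name <- df$name
    ann <- as_annotation_set(ann)
    ann <- sort_intervals(ann)
    genes <- ann[ann$class == "gene"]
    n_act <- round(config$frac_active * length(genes))
    active <- stats::setNames(rep(FALSE, length(genes)), genes$name)
    active[sample(genes$name, n_act)] <- TRUE
    edf <- do.call(rbind, enh)
    enhancers <- GenomicRanges::GRanges(edf$chrom,
                                        IRanges::IRanges(edf$start, width = 1L),
                                        seqinfo = as_seqinfo(genome))
    enhancers$name <- edf$name
    list(annotations = ann, genes = genes, active = active,
         enhancers = sort_intervals(enhancers))
  })
}

#' Place true binding peaks for one complex
#'
#' Candidate sites are active-gene promoters, tRNAs and enhancer points;
#' each candidate is bound independently at its category's configured rate.
#' For the X-specific complex (`x_bias > 1`) X-linked candidates keep their
#' rates while autosomal rates are divided by `x_bias`, so the X-to-autosome
#' odds per candidate equal `x_bias` (160 reproduces the ~97% X-specificity
#' of the dosage-compensation condensin).
#'
#' @param config A [simulation_config()].
#' @param genome A `GenomeModel`.
#' @param ann Result of [generate_annotations()].
#' @param complex `"condensin_I_IDC"` (X-biased) or `"condensin_II"`.
#' @param seed Integer seed.
#' @return A truth [peak_set()] with `site_class`, `height`, `gene` (for
#'   promoter sites) and `complex` columns; `summit_score` holds the
#'   planted fold height.
#' @export
generate_true_peaks <- function(config, genome, ann,
                                complex = c("condensin_II",
                                            "condensin_I_IDC"),
                                seed = config$rng_seed) {
  complex <- match.arg(complex)
  with_seed(seed, {
    genes <- ann$genes
    tssp <- tss_positions(genes)
    neg <- as.character(GenomicRanges::strand(genes)) == "-"
    cand <- rbind(
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                 pos = ifelse(neg, tssp + sample(50:300, length(genes), TRUE),
                              tssp - sample(50:300, length(genes), TRUE)),
                 site_class = "promoter", gene = genes$name,
                 p = ifelse(ann$active[genes$name],
                            config$frac_active_promoters_bound, 0)),
      local({
        tr <- ann$annotations[ann$annotations$class == "tRNA"]
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(tr)),
                   pos = GenomicRanges::start(tr) +
                     GenomicRanges::width(tr) %/% 2L,
                   site_class = "tRNA", gene = NA_character_,
                   p = config$frac_trnas_bound)
      }),
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(ann$enhancers)),
                 pos = GenomicRanges::start(ann$enhancers),
                 site_class = "enhancer", gene = NA_character_,
                 p = config$frac_enhancers_bound))
    # X-specific complex: X candidates bind at their configured rates,
    # autosomal candidates at rate / x_bias, so the per-candidate odds
    # ratio X : autosome equals x_bias at any genome scale
    p_eff <- if (complex == "condensin_I_IDC" && config$x_bias != 1)
      cand$p * ifelse(cand$chrom == genome$x_chrom, 1, 1 / config$x_bias)
    else cand$p
    sel <- which(stats::runif(nrow(cand)) < p_eff)
    picked <- cand[sel, , drop = FALSE]
    n <- nrow(picked)
    width <- pmax(100L, round(stats::rnorm(n, config$peak_width_mean,
                                           config$peak_width_sd)))
    height <- stats::rlnorm(n, log(config$enrichment_height),
                            config$height_sdlog)
    L <- genome$chrom_lengths[picked$chrom]
    summit <- pmin(pmax(picked$pos, width %/% 2L + 2L),
                   L - width %/% 2L - 2L)
    gr <- GenomicRanges::GRanges(
      picked$chrom,
      IRanges::IRanges(pmax(1L, as.integer(summit - width %/% 2L)),
                       pmin(as.integer(L),
                            as.integer(summit + width %/% 2L))),
      seqinfo = as_seqinfo(genome))
    gr$site_class <- picked$site_class
    gr$gene <- picked$gene
    gr$complex <- complex
    gr$height <- height
    peak_set(gr, summit = as.integer(summit), summit_score = height)
  })
}

#' Generate the genome sequence (background GC, summit GC elevation, motifs)
#'
#' Bases are i.i.d. at `gc_background`; within +/-100 bp of each supplied
#' true summit the GC probability is raised to `gc_at_peaks`; finally the
#' complex's consensus motif is written centered at each summit with
#' probability `motif_plant_prob` (random strand). Deterministic given the
#' seed.
#'
#' @param config A [simulation_config()].
#' @param genome A `GenomeModel` (default [sim_genome_model()]).
#' @param true_peaks Optional named list of truth peak sets (names
#'   containing `IDC` get the `motif_idc` consensus, others `motif_ii`).
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @export
generate_genome <- function(config, genome = sim_genome_model(config),
                            true_peaks = NULL, seed = config$rng_seed) {
  with_seed(seed, {
    p_bg <- c(A = (1 - config$gc_background) / 2,
              C = config$gc_background / 2,
              G = config$gc_background / 2,
              T = (1 - config$gc_background) / 2)
    seqs <- lapply(genome$chrom_lengths, function(L)
      sample(names(p_bg), L, replace = TRUE, prob = p_bg))
    if (!is.null(true_peaks)) {
      p_pk <- c(A = (1 - config$gc_at_peaks) / 2,
                C = config$gc_at_peaks / 2,
                G = config$gc_at_peaks / 2,
                T = (1 - config$gc_at_peaks) / 2)
      for (nm in names(true_peaks)) {
        tp <- true_peaks[[nm]]
        motif <- if (grepl("IDC", nm, ignore.case = TRUE))
          config$motif_idc else config$motif_ii
        mb <- strsplit(motif, "")[[1L]]
        mb_rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[mb])
        ch <- as.character(GenomeInfoDb::seqnames(tp))
        for (i in seq_along(tp)) {
          L <- genome$chrom_lengths[[ch[i]]]
          s <- tp$summit[i]
          at <- max(1L, s - 100L):min(L, s + 100L)
          seqs[[ch[i]]][at] <- sample(names(p_pk), length(at),
                                      replace = TRUE, prob = p_pk)
          if (stats::runif(1) < config$motif_plant_prob) {
            m <- if (stats::runif(1) < 0.5) mb else mb_rc
            at_m <- (s - length(m) %/% 2L):(s - length(m) %/% 2L +
                                              length(m) - 1L)
            if (at_m[1L] >= 1L && at_m[length(m)] <= L)
              seqs[[ch[i]]][at_m] <- m
          }
        }
      }
    }
    vapply(seqs, paste, "", collapse = "")
  })
}

#' Generate per-subunit replicate coverage tracks and matched inputs
#'
#' Per replicate, coverage is `Poisson(lambda)` with
#' `lambda = background * (1 + sum_p h_p nu_p exp(-(x - s_p)^2 / 2 sigma_p^2))`
#' over the complex's true peaks (`sigma = width/4`), where `nu_p` is
#' multiplicative per-peak replicate noise (`N(1, replicate_noise)`,
#' truncated at 0, and 0 with probability `replicate_dropout`). Input
#' tracks are pure `Poisson(background)`.
#'
#' @param config A [simulation_config()].
#' @param genome A `GenomeModel`.
#' @param true_peaks A truth [peak_set()] from [generate_true_peaks()].
#' @param seed Integer seed.
#' @param n_input_replicates Input replicates to draw.
#' @return List: `chip` (subunit -> list of replicate `CoverageTrack`s),
#'   `input` (list of replicate tracks), `truth` (the peak set).
#' @export
generate_binding_tracks <- function(config, genome, true_peaks,
                                    seed = config$rng_seed,
                                    n_input_replicates = 2L) {
  with_seed(seed, {
    ch_names <- chrom_names(genome)
    lens <- genome$chrom_lengths
    ch <- as.character(GenomeInfoDb::seqnames(true_peaks))
    sig <- GenomicRanges::width(true_peaks) / 4
    bump_lambda <- function(nu) {
      lam <- lapply(lens, function(L) rep(1, L))
      for (i in seq_along(true_peaks)) {
        if (nu[i] == 0) next
        s <- true_peaks$summit[i]
        L <- lens[[ch[i]]]
        at <- max(1L, round(s - 4 * sig[i])):min(L, round(s + 4 * sig[i]))
        lam[[ch[i]]][at] <- lam[[ch[i]]][at] +
          true_peaks$height[i] * nu[i] *
          exp(-((at - s)^2) / (2 * sig[i]^2))
      }
      lam
    }
    draw_track <- function(lam) {
      vals <- lapply(lam, function(l)
        as.numeric(stats::rpois(length(l), config$background_rate * l)))
      coverage_track(vals, genome)
    }
    chip <- list()
    for (su in seq_len(config$n_subunits)) {
      reps <- list()
      for (r in seq_len(config$n_replicates)) {
        nu <- pmax(0, stats::rnorm(length(true_peaks), 1,
                                   config$replicate_noise))
        nu[stats::runif(length(nu)) < config$replicate_dropout] <- 0
        reps[[sprintf("rep%d", r)]] <- draw_track(bump_lambda(nu))
      }
      chip[[sprintf("subunit%d", su)]] <- reps
    }
    flat <- lapply(lens, function(L) rep(1, L))
    input <- lapply(seq_len(n_input_replicates), function(r)
      draw_track(flat))
    names(input) <- sprintf("rep%d", seq_len(n_input_replicates))
    list(chip = chip, input = input, truth = true_peaks)
  })
}

#' Derive noisy per-subunit peak sets from the truth
#'
#' Emulates upstream peak calling: each subunit's combined set contains all
#' true peaks (slightly jittered per subunit) plus `n_false` spurious peaks;
#' per-replicate sets drop true peaks with probability `dropout` and contain
#' each spurious peak with probability `false_rep_prob` (spurious support
#' below any majority).
#'
#' @param config A [simulation_config()].
#' @param genome A `GenomeModel`.
#' @param true_peaks Truth peak set.
#' @param n_false Spurious peaks per subunit.
#' @param dropout Per-replicate true-peak dropout probability.
#' @param false_rep_prob Per-replicate spurious-peak occurrence probability.
#' @param seed Integer seed.
#' @return List per subunit: `combined` (`GRanges`), `replicates` (list of
#'   `GRanges`), `is_true` flags for the combined set.
#' @export
generate_subunit_peaks <- function(config, genome, true_peaks,
                                   n_false = 10L, dropout = 0.1,
                                   false_rep_prob = 0.3,
                                   seed = config$rng_seed) {
  with_seed(seed, {
    out <- list()
    for (su in seq_len(config$n_subunits)) {
      jit <- sample(-50:50, length(true_peaks), TRUE)
      shifted <- clamp_to_genome(suppressWarnings(
        GenomicRanges::shift(GenomicRanges::granges(true_peaks), jit)),
        genome)
      false_pk <- shuffle_peaks(
        peak_set(GenomicRanges::GRanges(
          sample(analysis_chroms(genome), n_false, TRUE),
          IRanges::IRanges(1L, width = pmax(
            100L, round(stats::rnorm(n_false, config$peak_width_mean,
                                     config$peak_width_sd)))))),
        genome)
      combined <- c(shifted, GenomicRanges::granges(false_pk))
      is_true <- c(rep(TRUE, length(shifted)), rep(FALSE, n_false))
      reps <- lapply(seq_len(config$n_replicates), function(r) {
        keep <- c(stats::runif(length(shifted)) > dropout,
                  stats::runif(n_false) < false_rep_prob)
        combined[keep]
      })
      names(reps) <- sprintf("rep%d", seq_len(config$n_replicates))
      out[[sprintf("subunit%d", su)]] <-
        list(combined = combined, replicates = reps, is_true = is_true)
    }
    out
  })
}

#' Generate a replicate expression table coupled to binding
#'
#' Two coupling modes. In *shift* mode (default) log-expression is the
#' baseline plus `expr_active_shift` for latently active genes plus
#' `expr_bound_shift` for genes whose promoter carries a true peak, plus
#' gene-level log-normal noise -- a positive binding-expression rank
#' correlation arises mechanistically. In *copula* mode (`rho_target`
#' given) the per-gene median is drawn from a Gaussian copula against the
#' supplied `covariate` so Spearman's rho between covariate and expression
#' is `rho_target` in expectation; this is the mode used for planted-rho
#' recovery. Replicates add log-normal noise; the reported median is the
#' median of the replicates.
#'
#' @param config A [simulation_config()].
#' @param ann Result of [generate_annotations()].
#' @param bound_genes Named logical vector of promoter-bound flags (shift
#'   mode).
#' @param rho_target Optional target Spearman correlation (copula mode).
#' @param covariate Named numeric vector (gene -> binding signal) required
#'   in copula mode.
#' @param seed Integer seed.
#' @return An [expression_table()].
#' @export
generate_expression <- function(config, ann, bound_genes = NULL,
                                rho_target = NULL, covariate = NULL,
                                seed = config$rng_seed) {
  genes <- ann$genes$name
  n <- length(genes)
  with_seed(seed, {
    if (!is.null(rho_target)) {
      if (is.null(covariate)) stop("copula mode needs a covariate")
      covariate <- covariate[genes]
      r <- 2 * sin(pi * rho_target / 6)  # Spearman -> Pearson (copula)
      u <- (rank(covariate, ties.method = "random") - 0.5) / n
      z <- r * stats::qnorm(u) + sqrt(1 - r^2) * stats::rnorm(n)
      med <- stats::qlnorm(stats::pnorm(z), config$expr_meanlog,
                           config$expr_sdlog)
    } else {
      if (is.null(bound_genes))
        bound_genes <- stats::setNames(rep(FALSE, n), genes)
      mu <- config$expr_meanlog +
        config$expr_active_shift * as.numeric(ann$active[genes]) +
        config$expr_bound_shift * as.numeric(bound_genes[genes] %in% TRUE)
      med <- stats::rlnorm(n, mu, config$expr_sdlog)
    }
    reps <- med * matrix(exp(stats::rnorm(n * config$n_expr_reps, 0,
                                          config$expr_rep_sd)),
                         n, config$n_expr_reps)
    expression_table(genes, reps)
  })
}

#' Generate a differential-expression call table
#'
#' Samples `n_de` differentially expressed genes; direction of change is
#' up with probability `p_up_bound` for bound genes and `p_up_unbound`
#' otherwise (the repressive-complex design: loss of the complex mostly
#' raises its direct targets).
#'
#' @param ann Result of [generate_annotations()].
#' @param bound_genes Named logical vector.
#' @param n_de Number of DE genes.
#' @param p_up_bound,p_up_unbound Up-direction probabilities.
#' @param seed Integer seed.
#' @return data.frame: gene, lfc, padj, direction.
#' @export
generate_de_table <- function(ann, bound_genes, n_de = 300L,
                              p_up_bound = 0.83, p_up_unbound = 0.67,
                              seed = 1L) {
  with_seed(seed, {
    genes <- sample(ann$genes$name, min(n_de, length(ann$genes)))
    bound <- bound_genes[genes] %in% TRUE
    up <- stats::runif(length(genes)) <
      ifelse(bound, p_up_bound, p_up_unbound)
    data.frame(gene = genes,
               lfc = ifelse(up, 1, -1) * stats::rlnorm(length(genes),
                                                       log(0.8), 0.4),
               padj = stats::runif(length(genes), 0, 0.05),
               direction = ifelse(up, "up", "down"))
  })
}

#' Generate transcription-factor peak sets and HOT regions
#'
#' Each TF set overlaps the condensin truth at its configured rate: that
#' fraction of its sites are jittered copies of randomly chosen true peaks,
#' the rest are random placements. HOT (high-occupancy target) regions are
#' the merged loci covered by at least `hot_k` TFs.
#'
#' @param config A [simulation_config()].
#' @param genome A `GenomeModel`.
#' @param true_peaks Truth peak set of the reference complex.
#' @param tf_rates Named numeric vector of overlap rates.
#' @param n_sites Sites per TF.
#' @param hot_k Minimum TF count defining a HOT region.
#' @param seed Integer seed.
#' @return List: `tf_sets` (named list of `GRanges`), `hot_regions`
#'   (`GRanges`), `rates`.
#' @export
generate_tf_sets <- function(config, genome, true_peaks,
                             tf_rates = c(TF_A = 0.6, TF_B = 0.45,
                                          TF_C = 0.3, TF_D = 0.15,
                                          TF_E = 0.05, TF_F = 0),
                             n_sites = 80L, hot_k = 3L,
                             seed = config$rng_seed) {
  with_seed(seed, {
    tf_sets <- lapply(tf_rates, function(rate) {
      k <- round(rate * n_sites)
      parts <- list()
      if (k > 0) {
        pick <- sample(seq_along(true_peaks), k, replace = k >
                         length(true_peaks))
        at <- true_peaks$summit[pick] + sample(-100:100, k, TRUE)
        parts$true <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(true_peaks)[pick],
          IRanges::IRanges(pmax(1L, at - 100L), at + 100L))
      }
      if (k < n_sites)
        parts$rand <- GenomicRanges::granges(shuffle_peaks(
          peak_set(GenomicRanges::GRanges(
            rep(analysis_chroms(genome)[1L], n_sites - k),
            IRanges::IRanges(1L, width = 200L))), genome))
      out <- clamp_to_genome(do.call(c, unname(parts)), genome)
      GenomeInfoDb::seqlevels(out) <- chrom_names(genome)
      GenomeInfoDb::seqinfo(out) <- as_seqinfo(genome)
      sort_intervals(out)
    })
    cov <- Reduce(`+`, lapply(tf_sets, GenomicRanges::coverage))
    hot <- GenomicRanges::GRanges(IRanges::slice(cov, lower = hot_k,
                                                 rangesOnly = TRUE))
    list(tf_sets = tf_sets, hot_regions = hot, rates = tf_rates)
  })
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator under one master seed and (optionally) writes the
#' complete file bundle -- FASTA, chromosome sizes, GFF3 annotations,
#' bedGraph ChIP/input tracks, BED truth peak files, expression and DE
#' tables, TF BED files and a JSON truth sidecar -- so the whole pipeline
#' can run from files alone.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (`NULL` = in-memory only).
#' @param seed Master seed (default `config$rng_seed`); stage seeds are
#'   derived from it.
#' @return The bundle as a list (genome, sequences, annotations, truth,
#'   tracks, subunit_peaks, expression, de_table, tf, paths).
#' @export
simulate_bundle <- function(config = simulation_config(), out_dir = NULL,
                            seed = config$rng_seed) {
  seeds <- derive_seeds(seed, 8L)
  genome <- sim_genome_model(config)
  ann <- generate_annotations(config, genome, seed = seeds[1L])
  truth <- list(
    condensin_I_IDC = generate_true_peaks(config, genome, ann,
                                          "condensin_I_IDC",
                                          seed = seeds[2L]),
    condensin_II = generate_true_peaks(config, genome, ann, "condensin_II",
                                       seed = seeds[3L]))
  sequences <- generate_genome(config, genome, truth, seed = seeds[4L])
  tracks <- list(
    condensin_I_IDC = generate_binding_tracks(config, genome,
                                              truth$condensin_I_IDC,
                                              seed = seeds[5L]),
    condensin_II = generate_binding_tracks(config, genome,
                                           truth$condensin_II,
                                           seed = seeds[5L] + 1L))
  subunit_peaks <- generate_subunit_peaks(config, genome,
                                          truth$condensin_II,
                                          seed = seeds[6L])
  bound <- stats::setNames(ann$genes$name %in%
                             truth$condensin_II$gene, ann$genes$name)
  expression <- generate_expression(config, ann, bound_genes = bound,
                                    seed = seeds[7L])
  de_table <- generate_de_table(ann, bound, seed = seeds[7L] + 1L)
  tf <- generate_tf_sets(config, genome, truth$condensin_II,
                         seed = seeds[8L])
  bundle <- list(config = config, genome = genome, sequences = sequences,
                 annotations = ann, truth = truth, tracks = tracks,
                 subunit_peaks = subunit_peaks, bound_genes = bound,
                 expression = expression, de_table = de_table, tf = tf)
  if (!is.null(out_dir)) bundle$paths <- write_bundle(bundle, out_dir)
  bundle
}

# Internal: small integer sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 100000L) * 10000L + 7919L * seq_len(n) %% 10000L
}

# Internal: write the bundle as plain-text files.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  paths <- list()
  writeLines(unlist(lapply(names(bundle$sequences), function(ch)
    c(paste0(">", ch), gsub("(.{70})", "\\1\n", bundle$sequences[[ch]])))),
    paths$fasta <- p("genome.fa"))
  write_chrom_sizes(bundle$genome, paths$chrom_sizes <- p("chrom.sizes"))
  ann_out <- bundle$annotations$annotations
  ann_out$type <- ann_out$class
  rtracklayer::export(ann_out, paths$gff <- p("annotations.gff3"),
                      format = "gff3")
  for (cx in names(bundle$truth))
    write_intervals(bundle$truth[[cx]],
                    paths[[paste0("truth_", cx)]] <-
                      p(sprintf("truth_%s.bed", cx)))
  for (cx in names(bundle$tracks)) {
    tr <- bundle$tracks[[cx]]
    for (su in names(tr$chip))
      for (r in names(tr$chip[[su]]))
        write_track(tr$chip[[su]][[r]],
                    p(sprintf("chip_%s_%s_%s.wig", cx, su, r)), "wiggle")
    for (r in names(tr$input))
      write_track(tr$input[[r]], p(sprintf("input_%s_%s.wig", cx, r)),
                  "wiggle")
  }
  write_expression_table(bundle$expression,
                         paths$expression <- p("expression.tsv"))
  utils::write.table(bundle$de_table, paths$de <- p("de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (tf in names(bundle$tf$tf_sets))
    write_intervals(bundle$tf$tf_sets[[tf]], p(sprintf("tf_%s.bed", tf)))
  if (length(bundle$tf$hot_regions))
    write_intervals(bundle$tf$hot_regions, p("hot_regions.bed"))
  truth_meta <- list(
    seed = bundle$config$rng_seed,
    n_true_peaks = lapply(bundle$truth, length),
    tf_rates = as.list(bundle$tf$rates),
    bound_genes = names(bundle$bound_genes)[bundle$bound_genes])
  jsonlite::write_json(truth_meta, paths$truth_json <- p("truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$dir <- out_dir
  paths
}
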