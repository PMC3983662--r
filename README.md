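# peakscape

Downstream analysis of ChIP-seq for multi-subunit chromosomal protein
complexes — written for the condensin complexes of *Caenorhabditis elegans*
(condensin I, the X-specific dosage-compensation condensin I^DC, and
condensin II), but applicable to any system where several subunits of one
complex are ChIPped in replicate and the questions are *where* the complex
binds and *what* that binding relates to.

Upstream steps (read alignment, raw peak calling, RNA-seq quantification,
DE model fitting) are out of scope: the inputs are coverage tracks
(bedGraph/wiggle), peak lists (BED), annotations (GFF3/BED), genome
sequence (FASTA) and expression/DE tables. The package provides:

* **Signal processing** — normalization of per-base coverage to the
  genome-wide median (mitochondrial chromosome excluded), input
  subtraction, replicate averaging, background z-scoring, separate
  X/autosome normalization for dosage-compensation mutants, and mutant/WT
  enrichment ratios within peaks.
* **Consensus peaks** — strict-majority replicate filtering, k-of-n
  subunit consensus (bases covered by ≥ 2 of 3 non-SMC subunit peak sets),
  summit calling (argmax, leftmost tie), and splitting of multi-summit
  peaks at valleys below `0.85 ×` the lower flanking maximum.
* **Permutation overlap enrichment** — ±200 bp summit windows tested
  against promoters, gene bodies, 3′ regions, tRNAs, short/long ncRNAs and
  transcription-factor peak panels (with HOT-region masking), against a
  null of 10,000 genome-wide length-preserving shuffles:

  `fold = observed overlap fraction / mean null fraction`,
  `p = 2(r+1)/(N+1)` two-sided (floor 0.0002 at N = 10,000).
* **Profiles** — summit heat-map matrices (median signal, 50 bp bins,
  1.5 kb windows, rows ordered by summit score), TSS metagene curves by
  expression class with 95% bands, and 15 bp sliding-window GC profiles
  with a random-coordinate control.
* **Expression integration** — 500 bp promoter signal, Spearman
  binding–expression correlation (genome/X scope), bound-gene calls within
  1 kb of the TSS, and the DE × binding contingency summary.
* **Motif context** — log-odds PWM scanning on both strands, fraction of
  motifs bound, conditioning on mark-enriched 2 kb windows, and the
  clustering effect (P(bound | ≥2 motifs/kb) / P(bound | 1 motif/kb)).
* **Chromatin features** — 1 kb-window Pearson correlation matrices with
  hierarchical leaf ordering, 250 bp bound/unbound window labels, and
  permutation feature importance (mean decrease in held-out accuracy)
  under an injectable classifier contract.
* **Synthetic data** — a seeded generator emitting the complete input
  bundle (genome + FASTA, annotations, per-subunit replicate tracks,
  inputs, truth peaks, TF sets, HOT regions, expression and DE tables)
  with planted, recoverable parameters, so the whole pipeline is testable
  offline.

## Worked example

```r
library(peakscape)

cfg    <- simulation_config(n_chroms = 4, chrom_length = 100000,
                            n_genes = 40, rng_seed = 7)
bundle <- simulate_bundle(cfg)

# ChIP enrichment for one subunit: normalize, subtract input, merge reps
tracks <- bundle$tracks$condensin_II
input  <- merge_replicates(lapply(tracks$input, median_normalize))
enr    <- merge_replicates(lapply(tracks$chip$subunit1, function(t)
            subtract_input(median_normalize(t), input)))

# complex-level consensus peaks with summits
filtered <- lapply(bundle$subunit_peaks, function(s)
              majority_replicate_filter(s$combined, s$replicates))
cons  <- consensus_k_of_n(filtered, k = 2, genome = bundle$genome)
sm    <- smooth_track(enr)                # fragment-scale smoothing
peaks <- call_summits(cons, sm)
peaks <- split_peaks(peaks, sm, min_height = summit_median_height(peaks))
cat("true condensin II peaks:", length(bundle$truth$condensin_II),
    "| consensus intervals:", length(cons), "\n")
cat("final peaks after splitting:", length(peaks), "\n")

# promoter enrichment against the 10,000-shuffle null
prom <- derive_promoters(bundle$annotations$genes, bundle$genome, 1000)
permutation_test(peaks, prom, bundle$genome, analysis_config(rng_seed = 7))
```

Output (printed by the code above):

```
true condensin II peaks: 29 | consensus intervals: 29
final peaks after splitting: 29
Permutation overlap test (N = 10000, seed = 7)
  observed: 17/29 peaks (58.6%); null mean 34.9%
  fold enrichment 1.68, p = 0.0184 (enriched)
```

All 29 planted peaks are recovered one-to-one by the consensus/splitting
machinery. 58.6% of peaks fall in 1 kb promoters versus 34.9% expected at
random — a 1.68-fold enrichment. The fold is modest because this miniature
genome is annotation-dense (promoters alone cover about a third of it);
the permutation machinery, not the biology of a 400 kb toy genome, is the
point. Adding the binding–expression link:

```r
ps  <- promoter_signal(enr, bundle$annotations$genes, bundle$genome,
                       upstream = 500)
binding_expression_correlation(ps, expression_medians(bundle$expression))
#> [1] 0.14   # positive: bound promoters sit before more-expressed genes
```

The full pipeline (simulate → signal → peaks → enrich → profiles →
expression → motifs → features), with per-stage TSV/JSON outputs and a
manifest of seeds, timings and file digests:

```r
run_pipeline(NULL, out_dir = "run1", seed = 7)
```

Reruns with the same seed are byte-identical (a tested property). A thin
CLI wraps the same stages:
`Rscript -e 'peakscape::peakscape_cli()' run --out run1 --seed 7`.

## Documentation

`vignettes/peakscape-methods.Rmd` documents the signal model, the consensus
and split rules, the permutation-null and p-value conventions, what the
synthetic generator does and does not emulate, and every place where an
unstated upstream convention forced a declared design choice.
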