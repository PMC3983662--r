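---
title: "Methods: models, parameters and design choices in peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in peakscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscape)
```

## The problem

Condensins are five-subunit SMC complexes that organize chromosomes.
*C. elegans* carries three: condensin I, condensin II, and the X-specific
condensin I^DC^ of the dosage compensation complex, which differs from
condensin I by a single SMC subunit. ChIP-seq of the non-SMC subunits gives,
per subunit and replicate, a per-base coverage track and a peak list; the
scientific questions downstream are where the complexes bind (promoters,
tRNAs, ncRNAs, enhancers), how binding relates to transcription, sequence
(GC, motifs) and chromatin state, and how signal changes in mutants.
`peakscape` implements that downstream analysis as a reusable, tested
pipeline, together with a synthetic-data generator so every stage can be
validated without any deposited data.

## Signal model

Tracks are per-base numeric vectors per chromosome with an explicit
normalization state: `raw -> median_normalized -> input_subtracted ->
zscored`.

* **Median normalization** divides every base by the genome-wide median of
  per-base coverage over non-excluded chromosomes (the mitochondrial
  chromosome is excluded). Division, not subtraction: it makes tracks from
  different sequencing depths commensurable so the subsequent ChIP − input
  difference is meaningful. The median is taken over *all* bases including
  zeros; a zero median (a degenerate, very sparse track) is an error rather
  than a silent fallback to the mean — at toy scale this is the safer
  failure mode, and it is documented here on purpose.
* **Input subtraction** is a plain per-base difference of two
  median-normalized tracks. Negative values are retained: downstream
  statistics are medians and means over windows, which tolerate them, and
  clipping would bias the background toward zero.
* **Replicate merging** is the per-base arithmetic mean.
* **Z-scoring** standardizes by the mean and standard deviation of all
  bases *outside* the peak regions (the presumed background), so wild-type
  and mutant tracks become comparable. For mutant/wild-type ratios each
  track is standardized against **its own** background; a pooled background
  is a defensible alternative, but per-track backgrounds keep the two
  estimates independent and are what we implement.
* **X/autosome split processing** computes the median divisor separately
  for the X and for the autosomes before recombining — needed for
  dosage-compensation-mutant samples in which X coverage is systematically
  halved relative to autosomes.

## Consensus peaks, summits, splitting

Upstream peak calling (MACS-style) is out of scope; the inputs are peak
lists. Three operations turn subunit-level lists into complex-level peaks:

1. **Majority replicate filter**: a peak called on pooled reads is kept only
   if it overlaps (>= 1 bp) peaks in a *strict* majority of the individual
   replicates. With two replicates this means both — the conservative
   reading of "majority", chosen for determinism and logged as such.
2. **k-of-n consensus**: the maximal runs of bases covered by peaks of at
   least k of the n non-SMC subunits (k = 2, n = 3 by convention). This is
   computed on coverage Rle vectors and verified in the tests against a
   per-base counting oracle.
3. **Summits and splitting**: the summit is the base of maximal enrichment
   (ties broken leftmost, for determinism). Long consensus intervals that
   span several binding events are split: local maxima with height at least
   `min_height` (by convention the median of all summit heights of the data
   set) seed sub-peaks; walking the retained maxima left to right, the
   minimum between the current sub-peak's maximum and the next retained
   maximum is a cut point iff
   `valley < separation_float * min(flanking maxima)`, with
   `separation_float = 0.85`. The published tool that inspired this step
   does not document its exact rule, so this rule *is* the package's
   defined contract: it reproduces the intuitive meaning of a "separation
   float" (a valley must drop below 85% of the lower flanking summit),
   conserves covered bases exactly, and is tested against an independent
   valley-scan oracle.

## Permutation overlap enrichment

The unit of overlap is the window ±200 bp around each summit; annotations
are 1 kb promoters and 3′ regions (for ncRNAs, a 1 kb window centered on
the TSS/TES — "1 kb around" is read as a window of total length 1 kb; the
alternative reading, ±1 kb, only rescales the annotation coverage and is
available by passing a different length), gene bodies, tRNAs, and ncRNAs
split at 200 bp into short/long. Overlap needs >= 1 shared base.

The null distribution re-places the peak windows uniformly at random over
the non-excluded genome 10,000 times, preserving each window's length:
a chromosome is drawn with probability proportional to its placeable length
(L − w + 1), the start uniformly. Shuffles are genome-wide (a
within-chromosome mode exists for X-restricted questions); shuffled windows
may overlap each other — the simplest null consistent with "randomly
distributing the peaks", and the inflation this could cause is negligible at
realistic peak densities. Fold enrichment is the observed overlap fraction
over the mean null fraction.

The empirical p-value convention is fixed as

> p = 2 (r + 1) / (N + 1), two-sided, capped at 1, reported to 4 decimals,

where r counts null overlaps at least as extreme as the observed one in the
observed direction. The source analyses only print their floor (0.0002 at
N = 10,000), not their formula; this convention is *declared*, chosen
because it is a valid (conservative) permutation p-value and reproduces that
floor exactly. The implementation avoids materializing 10,000 interval sets:
shuffled placements are drawn vectorized and tested against a sorted merged
annotation index via binary search, which is what keeps 10,000 permutations
in the sub-second range at desk scale.

TF-panel tests optionally mask HOT (high-occupancy target) regions first,
removing both peaks and TF sites that touch them, so promiscuous loci do not
drive the ranking.

## Profiles and GC

Anchored profile matrices take the median signal in 50 bp bins across
±750 bp (a 1.5 kb window) around summits, rows ordered by decreasing summit
score; TSS metagene curves average across genes per expression class (top
vs bottom quartile by default). The "95% confidence" band of the source
figures is unspecified; the default band is the normal approximation
`mean ± 1.96·sd/sqrt(n)` across genes, with a bootstrap percentile band as
an option, and the choice is recorded in the output metadata. GC content is
computed per base as the GC fraction of a centered 15 bp sliding window
(7 bp each side; windows truncated at chromosome ends; non-ACGT bases count
as non-GC and are tallied). Summit GC profiles carry a control computed the
same way over 1,500 uniformly drawn positions under a caller-supplied seed.
Bases that fall off a chromosome end are treated as missing and excluded
from their bin's summary, never zero-filled.

## Expression and differential expression

Per-gene expression is the median of replicate FPKM values. Promoter signal
is the median enrichment in the 500 bp strand-aware window upstream of the
TSS (500 bp for signal/correlation analyses, 1 kb for annotation overlap —
both appear in the source analyses and both are config values).
Binding–expression association is Spearman rank correlation. A gene is
"bound" iff a peak summit lies within 1 kb of its TSS; the source text is
ambiguous between upstream-only and symmetric, so the default is the
symmetric ±1 kb window with an `upstream_only` switch. The DE × binding
summary cross-tabulates an externally supplied DE table (gene, direction)
against bound flags with row percentages; fitting the DE model itself is
out of scope by design.

## Motifs

De-novo discovery is out of scope; the module accepts a PWM or consensus
string (the condensin motifs share a GCGC core, the X-specific one extended
by AGGG). The biophysical-affinity scanner used by the source analyses has
no published parameters, so scanning is standard log2-odds over both strands
with a declared threshold, defaulting to 80% of the maximal attainable
score. Because the threshold is ours, the motif-context statistics (fraction
of motifs bound, its increase inside mark-enriched 2 kb windows, the ~2.5×
clustering effect of >= 2 motifs per 1 kb window) are *structural* targets
recovered on synthetic truth, not numeric reproductions. The clustering
effect conditions on non-overlapping 1 kb tiles, assigning each motif hit to
the tile containing its midpoint.

## Chromatin features and classification

Track correlation uses the median signal in 1 kb windows, Pearson
correlation, and hierarchical clustering on the distance 1 − r. The linkage
is not stated in the source; average linkage is the default and exposed.
Bound/unbound classification uses 250 bp windows labeled by >= 1 bp overlap
with consensus peaks. Feature importance is the mean decrease in held-out
accuracy when one feature's values are permuted, averaged over repeats, on
a stratified 70/30 split. The classifier is injected through a fit/predict
contract; the classical choice is a random forest of 10,000 trees, but no
forest implementation is assumed present, so the default plug-in is
plain logistic regression — for the recovery questions asked
here (which features carry signal at all) the two agree, and the contract
makes the forest a drop-in. The out-of-bag variant of importance is noted
as an alternative; held-out is the default.

## The synthetic world

The generator emits the full input bundle (FASTA, chrom.sizes, GFF3,
per-subunit replicate wiggle tracks plus inputs, BED truth peaks, TF BEDs,
HOT regions, expression and DE tables) under one master seed, with derived
stage seeds, so byte-identical reruns are a tested property. Its defaults
are a fixed stated world:

* 5 autosomes + X of 200 kb each (≈1/100 of the real ~100 Mb genome) plus
  a 10 kb excluded mitochondrial chromosome; ~36% background GC (the
  *C. elegans* genome-wide value), elevated to 55% within ±100 bp of
  summits.
* ~50 genes, 8 tRNAs, 12 ncRNAs and 10 intergenic enhancer candidates per
  chromosome; the top expression quartile of genes is "active".
* True peaks arise at 20% of active promoters, 30% of tRNAs and 50% of
  enhancer candidates; widths ~N(400, 80²) bp (sequencing fragments are
  200–800 bp); per-peak heights log-normal around 5-fold over a Poisson
  background of mean 10×.
* Coverage is Poisson with a Gaussian bump (sd = width/4) per peak — the
  read-level shape is not specified by any source and downstream code only
  needs summits and enrichment to be recoverable; replicates share true
  peaks and differ by Poisson resampling plus multiplicative per-peak noise
  (sd 0.3), with optional per-replicate dropout to exercise the majority
  filter.
* The X-specific complex binds X candidates at the configured rates and
  autosomal candidates at rate/`x_bias`. The default `x_bias = 160` makes
  ~97% of its sites X-linked — the empirically observed specificity — at
  any genome scale. (A pure placement-odds reading of a bias parameter
  cannot exceed `x_bias·nX/(x_bias·nX + nA)` and would silently saturate on
  small genomes; the per-candidate-rate mechanism does not.)
* Expression is log-normal; in *shift* mode active and bound genes get
  additive log shifts (+3, +0.5), producing a positive binding–expression
  rank correlation mechanistically. In *copula* mode a target Spearman rho
  is planted directly against a supplied binding covariate via a Gaussian
  copula (`r = 2 sin(pi * rho / 6)`), which is what the rho-recovery tests
  use. DE tables sample genes whose direction is up with probability 0.83
  if bound and 0.67 otherwise, mirroring the repressive-complex structure.

What the generator does **not** emulate: mappability and blacklist
structure, fragment-length effects, GC amplification bias, copy-number
variation, and realistic annotation geometry (operons, nested genes). A
green test therefore establishes that the *statistical machinery* is
correct and parameters are recoverable from data with the assumed
structure — not that any biological conclusion would replicate on real
sequencing data.

## Numerical conventions and degenerate inputs

Internal coordinates are the Bioconductor `GRanges` convention (1-based
closed); BED enters and leaves through `rtracklayer` conversion, which is
equivalent to the 0-based half-open internal convention originally
envisioned and eliminates hand-rolled off-by-one risk. Outputs sort by
(chromosome, start) with lexicographic chromosome order. Summit ties break
leftmost; valley positions take the leftmost deepest base. All stochastic
operations either take an explicit seed or restore the caller's RNG state.
Regions with non-positive wild-type means are excluded from mutant/WT
ratios and counted; genes whose promoter window falls entirely off its
chromosome are skipped and logged; windows with no in-bounds bases are
`NA`, not zero.

## Known limitations

* The split rule and the empirical-p convention are declared package
  contracts, faithful in spirit but not guaranteed bit-compatible with the
  unpublished tools they replace.
* The permutation null is uniform placement; GC- or accessibility-matched
  nulls are deliberately out of scope.
* `n = 10,000` permutations bounds the reportable p at 0.0002; smaller
  p-values require more permutations.
* The default classifier is linear; interactions among chromatin features
  would need the random-forest plug-in.
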