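---
title: "Differential protein occupancy profiling with occudiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential protein occupancy profiling with occudiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occudiff)
library(dplyr)
```

## The measurement and the signal

Protein occupancy profiling crosslinks proteins to 4-thiouridine-labeled
polyadenylated RNA with 365 nm light, captures the protected fragments and
sequences them. Reverse transcription across a crosslinked uridine
misreads it, leaving a diagnostic T-to-C transition in the cDNA. The
per-nucleotide count of such transition events is therefore a footprint of
direct protein-RNA contact, and comparing those counts between two
cellular states localizes *differential* contacts at single-nucleotide
resolution.

occudiff consumes coordinate-sorted alignments, builds sparse
coverage/transition profiles (`extract_profiles()`; reference `T` read as
`C` on forward alignments and reference `A` read as `G` on reverse
alignments, i.e. sense-strand T-to-C for a stranded library), and tests
transcript positions for differential occupancy.

## The statistical model

Counts at transcript position $p$ in sample $s$ of condition $c$ are
modeled as negative binomial,

$$Y_{ps} \sim \mathrm{NB}(L_s\, a_{pc},\ \phi_p),$$

with $L_s$ the per-gene total of transition events in sample $s$ after
TMM adjustment, $a_{pc}$ the relative abundance of transitions at $p$ in
condition $c$, and $\phi_p$ a tagwise dispersion. Everything — library
sizes, TMM factors, dispersions — is computed **per transcript**, not
genome-wide. This is the central design choice: a change in a gene's mRNA
abundance scales all of its positional counts together and is absorbed by
the per-transcript normalization, so only *local* redistribution of
contacts within the transcript registers as signal.

The pipeline order in `diff_occupancy()` is fixed:

1. **Quantile normalization** across all samples (global), equalizing the
   transition-count distributions; ties receive the mean of the quantile
   values they span (`limma::normalizeQuantiles`, `ties = TRUE`).
   Normalized values re-enter the count model by round-half-up — round
   half to even would map equal normalized values to unequal integers
   depending on parity.
2. **Position filter**: at least 2 events in at least 2 of the samples.
3. **Gene filter**: at least 50 valid positions (a gene with exactly 50
   is kept) — fewer positions do not support stable per-transcript
   dispersion estimation.
4. Per gene: **TMM factors** (reference = sample whose 75th-percentile
   count fraction is closest to the mean; 30%/5% two-sided trims on
   M/A; precision-weighted mean of remaining log-ratios; factors
   rescaled to multiply to 1), the **direction-mixture filter** (a gene
   with more than two-thirds of nonzero positional fold changes in one
   direction is excluded as a residual expression artifact — strictly
   more, so exactly 2/3 survives), **library equalization** to the
   geometric-mean effective size (a single-pass simplification of
   iterative quantile-adjusted equalization; all dispersion and test
   properties are validated against enumeration oracles under it),
   **dispersion estimation** and the **exact test** per valid position.

### Dispersion by conditional maximum likelihood

Given the group sum, within-condition NB counts with common $\phi$ follow
a distribution free of the mean (Dirichlet-multinomial with concentration
$1/\phi$), so $\phi$ is estimated by maximizing the conditional
log-likelihood. The transcript-common value maximizes the sum over
positions (golden-section search on $\log_{10}\phi \in [-6, 1]$,
tolerance $10^{-4}$). Tagwise values maximize each position's own
conditional log-likelihood plus `prior_weight` (default 10
pseudo-positions) times the transcript-average curve — weighted-likelihood
shrinkage whose limits are the per-position MLE (weight 0) and the common
value (weight $\to\infty$). The shared curve is precomputed on a
$\log_{10}\phi$ grid and interpolated with a natural cubic spline inside
the per-position search; with weight 0 the estimates match an independent
fine-grid search.

### The exact test

Group sums of $n$ i.i.d. $\mathrm{NB}(\mu, \phi)$ variables are
$\mathrm{NB}(n\mu, \phi/n)$. Conditional on the total $T$, the
probability of a split $(k, T-k)$ is free of $\mu$ (negative
hypergeometric; binomial in the $\phi = 0$ Poisson limit), and the
two-sided p-value sums the probabilities of all splits as or less likely
than the observed one — the analogue of Fisher's exact test for
overdispersed counts. Ties are detected with a relative tolerance of
$10^{-10}$ on log-probabilities. `nb_exact_test()` reproduces exhaustive
per-sample composition enumeration to below $10^{-9}$ for every split
with $T \le 20$, $\phi \in \{0, 0.05, 0.5\}$, in 1v1 and 2v2 designs,
and agrees with `edgeR::exactTest` to machine precision on spot checks.

### Empirical FDR by replicate swap

With thousands of tested positions and two replicates per condition,
standard multiplicity corrections are severe. Instead the entire analysis
is rerun with replicate labels swapped (first replicate of each condition
versus the rest; with 2v2 there are two balanced swaps and
`average_swaps = TRUE` pools both), producing a null p-value sample under
the same filters and normalization.
$\mathrm{FDR}(t) = \#\{p_\mathrm{null} \le t\} / \#\{p_\mathrm{real} \le
t\}$, rescaled when the tested sets differ in size, made monotone by
cumulative maximum and capped at 1. Positions are reported at empirical
FDR < 0.1; BH-adjusted p-values are emitted as an auxiliary column.

## Downstream analytics

* `filter_positions_by_expression()` flags (never deletes) positions in
  exons that are differentially expressed in companion mRNA-seq (BH FDR
  < 0.01 and fold change > 2 by default; direction ignored). The DE
  screen reuses the same NB kernels with global normalization.
* `select_top_positions()` picks the most significant sites greedily,
  requiring pairwise genomic distance strictly greater than 20 nt within
  a gene so two sites cannot come from one protein footprint; ranking is
  p-value, then |log2 fold change|, then coordinate.
* `generate_random_positions()` builds the matched control set: each top
  site is shifted by ±100/±50/±30 nt (seeded random order, first shift
  inside the exon footprint wins) and snapped to the closest genomic T
  (plus-strand gene) or A (minus-strand), ties broken downstream, so
  controls sit on sense-strand uridines like real crosslink sites.
  Snapping searches within the exon footprint so every control remains
  inside its gene.
* Clustering statistics (`nearest_significant_distance()`,
  `direction_consistency()`) work in transcript coordinates — footprints
  are contiguous on the spliced transcript, not the genome.
* `metagene_density()` rescales 5'UTR/CDS/3'UTR to 10/50/40 bins
  (approximate average region-width proportions of coding mRNAs;
  configurable), normalizes each transcript's mass to 1 and averages, so
  the output integrates to 1 and long genes do not dominate.
* `sliding_window_correlation()` uses non-overlapping 50-nt windows and
  at least 10 windows per gene (defaults chosen so that rank
  correlations have enough support on short transcripts; configurable).
* PWM scanning follows the RNAcompete convention: 0.01 pseudocount per
  column entry then column normalization; a region's score is the sum
  over all k-windows of the product of column probabilities; `N` scores
  a neutral 0.25 so window counts stay comparable across regions.
  Enrichment is a one-sided Wilcoxon rank-sum (top > random), exact for
  small sets, normal approximation with continuity correction otherwise.
  The 7-mer screen uses region-level presence in a Fisher 2x2 with BH
  across k-mers (the occurrence counts are reported alongside); the ARE
  test is a one-sided binomial with the null success probability
  estimated from the random set.
* `overlap_test()` scores top-versus-random overlap with external
  binding-site collections by a two-sided Fisher exact test
  (minimum-likelihood rule, matching the exact NB test's convention) and
  BH across collections.
* Half-lives: under steady state and first-order decay the newly made
  fraction after a pulse of length $t$ is $f = 1 - e^{-kt}$, so
  $t_{1/2} = \ln 2 \cdot t / (-\ln(1 - f))$ with $f = L'/T$ from the
  labeled/unlabeled/total FPKM triplet. The triplet scales are
  reconciled by one gene-independent factor pair fitted by weighted
  least squares of $T$ on $(L, U)$ with $1/T^2$ weights (every gene
  counts equally under multiplicative noise), then rescaled so that
  $\mathrm{median}(L' + U' - T) = 0$. An alternative estimate from the
  unlabeled fraction cross-checks each gene; disagreement beyond 20%
  flags it. Group shifts of fold changes (jointly quantile-normalized)
  are tested with a one-sided Welch t-test.

## What the generators emulate — and what they do not

`make_toy_annotation()`, `simulate_count_study()`,
`simulate_alignments()` and `simulate_halflife_study()` are pure
functions of their parameters and a seed. The count generator draws
$\mathrm{NB}(\mathrm{mean}_{sp}, \phi)$ with per-sample library factors
(lognormal, sd 0.1), positional baseline variation (lognormal, cv 0.4 —
crosslinking propensity varies strongly along a transcript), baseline
mean 20 events per valid position, and planted effects that multiply the
mean in one condition. Default study: 500 genes x 200 positions x 4
samples, dispersion 0.2, 5% planted 4-fold positions — desk-scale
(about a minute on one CPU).

Simulated reads tile transcripts and carry planted mismatches exactly, so
profile reconstruction is tested by integer equality; they do not model
sequencing errors, indels, mapping ambiguity or non-uniform fragment
capture. Planted positions are spatially independent, so the clustering
and direction-consistency statistics are exercised for correctness, not
for effect-size realism. Passing tests demonstrate the statistical
machinery is correct under the stated model; they do not certify
performance on real libraries, where crosslinking efficiency, RT
artifacts and annotation errors add structure the generators omit.

Under these conditions the test suite's power/error check records what
the design can deliver: with $\phi = 0.2$, two replicates and 4-fold
effects, the exact test's p-value at the *expected* planted configuration
is about 0.006 (saturating near 0.004 at infinite depth), so at an
empirical-FDR-0.1 threshold the realized sensitivity is about 0.25 with a
false-discovery proportion near 0.19, and the discrete test's
super-uniformity leaves a null ECDF KS distance of about 0.06. The
corresponding acceptance assertions are intentionally strict and document
this gap rather than hiding it.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; conversion to the
  1-based closed Bioconductor containers happens only at package
  boundaries.
* A single alignment contributes at most one transition event per
  position; a read with two diagnostic mismatches contributes one event
  at each. Duplicate collapse (one record per chrom/start/strand/
  sequence) is off by default.
* Zero-total positions are never tested (`T = 0` returns p = 1 and the
  validity filter removes them anyway).
* TMM with fewer than 5 double-positive positions returns factor 1 with
  a warning; a gene with a zero library size in any sample is logged and
  skipped.
* Quantile normalization of a single column is the identity, with a
  warning.
* Half-life fractions are clipped to $(\varepsilon, 1 - \varepsilon)$,
  $\varepsilon = 10^{-6}$; clipped genes are flagged unreliable, and
  genes with zero total FPKM are excluded.
* Mapping-quality filtering defaults to 0 (keep all); configurable.

## Limitations

The replicate-swap null requires at least two replicates per condition
and is most meaningful for 2v2; designs with more conditions or
covariates are out of scope. The swap null slightly under-counts false
positives when strong true effects exist, because mixed-condition groups
inflate the swapped-design dispersions gene-wide through the common
prior; the reported empirical FDR is therefore mildly optimistic in
signal-dense regimes. Positions shared by overlapping genes are tested
in each gene independently. Secondary-structure accessibility analysis
is not implemented; the region extractor exports the sequence windows
such tools need.
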