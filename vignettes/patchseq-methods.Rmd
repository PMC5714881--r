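---
title: "Models and methods behind patchlink"
author: "patchlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patchlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchlink)
```

patchlink implements the computational side of a patch-seq workflow: single
neurons are labeled in vivo, patched in acute slices, and their RNA harvested
through the pipette for CEL-seq-style sequencing with 6-nt UMIs and 6-nt cell
barcodes. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Quantification

CEL-seq retains one molecule per transcript, so molecule counts (distinct
UMIs per gene and cell, exact string match, no UMI error correction) are
normalized as transcripts per million: each cell's counts over the
normalization gene set are scaled to sum to 10^6. Spike-in rows are excluded
from the denominator by default because the endogenous fraction varies from
cell to cell; `tpmNormalize(includeSpikeIns = TRUE)` switches this off, which
is also the natural setting for spike-only plates.

Genes are kept when tpm exceeds 5 — a strict inequality, so a gene sitting
exactly at 5 is dropped. The rule is evaluated per cell and a gene survives
if *any* cell exceeds the threshold (maximally inclusive); requiring the
across-cell mean to exceed it is available via `aggregate = "mean"`. tpm is
not renormalized after filtering, so filtering is idempotent. Downstream
correlation analyses use `log10(tpm + 1)` z-scores per gene; the base and
pseudocount are our choice (the transform is only described as
log-normalization in the protocols this follows), and genes constant across
cells get all-zero rows rather than NaNs.

## Spike-in model and detection efficiency

Every spiked molecule is assumed captured independently with probability
`p`, giving the detection curve

> P(detected | n molecules) = 1 − (1 − p)^n.

`detectionEfficiency()` is the plain detected-to-spiked ratio, pooled by
weighting samples by their spiked totals (the grand ratio), with per-sample
and per-species values alongside. `fitDetectionEfficiency()` inverts the
curve by least squares, reducing to the exact algebraic inversion
`p = 1 − (1 − f)^(1/n)` for a single point. At p = 0.125 the model gives a
48.7% chance of detecting one of five molecules:

```{r}
detectionProbability(5, 0.125)
```

UMI collisions are simulated explicitly: detected molecules draw UMIs
uniformly from the 4^6 = 4096 space and unique UMIs are counted, so at high
per-species molecule numbers the observed efficiency is biased slightly
downward. The default synthetic design (`defaultSpikeInDesign()`) spreads
10^4 molecules over 92 species on a geometric dilution series spanning three
decades, which keeps per-species collision loss negligible — the
configuration a real ERCC mix approximates.

## Technical noise and variable genes

Spike-ins are added equally to every sample, so their variability is purely
technical. Across spike species the squared coefficient of variation is
fitted as

> CV²(μ) = a₁ / μ + a₀

by a gamma-family GLM with identity link (falling back to ordinary least
squares when the gamma fit is degenerate, e.g. exact zeros), using species
above the 40th percentile of mean expression — low-mean species carry almost
no information about a₀ and destabilize the fit. For Poisson counts a₁ ≈ 1
and a₀ ≈ 0; a₁ is expressed in the units of the supplied means, so the fit
should be made on the same scale as the matrix being tested.

A gene is called more variable than noise when its observed variance exceeds
the technical expectation inflated by a minimum biological CV of 50%
(`minBioCV = 0.5`): the statistic `(n − 1) · var_obs / (μ²(a₀ + 0.25) +
a₁μ)` is referred to a chi-square with n − 1 degrees of freedom and adjusted
by Benjamini–Hochberg at FDR 0.1 (the published approach this follows leaves
the significance level unstated; 0.1 is our configurable default). The
minimum-CV inflation makes the test conservative on purely technical data —
the flagged fraction in calibration simulations sits well below the nominal
FDR — and concentrates power on genes whose biological CV is at least ~50%.

## Contamination

**Cross-species (library) contamination.** Rat neurons are processed in
parallel with mouse neurons; reads from all cells are mapped to the rat
mitochondrial genome after masking. `maskSharedKmers(k = 40)` replaces with
N every target position covered by a 40-mer that occurs in the reference on
either strand. This coverage-masking is the strictest reading of "shared
identical stretches shorter than 40 bases": afterwards no shared 40-mer
exists at all, which yields a small theorem — an error-free read of length
≥ 41 drawn from the reference contains a 40-mer, so it can never match the
masked target exactly. With 43-nt reads the zero-mapping guarantee is exact,
and the tests verify it both by brute-force shared-k-mer scans and by
exhaustively mapping every reference 43-mer. Mapping is exact full-length
matching on either strand (`mapReadsExact()`); mismatches, indels and
circular mitochondrial topology are deliberately out of scope, and masking
treats the sequences as linear — a documented limitation.

Per-cell contamination is the mouse cell's mapped read count divided by the
summed mapped reads of all rat cells (when several rat cells are present
their counts are pooled), with the median reported across mouse cells.
Reads lost to masked regions affect numerator and denominator alike, so the
ratio still recovers the injected hop rate.

**Tissue (harvest) contamination.** GABAergic and glutamatergic neurons are
intermingled but express disjoint markers. With S = tpm(Slc17a7) and G the
arithmetic mean of tpm(Gad1), tpm(Gad2), tpm(Slc32a1), the GABAergic
contamination of a glutamatergic cell is `1 − S/(S+G) = G/(S+G)`, and
symmetrically for GABAergic cells. The mean-of-three reading of the marker
aggregate is the default; the pooled-sum reading (3× larger G) is available
via `gabaAggregate = "sum"`. The estimate is a per-cell ratio, hence
invariant to that cell's scale, and cells with S + G = 0 are reported
missing rather than zero.

## Sigma-scores and the shuffle separation test

For each gene, with per-group means and (n−1) sample variances,

> σ(g) = |mean_A − mean_B| / sqrt((var_A + var_B) / 2).

The printed source formula is typographically ambiguous about its
denominator; the default above is the dimensionally consistent d-prime form,
and `form = "literal"` provides the alternative that divides by the variance
average itself. Genes with zero pooled variance get σ = 0 when the means
also agree and an infinite sentinel otherwise; sentinels rank first but are
excluded (and counted) in score comparisons, since their value is not a real
number. Ranking is descending with lexicographic tie-breaks, so it is fully
deterministic.

The separation test compares the top-250 sigma-scores of the original
labeling against those of proportionally reshuffled labelings (each
labeling's own top-250), via a two-sided Mann–Whitney U test. Exact
enumeration (no ties, n_A·n_B ≤ 10 000) is used where feasible; otherwise
the tie-corrected normal approximation is evaluated through the log survival
function of the standard normal, so complete separation at 250 vs 250 yields
its closed-form value log₁₀ p = −82.65 rather than underflowing to zero.
Verdicts follow the two significance bands: *distinct* when the median
log₁₀ p over reshuffles is below −70, *similar* when every reshuffle stays
above −10, *indeterminate* between — the median is used because single
reshuffles fluctuate. The number of reshuffles defaults to 100
("multiple times" is otherwise unquantified); 10–20 suffice in practice and
are what the test suite uses. Sidedness is our choice: two-sided, the
conservative default.

Note that k = 250 interacts with the gene count: even complete separation of
top-k sets caps log₁₀ p at the k-vs-k Mann–Whitney bound (≈ −66.5 at
k = 200), so the −70 band implicitly assumes k = 250.

## Tuning classification

dF/F is `(F − F0)/F0` with F0 the mean of the 2-s gray baseline preceding
each 4-s grating, at 2 frames/s (4 baseline, 8 stimulus frames). Per-direction
responses are means over ≥ 8 trials (fewer is an error), summed over the 8
directions without rectification. A cell is tuned when one stimulus's sum is
at least 4× the other's, with a negative competitor floored at 0 — otherwise
the ratio is ill-defined.

Two points the 4× rule leaves open are resolved here as package design
choices:

- *Dual responders.* Cells responding significantly to both stimuli are
  excluded. "Significant" is undefined upstream; we use z > 3: the summed
  response must exceed 3 standard deviations of what baseline noise alone
  would produce in that sum. The noise propagation includes the variance of
  estimating F0 from only 4 baseline frames (var of a trial's mean dF/F ≈
  σ²(1/n_stim + 1/n_base)), which is the dominant term at short baselines.
- *Unresponsive cells.* The ratio rule compares only the two sums and is
  blind to their absolute size, so a silent cell would be called tuned by
  the sign of its noise roughly half the time. `classifyTuningCells()`
  therefore also requires the winning stimulus to be significant
  (`requireSignificant = TRUE`); the raw `classifySpeedTuning()` operation
  keeps the pure ratio semantics. With the gate, the residual false-tuned
  rate for silent cells is the z > 3 tail (~0.3% per cell) rather than ~50%.

## What the generators emulate — and what they do not

The synthetic-data module generates every input with recorded ground truth:

- *Counts*: negative binomial with variance μ + φμ², the accepted
  single-cell count model (no particular expression distribution is implied
  by the workflow itself — this is our choice). Defaults are the study conditions: 5,000 genes, 65 + 65
  cells, 300 markers at 8-fold change, dispersion 0.5; per-gene means are
  log-uniform over 0.1–100 molecules, giving realistic per-cell totals of
  ~10⁴–10⁵ molecules. The fold change multiplies marker means in the first
  group only (not split between groups), which keeps the planted truth
  directly interpretable. Four class marker genes (Slc17a7 vs
  Gad1/Gad2/Slc32a1) are planted with zero opposite-class baseline so pure
  cells have exactly zero opposite-class signal.
- *Ambient contamination* adds opposite-class marker molecules as Poisson
  draws with mean `own_level · f/(1 − f)`, which makes the marker
  estimator's expectation equal the planted fraction f exactly (the ratio's
  Jensen bias is second-order and negligible at the planted levels).
- *Genome pairs* are uniform random sequences with planted exact homology
  blocks; a rejection check guarantees no accidental shared 40-mer beyond
  the planted ≥ 40-nt blocks, so masking outcomes are exactly predictable.
- *Read sets* are error-free 43-nt substrings of the cell's own species'
  genome, either strand; rat reads hop to a uniformly chosen mouse barcode
  with the configured probability. Sequencing error is deliberately absent —
  the masking logic is about exact homology, and error modeling would only
  blur the planted truth.
- *Tuning traces* are Gaussian noise around a constant baseline with an
  additive dF/F response at every direction of the preferred stimulus.

Not emulated: amplification bias beyond a single capture probability,
gene-length or GC effects, doublets, splice variants and non-coding classes,
spatial tissue structure, direction (as opposed to speed) tuning, and
sequencing error. Passing recovery tests therefore demonstrates the
estimators' correctness under their own model assumptions, not robustness to
every artifact of real data.

## Problem sizes and reproducibility

Every generator takes an explicit seed and restores the caller's RNG state,
so all results in the tests, the pipeline report and the acceptance script
are bit-reproducible. The test suite runs the separation test at the full
study scale (5,000 × 130), 50 null replicates for the similarity band,
20 seeds per hop rate at 10⁵–2×10⁵ rat reads for cross-contamination
recovery (more reads at the lowest rate so the expected hop count stays in
the tens), 100 seeds for efficiency recovery, and exhaustive rank-sum
enumeration up to group sizes of 7 — sizes at which each property is sharply
testable while the whole suite stays in the minutes range.

`runPipeline()` chains all stages at the study scale and logs every derived
seed in its JSON report; rerunning with the same configuration reproduces
the report byte for byte.
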