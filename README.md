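# patchlink

Quality control and differential expression for **patch-seq** experiments —
single neurons labeled *in vivo* (by position, axonal projection, or visual
response properties), patch-clamped in acute slices, and their RNA harvested
through the pipette for CEL-seq-style single-cell RNA sequencing.

Patch-seq transcriptomes are shallow and contamination-prone, and typical
comparisons involve tens of cells per population, so the analysis needs its
own machinery:

- **Quantification** — UMI-based molecule counting (6-nt UMI + 6-nt cell
  barcode tag reads), transcripts-per-million (tpm) normalization, a strict
  `tpm > 5` expression filter, and the `log10(tpm + 1)` z-score transform.
- **Spike-in QC** — ERCC-style detection efficiency, the per-molecule
  binomial detection model `P(detect | n, p) = 1 − (1 − p)^n`, a
  `CV² = a₁/μ + a₀` technical-noise fit, variable-gene calling against that
  fit with a minimum biological CV of 50%, and sample-correlation summaries.
- **Contamination** — two estimators: (i) cross-species barcode
  contamination, mapping 43-nt reads to a rat mitochondrial genome whose
  k-mers shared with the mouse genome have been masked at `k = 40` so mouse
  reads cannot map at all; (ii) marker-based tissue contamination from
  GABAergic (Gad1, Gad2, Slc32a1) vs glutamatergic (Slc17a7) marker shares,
  `contamination = G / (S + G)` for a glutamatergic cell.
- **Differential expression** — the per-gene sigma-score
  `σ(g) = |mean_A − mean_B| / √((var_A + var_B)/2)`, descending ranking,
  proportional label shuffling, and a Mann–Whitney U test (computed in log
  space, so p-values like 10⁻⁸³ are representable) comparing the top-250
  sigma-scores of the original vs shuffled labelings. Verdict bands:
  *distinct* when the median log₁₀ p < −70, *similar* when all reshuffles
  stay above −10.
- **Tuning** — dF/F against a 2-s gray baseline at 2 frames/s, trial
  averages over ≥8 trials, sums over 8 grating directions, and the 4-fold
  rule classifying cells as high-speed or low-speed tuned.
- **Synthetic data** — negative-binomial two-population count matrices with
  planted markers, spike-in plates with known capture, genome pairs with
  planted exact homology blocks, barcoded read sets with a known hop rate,
  and dF/F trace sets — each with recorded ground truth, so every estimator
  is validated by parameter recovery.

## Worked example

Simulate the standard comparison — 65 + 65 cells, 5,000 genes, 300 marker
genes at 8-fold change — quantify, and test population separation:

```r
library(patchlink)

sim  <- simulateTwoPopulations(simConfig(seed = 1))
expr <- filterExpressedGenes(tpmNormalize(sim$counts), threshold = 5)

res <- shuffleSeparationTest(expr, k = 250, nShuffles = 20, seed = 2)
res
#> ShuffleTestResult: top-250 sigma-scores vs 20 proportional reshuffles
#>   log10 p: median -82.65 (range -82.65 .. -82.65)
#>   verdict: distinct
```

The two planted populations separate completely: every reshuffle's top-250
sigma-scores sit entirely below the original's, giving the saturated
250-vs-250 Mann–Whitney value log₁₀ p = −82.65, far past the −70 "distinct"
band. The ranking itself puts planted structure on top — 98.4% of the
top-250 genes are planted markers (class markers rank first):

```r
head(as.data.frame(rankGenes(sigmaScores(expr)))[, c("gene", "sigma", "rank")], 3)
#>    gene    sigma rank
#> 1  Gad1 2.417846    1
#> 2  Gad2 2.322424    2
#> 3  gene00458 2.189656    3
```

The spike-in detection model reproduces the characteristic shallow-coverage
operating point — with ~12.5% per-molecule efficiency, five spiked molecules
are detected about half the time:

```r
detectionProbability(5, 0.125)
#> [1] 0.4870911
```

`runPipeline(pipelineConfig(seed = 1))` runs every stage (simulate →
quantify → spike-in QC → contamination → differential expression → tuning)
and returns a machine-readable report.

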