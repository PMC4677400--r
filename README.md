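# miRescue

Quantification of miRNA-mediated transcriptome rescue.

## The problem

In a rescue experiment, a single regulator — for example a miRNA mimic
co-injected with a morpholino knockdown in zebrafish embryos — is tested
for its ability to return a perturbed transcriptome toward the control
state. The design has three conditions (control, perturbed, perturbed +
treatment) profiled in a few biological replicates, preceded by a
small-RNA sequencing screen that nominates the miRNA. miRescue is for
analysts of such experiments: it implements the complete downstream
quantification as composable, tested R functions.

## The statistics at its core

* **Small-RNA screen** — rpm normalization
  (`counts / library size × 10⁶`) and the two-filter rule: group-mean
  fold change ≥ 1.8 in either direction *and* max group mean > 200 rpm.
* **Differential expression** — gene-level moderated t-tests (limma; plain
  Welch optional) on log2 intensities; DE call `2^|Δ| > 1.3`, `p < 0.05`,
  BH `q < 0.05`.
* **Rescue quantification** — over D₁ ∩ D₂ (the two DE sets), each gene
  gets coordinates `x = log2FC(perturbed vs control)`,
  `y = log2FC(treated vs perturbed)` and a quadrant label (QII: up then
  down; QIV: down then up — the inversely modulated quadrants). Summary
  metrics: `fraction affected = |D₁∩D₂| / |D₁|`,
  `fraction inverse = (|QII|+|QIV|) / |D₁∩D₂|`, and the Pearson r of
  (x, y).
* **Targets** — canonical seed-match prediction over 3'UTRs (6mer,
  7mer-A1, 7mer-m8, 8mer; longest type wins) and exact hypergeometric
  tails `P(X ≥ k)` / `P(X ≤ k)` per quadrant against a background
  universe.
* **Global structure** — correlation-distance/average-linkage sample
  dendrograms with multiscale-bootstrap AU support (probit fit of
  `Φ⁻¹(1−BP_r) = v√r + c/√r` over resample scales, `AU = 100(1−Φ(v−c))`),
  covariance PCA of log2 values, and top-decile |loading| probe
  selection.
* **Synthetic data** — a generator that plants perturbation effects,
  a rescue fraction with near-total inverse modulation, target flags with
  a known odds ratio, miRNA fold changes, and UTR seed sites — all
  recorded in a truth manifest for recovery testing.

## Worked example

```r
library(miRescue)

sim <- simulateExpression(SimulationParams(seed = 7))
g   <- summarizeProbes(sim$se)
cond <- as.character(SummarizedExperiment::colData(sim$se)$condition)
s    <- colnames(sim$se)

c1 <- runContrast(g, s[cond == "control"],   s[cond == "perturbed"])
c2 <- runContrast(g, s[cond == "perturbed"], s[cond == "treated"])
qt <- buildQuadrantTable(c1, c2)
m  <- rescueMetrics(qt, nAltered = length(callDE(c1)))
str(m[c("nAltered", "nIntersect", "fractionAffected",
        "fractionInverse", "pearsonR")])
#> List of 5
#>  $ nAltered        : int 7949
#>  $ nIntersect      : int 4829
#>  $ fractionAffected: num 0.607
#>  $ fractionInverse : num 0.984
#>  $ pearsonR        : num -0.956
quadrantCounts(qt)
#>   QI  QII QIII  QIV
#>   39 2380   40 2370
```

Of the 7949 genes altered by the perturbation, 60.7% also respond to the
treatment; 98.4% of the responders move in the opposite direction
(quadrants QII and QIV), and the two fold changes are strongly
anticorrelated (r = −0.96) — the generator planted a 0.60 rescue fraction
with a 0.987 inverse-modulation rate, so the pipeline recovers the study
structure it was built to measure. `runPipeline(pipelineConfig(seed = 7))`
runs the same stages plus the miRNA screen, target enrichment, AU
clustering and PCA from one configuration and writes per-stage TSVs, a
Newick dendrogram and a JSON report.

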