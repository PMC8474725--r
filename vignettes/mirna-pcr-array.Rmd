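---
title: "miRNA PCR array analysis with miRct: methods and modelling choices"
author: "miRct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA PCR array analysis with miRct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRct)
```

# The data and the problem

A miRNA PCR array in the miScript 384-well format profiles 372 mature
miRNAs per sample by RT-qPCR, with 12 wells reserved for controls: two
replicate cel-miR-39 spike-ins, six snoRNA/snRNA endogenous controls
(SNORD61, SNORD68, SNORD72, SNORD95, SNORD96A and RNU6B), two replicate
miRTC reverse-transcription controls (RTC) and two positive PCR controls
(PPC). The raw observation per well is a threshold cycle Ct — the PCR
cycle at which fluorescence crosses a detection threshold — on a log2
scale: one cycle lower means roughly twice as much template. Wells that
never cross the threshold are reported as "not detected".

miRct takes the three standard inputs — the Ct count table (wells ×
samples), the well annotation linking each well to its assay, and the
sample sheet mapping sample to group — and carries them through sample
QC, normalization, differential expression and functional annotation.
Multiple plates per sample set are concatenated by (plate, well) key and
replicate assay wells are collapsed later by averaging.

# Quality control

Two sample-level checks are applied, in this order, and both statistics
are always recorded for every sample:

* **Missingness.** The fraction of not-detected miRNA wells per sample
  must not exceed `maxNaFraction` (default 0.10). The denominator covers
  the 372 miRNA wells only: dropout of *control* wells is diagnosed by the
  RT check below, and counting it here would penalise the same failure
  twice. The denominator choice is a configuration switch (`mirnaOnly`)
  for users who prefer the whole plate.
* **RT efficiency.** The RTC assay amplifies an artificial RNA template
  (so it fails when reverse transcription fails), while the PPC contains a
  pre-dispensed DNA target (so it fails only when PCR itself is
  inhibited). We compare them as the Ct difference
  mean Ct(RTC) − mean Ct(PPC), in cycles, with pass threshold 5. The
  vendor literature phrases the criterion as a "ratio", but Ct is already
  a log quantity — a literal quotient of cycle numbers has no physical
  meaning, and the conventional criterion is a ΔCt. We therefore default
  to the difference form with the published threshold of 5, and expose
  both the form (`rtForm = "difference" | "quotient"`) and the threshold
  so users can match whichever rule their kit documentation states.

A sample failing either check is excluded from all later stages, with the
reason ("NA fraction", "RT efficiency", or "controls missing" when its
RTC/PPC wells are all undetected) recorded in the QC report and in the run
report. The missingness *structure* is summarised as exclusive
intersection counts of the per-sample missing-miRNA sets — the numbers
behind an upset plot — which makes batch-like dropout patterns visible.

# Normalization

Replicate wells of an assay are collapsed to their arithmetic mean Ct over
detected wells (missing only when all replicates are missing). Each
sample's **reference Ct** is then the arithmetic mean of its control
assays — the six endogenous snoRNA/snRNA controls by default, or the
cel-miR-39 spike-in in exogenous mode, the usual choice for serum/plasma
where no endogenous RNA is reliably stable. An arithmetic mean of Cts is a
geometric mean of linear abundances, the standard aggregation for
log-scale quantities. Controls missing in a sample are dropped from that
sample's mean rather than failing the run — single-control dropout is
common — and the controls actually used per sample are recorded in the
object metadata; only a sample with *no* usable control is an error.

Expression is reported as −ΔCt = Ct~ref~ − Ct~miRNA~, i.e. log2 relative
expression with "larger = more abundant", so downstream log fold changes
have the usual sign convention. Because any per-sample global offset
(pipetting volume, input RNA quantity, RNA degradation) adds the same
constant to the reference and to every miRNA well, it cancels exactly in
the subtraction; this invariance is asserted to machine precision in the
test suite. The linear-scale companion 2^−ΔCt^ is available via
`relativeExpression()`. Differential analysis consumes the log2 scale, not
the linear one, since the linear model below assumes approximately
additive errors.

# Differential expression

For each miRNA the two-group model is fitted complete-case: with n₁ and n₂
usable samples, β̂ = mean(test) − mean(reference) is the log2 fold change,
s² the pooled within-group variance on d = n₁ + n₂ − 2 degrees of freedom,
and v = 1/n₁ + 1/n₂. miRNAs with fewer than two usable samples in either
group are dropped and listed — no imputation, as the simplest defensible
contract for data whose missingness is abundance-related.

With 372 parallel assays and typically a handful of samples per group,
per-miRNA variance estimates are noisy. We place the standard scaled
inverse-chi-square prior on the true variances, equivalent to
s² ~ s₀²·F(d, d₀), and estimate (d₀, s₀²) by moment matching on log s²:
the residuals e = log s² − ψ(d/2) + log(d/2) have theoretical variance
ψ′(d/2) + ψ′(d₀/2), so the excess of var(e) over its sampling part
ψ′(d/2) is inverted through the trigamma function (Newton iteration) to
give d₀. When the observed dispersion does not exceed the sampling part,
the data show no variance heterogeneity: d₀ = ∞ and s₀² is the mean
observed variance. The posterior variance
s̃² = (d₀s₀² + d·s²)/(d₀ + d) gives the moderated statistic
t̃ = β̂/√(s̃²·v) on d₀ + d degrees of freedom (standard normal at
d₀ = ∞). At d₀ = 0 the machinery collapses to the classic pooled
two-sample t-test, which the tests verify row by row to machine precision,
and the estimator agrees with the reference empirical-Bayes implementation
in the limma package to 10 decimal places on shared fixtures.

P-values are two-sided and adjusted by the Benjamini–Hochberg step-up
(`adjust = "bonferroni"` is available for users wanting family-wise
control); a miRNA is significant when its adjusted p falls below `alpha`
(default 0.05). Significant miRNAs are clustered for the heatmap with
Euclidean distance and complete linkage on row z-scores — z-scoring
prevents high-abundance miRNAs from dominating the distances; the metric
and linkage are fixed, not options, so that the published figure of a run
is reproducible from its tables. Constant rows z-score to zeros rather
than NaN. With fewer than two significant miRNAs the heatmap is skipped
with a notice — a legitimate outcome, not an error.

# Functional analysis

Target mapping uses an offline TSV snapshot (miRNA, gene, source database,
evidence class, optional score) emulating the union of validated
(miRTarBase-, TarBase-like) and predicted (DIANA-microT-like) interaction
databases. Working from a file rather than live web queries keeps runs
reproducible, citable and possible on air-gapped systems; any real
database export can be converted to the four/five-column format. miRNA
name matching is exact after case-folding — no -3p/-5p arm expansion,
which would silently inflate target lists. Genes can be required to have
support from ≥ `minSources` distinct databases.

The target list is tested against GMT gene-set collections (GO- and
KEGG-style) by the upper-tail hypergeometric test, accumulated in log
space for stability at large counts. The default universe is the union of
the collection's genes; the pipeline intersects that with the genes
present in the target table, since genes that cannot be mapped can never
be drawn into a query and would bias the background. Sets with fewer than
2 or more than 2000 genes after universe intersection are not tested
(degenerate or uninformative), and BH adjustment runs across all tested
sets. Rank-based (GSEA-style) enrichment and GO-graph redundancy trimming
are out of scope.

# The simulator

`simulatePlates()` is first-class, tested code, not a fixture: it
generates the standard layout with per-miRNA baseline Ct ~ Uniform(20, 32)
(the usable qPCR range between strong expression and the detection limit),
planted signed effects on `nDe` miRNAs, per-sample global shifts
N(0, `sampleShiftSd`²) applied to *every* well including controls
(emulating input-quantity variation — which is exactly what normalization
must remove), Gaussian well noise, uniform dropout over miRNA wells, and
optional forced RT failures. The reference conditions used across the
tests are 6 samples/group, 30 planted miRNAs at ±2 cycles, noise sd 0.5
cycles, 2% dropout and shift sd 1 cycle; under them the pipeline recovers
the planted set with sensitivity ≥ 0.8 at observed FDR ≤ 0.1
(empirically 1.0 and ≤ 0.07 across seeds).

What the simulator deliberately does **not** emulate: per-assay
amplification-efficiency differences, abundance-dependent dropout (unless
`structuredDropout = TRUE`, which biases dropout toward high-Ct assays),
inter-plate batch effects beyond a global shift, and heavy-tailed or
correlated noise. Green tests therefore demonstrate the pipeline's
correctness and its invariances, not that real plates meet the model's
assumptions; the QC stage exists precisely because real samples violate
them.

# Numerical and design notes

* Missing markers in Ct exports default to
  `{"Undetermined", "N/A", "NA", ""}` and are configurable; vendor exports
  are not consistent. Ct values above a configurable ceiling (35 cycles by
  default, standard practice for the quantification limit) are treated as
  not detected.
* Assay-name matching is case-insensitive with whitespace trimming
  throughout, since vendor exports vary in capitalisation.
* The trigamma inversion uses Newton steps on 1/ψ′, which is nearly
  linear; convergence tolerance 1e−10, at most 50 iterations.
* The hypergeometric tail and the BH step-up are asserted against
  brute-force enumeration and literal stepwise computation in the test
  suite; clustering is asserted against a naive O(n³) agglomerator.
* Problem sizes in the test and acceptance runs — single plates of 384
  wells, 12 samples, 2000 simulated variances for parameter recovery,
  exhaustive hypergeometric enumeration up to universe size 25 — were
  chosen as the smallest sizes at which each property is meaningfully
  exercised.
* Timing and peak memory are reported in the run report but never asserted
  in tests: they are hardware facts, not properties of the method.

# Worked run

```{r, eval = FALSE}
indir <- tempfile(); outdir <- tempfile()
sim <- simulatePlates(simulationScenario(seed = 42))
paths <- writeSimulatedInputs(sim, indir)
cfg <- runConfig(counts = paths[["counts"]],
                 annotation = paths[["annotation"]],
                 metadata = paths[["metadata"]],
                 outputDir = outdir)
runPipeline(cfg)
readRunReport(file.path(outdir, "report.json"))$counts
```

# Known limitations

Two-group single-contrast designs only: paired designs, covariates and
multi-factor models are out of scope, as are amplification-curve fitting,
melt-curve QC, proprietary binary thermocycler exports, inter-plate
calibration beyond the PPC check, and any live database queries. The
bundled target fixtures are synthetic; real analyses should export a
current interaction database into the documented TSV format.
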