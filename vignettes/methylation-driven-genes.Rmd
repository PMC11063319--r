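---
title: "Identifying methylation-driven genes from paired methylation and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying methylation-driven genes from paired methylation and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdriver)
```

## The analysis

DNA methylation at promoter CpGs tends to repress transcription. Given a
cohort with both a 450K-style methylation array and an expression array on
the same patients — here, seasonal allergic rhinitis (AR) patients and
healthy controls (HC) sampled during the pollen and the non-pollen season —
a *methylation-driven gene* is defined operationally by three joint
conditions:

1. its promoter CpG is a differentially methylated position (DMP) between
   AR and HC,
2. the gene itself is differentially expressed (DEG) between the groups,
3. across patient-matched samples, the gene's expression is significantly
   *negatively* rank-correlated with the CpG's methylation fraction
   (Spearman `Cor < -0.4`, `p < 0.05`).

Such pairs come in two classes: hypermethylated CpG with a downregulated
gene (`hyper_low`) and hypomethylated CpG with an upregulated gene
(`hypo_high`). The package implements the full screen and two companion
analyses: gene-set enrichment of the driver genes (hypergeometric ORA and a
single-CpG GSEA over the correlation-ranked transcriptome) and a weighted
co-expression network stage that relates expression modules to clinical
traits.

## Differential screening

Methylation is summarized as the beta value `beta = M / (M + U + 100)`,
bounded in [0, 1]; the offset stabilizes low-intensity probes and is
configurable (default 100). Quality control drops probes and then samples
whose missing rate exceeds 10% (values at exactly 10% are kept — the filter
describes what is retained), removes externally curated cross-reactive /
multi-mapped probes, and places Type-II probe beta values onto the Type-I
empirical distribution by per-sample quantile mapping. The quantile mapping
is a deliberate simplification of intensity-model corrections such as BMIQ:
it preserves rank order within each sample, maps into [0, 1], and is the
identity when the two designs already agree, but it does not model the
chemistry, so probe-level agreement with intensity-based normalizers is
approximate.

Expression preprocessing mirrors common bead-array practice: the per-sample
background level is estimated as the mean intensity of probes whose
detection p-value exceeds 0.5, subtracted, floored at one intensity unit
and log2-transformed. Within each group a probe is *detected* when its
detection p-value is below 0.05 in at least 50% of that group's samples
("at least" read inclusively); undetected probes are replaced by their
group mean, so they carry no within-group variance into the tests. Probes
are collapsed to unique genes by keeping the probe with the highest mean
expression (ties broken by probe ID for determinism).

Both data types are tested with an empirical-Bayes moderated two-group t.
Per feature the pooled variance `s^2` (d residual df) is shrunk toward a
prior fitted across features by method of moments on `log s^2`: the prior
df `d0` solves `trigamma(d0/2) = var(log s^2) - trigamma(d/2)` by Newton
iteration (tolerance 1e-8; `d0` capped at 1e6 to represent an effectively
infinite prior), and the posterior variance is
`(d0*s0^2 + d*s^2) / (d0 + d)`. With `d0 = 0` the statistic reduces
exactly to the ordinary pooled t, and as `d0` grows all features share one
variance; the test suite checks both limits and cross-checks the full fit
against the established limma implementation.

Calls use an *adaptive* effect threshold rather than a fixed fold-change
cutoff: `tau = mean(|effect|) + 2 * sd(|effect|)` over all tested features
(sample standard deviation; the strict inequality `|effect| > tau` decides
a call). Raw p-values below 0.05 gate the calls, mirroring the stated
screening criteria; BH-adjusted values are reported alongside for
transparency. DMPs are additionally restricted to promoter-annotated probes
(TSS1500, TSS200, 5'UTR, 1stExon). Tests run on beta values directly; an
M-value option (`meth_transform = "mvalue"`) is available, in which case
effects are still reported in beta units.

## Integration

Samples are matched across the two assays by (patient, season); duplicate
keys within one assay are a validation error. Each probe is correlated only
with its annotated gene (no all-vs-all scan). Spearman's rho uses average
ranks; the two-sided p-value is exact (full permutation null, cached per
sample size) for n <= 9 without ties and otherwise uses the
t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`. The exact small-n path
exists because the matched sample count in studies of this design is small
enough to make the approximation questionable; with ties present the
approximation is used at any n. Called pairs must satisfy `rho < -0.4`
(strict) and `p < 0.05`, have a DMP probe and DEG gene, and be
direction-consistent (hypermethylated CpG with a downregulated gene or
vice versa); inconsistent pairs are dropped with a warning. The
consistency check encodes the negative-regulation rationale that also
motivates excluding a gene whose correlated probes are not DMPs; it can be
disabled (`check_consistency = FALSE`), which is also how the package
exposes the limit identity "thresholds relaxed => calls = all DMP x DEG
candidates" used in the tests.

## Enrichment

ORA uses the hypergeometric upper tail `P(X >= k)` with BH adjustment
across the collection. The universe defaults to all genes on the platform
after collapse, since a narrower universe would overstate enrichment of
lists drawn from the tested genes. Gene sets are consumed from GMT only;
no live pathway-database retrieval is attempted, because term membership
drifts with database versions.

The single-CpG GSEA ranks all genes by their Spearman correlation with one
CpG's beta values and computes the classic weighted Kolmogorov-Smirnov
running sum (weight exponent 1 by default; 0 gives the unweighted
statistic). The null distribution permutes gene labels rather than
phenotypes: with ~15 matched samples a phenotype permutation null is too
coarse, and the gene-label null shares one permutation stream across all
sets, which keeps the procedure O(perms x sets x set size) via an
extrema-at-hits evaluation that the tests verify against a literal
element-by-element walk. Empirical p-values are `(r + 1)/(n + 1)` against
the same-sign null; NES divides by the mean same-sign null ES; FDR q
follows the positive/negative pooling convention. GSEA permutations are
the only stochastic step in the analysis path; the pipeline derives its
stream from the global seed.

## Co-expression stage

Genes are filtered to the top 25% by median absolute deviation, and
samples whose first merge in an average-linkage clustering (Euclidean
distance on gene-standardized profiles) exceeds `median + 3 * MAD` of all
first-merge heights are removed as outliers; if more than 25% of samples
would be removed the operation aborts, and the pipeline then proceeds with
all samples and a warning.

The soft-threshold power is chosen as the smallest candidate whose signed
scale-free fit index (R^2 of log frequency vs log mean connectivity over
ten equal-width connectivity bins, signed by the negative slope) reaches
0.85. Two numerical guards matter in practice. First, powers whose mean
connectivity falls below 1 are ineligible: there the network is essentially
disconnected and the binned fit becomes spuriously high. Second, when no
power reaches the target the package uses the sample-size default for
unsigned networks (9 below 20 samples, 8 below 30, 7 below 40, else 6)
instead of the argmax of the fit index — on latent-factor data, whose
degree distribution is genuinely not scale-free, the argmax tends to sit at
extreme powers that collapse the adjacency. The fit table is always
returned so the choice can be inspected.

Topological overlap is the standard
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` on the
unsigned adjacency `|cor|^power`. Modules come from average-linkage
clustering of `1 - TOM` with a *static* cut at 0.99 of the largest merge
height; branches below `min_module_size` (default 100) are grey. The
dynamic hybrid tree cut was deliberately not reimplemented: its recursive
heuristics are out of proportion to what this analysis consumes (one key
module and a gene list), at the cost that module counts on real data are
only approximately comparable to dynamic-cut results. Module eigengenes
are unit-norm first right singular vectors of the gene-standardized module
submatrix, sign-aligned to the module's mean profile. Module-trait
correlations (Pearson; traits encoded group AR=1/HC=0, sex F=1/M=0,
symptom score numeric) flag key modules at `Cor > 0.4`, `p < 0.05`. The
threshold is signed by default, following the literal reading of the rule;
`use_abs = TRUE` is available since a strongly anti-correlated module is
biologically no less interesting. The same rule extracts the neighborhood
of a key gene within its module.

## The synthetic cohort

`generate_dataset()` builds the paired dataset every stage is validated
on. Its defaults are the study conditions: 8 patients per arm, each
measured in both seasons on both assays (so 32 samples per assay and 16
matched samples per season); 3,000 methylation probes; 2,000 genes; 30
planted promoter DMPs at `delta beta = 0.3` plus an equally sized decoy set
with the same shift but gene-body annotation (which the promoter criterion
must reject); 30 planted DEGs at `log2FC = 1.5`; 15 driver pairs at
Spearman `-0.8`; three 120-gene modules with within-module correlation
about 0.7; a symptom-score trait correlated 0.8 with the first module's
factor; 2% completely-at-random missingness in beta.

Background beta values are a two-component Beta(2,10)/Beta(10,2) mixture,
reproducing 450K bimodality without modelling intensities. A driver pair
couples the two assays through a shared latent `X` per (patient, season):
`beta = pnorm(X)` and expression `y = a - b*X + noise`, a monotone
decreasing link, so the planted Spearman correlation is exact under
monotone transforms. The group separation of `X` is set so the population
beta difference equals `delta_beta`; the slope `b` is set so the expected
expression difference equals `log2fc`; and the noise SD is solved
numerically (bisection on a large fixed quasi-random sample) so the
population Spearman over the two-group mixture equals `driver_cor`. The
within-group latent spread is kept small (0.05 on the latent scale): this
concentrates the realized fold change of driver genes on the planted
`log2fc` — with a wide latent spread, the noise required to hold the
Spearman target inflates the realized fold-change distribution and the
generator would no longer plant the effect size it claims. One driver gene
additionally loads on the first module factor (within its noise budget, so
the Spearman target is untouched), emulating a key methylation-driven gene
sitting inside the trait module.

Background genes carry heterogeneous biological variability (SD uniform on
0.3-0.8 in log2 units) so the MAD filter selects a mixture of module and
non-module genes rather than acting as a module oracle. Detection
p-values follow intensity: about 5% of background genes sit below the
detection limit everywhere, and a further 2% hover at the limit — just
detectable in HC, undetected in AR — giving the per-group detection filter
real work with modest fold changes. (Fully silencing a visible gene in one
arm would hand the adaptive threshold a handful of extreme fold changes
and is not the regime a mean + 2 sd rule is meant for.) Missingness is
completely at random, matching the assumption behind the 10% filter. One
master seed is expanded into named per-component streams, so enlarging one
component does not perturb the draws of another.

What the generator does *not* emulate: Infinium I/II chemistry biases
(design type is assigned but both types share one beta model, so the
normalization step is exercised only for rank/range behavior), batch
effects, genomic coordinates, and realistic effect-size spectra — the
planted effects are homogeneous by design so that recovery rates are
interpretable. Passing recovery tests therefore demonstrates that the
screen finds what its thresholds define under its own assumptions, not
that those thresholds are optimal for real arrays.

## Validation design

The test suite validates every statistic against an independent oracle
written from the definition: ordinary pooled t (prior df 0), combinatorial
enumeration of the hypergeometric tail, a literal running-sum walk for the
GSEA ES, the O(n^3) TOM formula, the explicit rank formula for Spearman
with ties, full permutation enumeration for the exact small-n p-value, and
power iteration for eigengenes. Calibration checks hold the moderated
test's type-I error in [0.04, 0.06] on 5,000 null features at n = 8+8
pooled over 20 seeds, require GSEA null p-values to pass a uniformity KS
test over 500 random sets, and require the driver-pair screen to call
essentially nothing (< 0.05 pairs per run) on a global-null cohort over
200 seeds. Recovery checks (50 seeds at the default conditions) require
driver-pair sensitivity >= 0.8 and precision >= 0.9; module recovery uses
two 120-gene blocks with the between-block factor correlation made exactly
zero in-sample — with iid factors the chance correlation between two
factors at n = 18 (SD about 0.24) merges the blocks in a fifth of
replicates, which stresses the fixture rather than the detector.

Problem sizes throughout (3,000 probes, 2,000 genes, 16-32 samples, 20-50
seeds, 500-1,000 permutations) were chosen so that the complete suite and
the acceptance script each run in minutes while keeping every estimate's
Monte-Carlo error well inside the asserted margins.

## Known limitations

The probe-type normalization and background correction are documented
simplifications of BMIQ/normexp; counts from public benchmark datasets are
therefore only approximately reproducible. Raw (not FDR-adjusted) p-values
gate the differential calls by design, so genome-scale error control is
descriptive, not inferential. The static tree cut undercounts modules
relative to dynamic hybrid cutting on real data. The co-expression stage
assumes the trait is linear in the eigengene; and with 16-19 samples all
correlation thresholds are coarse instruments — the package reproduces the
analysis faithfully rather than improving its statistics.
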