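# methdriver

Identification of **methylation-driven genes** from paired DNA methylation
(Illumina 450K-style) and gene expression microarray data, built for
two-group designs such as allergic rhinitis (AR) patients versus healthy
controls (HC) sampled in and out of the pollen season. The package is
aimed at bioinformaticians who want the complete screen — from raw
intensity matrices to CpG–gene pairs, enrichment and co-expression
modules — as tested, reusable functions with a synthetic cohort that has
known ground truth.

## The method

A gene is *methylation-driven* when three conditions hold jointly:

1. **DMP** — its promoter CpG (TSS1500, TSS200, 5'UTR, 1stExon) differs
   between groups: empirical-Bayes moderated t on beta values
   (`beta = M/(M + U + 100)`), raw `p < 0.05`, and
   `|Δβ| > mean(|Δβ|) + 2·sd(|Δβ|)` (adaptive threshold over all probes);
2. **DEG** — the gene differs in expression under the analogous criteria,
   `|log2FC| > mean(|log2FC|) + 2·sd(|log2FC|)` and `p < 0.05`;
3. **negative coupling** — across patient-matched samples, Spearman
   `Cor(β, expression) < −0.4` with `p < 0.05`, and the directions oppose
   (hypermethylated ⇒ downregulated, `hyper_low`; hypomethylated ⇒
   upregulated, `hypo_high`).

Around this core the package provides hypergeometric over-representation
analysis, single-CpG GSEA (weighted Kolmogorov–Smirnov running sum,
gene-label permutation null), and a WGCNA-style co-expression stage
(MAD top-25% filter, soft threshold at scale-free `R² ≥ 0.85`,
topological overlap, static-cut modules with minimum size 100, module
eigengenes, module–trait correlation at `Cor > 0.4`), plus a synthetic
paired-data generator with planted DMPs, DEGs, driver pairs, and
trait-linked co-expression modules.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential.R
Rscript analysis/03_integrate.R
Rscript analysis/04_enrich.R
Rscript analysis/05_coexpress.R
Rscript analysis/06_recovery.R
```

generates a synthetic two-season cohort (8 AR + 8 HC patients per assay
and season; 30 planted promoter DMPs at Δβ = 0.3, 30 DEGs at log2FC = 1.5,
15 driver pairs at Spearman −0.8, three 120-gene modules) and prints, for
example:

```
[pollen] delta-beta threshold 0.144 -> 42 promoter DMPs (20 hyper / 22 hypo)
[pollen] log2FC threshold 1.181 -> 61 DEGs (14 up / 47 down)
[pollen] 16 matched samples; 86 scored pairs pass Cor < -0.4 & p < 0.05; 12 driver pairs (7 hyper-low / 5 hypo-high)
season comparison: 1 genes unique to pollen, 3 unique to non-pollen, 11 shared
detected 3 modules: turquoise (128), blue (126), brown (121)
  blue ~ symptom_score: cor 0.80 (p=0.000205)
pollen-season recovery of planted pairs: 12/15 (precision 1.00)
```

The thresholds (0.144 in beta units, 1.181 in log2 units) are the adaptive
mean + 2 sd cutoffs computed from the data; the 12 called pollen-season
pairs are all planted truths (precision 1.00), and the blue module is the
planted trait-linked module recovered with its 0.8 symptom-score
correlation. Tables land under `results/`.

The same screen is available as one call:

```r
library(methdriver)
d <- generate_dataset(sim_config(seed = 1))
res <- run_pipeline(d$meth, d$expr, gene_sets = d$gene_sets)
res$manifest                    # counts per stage
res$seasons$pollen$pairs        # called CpG-gene pairs
```

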