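# btmdcnet

Differential co-expression network analysis of blood transcription modules
(BTMs) for longitudinal vaccine-response transcriptomes in two subject
groups — for example hemodialysis (HD) patients with end-stage renal
disease versus matched healthy controls (HC) profiled before and seven
days after each dose of a two-dose mRNA vaccine (timepoints `V1D0, V1D7,
V2D0, V2D7`).

The scientific question the package addresses: immune dysfunction does not
only change the *level* of gene expression, it changes the *coordination*
between immune programs. Summarizing a transcriptome into a few hundred
BTM activities and comparing the correlation structure of those activities
between groups exposes weakened coregulation that differential expression
misses.

## What it computes

- **Module eigengenes.** For each BTM, the first principal component of
  its standardized gene-by-sample submatrix: `E_m = v1 / sd(v1)` from the
  SVD of the per-gene z-scored submatrix, with a deterministic sign
  convention (aligned with the module mean profile).
- **Node selection.** A repeated-measures ANOVA per eigengene (fixed
  effects group + timepoint, random subject intercept, computed as the
  numerically equivalent subject-blocked two-way ANOVA for complete
  designs), Benjamini–Hochberg FDR across modules, then removal of
  redundant modules overlapping at Jaccard index > 0.2 (the larger module
  is kept).
- **Co-expression networks.** Pairwise Pearson correlations between
  eigengenes: per group (subjects x 4 timepoints pooled, e.g. n = 76 and
  n = 48) and per subject (n = 4 timepoints).
- **Fisher-Z difference network.** `z = arctanh(r)` per edge; the group
  difference is standardized by `sqrt(1/(n_HD-3) + 1/(n_HC-3))` (a literal
  unstandardized mode is also provided), converted to two-sided normal
  p-values, FDR-adjusted across edges, and classified into six edge
  classes: positive-in-both but weaker/stronger in HD, negative-in-both
  but weaker/stronger in HD, and the two discordant-sign classes.
- **Family summaries.** Percentages of each edge class within a BTM
  family (denominator `n(n-1)/2`), between a family and the rest of the
  network, and pairwise between families.
- **Single-subject comparison.** Median positive and median negative
  Fisher-Z edge weight per subject over significantly co-expressed edges,
  compared between groups with a pooled-variance Student's t-test.
- **Regulatory differences.** Given two externally computed TF-by-gene
  regulatory networks, the elementwise difference, a gene ranking by the
  most dysregulated edge per gene, and preranked gene-set enrichment
  (weighted Kolmogorov–Smirnov ES, gene-label permutation p, BH q,
  leading-edge/core-enrichment genes).
- **Cell deconvolution.** Marker-based signature construction from a
  labeled single-cell reference, non-negative least-squares proportion
  estimates for 16 immune cell populations, and Wilcoxon rank-sum
  comparisons between groups and timepoints.
- **Cohort statistics.** Continuity-corrected chi-squared and
  pooled-variance t-tests that reproduce a printed demographics table
  from its summary numbers.
- **Synthetic cohorts.** A hierarchical latent-factor generator with
  ground truth (planted coupling, group multiplier, timepoint shifts,
  regulatory edge differences, mixture proportions) used for calibration
  and parameter-recovery testing throughout.

## Worked example

```r
library(btmdcnet)

sim <- generate_cohort(seed = 7)        # 12 HD-like vs 19 control subjects
sim$study
#> ExpressionStudy: 720 genes x 124 samples
#>   groups: HC (n=76), HD (n=48)
#>   timepoints: V1D0, V1D7, V2D0, V2D7

eig <- eigengenes_by_group(sim$study, sim$btms)
comb <- combine_group_eigengenes(eig, sim$study$metadata)
select_modules(comb, sim$study$metadata, sim$btms)
#> SelectionResult: 32 of 48 modules pass the timepoint-effect FDR; 32 retained after overlap filtering

net_hd <- group_network(eig$HD, sim$study$metadata, "HD")
net_hc <- group_network(eig$HC, sim$study$metadata, "HC")
diffnet <- z_difference_network(net_hd, net_hc)
table(diffnet$class)
#> pos_weaker_hd     unchanged
#>             5          1123

across <- across_group_network(eig, sim$study$metadata)
mask <- list(positive = significant_edges(across, 0.05, "positive"),
             negative = significant_edges(across, 0.05, "negative"))
med <- subject_median_table(eig, sim$study$metadata, edge_mask = mask)
compare_median_edges(med$median_pos[med$group == "HD"],
                     med$median_pos[med$group == "HC"])
#> median positive edge weight: HD 0.714 vs HC 0.844, t = -2.70, p = 0.0114
```

The negative t confirms the planted direction: the HD-like group's
subjects have weaker positive coregulation between modules. All of the
significantly different group-level edges fall in the `pos_weaker_hd`
class. Cohort statistics work directly from printed summaries:

```r
yates_chisq_2x2(8, 4, 3, 16)     # hypertension: 8/12 vs 3/19
#> yates_chisq_2x2: statistic = 6.242, df = 1, p = 0.01247
pooled_t_from_summary(59, 12, 12, 46, 16, 19)   # age, mean +/- sd
#> pooled_t: statistic = 2.413, df = 29, p = 0.02238
```

A one-call demonstration that writes every stage output (networks, edge
lists, difference network, family summaries, subject medians, manifest)
to a directory:

```r
run_pipeline(list(seed = 7), out_dir = "demo_run", demo = TRUE)
```

or from a shell: `inst/cli/btm-dcnet demo --out demo_run --seed 7`.

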