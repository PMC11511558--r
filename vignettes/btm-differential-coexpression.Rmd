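---
title: "Differential co-expression of blood transcription modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression of blood transcription modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btmdcnet)
```

## The problem and the model

Chronic immune dysfunction — as in end-stage renal disease on maintenance
hemodialysis — can leave mean expression levels largely intact while
degrading the *coordination* between immune programs. This package
implements an analysis built around that idea for longitudinal vaccine
response data: two subject groups (an affected HD-like group and
controls), four timepoints per subject (before and seven days after each
of two vaccine doses), and gene expression summarized at the level of
blood transcription modules (BTMs) — curated sets of co-expressed blood
genes grouped into immunological families (B cells, cell cycle, DC/APC,
IFN type I, Myeloid/Inflamm, T/NK cells, other).

Each module is reduced to its **eigengene**: the first principal
component of the module's gene-by-sample submatrix. Genes are z-scored
per gene before extraction (a correlation-scale PCA), so a module with
heterogeneous gene variances is not dominated by one gene. The eigengene
is the first right singular vector rescaled to unit variance; because
genes are centered, it has exactly zero mean. PCA signs are arbitrary, so
we fix them deterministically: the eigengene is flipped to correlate
non-negatively with the per-sample mean of the standardized module genes,
with a fallback to the alphabetically first gene's loading when that
correlation is exactly zero. `variance_explained` is
$d_1^2 / \sum_i d_i^2$ from the singular values of the standardized
matrix.

Eigengenes are extracted once per group over all of that group's samples
(a `pooled` scope is available as a configuration switch).
Single-subject analyses reuse the group-extracted values restricted to
the subject's four samples — re-fitting a PCA on four points would be
unstable and would decouple the subject networks from the group networks.

## Node selection

Candidate network nodes are modules whose eigengene shows a timepoint
effect: a repeated-measures ANOVA with fixed effects of group and
timepoint and a random subject intercept. For the complete balanced
design analyzed here this p-value equals the F-test for timepoint in the
subject-blocked two-way ANOVA `lm(eigengene ~ subject + timepoint)` —
the between-subject group contrast is absorbed by the subject blocks —
and that is how it is computed, avoiding estimator-specific differences
between mixed-model implementations (the equivalence to `lmer` is
asserted in the test suite). P-values are Benjamini–Hochberg corrected
across modules; the default selection threshold is q < 0.05, exposed as
`anova_q`.

Redundant candidates are removed by pairwise Jaccard overlap of their
gene sets: pairs with J > 0.2 are processed greedily in descending-J
order (ties by module id), dropping the smaller module (size ties drop
the lexicographically later id) and skipping pairs whose member was
already dropped. The explicit ordering and tie rules make the filter
deterministic and idempotent.

## Networks and their comparison

Group networks are pairwise Pearson correlations between eigengenes over
all of a group's samples pooled across subjects and timepoints (n = 4 x
subjects per edge); subject networks use the subject's four samples only
and require all four timepoints. Zero-variance eigengenes yield NaN
edges, which are excluded from all downstream summaries rather than
imputed.

Two group networks are compared edgewise on the Fisher-Z scale,
$z = \mathrm{arctanh}(r)$. The default difference statistic is the
classical two-correlation z-test,
$(z_{HD} - z_{HC}) / \sqrt{1/(n_{HD}-3) + 1/(n_{HC}-3)}$, whose null is
calibrated; a `literal` mode that treats the raw difference
$z_{HD}-z_{HC}$ as a standard normal deviate is also provided, because
verbal descriptions of Z-difference networks are often ambiguous between
the two readings. Both are flagged in the output. Edge p-values are BH-adjusted across all
finite edges; edges with q above `alpha` are classified `unchanged` and
exported with a difference of 0.

Significant edges fall into six mutually exclusive classes by the signs
and relative magnitudes of the two correlations (weaker/stronger positive
in HD, weaker/stronger negative in HD, discordant positive/negative in
HD). An exact zero correlation in one group joins the discordant branch
implied by the other group's sign; zero in both stays `unchanged`. The
test suite proves exhaustiveness and mutual exclusivity by enumeration
over a dense grid. Family-level summaries divide class counts by the
number of *possible* edges: $n(n-1)/2$ within a family, $n_f(N-n_f)$
between a family and the rest, $n_f n_g$ for a family pair; families
with fewer than two modules report NA percentages rather than 0/0.

At the single-subject level no per-edge inference is attempted — with
n = 4 samples per correlation it would be meaningless. Instead each
subject is summarized by the median Fisher-Z weight over positive and
over negative edges, restricted by default to edges whose pooled
across-group correlation is FDR-significantly nonzero with the matching
sign (`coexpression_significant`); masking by edges significant in the
group-difference network, or no mask, are configuration options. Group
medians are compared with a two-sided pooled-variance Student's t-test.

## Regulatory differences and enrichment

TF-by-gene regulatory weight matrices for the two groups are *inputs* —
they come from an external reconstruction method; this package only
differences them (HD minus control, order-normalized) and analyzes the
difference. A deliberately simple `build_prior_network()` (motif prior +
expression correlation) exists so synthetic tests run self-contained; it
is documented as not being a message-passing reconstruction and should
not be used for real analyses.

Genes are ranked by `signed_extreme` aggregation: each gene's score is
its most dysregulated edge (maximal absolute difference, sign kept; ties
resolved toward the lexicographically larger TF name), so the ranking
reflects each gene's strongest regulatory change; a `sum` aggregation is
available as an alternative since no single aggregation rule is
canonical. The
ranked list feeds a preranked gene-set enrichment: the weighted
Kolmogorov–Smirnov running statistic with hit increments proportional to
|score| (exponent configurable), miss decrements 1/(N - n_set), ES the
signed maximal deviation, and leading-edge ("core enrichment") genes
those at or before the extremum for positive ES, at or after it for
negative ES. When every in-set score is zero the hit increments fall back
to equal weights rather than dividing by zero.

Significance comes from gene-label permutations with the (b+1)/(n+1)
estimator against the **two-sided |ES| null**. A sign-stratified null was
considered and rejected: rankings aggregated from sparse difference
matrices are heavily tied and sign-asymmetric, and under such rankings a
saturated |ES| ties exactly with the small fraction of permutations
containing the extreme-ranked genes, inflating the planted set's p while
sets of the opposite sign are compared against an uncontaminated null —
the |ES| null applies the same reference to every set. Permutation
p-values are BH-corrected across sets.

## Deconvolution

Cell-type proportions are estimated from bulk expression by non-negative
least squares against a signature matrix, normalized to sum to one. This
constrained least-squares estimator is a deliberately simple, clearly
documented solver — support-vector regression and batch-correction modes
of production deconvolution tools are out of scope — and is adequate here
because only *relative* proportions feed the downstream rank tests.
Signatures are built from a labeled reference by ranking genes per type
on log2 fold change (pseudocount 1) of the type mean versus the mean of
all other cells and keeping the top `markers_per_type` (default 50; both
the count and the statistic are configuration-exposed since marker
selection rules vary between deconvolution tools). Group and timepoint comparisons use two-sided
Wilcoxon rank-sum tests (exact for small tie-free samples), reported as
raw p-values with significance stars; an optional FDR column is off by
default to match the raw-star annotation convention. Between-timepoint
comparisons are rank-sum, not signed-rank, deliberately matching the
described analysis.

## Cohort statistics

The demographics table is reproduced from printed summaries: counts per
group get the Yates continuity-corrected chi-squared
($\chi^2 = N(\max(0, |ad-bc| - N/2))^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$,
1 df), continuous "mean ± sd" rows get the pooled-variance Student's t
from summary statistics. Printed tables rarely name their tests; these two standard defaults were
identified by the verifiable fact that they reproduce every printed
p-value of the packaged example table to three significant figures, and
Fisher's exact p is reported alongside for comparison. The claim made is
only that they reproduce the printed values.

## The synthetic cohort generator

The generator exists to realize, with known ground truth, every null and
alternative the pipeline is supposed to detect. Its model: per sample, a
global immune-activity factor $g$ and one factor $f$ per family; module
$m$ in family $F$ with orientation $s_F \in \{+1, -1\}$ has eigensignal

$$ e_m = \sqrt{\rho/2}\,(s_F\, g + f_F) + \sqrt{1 - \rho}\, u_m, $$

with $\rho$ = `coupling` in the control group and
`coupling * hd_multiplier` in the HD-like group. Same-family modules
therefore correlate at exactly $\rho$, different families at
$\pm\rho/2$ — positive between families with the same orientation,
negative between innate-oriented (DC/APC, IFN type I, Myeloid/Inflamm,
cell cycle) and adaptive-oriented (B cells, T/NK cells) families, so the
negative-coregulation analyses have real structure to find. Genes load on
their module's eigensignal with U(0.5, 1) loadings plus i.i.d. Gaussian
noise; family-level timepoint shifts (drawn once, shared by both groups)
give the selection ANOVA a true effect; per-subject, per-module random
intercepts exercise the subject blocking and cancel within-subject.

Defaults are the study conditions the pipeline targets: 12 vs 19
subjects with complete four-timepoint series, 48 modules (8 per family),
15 genes per module, coupling 0.7, HD multiplier 0.5, gene noise sd 0.5,
timepoint shift sd 0.3, subject intercept sd 0.3. Two sizing choices
deserve explanation. Timepoint shifts are shared between groups, so
their variance inflates both groups' correlations equally and
*compresses* the group contrast on every edge; 0.3 keeps the ANOVA
effect overwhelmingly detectable for typical families while limiting
that compression. The module count was set by a power analysis of the
median-edge recovery test (the headline weakened-coregulation contrast):
per-subject medians over four-sample correlations are intrinsically
noisy, and at 24 modules the planted contrast was recovered in only
~89% of replicates, i.e. the generator failed its purpose of making the
alternative reliably detectable at this scale; power was 0.935 at 30,
0.960 at 36 and 0.985 at 48 modules (200 replicates each), so 48 — still
an order of magnitude below the full BTM catalogue — was fixed as the
default. Replicates stay around 0.2 s, keeping hundreds of replicates
inside routine test runs.

What the generator deliberately does **not** emulate: RNA-seq counts
(library size, dispersion — the pipeline consumes variance-stabilized
values), gene-gene correlation beyond the module factor, missing
timepoints, covariates such as age or infection history, and realistic
regulatory noise (the planted regulatory pair differs in exactly the
planted edges). Consequently, passing recovery tests demonstrates that
the *methods* detect what they claim under their own assumptions — not
that real cohorts of this size would yield the same power, particularly
for the negative-edge direction, which is planted only at half coupling
(cross-family) and is recovered far less reliably than the positive
direction. Determinism: all sub-generators derive child seeds from the
one seed argument, so equal seeds give bit-identical studies.

## Numerical choices and degenerate inputs

- Correlations of exactly ±1 are clamped to ±(1 − 1e−7) before
  arctanh, with a warning.
- Constant genes are dropped before eigengene extraction (a module that
  is entirely constant is an error); constant eigengenes yield p = 1
  with a degeneracy flag in the ANOVA; zero-variance network rows give
  NaN edges excluded downstream.
- NNLS solutions that are identically zero return a uniform proportion
  vector with a degeneracy flag rather than 0/0.
- The chi-squared statistic with an empty margin reports p = 1 with a
  flag; a zero pooled variance with equal means gives t = 0, p = 1, and
  with unequal means is an error.
- All stochastic procedures (permutations, generators) take explicit
  seeds and restore the caller's RNG state.

## Problem sizes used in validation

The packaged checks run at deliberately modest sizes: 200 null cohorts
for edge-level false-positive calibration, 100 cohorts for median-edge
recovery, 50 regulatory replicates (30 TFs x 400 genes, 12 planted
edges, 500 permutations), and 50-sample mixtures over the 16-type
signature. These sizes give Monte-Carlo standard errors a few times
smaller than the margins being tested while keeping the whole suite
around a minute.
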