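---
title: "Methods: single-cell and tissue-restricted-antigen analysis of AIRE-expressing dendritic cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell and tissue-restricted-antigen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`etacpipe` analyzes candidate extra-thymic AIRE-expressing cells (eTACs) from
count data along two arms. The single-cell arm takes a genes × cells matrix
of unique-read counts from a plate-based protocol (with ERCC spike-ins) and
produces QC-filtered, normalized expression, highly variable genes, cell
clusters, a maturation pseudotime with meta-stable states, and differential
expression between cell groups. The bulk arm takes population-level count
profiles plus a tissue atlas and asks whether a population expresses
tissue-restricted antigens (TRAs) promiscuously, the hallmark of medullary
thymic epithelial cells (mTECs). Everything starts from count matrices;
alignment and quantification are upstream of this package.

# Single-cell quality control and normalization

Cells are removed when **any** of three rules fires, each with a strict
inequality: total reads < 100,000; genes detected < 1,000; sparsity
(fraction of zero-count genes) > 95%. The fraction of counts attributable to
ERCC-like technical genes is reported per cell but is deliberately not a
removal filter — spike-in content varies with well chemistry and the three
count-based rules already remove broken wells. Genes with > 95% zero counts
across retained cells are removed; technical genes are exempt because the
mean–variance trend fit downstream prefers them.

Size factors use pool deconvolution: cells are ordered on a ring by library
size, and for every window of consecutive cells (window sizes 21, 41, 61,
81, 101, truncated to the cell count) the pooled count vector is compared to
the average pseudo-cell by the median ratio over genes with positive
pseudo-cell expression. Each window yields one linear equation — the sum of
the member cells' factors equals the pool's median ratio on the scale where
factors average one — and the stacked system is solved by least squares,
with a low-weight (1%) anchor on library-size factors that makes small
systems identifiable without influencing well-determined ones. Pooling
cancels the zero-count bias that makes per-cell median ratios unusable for
sparse data. Non-positive solutions trigger a non-negative refit
(Lawson–Hanson), and cells that remain degenerate fall back to library-size
factors with a warning. Factors are rescaled to geometric mean 1; spike-ins
are excluded from estimation since they do not scale with cell content.
Expression is then `log2(count / factor + 1)`; the pseudo-count of 1 keeps
zeros at zero on the log scale.

# Highly variable genes

The squared coefficient of variation of size-factor-normalized counts is
fit against the mean as `CV² = a1/μ + α0` by a gamma-family GLM with
identity link — `a1` captures shot noise (`a1 ≈ 1` for Poisson counts) and
`α0` the asymptotic technical CV² at high expression. The fit is computed on
the **linear** scale: this is the parameterization under which the
chi-squared excess test below has its sampling theory, whereas a fit against
mean log2 expression (provided as `fit_on = "log2"` for comparison) does
not. Fit genes are the ERCC-like spike-ins when at least 20 are present —
they are free of biological variance by construction — otherwise all genes
above the 10th percentile of positive means.

Each gene is tested with the statistic `(n−1)·CV²_g / trend(μ_g)` against
the upper tail of χ² with `n−1` degrees of freedom; genes at `p ≤ 0.01`
(no multiple-testing correction before the cut, an FDR mode is optional) are
highly variable. Whether the trend should be spike-in-restricted for any
given dataset is left as a flag (`use_technical`), since either convention
is defensible; the default prefers spike-ins.

# Clustering and embedding

The cell–cell dissimilarity is `1 − ρ` with Spearman's ρ over the HVGs,
midranks for ties; rank correlation is insensitive to residual
normalization error. Zero-variance cells carry no rank information and are
assigned maximal dissimilarity (2) with a warning rather than failing the
run. Trees are average-linkage (UPGMA). Clusters come from a dynamic tree
cut implemented as the "tree" variant: splits are examined from the root
down and accepted only when both branches hold at least `min_module_size`
(default 30) cells; undersized branches are set aside and merged into the
accepted cluster nearest by average dissimilarity. The "hybrid" variant's
extra parameters (deepSplit, core-scattering thresholds) would all have to
be invented here, so the variant with no free parameters beyond the minimum
size was chosen. Labels are canonicalized by decreasing cluster size with
ties broken by smallest member id, making them invariant to input order.
The 2-D embedding is Barnes–Hut t-SNE on the HVGs (perplexity 50, seed
recorded in the output, default 42).

# Diffusion pseudotime and meta-stable states

Cells are cosine-normalized (unit Euclidean norm over HVG expression), and a
symmetric k-nearest-neighbor graph (`k = 21`, union symmetrization) is built
on Euclidean distances. The Gaussian kernel uses a per-cell local bandwidth
— the distance to the `⌈k/2⌉`-th neighbor — so dense and sparse regions of
the trajectory are treated comparably (a single global bandwidth is
available as `kernel_scale = "global"`). The kernel is density-normalized by
the product of row sums (the anisotropic α = 1 correction, which removes
sampling-density bias from the operator), row-normalized to a stochastic
transition matrix, and eigendecomposed via its symmetric conjugate. The
trivial constant eigenvector is dropped; the next three eigenvector /
eigenvalue pairs, scaled by their eigenvalues, are the diffusion components,
with "first 3 eigenvalues" read as the first three non-trivial pairs. DC1 is
pseudotime. If the graph is disconnected the largest component is analyzed
and the remaining cells are labeled unassigned (state 0) with a warning.

Meta-stable states are the exact optimum of 1-D k-means (`k = 4`) on DC1:
in one dimension the optimal partition is contiguous in sorted order, so
dynamic programming finds the global minimum WCSS deterministically — no
seed, no restarts. Ties are broken toward equal segment sizes so degenerate
inputs have a canonical answer. Pseudotime orientation is fixed by anchor
markers (e.g. CCR7/CCL19-like maturation genes): DC1 is flipped if their
mean expression decreases along it. Branches (two in the emulated design)
are reported descriptively from DC2 relative to the DC1 extremes; the state
partition itself uses DC1 only.

# Differential expression

Per-gene ordinary least squares on log2 values with a two-level group
contrast and additive categorical blocking on donor and plate column.
Aliased blocking columns are dropped and logged; if the group indicator
itself lies in the span of the blocks, the design is rejected with the
confounded factors named. Variances are moderated by fitting a scaled
inverse-χ² prior to the residual variances via the closed-form moments of
log s² (digamma/trigamma inversion): prior df `d0` and prior variance
`s0²`, posterior `s̃² = (d0·s0² + d·s²)/(d0 + d)`. When the spread of log s²
does not exceed sampling noise, `d0 = ∞` and `s0²` is the mean observed
variance, so identical variances are a fixed point of moderation. The
moderated t uses `d + d0` degrees of freedom; genes with numerically zero
variance and effect get `t = 0, p = 1` rather than being dropped. BH FDR is
controlled at 1%. This moderation shrinks **variances**, not coefficients —
the standard empirical-Bayes t framework; an optional ridge-style
coefficient shrinkage is deliberately not the default since it changes the
estimand.

# Bulk normalization and downsampling

Bulk libraries are depth-matched by drawing exactly `target` reads per
sample without replacement from its count vector — a multivariate
hypergeometric draw realized by sequential univariate draws, which on
unique-read counts is distributionally equivalent to subsampling the
alignment (default target 20M reads; samples at or below target pass
through, logged). Size factors are median-of-ratios against the
geometric-mean pseudo-sample, computed as the exponentiated median of log
ratios (identical for odd reference-gene counts, and the convention of the
reference implementation); log2 values use a constant offset of 1.

# The τ index and the TRA report

For each gene's atlas profile, `τ = Σ(1 − x_i/max x) / (N − 1)` over
`N = 107` tissue groups. The formula requires max-normalization — without
it τ is unbounded — and that is the only faithful reading implemented. τ is
computed on linear atlas values by default for determinism against the
formula; a `log2(x+1)` pre-transform (the original τ literature's choice,
which compresses dynamic range and raises τ of moderately skewed genes) is
available as `log2_first`. Classification: τ ≥ 0.8 TRA, τ ≤ 0.4
constitutive, otherwise miscellaneous, boundaries included; all-zero
profiles are unclassifiable and excluded with a count.

"Expressed" genes per population are those with mean size-factor-normalized
count ≥ 1 across the population's replicates, applied after downsampling to
a common depth. No published rule defines "expressed" here, so the
threshold is an explicit configuration stamped into every report. The
report contains per-population category proportions (summing to 1 over
classified expressed genes), τ-distribution quantiles with a one-sided
Mann–Whitney shift statistic per population pair (descriptive — the shift
is a distributional claim, not a hypothesis test battery, so no FDR),
gene-centered PCA of samples over expressed TRA genes, average-linkage
clades on 1 − Pearson r, and an expression panel for a user-supplied
homolog set with absent genes reported as missing. The atlas and expression
matrices join on exact gene-id equality; ids are opaque strings and no
annotation-build conversion is attempted.

# Synthetic data: what it emulates, and what it does not

The generators produce every input class with known truth, under these
conditions (all defaults, chosen once):

* **Atlas** (`atlas_spec`): 107 tissue groups; 10% TRA genes expressed in
  1–3 tissues (lognormal level, median 100), 60% constitutive (uniform
  across tissues, median 20), 30% "miscellaneous" expressed uniformly in a
  random 33–60% of tissues — which places their τ between the two
  thresholds; multiplicative lognormal noise with CV 0.1, a typical
  replicate-level variability for aggregated atlas expression.
* **Single cell** (`sc_sim_spec`): 200 cells, 2,000 genes, 2 donors, 12
  plate columns; latent maturation time `t ~ U(0,1)` (a bimodal option
  mimics two density branches); lognormal true size factors (sdlog 0.3);
  NB counts with dispersion 0.1; 25 monotone-up (CCR7/CCL19-like), 25
  monotone-down (CCR6-like), and 10 transient (AIRE-like) program genes,
  the transient mean exactly zero outside `t ∈ [0.75, 1]` and ramping
  linearly within it — a discontinuous onset would disconnect the kNN graph
  at the window boundary, which is a property of step functions, not of
  maturation; multiplicative lognormal donor (sdlog 0.15) and plate-column
  (sdlog 0.08) effects; 50 ERCC-like genes independent of size factor and
  batch.
* **Bulk** (`bulk_sim_spec`): populations share lognormal baseline means;
  TRA-panel genes have a low shared "leaky" baseline (lognormal, median
  0.05 before library scaling) in every population, and program-on
  (mTEC-like) populations additionally express the panel at a shared
  per-gene lognormal profile around the configured level. The shared leaky
  baseline matters: real TRA-silent populations still express a structured
  subset of TRA genes, and without it their replicates would not correlate
  over TRA genes and the clade analysis would be testing noise.

What the generators do **not** emulate: UMI chemistry, doublets, ambient
RNA, mitochondrial stress signatures, gene–gene correlation beyond the
planted programs, isoform structure, or annotation mismatch between atlas
and experiment. Passing tests therefore demonstrate that the
implementations recover the structures they claim to recover under the
stated noise model — not that any particular real dataset satisfies that
model.

# Numerical choices

Strict inequalities in all QC filters, boundaries included in τ
classification, exactly as stated above. UPGMA and merge ties are broken
lexicographically; eigenvector signs are fixed by making the
largest-magnitude entry positive; t-SNE randomness is confined to its
recorded seed; the k-means DP breaks WCSS ties toward equal segment sizes.
Local kernel bandwidths are floored at a tiny positive value so duplicated
cells (zero distance) cannot produce a zero bandwidth. Gamma-GLM trend fits
fall back to the OLS line on `1/μ` if IRLS fails, and a trend that is
non-positive anywhere over the observed means is a hard error, not a
warning. Problem sizes in the test and acceptance suites (200 cells, 2,000
genes, 10,000 atlas genes, 5,000 moderation genes, 10,000 downsampling
draws) were chosen so every recovery property is measured with comfortable
Monte-Carlo margin while the whole suite runs in well under a minute each.

# Known limitations

* The dynamic-tree-cut variant ("tree", minimum size only) may split or
  merge differently from the hybrid variant on borderline dendrograms, so
  exact cluster counts on real data can differ from analyses that used
  hybrid settings.
* The diffusion map is a spectral method: pseudotime is defined up to
  monotone distortion, and the anchor-based orientation needs at least one
  informative marker.
* Deconvolution size factors assume most genes are non-differential across
  cells; on data violating this (e.g. strong cell-cycle structure across
  the whole transcriptome) factors can absorb biology.
* `d0` estimation uses all genes; strong heteroskedasticity across
  expression strata is not modeled (no trended prior).
* The TRA arm's conclusions are conditional on the atlas's tissue-group
  composition and on the declared "expressed" threshold; both are inputs,
  not estimates.
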