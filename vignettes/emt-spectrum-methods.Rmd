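---
title: "Methods: scoring SCLC subtypes on the EMT spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring SCLC subtypes on the EMT spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtspectrum)
```

## Scope and model

Small cell lung cancer cells occupy at least five transcriptional subtypes
(A, A2, N, P, Y; mouse data often resolve merged A/N and P/Y classes).
`emtspectrum` asks where these subtypes sit on the epithelial–mesenchymal
(EMT) spectrum. The pipeline has four statistical components: per-cell
enrichment scoring of epithelial (E) and mesenchymal (M) gene sets by the
ssGSEA running-sum statistic; an alternative E/M scoring by non-negative
principal component analysis (nnPCA); a stratified resampling test that
maps archetypes (extremal expression states from archetypal analysis,
supplied as per-cell simplex weights) onto subtype signatures; and
subtype-contrast statistics that split the M program into divergent M1 and
M2 halves. A synthetic single-cell generator with planted ground truth
closes the loop, making every downstream claim checkable.

Archetype-vertex discovery, expression imputation, and the construction of
the 105-gene subtype signature matrix are upstream of this package;
archetype weights and signature scores enter as inputs.

## Preprocessing

The preprocessing chain is order-fixed and layer-tagged: raw counts →
per-cell total-count normalization → `log1p` → (optionally) per-gene
scaling. Each stage refuses input from the wrong layer, which prevents,
for example, scoring raw counts as if they were log-normalized.

Choices left open by convention and fixed here once:

* `normalize_total` target: the median of per-cell totals (`target_sum =
  "auto"`), the standard total-count convention; configurable.
* `scale_genes`: population (n-denominator) standard deviation, zero-variance
  genes set to all-zero, default clip ±10 — the common single-cell scaling
  convention. Scaling is available but the scoring stages below deliberately
  consume the lognorm layer.
* Cell/gene filters default to ≥ 200 detected genes per cell and ≥ 3 cells
  per gene; these are dataset-specific QC knobs, not scientific claims.
* Highly variable genes use the classic dispersion flavor implied by the
  parameter set (`min_mean = 0.0125`, `max_mean = 5`, `min_disp = 0.8`):
  mean and variance/mean dispersion on `expm1` of the lognorm layer, 20
  equal-frequency mean bins, within-bin z-scoring of dispersion. With bins
  of size *b*, the largest attainable z-score is bounded
  (≈ `sqrt(b - 1)`), so very small gene panels should lower `n_bins`.

Gene symbols are matched uppercased everywhere, so mouse-cased (`Vim`) and
human (`VIM`) data hit the same signatures; no ortholog mapping beyond
casing is attempted.

## ssGSEA scoring

For each cell, genes are ranked by expression descending with average
ranks for ties. Walking the ranking, the in-set CDF is weighted by
`rank^alpha` and the out-set CDF is uniform over the out-of-set genes; the
score is the **sum over all positions** of their difference. This full
running sum is stated explicitly because GSEA variants differ (the
classical enrichment score is the maximum deviation instead).

* `alpha` defaults to 0.25, the customary ssGSEA exponent; `alpha = 0`
  reduces the statistic to a pure rank statistic with a closed form, which
  is what the test suite's brute-force oracle enumerates exactly.
* Because only ranks enter, unnormalized scores are invariant to any
  strictly monotone transform of a cell's expression vector (a tested
  property).
* The optional normalization divides all scores in a run by
  `max − min` across cells, never per cell; it is off by default so scores
  from different sets remain on the same additive scale.
* A set covering none or all of the matrix genes leaves one of the CDFs
  undefined and is a hard error rather than a silent zero.

The overlap-robustness rerun (`exclude_overlap`) removes from each EMT set
its intersection with the subtype signature and rescores; the pipeline
reports the per-axis Spearman correlation between before/after scores. On
default synthetic data (20 planted shared genes) this exceeds 0.99,
mirroring the expectation that a ~4% Jaccard overlap cannot drive the
placement.

## nnPCA

The model maximizes `wᵀ C w` over unit loadings `w ≥ 0`, where `C` is the
covariance of the centered, gene-set-restricted matrix `X`. The EM
formulation projects (`y = X w_t`) and re-estimates `w` by minimizing
`Σ_n ‖x_n − y_n w‖²` under the constraint; the constrained minimizer has
the closed form `w ∝ max(Xᵀ y, 0)` (the objective is separable in the
coordinates of `w`), followed by renormalization. This was chosen over an
iterative NNLS solver for determinism and speed; an SVD oracle test
verifies the two agree when the constraint is inactive, and a grid-search
oracle covers the constraint-active degenerate case.

Numerical choices:

* **Initialization**: the absolute value of the leading right singular
  vector of the current (deflated) matrix — deterministic, no restarts.
  The seed argument is consumed only by the degenerate fallback tie-break.
* **Convergence**: infinity norm of the loading change `< 1e-6`, at most
  500 iterations; non-convergence is flagged, logged and non-fatal.
* **Orthogonality** is achieved by deflating in score space,
  `X ← X − y (yᵀX)/(yᵀy)`, so the scores of successive components are
  orthogonal *by construction* — exactly, including when the
  non-negativity constraint is active. (Rank-one loading deflation
  `X − y wᵀ` guarantees this only at unconstrained fixed points, which is
  why the projection form is used.)
* **Degenerate fallback**: if `Xᵀy` has no positive entry there is no
  feasible positive direction; the component restarts from the
  highest-variance single-gene axis (ties broken by a seeded draw) and the
  loop continues.
* **Variance explained** is `var(y_k)` divided by the total variance of
  the centered restricted matrix *before any deflation*; the denominator
  choice is recorded in the serialized model. Scores are reported raw —
  negative values are expected after centering and are never shifted or
  re-signed.

Component selection is the two-criterion rule: keep the five components
with the highest variance explained, then re-rank them by the variance of
the per-subtype mean scores, descending; ties break by variance explained,
then by index. The leading E component on synthetic data explains more
variance than the leading M component while the two M components are
comparable — the signature of a coherent E program against a mesenchymal
program split across two orthogonal directions.

## Archetype subtyping by stratified resampling

Cells with an archetype weight strictly above 0.95 are that archetype's
specialists; the threshold must exceed 0.5 so the label is unique, and the
bound is strict (a weight of exactly 0.95 is a generalist). For each
archetype × signature pair, the specialists' mean signature score `m` is
compared with `B = 1000` resampled means of size `n_a` drawn with
replacement from the non-specialist cells. Because some time points
contribute very few cells, the draw is allocated evenly across strata,
with the remainder going to the largest strata (then name order) — a
deterministic rule given the seed.

* The p-value counts null means **at or above** `m`. Under the literal
  "percentage above" reading, constant data would give `p = 0`
  (spurious enrichment); counting ties against enrichment yields the
  conservative `p = 1` there. `strict_greater = TRUE` restores the literal
  reading, and `smoothing = TRUE` gives `(count + 1)/(B + 1)`.
* P-values are Holm-adjusted across the whole archetype × signature
  family; `q < 0.1` is significant. Archetypes significant for several
  signatures get merged labels in canonical subtype order (`A/N`, `P/Y`);
  archetypes significant for none stay `unassigned`.
* Calibration is tested: with specialists drawn from the null, the p-value
  distribution is approximately uniform, and the family-wise
  false-labeling rate over simulated archetypes stays within the Holm
  bound plus Monte-Carlo margin.

## M1/M2 divergence and correlations

Mesenchymal genes are contrasted between the N-class (or merged A/N) and
Y-class cells on the **lognorm** layer (comparisons are never made on the
scaled layer, whose per-gene standardization destroys additive meaning).
Each gene gets the N−Y difference of means, a two-sided Mann–Whitney
p-value (exact enumeration at small tie-free sizes via `wilcox.test`, the
tie-corrected normal approximation otherwise), and a Benjamini–Hochberg
q-value computed across the M set. `q < 0.05` splits the significant genes
by sign into M1 (higher in NE) and M2 (higher in Y); the rest stay
unclassified. Holm is reserved for the subtyping family-wise test and BH
for this discovery-style gate, mirroring the different error-rate goals.
Classification is per dataset; cross-dataset consistency is reported as
the Pearson correlation of the per-gene mean differences over shared genes
rather than by intersecting significance calls.

Score–score and score–gene associations use Spearman correlation per cell
stratum. ASCL1 positivity is defined as any detected transcript (lognorm
expression > 0) — positivity thresholds are never standardized in the
field, so the most inclusive definition is the default and the threshold
is an argument. Strata with fewer than 3 cells are skipped, not errored.

## The synthetic generator

`simulate_dataset()` emits negative-binomial counts
(`var = mu + phi mu²`, shared dispersion `phi = 0.4`) with lognormal
library sizes (meanlog `log(5000)`, sdlog 0.3) for five subtypes × 500
cells over a gene universe of 232 E, 96 M1, 97 M2, 85 signature-only and
1000 background genes. Planted structure, all on the log-mean scale with
effect size 1.0 by default:

* E genes up in A2 (full effect) and mildly in A (0.4×), down in P/Y
  (−0.4×) — A is intermediate on both axes.
* M1 genes up in A and N; M2 genes up in P and Y; each subtype's signature
  block up in its own subtype. The 20 overlap genes are EMT genes placed
  in the signature of the subtype where their program is active (10 E in
  the A2 block, 5 M1 in N, 5 M2 in Y), so their two roles are consistent.
* A per-cell latent epithelial factor (SD 0.3, loading 0.7) scales E-gene
  means within the NE subtypes *and* tilts the A2 archetype weight of
  generalist cells, creating the within-subtype A2–E coupling the
  correlation stage is designed to detect. Treated cells receive an extra
  M2 latent shift (+0.5), emulating a treatment-induced mesenchymal drift.
* 70% of cells are specialists (own-archetype weight drawn above 0.95);
  generalists get near-uniform Dirichlet weights. Time points (3) and
  treatment (50%) are assigned independently.

The effect size, set sizes, overlap and specialist threshold mirror the
study conditions the pipeline targets; baseline expression levels and the
latent-factor scale were chosen once as typical of UMI data with clearly
resolvable subtypes and are not tuned per test. The generator does **not**
emulate batch effects, doublets, ambient RNA, zero-inflation beyond NB
sampling, gene–gene correlation outside the planted programs, or realistic
gene-level mean–variance trends. Green tests therefore certify that the
statistics recover structure they are designed for under their own
assumptions — not that any particular real dataset satisfies those
assumptions.

Validation problem sizes: unit and property tests run on matrices of tens
of cells; the end-to-end checks use the full default of 2500 cells ×
~1600 genes, 1000-resample enrichment tests, 200 calibration replicates and
500 simulated null archetypes, sizes at which the Monte-Carlo margins in
the assertions are comfortable.

## Degenerate inputs and edge rules

* Duplicate cell/gene IDs, dimension mismatches and missing MTX companion
  files are hard errors naming the offenders.
* All-zero cells cannot be total-count normalized and are reported by ID;
  filter first.
* Constant genes scale to all-zero; a gene set covering all or none of the
  matrix is unscoreable; a stratum with no non-specialist cells aborts the
  resampling test by name.
* Text round trips are exact: matrices are written with full double
  precision (`%.17g` for CSV; Matrix Market via `Matrix`).

## Limitations

* ssGSEA scores are comparable within a run, not across datasets with
  different gene universes; the cross-dataset statistic is therefore the
  correlation of contrasts, never of raw scores.
* nnPCA deflation makes component *scores* orthogonal; the loadings of
  later components are not orthogonal in general (non-negative vectors
  rarely can be), matching the behavior of non-negative factorizations.
* The resampling test conditions on the supplied archetype weights; errors
  in upstream archetype fitting propagate.
* With `B = 1000`, p-values are granular at 0.001; Holm-adjusted decisions
  near the threshold should be read with that granularity in mind.
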