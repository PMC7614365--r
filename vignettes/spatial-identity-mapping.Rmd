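---
title: "Spatial identity mapping of spheroids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial identity mapping of spheroids: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromap)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design choices that were
genuinely open.

## The mapping model

A query culture is summarised as a pseudo-bulk profile: the arithmetic mean
of the CP10K-log1p normalized expression
(`norm = ln(1 + raw * 1e4 / total)`) over all QC-passing cells. Averaging
before correlating is deliberate — single-cell profiles of full-length
protocols are noisy, and the identity question ("which embryo region does
this culture resemble?") is a population-level one.

**Static mapping.** For each spatially anchored reference sample `i` (an
embryo sample with a known vertex on a triangulated surface, in μm), we
compute the sample Pearson correlation `r_i` between the query and the
reference profile over a shared gene set. Correlation is scale-free, so
depth differences between in-vitro and in-vivo libraries largely cancel;
Spearman is available (`method = "spearman"`) for heavy-tailed deviations.
Multiple samples anchored at one vertex are averaged so the interpolation
problem stays well posed.

The anchored values are then interpolated to every mesh vertex by Gaussian
process regression with a squared-exponential kernel on 3D vertex
coordinates,

$$k(u, v) = \sigma_f^2 \exp\left(-\frac{\lVert x_u - x_v\rVert^2}{2\ell^2}\right),$$

with posterior mean $\bar f = m + k_*^\top (K + \sigma_n^2 I)^{-1}(y - m)$,
where `m` is a constant prior mean (the mean of the anchored values) and the
system is solved by Cholesky factorization with an escalating jitter
(1e-8 → ×10 → 1e-4, then an explicit error). Correlation fields fluctuate
around a decidedly non-zero level (~0.7–0.9 on synthetic data), which is why
the constant mean is the default; a zero-mean variant (`mean = "zero"`) is
kept because the textbook posterior formula, and hence the package's
linear-algebra oracle checks, are stated in that form. Predicted static
fields are clipped to [−1, 1]: GP means can overshoot the correlation range
between anchors, and the clip is recorded in the field's metadata.

**Distance choice.** The kernel distance is Euclidean in 3D, not geodesic
along the surface. For a surface sampled densely relative to `ℓ`, the two
are close; geodesic distances would couple the mapping to mesh quality and
are left as a config stub.

**Hyperparameters.** The mapping default is a *fixed* length-scale
`ℓ = diameter/6` with `σ_f² = var(y)` and `σ_n² = var(y)/10`. This was
calibrated on synthetic atlases: marginal-likelihood optimisation (which the
package also implements: 5 deterministic L-BFGS-B starts on
`(log ℓ, log σ_f², log σ_n²)` with bounds `ℓ ∈ [min edge length, diameter]`,
`σ_n² ≥ 1e-6`, analytic gradients) reliably drives `ℓ` to the diameter bound
because the dominant signal is the global disc-versus-amnion contrast; the
resulting ultra-smooth field washes out sub-lineage structure and can move
the field maximum out of the correct sub-region (notably from the proximal
amnion into the distal cap, whose flattened geometry concentrates vertices
and invites superposition overshoot). A scan over atlas seeds showed
`diameter/6` recovers all four regions' argmax reliably, `diameter/4`
fails the proximal amnion on some atlases, and `diameter/8` under-smooths
the posterior disc. Optimisation remains available (`optimize = TRUE`) and
is the right choice when the data really are a GP draw — the
parameter-recovery test demonstrates `ℓ` recovery within 25% in that
setting.

**Dynamic mapping** is the signed per-vertex difference
`Δ(v) = f_perturbed(v) − f_control(v)` of two static fields on the same mesh
with the same metric. Its null behaviour (two independent control
replicates) is a key diagnostic: the spatial mean of a null `Δ` should be
indistinguishable from zero relative to the Monte-Carlo error estimated
from replicate pairs. Note that the spatial mean of `|Δ|` is a positive
statistic whose expectation is necessarily of the same order as its
replicate spread; the signed spatial mean is the quantity that is actually
zero under the null, and both are reported.

**Ternary coordinates.** Marker triples (default SOX2 / TFAP2A / VTCN1:
disc, pan-amnion, mature amnion) are normalised to barycentric proportions
`p_i = m_i / Σm` and embedded with simplex corners (0,0), (1,0),
(1/2, √3/2); a perturbation arrow runs from the control point to the
perturbed point.

## The lineage space

Gene selection uses canonical correlation analysis between the in-vivo and
in-vitro pseudo-bulk sets **with genes as observations and profiles as
variables** — the cross-dataset convention of single-cell integration
tools. Covariances are ridge-regularized (`γ = 1e-3` by default; `γ = 0`
gives exact CCA) because profile sets can be few and collinear. The
implementation whitens in the profile subspace via an SVD, which is cheap
(profiles ≪ genes) and is cross-checked in the tests against both a
generalized-eigenproblem oracle and `stats::cancor`. Per-gene scores are the
absolute canonical-variate coordinates averaged over the two datasets,
maximised over the first `n_components = 2` pairs; the default `top_k`
(500 in the function, 300 in the pipeline configs, which use smaller gene
complements) is large enough for stable Pearson correlations downstream and
small enough to discard the background.

PCA is fitted on the in-vivo profiles over the selected genes (centered,
optionally scaled), with loading signs fixed (largest-magnitude entry
positive) so results are reproducible across linear-algebra backends. The
decision boundary is a linear soft-margin SVM (`C = 1`) in the PC1/PC2
plane only, matching the two-dimensional readout the method is used for;
`d(x) = w·x + b` is oriented so `d > 0` means embryonic disc. Stage
assignment is the argmax Pearson correlation against staged reference
pseudo-bulks, with ties broken CS5 < CS6 < CS7 and flagged.

## The synthetic data generator

The generator defines the study conditions for every validation claim; its
defaults are fixed and the tests run at those defaults.

* **Mesh**: two opposing spherical caps joined at a rim (disc cap deep,
  amnion cap flattened by 0.45 — columnar vs squamous), rim radius 100 μm,
  500 vertices by default, 2% seeded radial jitter. Regions: disc split
  anterior/posterior by the tangential x axis, amnion split
  proximal/distal at polar angle π/4.
* **Markers**: logistic gradients of a stated axis coordinate with stated
  baseline/amplitude/steepness. POU5F1 is disc-broad; SOX2 and NANOG are
  graded towards the anterior disc and TBXT/MIXL1/WNT8A towards the
  posterior disc. A panel in which a single gene carries the
  anterior/posterior distinction leaves correlation-based mapping
  underpowered — one gene among hundreds cannot move a Pearson argmax — so
  each sub-region is marked by several genes, all of them named markers of
  the corresponding compartments in the primate embryo. TFAP2A/TFAP2C are
  pan-amnion, VTCN1/GABRP/HAND1 grade towards the distal (mature) amnion,
  and ISL1 is low and rim-biased over the amnion. 1,990 background genes
  (constant, lognormal levels) and 300 random-smooth genes (exponentiated
  GP samples with an independent seed stream and `ℓ = radius/2` — a
  different value than the mapping default, to avoid circularity) complete
  the complement.
* **Counts**: negative binomial with `Var = m + m²/θ`, `θ = 10`; per-cell
  lognormal depth factors with log-sd 0.3 normalised to unit mean so that
  the expected count of a gene equals its field mean — this keeps the
  convex archetype-mixing model (`mean = (1−λ)·source + λ·target`) exactly
  linear in expectation, which the tests verify. The nominal depth scale
  (log-mean 9.2) matches full-length, Smart-seq-like libraries.
* **Stages**: the nominal stage (CS6) mean is the unmodified archetype;
  CS5/CS7 scale the marker block (×0.7 / ×1.3) and additionally up-regulate
  disjoint 30-gene background signatures. Purely scaling markers does not
  make stages identifiable by correlation — a reference with amplified
  markers correlates *better* with any marker-dominated query — so the
  stage signatures carry the recoverable identity.
* **Image stacks**: an epithelial shell (outer 30 μm; inner 14 μm columnar /
  28 μm squamous, i.e. an 8-fold thickness contrast) with ellipsoidal
  nuclei placed mid-shell on a jittered golden-spiral grid; major axes
  radial (epi) or tangential (am); 0.8 μm voxels; per-nucleus channel
  intensities drawn around per-kind means (DAPI 200; SOX2 150/10;
  TFAP2C 10/150, sd 10).

**What the generator does not emulate**: real gene counts or genome
annotation, sequencing error and doublets, batch effects, feeder-cell
contamination, segmentation errors in the label volumes, and optical
artefacts (PSF, bleaching). Passing the recovery tests therefore shows the
*method* is correct and well-calibrated under a realistic noise model — not
that any particular real dataset will map cleanly.

## Numerical choices and degenerate inputs

* Cholesky jitter escalation 1e-8 → 1e-4, then error; `σ_n² = 0` is allowed
  and noise-free interpolation is exact to 1e-8.
* Zero-variance profiles are errors in correlation (not NA propagation);
  zero-variance genes z-score to 0; DE fold changes use `ε = 0.01` on the
  normalized scale; intensity ratios use `ε = 1e-6`.
* HVG and CCA gene rankings break ties by gene order; stage ties break
  CS5 < CS6 < CS7; a query exactly on the SVM boundary reports the
  sentinel label `"boundary"`.
* Near-isotropic nuclei (eigenvalue ratio < 1.1) are flagged degenerate
  rather than assigned a meaningless angle; voxelized spheres can reach
  ratios ≈ 1.17, so analyses of deliberately spherical nuclei should raise
  the threshold.
* QC defaults (2,000 genes detected, 50,000 total counts) are full-length
  protocol scale; the synthetic pipeline configs use lower thresholds
  matched to the generator's depth. All are config-exposed.
* Wilcoxon p-values use the exact distribution where R provides it (small
  groups without ties) and the normal approximation otherwise; Dunn's
  post-hoc z statistics use the tie-corrected variance and Bonferroni
  adjustment.

## Problem sizes used in validation

The validation experiments run at the generator defaults: a 500-vertex
mesh, 2,302 genes (12 markers + 1,990 background + 300 random-smooth), 12
reference samples per region, and 200-cell queries; region recovery and
dynamic-map signal use 100 seeded runs each, the dynamic null 20 replicate
pairs, and the type-I-error calibration 10,000 Shapiro-Wilk draws at
n = 50. The GP parameter-recovery study runs at 120 anchors × 20 seeds —
enough to demonstrate consistency of the marginal-likelihood estimator
while keeping the suite quick. Unit tests use smaller meshes and gene
complements; at those reduced sizes the proximal/distal amnion distinction
is genuinely underpowered, so the pipeline wiring test asserts lineage-level
argmax placement and leaves exact sub-region recovery to the full-scale
validation.

## Known limitations

* The mapping treats the reference mesh as fixed; no registration across
  stages or specimens is attempted.
* Euclidean kernel distances ignore surface topology; across a deep cleft
  the interpolation can leak identity between surfaces that are close in
  3D but far along the tissue.
* The fixed-`ℓ` default trades marginal-likelihood optimality for argmax
  robustness; for questions about the *global* identity trend rather than
  sub-region placement, `optimize = TRUE` is preferable.
* CCA gene selection assumes the two datasets share most of their
  informative variation; a perturbation that creates genuinely novel
  programmes would be under-selected.
* The decision boundary is binary (disc vs amnion) and linear in PC1/PC2 by
  design; it is not a general cell-type classifier.
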