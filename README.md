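# spheromap

Spatial identity mapping of stem-cell spheroids onto a 3D primate embryo
reference.

## The problem

Stem-cell–derived spheroids are used as in-vitro models of the
postimplantation primate embryo: columnar *Epi-spheroids* model the
pluripotent embryonic disc, squamous *Am-spheroids* model the amnion. Before
such cultures can be used to dissect signalling (ACTIVIN/NODAL, BMP, FGF,
WNT), they must be **authenticated** against the embryo itself: which region
of the embryonic disc or amnion does a culture actually resemble, at which
developmental stage, and how does a signalling perturbation move it?

`spheromap` implements that authentication as a reusable pipeline for
computational biologists:

* **Static spatial identity mapping.** The query culture's pseudo-bulk
  profile `q` (mean CP10K-log1p expression of all QC-passing cells) is
  compared to spatially anchored reference samples by Pearson correlation
  `r_i = cor(q, ref_i)` on a shared gene set. Each `r_i` is attached to its
  anchor vertex on a triangulated embryo surface and interpolated to every
  vertex with Gaussian process regression using a squared-exponential kernel

  `k(u, v) = σ_f² exp(−‖x_u − x_v‖² / (2ℓ²))`,

  giving the posterior mean field `f(v) = k_*ᵀ (K + σ_n² I)⁻¹ y` (plus a
  constant prior mean), clipped to the correlation range [−1, 1].
* **Dynamic spatial identity mapping.** The signed per-vertex difference
  `Δ(v) = f_perturbed(v) − f_control(v)` localises where on the embryo a
  perturbation gains (Δ > 0) or loses (Δ < 0) identity.
* **Lineage space.** Canonical correlation analysis across the in-vivo and
  in-vitro pseudo-bulk sets selects the shared informative genes; PCA of
  those genes and a linear soft-margin SVM fitted on in-vivo samples give an
  embryonic-disc-vs-amnion decision boundary (`d(x) = w·x + b`, `d > 0` ⇔
  EmDisc). Stage assignment is the argmax Pearson correlation against staged
  reference pseudo-bulks.
* **Morphometrics.** On labelled 3D image stacks: per-nucleus orientation
  (principal axis of the voxel second-moment matrix versus the radial
  direction, folded to [0, 90]°), radial epithelial thickness, per-frame and
  summed channel intensities, DAPI normalisation, and the associated tests
  (Mann-Whitney, Welch t, Kruskal-Wallis + Dunn, Shapiro-Wilk).
* **Synthetic data.** Every input can be generated with known ground truth:
  a two-cap embryo mesh with four labelled regions, logistic marker
  gradients (SOX2/POU5F1/NANOG, TBXT/MIXL1/WNT8A, TFAP2A/TFAP2C,
  VTCN1/GABRP/HAND1, ISL1), negative-binomial counts
  (`Var = m + m²/θ`) with lognormal depth factors, archetype-mixing
  perturbations (`mean = (1−λ)·source + λ·target`), and voxelized spheroid
  stacks with controllable nuclear orientation and shell thickness.

## Worked example

Map a simulated amnion spheroid onto a synthetic embryo reference:

```r
library(spheromap)

atlas <- build_synthetic_atlas(seed = 1, n_vertices = 300, n_background = 500,
                               n_smooth = 80, samples_per_region = 8,
                               cca_top_k = 200, cells_per_archetype = 100)

m <- sample_spheroid_cells(atlas$fields, atlas$mesh, "Am_distal", "Am_distal",
                           0, sim_config(seed = 2, cells_per_spheroid = 100),
                           condition = "am_spheroid")
m  <- normalize_counts(qc_filter(m, min_genes_detected = 50,
                                 min_total_counts = 500))
pb <- pseudo_bulk(m, "condition")

proj  <- project_similarity(pb_profile(pb, "am_spheroid"), atlas$ref,
                            atlas$gene_set)
field <- gp_predict(fit_gp(proj$anchored, atlas$mesh), atlas$mesh,
                    query_id = "am_spheroid")
field_region_summary(field, atlas$mesh)
```

This prints (exact numbers depend only on the seeds above):

```
 EmDisc_anterior EmDisc_posterior      Am_proximal        Am_distal
           0.768            0.768            0.854            0.877
argmax region: Am_distal
```

i.e. the interpolated identity field peaks in the distal amnion — the region
the cells were simulated from — with correlations ~0.88 there versus ~0.77
over the embryonic disc. Classifying the same pseudo-bulk in the
SVM-bounded lineage space:

```r
model <- fit_pca(atlas$ref$profiles, atlas$gene_set, n_pcs = 2)
model <- fit_lineage_boundary(model,
           ifelse(grepl("^EmDisc", atlas$ref$lineage), "EmDisc", "Am"))
classify_profile(model, pb_profile(pb, "am_spheroid"))
#>   profile label  decision
#> 1   query    Am -2.721125
```

The negative decision value places the culture firmly on the amnion side of
the boundary. An end-to-end run (simulation → preprocessing → lineage space
→ static/dynamic maps → ternary coordinates → JSON report):

```r
report <- run_all(default_run_config(out_dir = "out", seed = 1))
```

A thin CLI wrapper for the same pipeline ships in `inst/cli/spheromap.R`.

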