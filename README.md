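# shaftshape

Does the shape of a long-bone shaft diverge between closely related taxa the
way their neutral genes do, or has selection pulled it away — and does the
answer change over growth? `shaftshape` implements a complete analysis
pipeline for that question, built around the four *Pan* taxa (three
chimpanzee subspecies and the bonobo) as its model system: landmark-free
morphometric quantification of femoral diaphysis surfaces, ontogenetic
trajectory analysis in shape space, population-genetic distance matrices,
Pst/Qst quantitative-genetic differentiation, and stage-wise tests of the
congruence between phenotypic and neutral genotypic distance structure.

## The method

**Phenotype quantification.** Each diaphysis mesh is sliced into cross
sections along its axis and summarized as a *morphometric map*: a fixed grid
(axial level × anatomical angle, anterior = 0°, medial = 90°, posterior =
180°, lateral = 270°) of the transverse radius of curvature — the radius of
the circle best fitting the sectional outline at each surface point. Sharp
crests such as the linea aspera appear as bands of small radius. Size is
removed by the level parameterization and by dividing each map by its median
radius.

**Shape space.** Normalized maps are vectorized and decomposed by PCA.
Taxon-by-stage mean shapes define per-taxon ontogenetic trajectories
(dental stages m2 → M1 → M2 → M3); trajectory length, direction and
location are compared by stage-stratified permutation tests, and the
ancestral (LCA) trajectory is reconstructed by squared-change parsimony —
the Brownian-motion maximum-likelihood ancestral state — on the *Pan*
phylogeny.

**Genotypes.** From biallelic genotype tables the package computes Nei's
standard distance, the Cavalli-Sforza–Edwards chord distance, Hudson's
ratio-of-averages Fst, and Euclidean distances between taxon centroids in
Patterson's normalized PC space (matrices **F**).

**Congruence.** Per ontogenetic stage *i*, phenotypic distance matrices
**M**_i (Euclidean in morphospace) and quantitative-genetic matrices
**Q**_i (pairwise Qst from Pst, `Qst = V_B / (V_B + 2 h² V_W)` with h² =
0.55 by default) are compared to **F** by principal coordinates embedding +
Procrustes superimposition, one-sided Mantel tests (exhaustive 24-relabeling
null for 4 taxa), and an individual-level resampling correlation of
median-normalized phenotypic vs. allele-sharing distances. Under neutral
divergence **M** and **Q** are scaled copies of **F**; `Qst > Fst` flags
diversifying selection.

**Synthetic data.** Because the original CT and sequence data are not
shipped, a generator produces diaphysis-like tube meshes (taxon-specific
deformation fields, a growing posterior ridge, per-taxon heterochrony
rates, smooth surface noise) and Balding–Nichols genotypes with prescribed
pairwise Fst, via a star-model decomposition. Two presets encode the study
conditions: `neutral_congruent` (drift-proportional shape divergence) and
`heterochronic_divergence` (drift early, selection-like divergence late).

## Worked example

```r
library(shaftshape)

cfg <- run_config(
  mode       = "synthetic",
  scenario   = scenario_preset("heterochronic_divergence",
                               n_pheno_per_cell = 5),
  n_levels   = 32, n_angles = 60,
  n_perm     = 999, n_draws = 1000,
  output_dir = "run1", master_seed = 11)

res <- run_pipeline(cfg)
print(res$space)
#> shape_space: 80 specimens, 79 components (grid 32 x 60)
#>   PC1+PC2 variance share: 55.9%
for (r in res$reports) print(r)
```

```
stage m2    F-M Mantel r =  0.978 (p = 0.0417)  F-Q r =  0.763 (p = 0.0417)  resampling R2 = 0.711 (p = 0.0010)  Procrustes d = 0.0473
stage M1    F-M Mantel r =  0.964 (p = 0.0417)  F-Q r =  0.611 (p = 0.1250)  resampling R2 = 0.626 (p = 0.0010)  Procrustes d = 0.0163
stage M2    F-M Mantel r = -0.244 (p = 0.6667)  F-Q r = -0.129 (p = 0.5417)  resampling R2 = 0.030 (p = 1.0000)  Procrustes d = 0.1336
stage M3    F-M Mantel r = -0.506 (p = 0.7917)  F-Q r = -0.655 (p = 0.8750)  resampling R2 = 0.172 (p = 1.0000)  Procrustes d = 0.1537
```

Reading the output: at the infant stage (m2) the phenotypic taxon
constellation matches the neutral genotypic constellation (Mantel r = 0.98
at the smallest p the 24-permutation null can produce, 1/24 ≈ 0.042, and a
strong individual-level resampling correlation, R² = 0.71). Toward
adulthood the taxon-specific divergent effects dominate: by M2/M3 the
Mantel correlation is gone, the resampling R² has collapsed and the
Procrustes residual has tripled — the drift-early / selection-late
signature the heterochronic preset encodes. The run directory contains the
morphospace scores, all distance matrices, a Table-1-style congruence
table (CSV + JSON), trajectory coordinates including the reconstructed LCA,
false-color map renderings, and a manifest with seeds and a config hash.

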