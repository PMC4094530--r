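---
title: "Morphometric mapping and genotype–phenotype congruence: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric mapping and genotype–phenotype congruence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`shaftshape` asks whether between-taxon divergence of a quantitative,
highly polygenic phenotype — the external shape of the femoral shaft —
tracks neutral genotypic divergence, and how the answer changes over
ontogeny. This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the design decisions that were genuinely
open.

## The phenotype model: morphometric maps

A diaphysis is, topologically, a tube. We slice it with planes orthogonal
to the shaft axis at levels `(i - 0.5) / n_levels` of the span between the
distal and proximal epiphyseal ends — midpoint placement avoids the
degenerate planes through the open tube ends — and resample each sectional
outline at `n_angles` equally spaced angles about its centroid. Angles
follow the anatomical convention (anterior 0°, medial 90°, posterior 180°,
lateral 270°), referenced to a per-specimen anterior vector; for synthetic
meshes this comes from the generator frame, for user meshes it must be
supplied — no automatic anatomical orientation is attempted. The axis is
the end-to-end line refined once by a least-squares line through the
section centroids; additional passes are available (`refine`) but change
nothing measurable on nearly straight shafts, and a single pass keeps the
procedure deterministic and cheap.

At each outline point the *transverse radius of curvature* is the radius
of the circle least-squares fitted (algebraic Kasa fit, computed on
window-centered coordinates for numerical stability) to `window`
neighboring points, with periodic wrap at the angular seam. With
`window = 3` the fit interpolates and is computed directly as the
circumcircle. Flat regions would send the radius to infinity; radii are
capped at 10× the section's mean centroid distance and floored at 1e-6,
and the number of clamped points is kept in the map metadata. Curvature
sign is discarded: the radius is a positive quantity.

Defaults: 100 levels × 180 angles, window 5. The map grid is a resolution
choice, not part of the model; analyses in this package's tests and
acceptance script use 24–32 levels × 48–60 angles, which resolves every
feature the generator produces at a fraction of the cost. Size is removed
by the level parameterization (length) and by dividing the map by its
median radius; a normalized map has median exactly 1 and is invariant to
uniform scaling of the mesh (verified to 1e-6 over scale factors 0.5–10).

## Shape space, trajectories, ancestral states

Normalized maps are vectorized and decomposed by SVD about the grand mean;
component signs follow a deterministic convention (largest-magnitude
loading positive). Morphospace analyses take an explicit `n_components`;
where a default is needed (phenotypic distance matrices, the resampling
test, trajectory comparison) we use the smallest leading set explaining
90% of variance, config-overridable. Qst uses the first three components
by default, mirroring the convention of Pst analyses on shape PC scores.

A taxon's ontogenetic trajectory is the ordered path of its stage means
(m2 → M1 → M2 → M3); its length is the summed segment norm and its
direction the unit vector from first to last stage mean — the chord, not a
per-segment average, because the chord is what trajectory plots compare
visually and it is well-defined even when intermediate stages wobble.
Trajectory comparisons permute specimens between the two taxa within each
stage (stage structure preserved): the angle p-value is one-sided (is the
observed angle larger than relabeling noise?), the length difference
two-sided.

Ancestral states minimize the branch-length-weighted sum of squared
changes along the tree — squared-change parsimony, the maximum-likelihood
reconstruction under Brownian motion — solved exactly from the linear
stationarity system, per stage and per coordinate. The default tree is the
fully resolved `(((troglodytes, schweinfurthii), verus), paniscus)` with
unit branch lengths: western chimpanzees are a *P. troglodytes* subspecies
and bonobos the outgroup, so a resolved ladder represents *Pan* systematics
better than an unresolved trifurcation; relative divergence times can be
supplied as Newick branch lengths. With unit branches the root
reconstruction is a weighted average that the tests cross-check against a
numerical optimizer.

## Genotypic distances

Four between-taxon matrices **F** are computed from biallelic genotype
tables: Nei's standard distance (J-coefficient form; the D\_A variant of
Nei, Tajima and Tateno is available by flag, since the two are often
conflated in the literature), the Cavalli-Sforza–Edwards chord distance in
the per-locus form `(2/π)√(2(1 − Σ√(p_A p_B)))` averaged over loci (chord
formulas differ by constants between publications, so the variant is
recorded in the matrix metadata), Hudson's Fst as a ratio of averages with
the standard small-sample correction of the numerator (robust for small,
unbalanced samples), and Euclidean distances between taxon centroids in
Patterson's normalized PC space (default dimension: number of taxa − 1).
Missing genotypes are handled pairwise-complete per locus; loci
monomorphic in a pair are skipped for Fst.

## Pst/Qst

For a taxon pair at one stage, per shape component, the pooled
within-taxon variance `V_W` and the small-sample-corrected between-taxon
variance `V_B = (m₁−m₂)²/2 − V_W(1/n₁+1/n₂)/2` (clipped at 0) give

  Qst = Σ V_B / (Σ V_B + 2 h² Σ V_W)

summed over components — summation preserves the variance-ratio
interpretation; a per-component mean is available by flag. The default
heritability is h² = 0.55. This pairwise two-group decomposition is a
deliberate, documented simplification relative to full R-matrix machinery
with sample-size bias correction: downstream analyses consume the *matrix
structure* of **Q**, and because h² enters all pairs as a common scale
factor, matrix-correlation statistics are nearly invariant to it —
`h2_sensitivity()` quantifies exactly that. Absolute Qst magnitudes, by
contrast, depend on the ratio of between- to within-taxon variance; the
mesh generator's conditions (strong heritable divergence, modest
environmental surface noise) put Pst-based Qst well above the generating
Fst at every stage, which is why all congruence conclusions here rest on
matrix correlation, not on Qst magnitude. The score-level generator
`simulate_drift_scores()` implements the drift-consistent calibration
(between-group variance `2F/(1−F)·h²·V_W`), under which the estimator's
mean tracks the generating F to within ±0.05 — the residual deviation is
the Jensen bias of a ratio whose numerator has ~3 effective degrees of
freedom, intrinsic to two-group Qst estimation, not an implementation
artifact.

## Congruence machinery

Distance matrices are embedded by classical scaling (PCO); negative
eigenvalues of non-Euclidean inputs are reported in metadata and their
axes dropped. Constellations are aligned by Procrustes superimposition in
the symmetric normalized form (vegan's engine behind the package surface),
so the residual does not depend on which matrix is the reference.

The Mantel statistic is the Pearson correlation of upper-triangle entries;
the null permutes taxon labels of the second matrix. With 4 taxa there are
only 24 relabelings, so the test enumerates them exhaustively and the
p-value has resolution 1/24 ≈ 0.042 — significance at the 5% level is
attainable only when the observed ordering beats all 23 alternatives. An
element-wise permutation scheme (shuffling off-diagonal entries
independently) is implemented and flagged as such; it is not a valid
matrix permutation test under label exchangeability but shows what a finer
null resolution would claim.

The individual-level resampling test draws `n_draws` (default 1000)
unordered cross-taxon pairs; each draw samples one phenotyped individual
from each taxon (Euclidean score distance) and, independently, one
genotyped individual from each (allele-sharing distance, 1 − mean shared
allele proportion — the individual-level metric is not dictated by any
convention, so the choice is recorded in the report). Both samples are
divided by their medians, making R² invariant to rescaling either side;
the p-value permutes the genotype-side taxon labels with the same pair
sequence. Phenotype and genotype individuals are sampled independently
because the two datasets need not contain the same specimens.

## The synthetic-data generator

The generator defines the study conditions; every downstream claim is
relative to them. A specimen surface is

  r(θ, z) = r₀(z) + ridge + drift field + divergent field + noise

with r₀ a 10 mm tube with 12% end flare, and a posterior (θ = 180°)
Gaussian ridge — a linea-aspera stand-in — whose amplitude grows linearly
with effective developmental age = stage index × heterochrony rate.
Lengths grow with age (90 mm at age 0, +25% per age unit); heterochrony
thus moves a taxon along a shared growth direction at its own rate.

Taxon-specific deformations are low-order trigonometric fields on (θ, z).
Two design points matter:

* **Curvature-space normalization.** A radial perturbation of angular
  order m changes sectional curvature in proportion to m² − 1, so fields
  normalized in surface mm would reach the curvature map with an
  essentially random magnitude dominated by their highest orders. Field
  coefficients are therefore shaped by 1/(m²−1) and normalized in the
  gain-weighted norm: each taxon's displacement arrives in map space with
  deterministic magnitude, spread nearly isotropically over ~200 modes.
  Order-1 modes (section translations, invisible to centroid-referenced
  curvature) are excluded.
* **Smooth noise.** Within-taxon noise is a random field of angular order
  ≤ 2 (RMS = `noise_sd`, default 0.25 mm), not vertex jitter: white noise
  would explode under the curvature differentiation and bury every signal.
  This emulates smooth individual variation (periosteal remodeling,
  soft-tissue-scale shape differences), not CT segmentation noise.

The drift component of taxon k is its field scaled by
`pheno_base_amp · √F_k`, where the per-taxon drift levels F_k come from
the least-squares star-model inversion of the pairwise Fst targets
(frequency-level Hudson Fst between star-model taxa is (F_i + F_j)/2; the
fit residual is recorded, and non-representable target matrices are
rejected). Genotypes are Balding–Nichols: ancestral frequencies uniform on
(0.05, 0.95), taxon frequencies Beta with variance `F_k p₀(1−p₀)`,
genotypes binomial. Defaults: 4 taxa × 4 stages, 10 phenotypes per cell
(the empirical sample is 146 femora over 16 cells, ≈ 9 per cell), 18
genotyped individuals per taxon (≈ N = 74 over 4 taxa), 2000 loci
(emulating the information content of ~150 kb of resequenced non-coding
sequence at SNP level; with a few hundred loci the between-pair signal of
individual-level allele-sharing distances drowns in locus-sampling noise,
which scales as 1/√L). Default drift levels F_k = 0.06/0.12/0.24/0.40
(bonobos most diverged) are deliberately well separated: with a
24-permutation Mantel null, near-exchangeable taxa make the smallest
attainable p-value unreachable no matter how strong the congruence.

Presets:

* `neutral_congruent` — drift-proportional divergence only, constant over
  stages, equal heterochrony rates. Phenotypic structure should track
  genotypic structure at every stage.
* `heterochronic_divergence` — adds taxon-specific divergent fields with
  amplitude growing as (stage index)^1.5 (amplitudes 0.32/0.10/0.28/0.14
  mm-scale, deliberately *decorrelated* from the drift ordering so that
  late-stage structure carries no residual neutral signal) and distinct
  heterochrony rates (1.0/0.7/1.2/1.4; the eastern chimpanzee's short,
  slow trajectory mirrors the shortest observed ontogenetic trajectory).
  Congruence is high in infancy and erodes toward adulthood, and
  last-stage Qst exceeds the generating F — the drift-early /
  selection-late signature.

What the generator does *not* emulate: real cortical-bone geometry
(no muscle attachment sites other than one ridge, no curvature of the
shaft axis beyond noise, no cross-sectional asymmetry drift), measurement
error of CT segmentation, missing data, or age-estimation uncertainty in
dental staging. Passing tests therefore demonstrate that the pipeline
recovers known structure under controlled conditions — not that real
femora behave this way.

## Numerical choices and degenerate inputs

* Section planes that miss the surface, cut it in more than one closed
  curve, or meet a hole are reported with the level index; loop counting
  walks the crossing-face graph. The check is exact but costs ~40% of map
  time, so bulk simulations may disable it after validating inputs once
  (`validate_inputs()` performs a full closed-tube audit).
* Collinear curvature windows clamp to the cap rather than erroring.
* Exact plane–vertex hits are resolved by nudging the plane 1e-9 inward.
* Permutation p-values use (b + 1)/(n + 1) when sampling and the exact
  proportion when enumerating; enumeration replaces sampling whenever the
  group sizes allow ≤ 10⁴ cases (mean-shape test) or n! ≤ 5040 (Mantel).
* All stochastic stages derive child seeds from one master seed via a
  fixed affine scheme; two runs with the same configuration are
  byte-identical, which the test suite asserts on the written artifacts.
* Problem sizes in tests and the acceptance script (mesh 48 × 60, maps
  24–32 levels × 48–60 angles, 20 replicate seeds for preset-level
  claims) were chosen once as the smallest sizes at which the generator's
  features are fully resolved and replicate medians are stable.

## Known limitations

* The curvature estimator reconstructs the spirit of published
  morphometric mapping of long-bone shafts; the original method's exact
  smoothing pipeline is not public, so constants (window, grid, clamps)
  are this package's own and are recorded in map metadata.
* Pst-based Qst magnitudes inherit every caveat of heritability
  assumptions; only their matrix structure is interpreted here.
* With four taxa the Mantel null has 24 states; p-values below 1/24 are
  impossible under label permutation, and reports should quote the
  resolution alongside the p-value.
* The interface accepts arbitrary taxa/stage counts, but the shipped
  presets and default tree are specific to the four-taxon *Pan* design.
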