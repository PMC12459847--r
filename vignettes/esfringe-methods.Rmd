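---
title: "Methods: ES trade-offs and synergies along urban-fringe-rural gradients"
author: "esfringe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ES trade-offs and synergies along urban-fringe-rural gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esfringe)
```

## The analysis in one paragraph

Metropolitan regions do not switch from city to countryside at a line:
between the built-up core and the rural hinterland lies a fringe belt in
which land use, population and economic intensity are transitional and
rapidly changing. `esfringe` studies how the outward movement of that
belt between two dates reorganises the supply of eight ecosystem services
(ES) and the relationships — synergies and trade-offs — among them. The
chain is: classify a 1-km grid into urban / fringe / rural zones at both
dates, type the transitions, compute eight fine-scale ES layers from
closed-form models, average them over village polygons (the smallest
planning unit), and analyse the village ES vectors with rank
correlations, a coupling-coordination degree model (CCDM) and
self-organizing-map (SOM) bundles.

## Zonation

Six features describe each 1-km cell: population density, GDP density,
the construction-land percentage PLAND = a/A × 100, mean nighttime-light
radiance, the landscape-fragmentation entropy W = −Σ Xₙ ln Xₙ over the
land-type proportions of the cell (0 for a single type, ln n at a uniform
mixture of n types), and a POI urban-function score. For the POI score,
each category's Gaussian kernel density nᵢ is combined with
hierarchical-analysis weights wᵢ; the per-type share
Fᵢ = nᵢwᵢ / Σ nᵢwᵢ × 100 is reported, and the cell feature is the
weighted total density min–max rescaled to [0, 100] across the grid — a
share alone would carry no urban-to-rural density gradient, which is the
signal the classifier needs. Kernel bandwidth defaults to 1000 m, one
feature cell. POI category weights are equal by default; they are a
stand-in for expert-elicited weights and fully configurable.

Classification uses a multilayer perceptron: two hidden layers of 128 and
64 rectified-linear units, dropout 0.5 after each, 3-class softmax
output, sparse categorical cross-entropy, Adam at learning rate 0.001, an
80/20 train/test split, and z-standardised features. Hidden activation,
epoch budget and batch size are not dictated by the architecture, so the
package uses standard choices — at most 200 epochs, batch 32, early
stopping (patience 20) on a 10 % validation split of the training
fraction. The held-out accuracy (correct / total) and per-class recalls
are reported with the model. Ties at the output argmax break toward the
lower class code (rural < fringe < urban) so classification is
deterministic. Water bodies are masked before feature assembly: connected
water components larger than 1 km² (strict inequality) become nodata;
small ponds stay.

Transitions between the two classified maps are typed into five classes —
urban maintenance (urban→urban), urban expansion (fringe→urban), fringe
maintenance, fringe expansion (rural→fringe), rural retention — with
downgrades (urban or fringe back to rural, urban to fringe) excluded as
negligible and non-systematic. The direct rural→urban jump is not named
by the five-class scheme; the package assigns it to urban expansion by
default and offers `rural_to_urban = "excluded"` as the alternative,
because a total typology keeps the transfer-matrix bookkeeping exact. The
zone transfer matrix is row-normalized over cells valid at both dates.

## The eight ES layers

All services are computed cell-wise at the fine resolution from
closed-form models with land-use-keyed parameter tables:

* **Food production.** Climate production potentials:
  WT = 30000 / (1 + e^(1.315 − 0.119 T)), WR = 30000 (1 − e^(−0.000664 R)),
  WV = 30000 (1 − e^(−0.0009695 (V − 20))) with L = 300 + 25T + 0.05T³ and
  V = 1.05R / √(1 + (1.05R/L)²); W = min(WT, WR, WV) and Yᵢ = W·Kᵢ. The
  precipitation- and evapotranspiration-limited forms are sometimes
  transcribed with a division (30000 / (1 − e^(−·))), which is unbounded,
  *decreasing* in precipitation and can exceed the 30 000 kg/ha/a ceiling
  — non-physical for a production potential. The package therefore
  defaults to the bounded saturating (multiplicative) forms of the
  Miami/Thornthwaite-Memorial family and keeps the division form behind
  `variant = "printed_division"` for fidelity testing. WT is bounded and
  increasing as printed and is used as-is.
* **Soil conservation.** SC = Rₑ·Kₑ·LS·(1 − C_f·P_f), clamped at 0.
* **Water yield.** Y = (1 − AET/P)·P, which collapses algebraically to
  max(P − AET, 0); P = 0 yields 0. Potential evapotranspiration is
  accepted and stored but unused by this formula — the package does not
  guess at a Budyko-type extension.
* **Carbon storage.** The four pools (above-ground, below-ground, soil,
  dead organic matter) are summed per land use; a product of pool
  densities would have mixed units and vanish whenever any pool is zero,
  so the sum — which is what pool-based carbon bookkeeping models
  actually do — is used.
* **Nutrient export.** ALV = HSS · pol for N and P; purification capacity
  is read as inversely proportional to export.
* **Habitat quality.** Q = H_j (1 − D²/(D² + k²)), half-saturation at
  D = k (default k = 0.5, a common half-saturation default). The
  degradation field D is not given in closed form anywhere, so the
  package defines it as a normalized-weight sum of linear distance decays
  from threat land uses (built-up weight 0.7 / 8 km, cropland 0.3 / 3 km
  by default): D = Σ w_r max(0, 1 − d_r / d_max,r) ∈ [0, 1].
* **Landscape aesthetics.** A pluggable input layer: fitting a
  presence-only suitability model is out of scope, so the generator
  supplies a smooth surface peaking near urban cores, matching the
  observed pattern that aesthetics (like water yield) peaks centrally.

Negative physical quantities are clamped to zero with a warning, and the
pipeline counts warnings in its manifest.

## Village-scale interaction analysis

Village values are area-weighted means of the service layers over each
village's valid (unmasked) cells. Min–max normalization is applied per
indicator with *both dates pooled*, so a village's normalized level is
comparable across time and a change of 0 means no change; per-date
normalization is available (`pool = FALSE`) for cross-sectional use.
Spearman correlation (average ranks on ties, the standard treatment)
either on levels per date or on per-village changes gives the
trade-off/synergy matrices; positive is synergy, negative trade-off.
Significance testing is deliberately omitted — the matrices are
descriptive, and coefficients are reported as-is.

The CCDM reads the eight normalized indicators as subsystems. Nitrogen
and phosphorus export are disservices, so they are inverted
(1 − normalized) into purification scores *before* entering the model;
`disservices = "raw"` disables this for comparisons whose sign semantics
must match the raw export. The coupling degree is, by default, the
geometric-to-arithmetic-mean ratio C = (ΠUᵢ)^(1/k) / mean(U): it is
exactly 1 when all subsystems are equal and 0 when any subsystem is
absent, which is the stated contract of the coupling concept. The
product-over-pairwise-sums form
C = [ΠUᵢ / Π_{i<j}(Uᵢ+Uⱼ)]^(1/k) is retained behind
`coupling_variant = "printed_product"`; it cannot reach 1 for equal
subsystems (for eight equal values it is far below 1), so it is not the
default. The composite level is the weighted sum T = ΣwᵢUᵢ with weights
0.12 for seven services and 0.16 for habitat quality (they sum to exactly
1; nitrogen and phosphorus are counted as separate indicators, which is
the only reading under which the weights close). Coordination is
D = C·T by default, with the conventional √(C·T) behind
`d_combiner = "sqrt_product"`; both are in [0, 1] and classified by
half-open intervals: [0, 0.2] F, (0.2, 0.4] E, (0.4, 0.5] D, (0.5, 0.6]
C, (0.6, 0.8] B, (0.8, 1] A — boundary values fall to the
lower-interval label (0.5 → D, 0.6 → C, 0.8 → B). Level changes between
dates are cross-tabulated into a 6 × 6 row-stochastic transfer matrix and
summarized as mean D per transition type. The directional trend of
incoordination villages (D ≤ 0.5) is summarized by a standard
deviational ellipse: weighted mean centre, semi-axes equal to the square
roots of the eigenvalues of the weighted coordinate covariance, and the
major-axis orientation in [0°, 180°) counter-clockwise from east.

Villages are attributed to zones and transition types by the majority of
their covering cells, ties toward the lower code.

## ES bundles

Village ES vectors (both dates pooled, purification orientation — see
`to_bundle_space()`) are clustered with a self-organizing map: a
rectangular node lattice of roughly 5√n nodes, online competitive
learning for 500 epochs with learning rate and Gaussian neighbourhood
radius decaying linearly, all seeded. Pooling the dates in one map is an
interpretive choice: it makes bundle classes directly comparable across
time, at the cost of letting the second date influence the first date's
prototypes. The cluster count is selected by computing the
Davies–Bouldin index for every candidate k in 2–15: the *occupied* SOM
prototypes are agglomerated hierarchically (Ward linkage) into k groups —
restricting the merge to occupied nodes guarantees every group holds at
least one village — villages inherit their prototype's group, and the k
with the lowest DB wins, ties toward the smaller k (parsimony).

Clusters are named from their mean profiles by a rule cascade with
configurable thresholds (high ≥ 0.6, low ≤ 0.3 on normalized means):
water yield and aesthetics high with food production low gives the
trade-off bundles (key when the remaining services are depleted, mild
otherwise); all services at mid-level or better gives the key synergistic
bundle; then the carbon/habitat/aesthetics, habitat/aesthetics (with
strong soil conservation), water purification and food production
dominance rules. The thresholds are the package's own operationalisation
of qualitative bundle descriptions; every assignment carries a rule trace,
and profiles matching no rule fall back to the nearest default archetype,
logged as such.

## The synthetic generator, and what passing tests do not show

The generator emulates the statistical structure the analysis assumes:
polycentric cores with exponentially decaying population / GDP /
nighttime-light fields (e-folding length 6 km by default), ground-truth
zones as distance rings (urban ≤ 4 km, fringe ≤ 9 km at the first date),
a fringe ring enlarged by `expansion_factor` (default 0.5, with the urban
radius growing by a quarter of that) at the second date, land-use mosaics
drawn from zone-conditional probabilities and re-drawn only where the
zone upgraded (urbanisation treated as irreversible, plus 3 % churn),
contiguous water bodies from a thresholded smooth random field (15 % of
the area by default), climate and soil fields generated at the 1-km scale
and bilinearly refined to the fine grid, POIs sampled toward the cores,
and villages as a seeded Voronoi tessellation (irregular polygons
exercise the zonal statistics). The default landscape is 40 × 40 km with
200 villages: large enough that 1000 labeled points fit on unmasked land
and that villages average a few km², small enough that the full pipeline
runs in about a minute. The fine grid subdivides each 1-km cell 33 × 33,
i.e. cells of 1000/33 ≈ 30.3 m — the closest subdivision to a 30-m
analysis resolution that nests exactly in the feature grid.

Ground-truth zones are deterministic distance thresholds while the
classifier sees noisy features; this emulates an expert point-labeling
protocol without re-implementing it. Bundle archetypes are mean vectors
in [0, 1]⁸ encoding the qualitative dominance patterns of the seven
bundle classes; `generate_village_es_matrix()` pushes them apart by a
`separation` factor (deviations from 0.5 scaled, clipped to [0, 1]) and
adds clipped Gaussian noise, retaining the planted truth.

What the synthetic landscapes do *not* emulate: real spatial
autocorrelation structure beyond smooth fields, georeferenced
coordinates, seasonality, the empirical covariance of climate and soil
variables, or policy-driven non-radial growth. Passing the recovery
tests therefore shows the pipeline is *correct* (it recovers structure it
is guaranteed to contain), not that any particular real landscape
satisfies its assumptions.

Two default bundle archetypes — CS-HQ-LA and HQ-LA — are deliberately
similar (both habitat/aesthetics dominated, differing mainly in carbon
and soil conservation). With strong separation and small noise the
Davies–Bouldin criterion can genuinely prefer merging them: the merged
configuration scores a lower index than the planted seven even under
ideal k-means clustering. Planted-recovery tests therefore use
well-separated archetype subsets; with the full vocabulary the selector
settles on six classes, merging that pair — a property of the index, not
a defect of the search.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed; each stage derives its own
  sub-seed from a tag hash, so adding a stage never shifts another
  stage's random numbers, and identical configurations are bit-identical.
* Zero-variance features standardise to 0; constant normalized
  indicators rescale to 0 with a warning; zero-variance indicators in a
  correlation stratum yield NA coefficients with a warning.
* Coupling with ΣU = 0 returns C = 0; coincident cluster centroids make
  the DB index infinite with a warning and such candidates are skipped;
  an all-identical village table is a degeneracy error for `select_k()`.
* Fewer than 5 villages in a stratum, fewer than 30 labeled points,
  fewer than 2 rows to normalize, and empty archetype libraries are
  errors, not silent defaults.
* The strict > 1 km² water threshold means an exactly-1-km² lake is
  retained.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on 16 × 16-km scenarios with a 4 × 4 fine subdivision;
the zonation-recovery and determinism checks run the default 40 × 40-km
scenario (1000 labeled points per date, as in the emulated protocol);
bundle recovery uses 10 seeds × 60 villages drawn from five planted
archetypes at separation 3 and noise 0.05. These sizes are the package's
reference configuration for desk-scale verification.

## Known limitations

* The classifier is a compact in-package implementation of the stated
  architecture; it has no GPU path and is sized for thousands, not
  millions, of labeled points.
* Rasters are planar matrices; georeferencing, reprojection and
  non-square cells are out of scope.
* The habitat degradation model uses Euclidean distance and linear decay
  only; exponential decay and accessibility weighting are not
  implemented.
* Landscape aesthetics is an input, not a fitted model.
* Bundle naming thresholds are heuristics; the rule traces exist
  precisely so that users can audit and re-threshold them.
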