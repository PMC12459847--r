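# esfringe

Ecosystem-service trade-offs and synergies along urban–fringe–rural
gradients.

`esfringe` is an R package for landscape ecologists studying how the
outward expansion of metropolitan fringe belts reshapes the supply of, and
the interactions among, ecosystem services (ES). It implements a complete,
reproducible analysis chain for two-date gridded landscapes:

1. **Zonation** — classify 1-km cells into *urban*, *fringe* and *rural*
   zones from six features (population density, GDP density, construction
   land share PLAND, nighttime light, landscape-fragmentation entropy, and
   a POI kernel-density urban-function score) with a multilayer-perceptron
   classifier (two hidden layers of 128 and 64 rectified-linear units,
   dropout 0.5, Adam at learning rate 0.001, 80/20 train/test split);
   large water bodies (> 1 km²) are masked first.
2. **Transition typology** — five transition classes between the dates
   (urban maintenance, urban expansion, fringe maintenance, fringe
   expansion, rural retention; downgrades excluded) and the 3 × 3
   row-stochastic zone transfer matrix.
3. **ES layers** — eight fine-scale service layers: food production from
   the Miami / Thornthwaite-Memorial climate potentials
   `W = min(WT, WR, WV)`, `WT = 30000 / (1 + e^{1.315 − 0.119 T})`,
   `WR = 30000 (1 − e^{−0.000664 R})`,
   `WV = 30000 (1 − e^{−0.0009695 (V − 20)})`, scaled by a land-use
   revision coefficient; soil conservation
   `SC = R_e · K_e · LS · (1 − C_f P_f)`; water yield
   `Y = (1 − AET/P) · P = max(P − AET, 0)`; carbon storage as the sum of
   four land-use pools; nitrogen and phosphorus export
   `ALV = HSS · pol`; habitat quality
   `Q = H_j (1 − D² / (D² + k²))` with a linear-decay threat-proximity
   degradation `D`; landscape aesthetics as a pluggable input layer.
4. **Village-scale interactions** — min–max normalization (Eq.
   `(x − min)/(max − min)`, dates pooled), Spearman trade-off/synergy
   matrices on levels or on 2-date changes, and the coupling-coordination
   degree model: coupling `C` (1 when all eight normalized services are
   equal, 0 when any is absent), composite level
   `T = Σ wᵢ Uᵢ` with weights 0.12 per service and 0.16 for habitat
   quality, coordination `D = C · T` classified into six levels from
   A (high-quality coordination, `D > 0.8`) to F (extreme incoordination,
   `D ≤ 0.2`), plus level-transfer matrices and standard deviational
   ellipses of incoordination villages.
5. **ES bundles** — self-organizing-map clustering of village ES vectors,
   cluster-count selection by the Davies–Bouldin index over 2–15 classes,
   rule-based naming into a seven-bundle vocabulary (key/mild trade-offs,
   key synergistic, CS-HQ-LA, HQ-LA, water purification, FP) and bundle
   transfer analysis.
6. **Synthetic landscapes** — a seeded generator of two-date scenarios
   (polycentric cores with decaying intensity fields, expanding fringe
   ring, contiguous water bodies, Voronoi village tessellations, planted
   bundle archetypes) so the whole pipeline is testable without external
   data.

Everything is deterministic under a single master seed.

## Worked example

A small single-core scenario, end to end:

```r
library(esfringe)

sc <- landscape_scenario(grid_rows = 16, grid_cols = 16, es_cells_per_km = 4,
                         n_cores = 1, urban_radius_cells = 3,
                         fringe_radius_cells = 6, n_villages = 30,
                         n_poi = 150, seed = 42)
pair <- generate_landscape_pair(sc)
villages <- generate_villages(sc)

mask <- mask_water(pair$t0)                      # water bodies > 1 km2
feats <- assemble_features(pair$t0, mask)
pts <- generate_labeled_points(feats, pair$truth_t0, 150, seed = 1)
model <- train_classifier(pts, classifier_spec(seed = 1, max_epochs = 60))
model
#> <zone_classifier> hidden 128/64, held-out accuracy 0.9333

z0 <- classify_zones(feats, model, "t0")
f1 <- assemble_features(pair$t1, mask_water(pair$t1))
z1 <- classify_zones(f1, model, "t1")
round(transfer_matrix(z0, z1)$shares, 3)
#>         to
#> from     rural fringe urban
#>   rural  0.256  0.674 0.070
#>   fringe 0.000  0.474 0.526
#>   urban  0.000  0.061 0.939
```

Two thirds of the rural cells became fringe while the urban core mostly
persisted — the expanding-fringe signature the generator plants. Village
coordination declines as the fringe grows:

```r
es0 <- assemble_es_stack(pair$t0)
es1 <- assemble_es_stack(pair$t1)
norm <- normalize_village_es(aggregate_villages(es0, villages, mask),
                             aggregate_villages(es1, villages, mask))
cc0 <- ccdm_villages(norm, date = "t0")
cc1 <- ccdm_villages(norm, date = "t1")
c(mean_D_t0 = mean(cc0$D), mean_D_t1 = mean(cc1$D))
#> mean_D_t0 mean_D_t1
#> 0.4599792 0.3630300
table(cc1$level)
#>  C  D  E  F
#>  4  9 13  3
```

The mean coordination degree drops from 0.46 (mild incoordination) to
0.36 (moderate incoordination) as urbanisation erodes regulating and
supporting services. Bundles are detected on the purification-oriented
normalized table:

```r
part <- select_k(to_bundle_space(norm), som_config(seed = 1, epochs = 150,
                                                   k_range = 2:8))
part
#> <bundle_partition> k = 8 (DB 1.0983), 58 rows
head(label_bundles(part)[, c("cluster", "bundle")], 4)
#>   cluster             bundle
#> 1       1     mild_tradeoffs
#> 2       2                 fp
#> 3       3                 fp
#> 4       4 water_purification
```

`run_pipeline(pipeline_config(...))` chains all of the above (both dates,
level and bundle transfers, deviational ellipses) and writes every stage
table as CSV plus a hash manifest, so a rerun can be verified
bit-for-bit.

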