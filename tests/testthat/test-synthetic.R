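test_that("scenario validation rejects degenerate inputs", {
  expect_error(landscape_scenario(grid_rows = 4), "degenerate grid")
  expect_error(landscape_scenario(water_fraction = 0.6), "water_fraction")
  expect_error(landscape_scenario(expansion_factor = -1), "expansion_factor")
  expect_error(landscape_scenario(n_cores = 1,
                                  core_centers = cbind(99, 99)),
               "outside grid")
})

test_that("same scenario generates bit-identical landscapes", {
  sc <- small_scenario(seed = 7)
  a <- generate_landscape_pair(sc)
  b <- generate_landscape_pair(sc)
  expect_identical(a$t0$layers$land_use$values, b$t0$layers$land_use$values)
  expect_identical(a$t1$layers$population_density$values,
                   b$t1$layers$population_density$values)
  expect_identical(a$t0$poi, b$t0$poi)
  expect_identical(a$truth_t1$values, b$truth_t1$values)
})

test_that("zero expansion leaves the ground-truth zones unchanged", {
  sc <- small_scenario(seed = 3, expansion_factor = 0)
  pair <- generate_landscape_pair(sc)
  expect_identical(pair$truth_t0$values, pair$truth_t1$values)
})

test_that("noiseless population decays monotonically along rays from a single core", {
  # core placed exactly on the centre of cell (16, 16) so that grid
  # distance grows strictly along every ray leaving that cell
  sc <- landscape_scenario(grid_rows = 32, grid_cols = 32,
                           es_cells_per_km = 1, n_cores = 1,
                           core_centers = cbind(15.5, 15.5), noise_sd = 0,
                           water_fraction = 0, n_villages = 10,
                           n_poi = 50, seed = 5)
  pair <- generate_landscape_pair(sc)
  pop <- pair$t0$layers$population_density$values
  # walk rays in the 8 compass directions plus knight-like slopes
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0), c(1, 1), c(1, -1),
                c(-1, 1), c(-1, -1), c(1, 2), c(2, 1), c(-1, 2), c(-2, 1))
  for (d in seq_len(nrow(dirs))) {
    i <- 16; j <- 16
    vals <- pop[i, j]
    repeat {
      i <- i + dirs[d, 1]; j <- j + dirs[d, 2]
      if (i < 1 || i > 32 || j < 1 || j > 32) break
      vals <- c(vals, pop[i, j])
    }
    expect_true(all(diff(vals) <= 1e-9),
                label = sprintf("ray %d non-increasing", d))
  }
})

test_that("ground-truth zones are monotone in core distance (nested rings)", {
  sc <- small_scenario(seed = 1, n_cores = 1,
                       core_centers = cbind(8, 8), noise_sd = 0)
  pair <- generate_landscape_pair(sc)
  z <- pair$truth_t0$values
  d <- sqrt(outer((seq_len(16) - 0.5 - 8)^2,
                  (seq_len(16) - 0.5 - 8)^2, "+"))
  d <- t(d)  # symmetric anyway
  # urban cells all closer than any fringe cell, fringe closer than rural
  expect_lt(max(d[z == 2]), min(d[z == 0]))
  expect_lt(max(d[z == 2]), sc$urban_radius_cells + 1e-9)
  expect_true(all(d[z == 1] > sc$urban_radius_cells))
  expect_true(all(d[z == 1] <= sc$fringe_radius_cells))
})

test_that("water bodies cover roughly the requested fraction as patches", {
  sc <- small_scenario(seed = 9, water_fraction = 0.2)
  pair <- generate_landscape_pair(sc)
  frac <- mean(pair$water)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)
  lu <- pair$t0$layers$land_use$values
  expect_true(all(lu[pair$water] == land_use_codes()[["water"]]))
})

test_that("village tessellation partitions the grid", {
  sc <- small_scenario(seed = 4)
  vil <- generate_villages(sc)
  idm <- vil$id_raster$values
  expect_false(any(is.na(idm)))
  expect_setequal(unique(as.vector(idm)), vil$ids)
  # coverage: cell counts over villages sum to the grid size
  expect_identical(sum(tabulate(idm)), length(idm))
  expect_identical(anyDuplicated(vil$ids), 0L)
})

test_that("labeled points are reproducible, on land, and class-representative", {
  sc <- small_scenario(seed = 2)
  pair <- generate_landscape_pair(sc)
  m <- mask_water(pair$t0)
  f <- assemble_features(pair$t0, m)
  pts <- generate_labeled_points(f, pair$truth_t0, 100, seed = 10)
  expect_identical(nrow(pts), 100L)
  expect_true(all(pts$label %in% 0:2))
  expect_identical(pts, generate_labeled_points(f, pair$truth_t0, 100, seed = 10))
  # no point on a masked cell
  expect_false(any(f$mask[cbind(pts$row, pts$col)]))
  # different seeds: different points, compatible class frequencies
  pts2 <- generate_labeled_points(f, pair$truth_t0, 100, seed = 11)
  expect_false(identical(pts$row, pts2$row))
  truth_prop <- prop.table(table(factor(pair$truth_t0$values[!f$mask],
                                        levels = 0:2)))
  chisq <- suppressWarnings(
    stats::chisq.test(table(factor(pts2$label, levels = 0:2)),
                      p = as.vector(truth_prop)))
  expect_gt(chisq$p.value, 0.001)
  expect_error(generate_labeled_points(f, pair$truth_t0, 10, seed = 1),
               "at least 30")
  expect_error(generate_labeled_points(f, pair$truth_t0, 1e6, seed = 1),
               "exceeds")
})

test_that("village ES matrices honour archetype geometry", {
  lib <- bundle_archetype_library()
  k <- nrow(lib$archetypes)
  # zero noise, unit separation: rows equal their archetype means
  lib0 <- bundle_archetype_library(lib$archetypes, within_sd = 0)
  tab <- generate_village_es_matrix(lib0, n_per_archetype = 3,
                                    separation = 1, seed = 1)
  expect_identical(nrow(tab), 3L * k)
  X <- as.matrix(tab[, bundle_indicator_names()])
  expect_equal(unname(X),
               unname(lib$archetypes[rep(seq_len(k), each = 3), ]),
               tolerance = 1e-12)
  # planted separation: ground-truth partition is strongly separated
  tabs <- generate_village_es_matrix(
    bundle_archetype_library(lib$archetypes, within_sd = 0.05),
    n_per_archetype = 10, separation = 3, seed = 2)
  Xs <- as.matrix(tabs[, bundle_indicator_names()])
  expect_gt(silhouette_oracle(Xs, tabs$archetype), 0.5)
  expect_error(generate_village_es_matrix(lib, 1), "n_per_archetype")
  expect_error(generate_village_es_matrix(lib, 5, separation = 0),
               "separation")
})
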