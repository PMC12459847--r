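make_zone <- function(m, tag = "t0") zone_map(m, tag, cell_size_m = 1000)

test_that("water masking is strict in the area threshold", {
  nr <- 20; nc <- 20; cs <- 500  # 0.25 km2 cells
  lu <- matrix(land_use_codes()[["cropland"]], nr, nc)
  lu[1:2, 1:3] <- land_use_codes()[["water"]]    # 6 cells = 1.5 km2 lake
  lu[10:11, 10] <- land_use_codes()[["water"]]   # 2 cells = 0.5 km2 pond
  st <- constant_stack(nr, nc, cs, overrides = list(land_use = lu))
  m <- mask_water(st, min_area_km2 = 1)
  expect_true(all(m[1:2, 1:3]))       # 1.5 km2 > 1: masked
  expect_false(any(m[10:11, 10]))     # 0.5 km2: retained
  expect_identical(sum(m), 6L)
  # exactly at the threshold: strict comparison keeps it
  lu2 <- matrix(land_use_codes()[["forest"]], nr, nc)
  lu2[1:2, 1:2] <- land_use_codes()[["water"]]   # exactly 1 km2
  st2 <- constant_stack(nr, nc, cs, overrides = list(land_use = lu2))
  expect_false(any(mask_water(st2, 1)))
  # all-land grid: empty mask
  st3 <- constant_stack(nr, nc, cs)
  expect_false(any(mask_water(st3)))
})

test_that("PLAND is the construction-land percentage of the window", {
  b <- land_use_codes()[["builtup"]]; c <- land_use_codes()[["cropland"]]
  m <- matrix(c, 10, 10)
  m[1:35] <- b
  expect_equal(compute_pland(m), 35)
  expect_equal(compute_pland(matrix(c, 5, 5)), 0)
  expect_equal(compute_pland(matrix(b, 5, 5)), 100)
  expect_error(compute_pland(matrix(NA_real_, 2, 2)), "nodata")
})

test_that("fragmentation entropy matches the enumeration oracle and its bounds", {
  c1 <- land_use_codes()[["cropland"]]; c2 <- land_use_codes()[["forest"]]
  expect_equal(compute_fragmentation(matrix(c1, 4, 4)), 0)
  expect_equal(compute_fragmentation(matrix(c(c1, c2), 4, 4)), log(2),
               tolerance = 1e-12)
  # proportions (0.4, 0.3, 0.2, 0.1) over a 10-cell window
  m <- matrix(c(rep(1, 4), rep(2, 3), rep(3, 2), 4), 1, 10)
  expect_equal(compute_fragmentation(m), 1.27985, tolerance = 1e-4)
  expect_equal(compute_fragmentation(m),
               entropy_oracle(c(0.4, 0.3, 0.2, 0.1)), tolerance = 1e-12)
  # bounds over random windows: 0 <= W <= ln(types present), max at uniform
  set.seed(99)
  for (rep in 1:20) {
    w <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
    W <- compute_fragmentation(w)
    ntypes <- length(unique(as.vector(w)))
    expect_gte(W, 0)
    expect_lte(W, log(ntypes) + 1e-12)
  }
  u <- matrix(rep(1:4, each = 9), 6, 6)  # uniform mixture of 4 types
  expect_equal(compute_fragmentation(u), log(4), tolerance = 1e-12)
})

test_that("POI function shares are scale-invariant and degenerate cases behave", {
  cfg <- poi_function_config(bandwidth_m = 500)
  one <- data.frame(x = c(250, 750), y = c(250, 750),
                    category = "commercial")
  r1 <- compute_poi_function(one, cfg, 4, 4, 500)
  expect_true(all(r1$shares$commercial[r1$density > 0] == 100))
  none <- data.frame(x = numeric(), y = numeric(), category = character())
  r0 <- compute_poi_function(none, cfg, 4, 4, 500)
  expect_true(all(r0$feature == 0))
  # duplicating every point (doubling all n_i) leaves shares unchanged
  two <- data.frame(x = c(250, 750, 900), y = c(250, 750, 300),
                    category = c("commercial", "commercial", "transport"))
  rA <- compute_poi_function(two, cfg, 4, 4, 500)
  rB <- compute_poi_function(rbind(two, two), cfg, 4, 4, 500)
  expect_equal(rA$shares$commercial, rB$shares$commercial, tolerance = 1e-12)
  expect_error(poi_function_config(bandwidth_m = -5), "bandwidth")
  expect_error(poi_function_config(weights = c(a = 0.5, b = 0.6)), "sum to 1")
})

test_that("feature assembly yields one row per unmasked 1-km cell", {
  sc <- small_scenario(seed = 21)
  pair <- generate_landscape_pair(sc)
  m <- mask_water(pair$t0)
  f <- assemble_features(pair$t0, m)
  expect_identical(dim(f$mask), c(16L, 16L))
  for (nm in feature_names()) {
    expect_true(all(is.na(f$features[[nm]][f$mask])))
    expect_true(all(is.finite(f$features[[nm]][!f$mask])))
  }
  expect_true(all(f$features$pland[!f$mask] >= 0 &
                    f$features$pland[!f$mask] <= 100))
  n_lu <- length(land_use_codes())
  expect_true(all(f$features$fragmentation_w[!f$mask] <= log(n_lu)))
})

test_that("transition typing covers all nine zone combinations", {
  z0 <- make_zone(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3), "t0")
  z1 <- make_zone(matrix(c(0, 1, 2, 0, 1, 2, 0, 1, 2), 3, 3), "t1")
  tc <- transition_codes()
  tm <- type_transitions(z0, z1)
  expected <- matrix(c(tc[["rural_retention"]], tc[["fringe_expansion"]],
                       tc[["urban_expansion"]],  # rural -> urban, default
                       tc[["excluded"]], tc[["fringe_maintenance"]],
                       tc[["urban_expansion"]],
                       tc[["excluded"]], tc[["excluded"]],
                       tc[["urban_maintenance"]]), 3, 3)
  expect_identical(unname(tm$values), unname(expected))
  # alternative handling of the rural -> urban jump
  tm2 <- type_transitions(z0, z1, rural_to_urban = "excluded")
  expect_identical(tm2$values[3, 1], tc[["excluded"]])
  # typing is total: every jointly valid cell coded
  expect_false(any(is.na(tm$values)))
  # identical maps produce only maintenance/retention codes
  tm3 <- type_transitions(z0, z0)
  expect_setequal(unique(as.vector(tm3$values)),
                  tc[c("rural_retention", "fringe_maintenance",
                       "urban_maintenance")])
})

test_that("transfer matrix row-normalizes hand-counted transitions", {
  z0 <- make_zone(matrix(c(0, 0, 1, 2), 2, 2), "t0")
  z1 <- make_zone(matrix(c(0, 1, 2, 2), 2, 2), "t1")
  tm <- transfer_matrix(z0, z1)
  expect_equal(unname(tm$shares),
               rbind(c(0.5, 0.5, 0), c(0, 0, 1), c(0, 0, 1)),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(tm$shares)), rep(1, 3))
  expect_equal(sum(tm$counts), 4)
  # identity on identical maps
  tmi <- transfer_matrix(z0, z0)
  expect_equal(unname(tmi$shares), diag(3), tolerance = 1e-12)
  # composition conserves cell counts against the typed map
  tmap <- type_transitions(z0, z1)
  expect_equal(sum(!is.na(tmap$values)), sum(tm$counts))
  # nodata handling
  z0n <- make_zone(matrix(c(0, NA, 1, 2), 2, 2), "t0")
  expect_equal(sum(transfer_matrix(z0n, z1)$counts), 3)
  zq <- make_zone(matrix(NA_integer_, 2, 2), "t0")
  expect_error(transfer_matrix(zq, zq), "jointly valid")
})

test_that("village majority attribution weights covering cells and breaks ties low", {
  idm <- matrix(1L, 4, 4)
  idm[, 3:4] <- 2L
  vil <- village_tessellation(raster_layer(idm, "village_id", "id", 500,
                                           c(0, 2000)))
  zl <- make_zone(matrix(c(2L, 1L, 0L, 1L), 2, 2), "t0")
  out <- village_majority(vil, zl)
  # village 1 covers cells coded 2 and 1 equally: tie -> lower code 1
  expect_identical(out[["1"]], 1L)
  expect_identical(out[["2"]], 0L)
})
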