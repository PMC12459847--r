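test_that("climate production potentials hit their closed-form anchors", {
  # exponent vanishes at T = 1.315 / 0.119: WT = 30000 / 2
  Tm <- matrix(1.315 / 0.119, 1, 1)
  fp <- food_production(Tm, matrix(1000, 1, 1))
  expect_equal(fp$WT[1, 1], 15000, tolerance = 1e-9)
  # asymptote from below at high temperature
  fp_hot <- food_production(matrix(60, 1, 1), matrix(5000, 1, 1))
  expect_lt(fp_hot$WT[1, 1], 30000)
  expect_gt(fp_hot$WT[1, 1], 29900)
  # precipitation-limited potential at R = 1000 mm (scalar oracle)
  expect_equal(fp$WR[1, 1], 30000 * (1 - exp(-0.664)), tolerance = 1e-12)
  expect_equal(fp$WR[1, 1], 14556.43, tolerance = 1e-2)
  # W = min of the three potentials, bounded by 30000
  expect_equal(fp$W[1, 1], min(fp$WT[1, 1], fp$WR[1, 1], fp$WV[1, 1]))
  expect_lte(fp$W[1, 1], 30000)
  expect_error(food_production(matrix(Inf, 1, 1), matrix(1, 1, 1)),
               "non-finite")
})

test_that("potential W is monotone in temperature and precipitation", {
  Ts <- seq(0, 35, by = 2.5)
  Rs <- seq(100, 2500, by = 200)
  W_T <- vapply(Ts, function(tt) {
    food_production(matrix(tt, 1, 1), matrix(1200, 1, 1))$W[1, 1]
  }, 0)
  W_R <- vapply(Rs, function(rr) {
    food_production(matrix(20, 1, 1), matrix(rr, 1, 1))$W[1, 1]
  }, 0)
  expect_true(all(diff(W_T) >= -1e-9))
  expect_true(all(diff(W_R) >= -1e-9))
  expect_true(all(W_T <= 30000) && all(W_R <= 30000))
})

test_that("printed division variant is kept for fidelity but unbounded", {
  div <- food_production(matrix(15, 1, 1), matrix(1000, 1, 1),
                         variant = "printed_division")
  expect_gt(div$WR[1, 1], 30000)  # non-physical: exceeds the Miami ceiling
})

test_that("soil conservation follows the USLE product with retention clamp", {
  expect_equal(soil_conservation(100, 0.3, 2, 0.5, 0.5)[1], 45)
  expect_equal(soil_conservation(100, 0.3, 2, 1, 1)[1], 0)
  expect_equal(soil_conservation(100, 0.3, 2, 0, 0.7)[1], 100 * 0.3 * 2)
  # multiplicative separability in erosivity
  a <- soil_conservation(matrix(c(50, 80), 1, 2), 0.25, 1.5, 0.2, 0.4)
  b <- soil_conservation(matrix(c(150, 240), 1, 2), 0.25, 1.5, 0.2, 0.4)
  expect_equal(b, 3 * a, tolerance = 1e-12)
  expect_error(soil_conservation(-1, 0.3, 2, 0.5, 0.5), "negative")
})

test_that("water yield equals precipitation excess identically", {
  expect_equal(water_yield(1000, 600)[1], 400)
  expect_equal(water_yield(500, 500)[1], 0)
  expect_equal(water_yield(300, 900)[1], 0)   # clamped
  expect_equal(water_yield(0, 0)[1], 0)
  # ratio form collapses to direct subtraction (conservation oracle)
  set.seed(31)
  P <- matrix(runif(100, 0, 2000), 10, 10)
  AET <- matrix(runif(100, 0, 1500), 10, 10)
  expect_equal(water_yield(P, AET), pmax(P - AET, 0), tolerance = 1e-12)
  expect_error(water_yield(-1, 0), "negative")
})

test_that("carbon storage sums the four pools and conserves totals", {
  tab <- data.frame(code = c(1L, 5L), land_use = c("cropland", "water"),
                    C_above = c(80, 0), C_below = c(20, 0),
                    C_soil = c(120, 0), C_dead = c(5, 0))
  lu <- matrix(c(1L, 1L, 5L, 1L), 2, 2)
  cs <- carbon_storage(lu, tab)
  expect_equal(cs[1, 1], 225)
  expect_equal(cs[1, 2], 0)
  # grid total equals count x per-code density (lookup conservation)
  expect_equal(sum(cs), 3 * 225 + 1 * 0)
  expect_error(carbon_storage(matrix(7L, 1, 1), tab), "missing")
})

test_that("nutrient export is the sensitivity-scaled coefficient", {
  expect_equal(nutrient_export(0.8, 5)[1], 4)
  expect_equal(nutrient_export(matrix(0, 3, 3), matrix(29, 3, 3)),
               matrix(0, 3, 3))
  expect_equal(nutrient_export(0.7, 10), 2 * nutrient_export(0.7, 5))
  expect_error(nutrient_export(-0.1, 5), "negative")
})

test_that("habitat degradation decays linearly to the threat radius", {
  codes <- land_use_codes()
  lu <- matrix(codes[["forest"]], 1, 21)
  lu[1, 1] <- codes[["builtup"]]
  params <- default_habitat_params()
  params$threats <- data.frame(land_use = "builtup", weight = 1,
                               max_dist_m = 1000)
  D <- habitat_degradation(lu, params, cell_size_m = 100)
  expect_equal(D[1, 1], 1)                        # on the threat source
  expect_equal(D[1, 6], 1 - 500 / 1000)           # midpoint of the decay
  expect_equal(D[1, 12], 0)                       # beyond the max distance
  expect_true(all(D >= 0 & D <= 1))
})

test_that("habitat quality follows the half-saturation response", {
  codes <- land_use_codes()
  lu <- matrix(codes[["forest"]], 1, 3)
  params <- default_habitat_params(k = 0.5)
  H <- params$suitability$H_j[params$suitability$land_use == "forest"]
  expect_equal(habitat_quality(lu, matrix(0, 1, 3), params)[1, 1], H)
  expect_equal(habitat_quality(lu, matrix(0.5, 1, 3), params)[1, 2], H / 2,
               tolerance = 1e-12)
  # scalar oracle: H = 0.9, D = 0.4, k = 0.5
  p2 <- default_habitat_params(k = 0.5)
  p2$suitability$H_j[p2$suitability$land_use == "forest"] <- 0.9
  q <- habitat_quality(lu, matrix(0.4, 1, 3), p2)[1, 1]
  expect_equal(q, 0.9 * (1 - 0.16 / 0.41), tolerance = 1e-12)
  expect_equal(q, 0.5488, tolerance = 1e-4)
  # strictly decreasing in D
  qs <- vapply(seq(0, 1, 0.1), function(d) {
    habitat_quality(lu, matrix(d, 1, 3), params)[1, 1]
  }, 0)
  expect_true(all(diff(qs) < 0))
  expect_error(default_habitat_params(k = 0), "k must be > 0")
})

test_that("the assembled ES stack has eight aligned layers with local sensitivity", {
  st <- constant_stack(8, 8, 250)
  es <- assemble_es_stack(st)
  expect_identical(names(es$layers), es_indicator_names())
  for (ly in es$layers) {
    expect_identical(dim(ly$values), c(8L, 8L))
  }
  # constant inputs -> constant outputs
  for (nm in c("FP", "CS", "WY", "TN", "TP", "LA")) {
    expect_equal(stats::sd(es$layers[[nm]]$values), 0)
  }
  # changing only precipitation changes only FP and WY (differential test)
  st2 <- constant_stack(8, 8, 250,
                        overrides = list(precipitation = matrix(1400, 8, 8)))
  es2 <- assemble_es_stack(st2)
  for (nm in c("FP", "WY")) {
    expect_false(isTRUE(all.equal(es$layers[[nm]]$values,
                                  es2$layers[[nm]]$values)))
  }
  for (nm in c("CS", "SC", "TN", "TP", "HQ", "LA")) {
    expect_equal(es$layers[[nm]]$values, es2$layers[[nm]]$values)
  }
  # missing parameter table entry is a named error
  st3 <- constant_stack(4, 4, 250)
  st3$layers$precipitation <- NULL
  expect_error(assemble_es_stack(st3), "precipitation")
})
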