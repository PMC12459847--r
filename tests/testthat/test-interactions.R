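toy_es_table <- function(n = 20, seed = 5, dates = c("t0", "t1")) {
  set.seed(seed)
  do.call(rbind, lapply(dates, function(dt) {
    tab <- data.frame(village_id = seq_len(n), date_tag = dt)
    for (nm in es_indicator_names()) tab[[nm]] <- runif(n)
    tab
  }))
}

test_that("village aggregation equals the per-cell accumulation oracle", {
  sc <- small_scenario(seed = 17)
  pair <- generate_landscape_pair(sc)
  vil <- generate_villages(sc)
  es <- assemble_es_stack(pair$t0)
  m <- mask_water(pair$t0)
  agg <- aggregate_villages(es, vil, m)
  # brute force: accumulate one cell at a time for three layers
  ids <- vil$id_raster$values
  for (nm in c("FP", "HQ", "WY")) {
    v <- es$layers[[nm]]$values
    for (vid in agg$village_id[1:5]) {
      s <- 0; cnt <- 0
      for (i in seq_len(nrow(ids))) {
        for (j in seq_len(ncol(ids))) {
          if (ids[i, j] == vid && !m[i, j] && !is.na(v[i, j])) {
            s <- s + v[i, j]; cnt <- cnt + 1
          }
        }
      }
      expect_equal(agg[[nm]][agg$village_id == vid], s / cnt,
                   tolerance = 1e-12)
    }
  }
  # constant layer: every village mean equals the constant
  es$layers$LA$values[] <- 5
  agg2 <- aggregate_villages(es, vil, m)
  expect_true(all(abs(agg2$LA - 5) < 1e-12))
})

test_that("min-max normalization pools dates and flags constants", {
  tab <- toy_es_table(15, seed = 2)
  norm <- normalize_village_es(tab[tab$date_tag == "t0", ],
                               tab[tab$date_tag == "t1", ])
  for (nm in es_indicator_names()) {
    expect_equal(min(norm[[nm]]), 0)
    expect_equal(max(norm[[nm]]), 1)
  }
  # midpoint of the pooled range maps to 0.5
  x <- tab$FP
  mid <- (min(x) + max(x)) / 2
  tab2 <- tab; tab2$FP[1] <- mid
  norm2 <- normalize_village_es(tab2[tab2$date_tag == "t0", ],
                                tab2[tab2$date_tag == "t1", ])
  expect_equal(norm2$FP[1], (mid - min(tab2$FP)) / (max(tab2$FP) - min(tab2$FP)))
  # constant indicator: all zeros with warning
  tab3 <- tab; tab3$CS <- 3
  expect_warning(norm3 <- normalize_village_es(tab3), "CS")
  expect_true(all(norm3$CS == 0))
})

test_that("spearman matrices agree with the rank-then-Pearson oracle", {
  tab <- toy_es_table(50, seed = 8)
  sp <- spearman_matrix(tab, date = "t0")
  t0 <- tab[tab$date_tag == "t0", ]
  for (a in es_indicator_names()) {
    for (b in es_indicator_names()) {
      expect_equal(sp$R[a, b], rank_pearson_oracle(t0[[a]], t0[[b]]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(sp$R, t(sp$R))
  expect_equal(unname(diag(sp$R)), rep(1, 8))
  # monotone pairs saturate at +/-1
  t0m <- t0
  t0m$CS <- exp(t0m$FP)         # strictly co-monotone with FP
  t0m$WY <- -t0m$FP^3           # strictly anti-monotone
  spm <- spearman_matrix(t0m, date = "t0")
  expect_equal(spm$R["FP", "CS"], 1)
  expect_equal(spm$R["FP", "WY"], -1)
  # invariance to strictly monotone transforms
  t0t <- t0; t0t$HQ <- qlogis(t0t$HQ / 2 + 0.25)
  expect_equal(spearman_matrix(t0t, date = "t0")$R["HQ", "FP"],
               sp$R["HQ", "FP"], tolerance = 1e-12)
})

test_that("change-mode correlations use per-village differences", {
  tab <- toy_es_table(30, seed = 12)
  spc <- spearman_matrix(tab, mode = "changes")
  a <- tab[tab$date_tag == "t0", ]
  b <- tab[tab$date_tag == "t1", ]
  d_fp <- b$FP - a$FP
  d_hq <- b$HQ - a$HQ
  expect_equal(spc$R["FP", "HQ"], rank_pearson_oracle(d_fp, d_hq),
               tolerance = 1e-12)
  expect_error(spearman_matrix(tab, date = "t0", villages = 1:4),
               "fewer than 5")
})

test_that("coupling degree satisfies its boundary contract and AM-GM bound", {
  expect_equal(coupling_degree(rep(0.37, 8)), 1)
  expect_equal(coupling_degree(c(0, runif(7))), 0)
  expect_equal(coupling_degree(c(0.2, 0.8)), 0.8)  # 2 sqrt(0.16) / 1
  set.seed(44)
  for (i in 1:50) {
    U <- runif(8)
    C <- coupling_degree(U)
    expect_gte(C, 0); expect_lte(C, 1 + 1e-12)
    if (max(U) - min(U) > 1e-6) expect_lt(C, 1)
  }
  expect_error(coupling_degree(c(1.2, rep(0.5, 7))), "\\[0, 1\\]")
  # printed product-over-pairwise-sums variant stays available
  cfg <- ccdm_config(coupling_variant = "printed_product")
  U <- c(0.2, 0.8)
  expect_equal(coupling_degree(U, cfg), (0.16 / 1)^(1 / 2))
  expect_lt(coupling_degree(rep(0.5, 8), cfg), 1)  # why it is not default
})

test_that("composite T is the exact weighted sum with default weights", {
  cfg <- ccdm_config()
  expect_equal(sum(cfg$weights), 1)
  expect_equal(unname(cfg$weights[["HQ"]]), 0.16)
  expect_equal(composite_T(rep(0.5, 8), cfg), 0.5)
  expect_equal(composite_T(rep(1, 8), cfg), 1)
  U <- stats::setNames(rep(0, 8), es_indicator_names())
  U[["HQ"]] <- 1
  expect_equal(composite_T(U, cfg), 0.16)
  expect_error(composite_T(rep(0.5, 5), cfg), "length mismatch")
  expect_error(ccdm_config(weights = stats::setNames(rep(0.2, 8),
                                                     es_indicator_names())),
               "sum to 1")
})

test_that("coordination degree classifies into the six levels with lower-closed bounds", {
  expect_equal(coordination_degree(1, 0.5), 0.5)
  expect_identical(classify_level(0.5), "D")
  expect_identical(classify_level(0.55), "C")
  expect_identical(classify_level(0), "F")
  expect_identical(classify_level(0.2), "F")
  expect_identical(classify_level(0.6), "C")
  expect_identical(classify_level(0.8), "B")
  expect_identical(classify_level(1), "A")
  expect_identical(ccdm_level_descriptions()[["D"]], "Mild incoordination")
  # the partition is total and single-valued on a fine grid of D values
  d <- seq(0, 1, by = 0.001)
  lv <- classify_level(d)
  expect_true(all(lv %in% ccdm_levels()))
  expect_identical(length(lv), length(d))
  # monotone: D increasing in T at fixed C, and in C at fixed T
  expect_true(all(diff(coordination_degree(0.7, seq(0, 1, 0.1))) > 0))
  expect_true(all(diff(coordination_degree(seq(0, 1, 0.1), 0.7)) > 0))
  # sqrt variant
  cfg <- ccdm_config(d_combiner = "sqrt_product")
  expect_equal(coordination_degree(0.5, 0.5, cfg), 0.5)
  expect_error(classify_level(1.2), "outside")
})

test_that("village CCDM inverts disservices and stays in bounds", {
  tab <- toy_es_table(25, seed = 3)
  norm <- normalize_village_es(tab[tab$date_tag == "t0", ],
                               tab[tab$date_tag == "t1", ])
  res <- ccdm_villages(norm, date = "t0")
  expect_true(all(res$C >= 0 & res$C <= 1 + 1e-12))
  expect_true(all(res$T >= 0 & res$T <= 1))
  expect_true(all(res$D >= 0 & res$D <= 1))
  expect_identical(res$level, classify_level(res$D))
  # inversion: a village with maximal nutrient output scores lower T than
  # the same village with minimal output
  row <- norm[norm$date_tag == "t0", ][1, ]
  hi <- row; hi$TN <- 1; hi$TP <- 1
  lo <- row; lo$TN <- 0; lo$TP <- 0
  expect_lt(ccdm_villages(hi)$T, ccdm_villages(lo)$T)
  # raw mode leaves them untouched
  cfg_raw <- ccdm_config(disservices = "raw")
  expect_gt(ccdm_villages(hi, cfg_raw)$T, ccdm_villages(lo, cfg_raw)$T)
})

test_that("level transfer matrices are row-stochastic and hand-countable", {
  r0 <- data.frame(village_id = 1:3, date_tag = "t0",
                   C = 1, T = c(0.55, 0.55, 0.85),
                   D = c(0.55, 0.55, 0.85), level = c("C", "C", "A"))
  r1 <- data.frame(village_id = 1:3, date_tag = "t1",
                   C = 1, T = c(0.55, 0.30, 0.85),
                   D = c(0.55, 0.30, 0.85), level = c("C", "E", "A"))
  lt <- level_transfer(r0, r1)
  expect_equal(lt$matrix["C", "C"], 0.5)
  expect_equal(lt$matrix["C", "E"], 0.5)
  expect_equal(lt$matrix["A", "A"], 1)
  nonzero <- rowSums(lt$counts) > 0
  expect_equal(unname(rowSums(lt$matrix)[nonzero]),
               rep(1, sum(nonzero)))
  # identical results give the identity on occupied levels
  lti <- level_transfer(r0, r0)
  expect_equal(lti$matrix["C", "C"], 1)
  expect_equal(lti$matrix["A", "A"], 1)
  expect_error(level_transfer(r0, r1[-1, ]), "mismatch")
})

test_that("deviational ellipse matches the weighted eigen-decomposition oracle", {
  # square corners: circular ellipse
  sq <- deviational_ellipse(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sq$semi_major, sq$semi_minor, tolerance = 1e-12)
  expect_equal(unname(sq$center), c(0.5, 0.5))
  # collinear points: zero minor axis, orientation along the line
  col <- deviational_ellipse(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(col$semi_minor, 0, tolerance = 1e-12)
  expect_equal(col$orientation_deg, 45, tolerance = 1e-9)
  # random weighted cloud vs cov.wt eigen oracle
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(40); y <- 0.6 * x + rnorm(40, sd = 0.4)
    w <- runif(40)
    e <- deviational_ellipse(x, y, w)
    cw <- stats::cov.wt(cbind(x, y), wt = w / sum(w), method = "ML")
    eg <- eigen(cw$cov, symmetric = TRUE)
    expect_equal(e$semi_major, sqrt(eg$values[1]), tolerance = 1e-9)
    expect_equal(e$semi_minor, sqrt(eg$values[2]), tolerance = 1e-9)
    ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
    expect_equal(e$orientation_deg %% 180, ang %% 180, tolerance = 1e-9)
    expect_true(e$orientation_deg >= 0 && e$orientation_deg < 180)
  }
  expect_error(deviational_ellipse(1, 1), "at least 2")
})
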