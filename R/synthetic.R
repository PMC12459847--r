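#' Synthetic landscape scenario
#'
#' Parameters of the seeded two-date synthetic landscape generator. The
#' generator emulates a polycentric metropolitan region: urban cores with
#' radially decaying socio-economic intensity, a transitional fringe ring
#' that expands outward between the two dates, contiguous water bodies,
#' land-use mosaics conditioned on the urban-fringe-rural gradient, and
#' climate/soil fields generated at the 1-km feature scale and bilinearly
#' refined onto the nested fine ES grid.
#'
#' @param grid_rows,grid_cols Feature-grid dimensions (1-km cells); at
#'   least 8 x 8.
#' @param cell_size_m Feature cell size in metres (default 1000).
#' @param es_cells_per_km Fine-grid subdivision of each feature cell; the
#'   default 33 gives ES cells of 1000/33 = 30.3 m, the closest nesting
#'   subdivision to a 30-m analysis resolution.
#' @param n_cores Number of urban cores.
#' @param core_centers Optional `n_cores x 2` matrix of core coordinates in
#'   km from the top-left origin (columns x, y measured rightward and
#'   downward); default: seeded placement, first core central.
#' @param decay_length_cells e-folding length (km) of the intensity decay.
#' @param urban_radius_cells,fringe_radius_cells Ground-truth zone radii
#'   (km) around each core at the first date.
#' @param expansion_factor Relative outward growth of the fringe ring
#'   between dates; the urban radius grows by a quarter of it.
#' @param water_fraction Fraction of cells covered by water bodies.
#' @param noise_sd Relative noise on the intensity layers.
#' @param n_villages Number of Voronoi village units.
#' @param n_poi Number of POI points at the first date.
#' @param seed Master seed; identical scenarios generate bit-identical
#'   output.
#' @return Object of class `landscape_scenario`.
#' @export
landscape_scenario <- function(grid_rows = 40, grid_cols = 40,
                               cell_size_m = 1000, es_cells_per_km = 33,
                               n_cores = 3, core_centers = NULL,
                               decay_length_cells = 6,
                               urban_radius_cells = 4,
                               fringe_radius_cells = 9,
                               expansion_factor = 0.5,
                               water_fraction = 0.15, noise_sd = 0.15,
                               n_villages = 200, n_poi = 800, seed = 1) {
  if (grid_rows < 8 || grid_cols < 8) stop("degenerate grid: need at least 8 x 8")
  if (water_fraction < 0 || water_fraction >= 0.5) {
    stop("water_fraction must be in [0, 0.5)")
  }
  if (expansion_factor < 0) stop("expansion_factor must be >= 0")
  stopifnot(n_cores >= 1, decay_length_cells > 0, noise_sd >= 0,
            urban_radius_cells > 0, fringe_radius_cells > urban_radius_cells)
  if (is.null(core_centers)) {
    core_centers <- with_seed(derive_seed(seed, "cores"), {
      ctr <- cbind(grid_cols / 2, grid_rows / 2)
      if (n_cores > 1) {
        extra <- cbind(
          stats::runif(n_cores - 1, 0.2 * grid_cols, 0.8 * grid_cols),
          stats::runif(n_cores - 1, 0.2 * grid_rows, 0.8 * grid_rows))
        ctr <- rbind(ctr, extra)
      }
      ctr
    })
  }
  core_centers <- matrix(as.numeric(core_centers), ncol = 2)
  if (nrow(core_centers) != n_cores) stop("core_centers must have n_cores rows")
  if (any(core_centers[, 1] < 0 | core_centers[, 1] > grid_cols |
          core_centers[, 2] < 0 | core_centers[, 2] > grid_rows)) {
    stop("core centers outside grid")
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 cell_size_m = cell_size_m, es_cells_per_km = es_cells_per_km,
                 n_cores = n_cores, core_centers = core_centers,
                 decay_length_cells = decay_length_cells,
                 urban_radius_cells = urban_radius_cells,
                 fringe_radius_cells = fringe_radius_cells,
                 expansion_factor = expansion_factor,
                 water_fraction = water_fraction, noise_sd = noise_sd,
                 n_villages = n_villages, n_poi = n_poi, seed = seed),
            class = "landscape_scenario")
}

# smooth unit-variance random field on the coarse grid (mean ~0)
smooth_field <- function(nr, nc, seed, passes = 4) {
  with_seed(seed, {
    f <- matrix(stats::rnorm(nr * nc), nr, nc)
    for (p in seq_len(passes)) {
      g <- f
      g[-1, ] <- g[-1, ] + f[-nr, ]
      g[-nr, ] <- g[-nr, ] + f[-1, ]
      g[, -1] <- g[, -1] + f[, -nc]
      g[, -nc] <- g[, -nc] + f[, -1]
      f <- g / 5
    }
    f / stats::sd(f)
  })
}

# bilinear refinement of a coarse matrix onto a sub x sub finer grid,
# interpolating between coarse cell centres (edges clamped)
refine_bilinear <- function(m, sub) {
  if (sub == 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  axis_weights <- function(n_coarse, n_fine) {
    pos <- (seq_len(n_fine) - 0.5) / sub + 0.5  # fractional coarse index
    k0 <- pmin(pmax(floor(pos), 1), n_coarse - 1)
    w <- pmin(pmax(pos - k0, 0), 1)
    W <- matrix(0, n_fine, n_coarse)
    W[cbind(seq_len(n_fine), k0)] <- 1 - w
    W[cbind(seq_len(n_fine), k0 + 1)] <- W[cbind(seq_len(n_fine), k0 + 1)] + w
    W
  }
  Wr <- axis_weights(nr, nr * sub)
  Wc <- axis_weights(nc, nc * sub)
  Wr %*% m %*% t(Wc)
}

# distance (km) from each cell centre of an NRxNC grid (cells of size
# 1/sub km) to the nearest core
core_distance <- function(nr_fine, nc_fine, sub, cores) {
  x <- (seq_len(nc_fine) - 0.5) / sub
  y <- (seq_len(nr_fine) - 0.5) / sub
  X <- matrix(rep(x, each = nr_fine), nr_fine, nc_fine)
  Y <- matrix(rep(y, times = nc_fine), nr_fine, nc_fine)
  d <- matrix(Inf, nr_fine, nc_fine)
  for (k in seq_len(nrow(cores))) {
    d <- pmin(d, sqrt((X - cores[k, 1])^2 + (Y - cores[k, 2])^2))
  }
  d
}

# ground-truth zone codes from core distance and radii
truth_zones_from_distance <- function(d, r_urban, r_fringe) {
  z <- matrix(0L, nrow(d), ncol(d))
  z[d <= r_fringe] <- 1L
  z[d <= r_urban] <- 2L
  z
}

# per-zone land-use sampling probabilities (rows: rural 0, fringe 1, urban 2)
.lu_probs <- rbind(
  rural  = c(cropland = 0.55, forest = 0.20, grassland = 0.10, wetland = 0.08,
             builtup = 0.06, bare = 0.01),
  fringe = c(cropland = 0.30, forest = 0.10, grassland = 0.10, wetland = 0.05,
             builtup = 0.40, bare = 0.05),
  urban  = c(cropland = 0.05, forest = 0.03, grassland = 0.05, wetland = 0.02,
             builtup = 0.80, bare = 0.05))

sample_land_use <- function(zone_codes_vec, seed) {
  codes <- land_use_codes()
  lu_names <- colnames(.lu_probs)
  with_seed(seed, {
    u <- stats::runif(length(zone_codes_vec))
    out <- integer(length(zone_codes_vec))
    for (z in 0:2) {
      idx <- which(zone_codes_vec == z)
      if (!length(idx)) next
      cum <- cumsum(.lu_probs[z + 1, ])
      pick <- findInterval(u[idx], cum) + 1
      pick[pick > length(lu_names)] <- length(lu_names)
      out[idx] <- codes[lu_names[pick]]
    }
    out
  })
}

#' Generate a two-date synthetic landscape pair
#'
#' Produces aligned landscape stacks for two dates together with the
#' ground-truth zone maps at the 1-km feature scale. Intensity layers
#' (population, GDP, nighttime light, landscape aesthetics) decay
#' exponentially with distance from the nearest core; between the dates the
#' fringe ring expands by `expansion_factor` and intensity gradients
#' flatten outward, while land use is re-drawn only where the ground-truth
#' zone upgraded (plus a small churn), emulating irreversible urbanisation.
#' Water bodies are contiguous patches carved from a thresholded smooth
#' random field, identical at both dates.
#'
#' @param scenario A [landscape_scenario()].
#' @return A list with elements `t0`, `t1` ([landscape_stack()]s),
#'   `truth_t0`, `truth_t1` ([zone_map()]s at the feature scale) and
#'   `water` (logical fine-grid matrix of water-body cells).
#' @export
generate_landscape_pair <- function(scenario) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  sc <- scenario
  nr <- sc$grid_rows; nc <- sc$grid_cols; sub <- sc$es_cells_per_km
  NR <- nr * sub; NC <- nc * sub
  es_cs <- sc$cell_size_m / sub
  lam0 <- sc$decay_length_cells
  lam1 <- lam0 * (1 + 0.5 * sc$expansion_factor)
  r_u0 <- sc$urban_radius_cells; r_f0 <- sc$fringe_radius_cells
  r_u1 <- r_u0 * (1 + 0.25 * sc$expansion_factor)
  r_f1 <- r_f0 * (1 + sc$expansion_factor)

  d_fine <- core_distance(NR, NC, sub, sc$core_centers)
  d_feat <- core_distance(nr, nc, 1, sc$core_centers)

  # water bodies: thresholded smooth field, shared by both dates
  water <- matrix(FALSE, NR, NC)
  if (sc$water_fraction > 0) {
    wf <- refine_bilinear(smooth_field(nr, nc, derive_seed(sc$seed, "water")), sub)
    water <- wf > stats::quantile(wf, 1 - sc$water_fraction)
  }

  zt0_fine <- truth_zones_from_distance(d_fine, r_u0, r_f0)
  zt1_fine <- truth_zones_from_distance(d_fine, r_u1, r_f1)

  lu0 <- sample_land_use(as.vector(zt0_fine), derive_seed(sc$seed, "landuse_t0"))
  lu0 <- matrix(lu0, NR, NC)
  # t1 land use: redraw where the zone upgraded, plus 3% background churn
  lu1 <- lu0
  upgraded <- zt1_fine > zt0_fine
  churn <- with_seed(derive_seed(sc$seed, "churn"),
                     matrix(stats::runif(NR * NC) < 0.03, NR, NC))
  redo <- upgraded | churn
  if (any(redo)) {
    lu_new <- sample_land_use(as.vector(zt1_fine[redo]),
                              derive_seed(sc$seed, "landuse_t1"))
    lu1[redo] <- lu_new
  }
  codes <- land_use_codes()
  lu0[water] <- codes[["water"]]
  lu1[water] <- codes[["water"]]
  # scatter small isolated ponds (single fine cells, below any masking
  # threshold) so that small-water retention is exercised
  ponds <- with_seed(derive_seed(sc$seed, "ponds"),
                     sample.int(NR * NC, max(3, round(0.002 * NR * NC))))
  lu0[ponds] <- codes[["water"]]
  lu1[ponds] <- codes[["water"]]

  noise <- function(tag) {
    if (sc$noise_sd == 0) return(matrix(0, NR, NC))
    sc$noise_sd * refine_bilinear(smooth_field(nr, nc, derive_seed(sc$seed, tag)), sub)
  }

  intensity_layers <- function(lam, amp_scale, tag) {
    decay <- exp(-d_fine / lam)
    list(
      population_density = clamp((200 + amp_scale * 14800 * decay) *
                                   (1 + noise(paste0("pop_", tag))), lo = 0),
      gdp_density = clamp((2 + amp_scale * 120 * decay) *
                            (1 + noise(paste0("gdp_", tag))), lo = 0),
      ntl = clamp(amp_scale * 62 * exp(-d_fine / (1.1 * lam)) *
                    (1 + noise(paste0("ntl_", tag))), lo = 0, hi = 63),
      la = clamp((0.15 + 0.75 * exp(-d_fine / (1.5 * lam))) *
                   (1 + 0.5 * noise(paste0("la_", tag))), lo = 0, hi = 1))
  }

  climate_layers <- function(tag, lu, warm = 0) {
    f <- function(nm, passes = 4) {
      refine_bilinear(smooth_field(nr, nc, derive_seed(sc$seed, paste0(nm, "_", tag)),
                                   passes), sub)
    }
    temperature <- 16 + warm + 1.2 * f("temp")
    precipitation <- clamp(1100 * (1 + 0.05 * warm) + 130 * f("precip"), lo = 0)
    # AET below precipitation, suppressed over impervious urban surfaces
    aet <- clamp(precipitation * (0.55 + 0.1 * f("aet")) *
                   (1 - 0.3 * exp(-d_fine / lam0)),
                 lo = 0, hi = 0.95 * precipitation)
    usle_R <- clamp(3500 + 2.5 * (precipitation - 1100) + 300 * f("erosiv"), lo = 0)
    usle_K <- clamp(0.24 + 0.04 * f("soilk"), lo = 0.05, hi = 0.5)
    usle_LS <- clamp(exp(0.3 + 0.5 * f("ls")), lo = 0.1, hi = 8)
    lut <- default_usle_cp()
    usle_Cf <- matrix(lut$C_f[match(lu, lut$code)], NR, NC)
    usle_P <- matrix(lut$P_f[match(lu, lut$code)], NR, NC)
    hss <- clamp(0.6 + 0.3 * f("hss"), lo = 0, hi = 1.2)
    pol <- default_export_coefficients()
    pol_N <- matrix(pol$pol_N[match(lu, pol$code)], NR, NC)
    pol_P <- matrix(pol$pol_P[match(lu, pol$code)], NR, NC)
    list(temperature = temperature, precipitation = precipitation, aet = aet,
         usle_R = usle_R, usle_K = usle_K, usle_LS = usle_LS,
         usle_Cf = usle_Cf, usle_P = usle_P, hss = hss,
         pol_N = pol_N, pol_P = pol_P)
  }

  make_stack <- function(date_tag, lu, lam, amp_scale, warm, n_poi) {
    lys <- c(list(land_use = lu),
             intensity_layers(lam, amp_scale, date_tag),
             climate_layers(date_tag, lu, warm))
    layers <- lapply(names(lys), function(nm) {
      raster_layer(lys[[nm]], name = nm, cell_size_m = es_cs,
                   origin = c(0, nr * sc$cell_size_m))
    })
    names(layers) <- names(lys)
    poi <- generate_poi(d_fine, water, lam, n_poi, es_cs,
                        c(0, nr * sc$cell_size_m),
                        derive_seed(sc$seed, paste0("poi_", date_tag)))
    landscape_stack(date_tag, layers, poi)
  }

  zt0_feat <- truth_zones_from_distance(d_feat, r_u0, r_f0)
  zt1_feat <- truth_zones_from_distance(d_feat, r_u1, r_f1)

  list(
    t0 = make_stack("t0", lu0, lam0, 1.0, 0, sc$n_poi),
    t1 = make_stack("t1", lu1, lam1, 1.2, 0.4, round(1.3 * sc$n_poi)),
    truth_t0 = zone_map(zt0_feat, "t0", sc$cell_size_m, c(0, nr * sc$cell_size_m)),
    truth_t1 = zone_map(zt1_feat, "t1", sc$cell_size_m, c(0, nr * sc$cell_size_m)),
    water = water)
}

# POI points clustered around cores; categories depend on core distance
generate_poi <- function(d_fine, water, lam, n_poi, es_cs, origin, seed) {
  cats <- c("commercial", "residential", "industrial", "public_service",
            "transport")
  ok <- which(!water)
  w <- exp(-d_fine[ok] / lam)
  with_seed(seed, {
    pick <- sample(ok, n_poi, replace = TRUE, prob = w)
    nr_f <- nrow(d_fine)
    i <- (pick - 1) %% nr_f + 1
    j <- (pick - 1) %/% nr_f + 1
    x <- origin[1] + (j - 1 + stats::runif(n_poi)) * es_cs
    y <- origin[2] - (i - 1 + stats::runif(n_poi)) * es_cs
    # commercial/public POIs concentrate near cores, industrial in the fringe
    dk <- d_fine[pick] / lam
    pcat <- cbind(0.35 * exp(-dk), 0.30, 0.20 * exp(-abs(dk - 1)),
                  0.20 * exp(-dk), 0.10)
    category <- vapply(seq_len(n_poi), function(r) {
      sample(cats, 1, prob = pcat[r, ])
    }, "")
    data.frame(x = x, y = y, category = category)
  })
}

#' Village tessellation
#'
#' Villages are the analysis units for all ES interaction statistics. The
#' constructor wraps an integer id raster in which every cell carries the
#' id of the village it belongs to (a discrete partition of the grid).
#'
#' @param id_raster A [raster_layer()] of positive integer village ids with
#'   no nodata cells.
#' @param sites Optional matrix of generating site coordinates (metres).
#' @return Object of class `village_tessellation`.
#' @export
village_tessellation <- function(id_raster, sites = NULL) {
  stopifnot(inherits(id_raster, "raster_layer"))
  if (any(is.na(id_raster$values))) stop("village ids must cover the grid")
  ids <- sort(unique(as.integer(id_raster$values)))
  structure(list(ids = ids, id_raster = id_raster, sites = sites),
            class = "village_tessellation")
}

#' @export
print.village_tessellation <- function(x, ...) {
  cat(sprintf("<village_tessellation> %d villages over %d x %d cells\n",
              length(x$ids), nrow(x$id_raster$values), ncol(x$id_raster$values)))
  invisible(x)
}

#' Generate a seeded Voronoi village tessellation
#'
#' Village sites are sampled over distinct feature cells (then jittered) and
#' every fine-grid cell is assigned to its nearest site, producing
#' irregular, pairwise non-overlapping polygons that partition the grid.
#'
#' @param scenario A [landscape_scenario()].
#' @return A [village_tessellation()] on the fine ES grid.
#' @export
generate_villages <- function(scenario) {
  sc <- scenario
  nr <- sc$grid_rows; nc <- sc$grid_cols; sub <- sc$es_cells_per_km
  NR <- nr * sub; NC <- nc * sub
  if (sc$n_villages > nr * nc) stop("more villages than feature cells")
  sites <- with_seed(derive_seed(sc$seed, "villages"), {
    cells <- sample.int(nr * nc, sc$n_villages)
    ci <- (cells - 1) %% nr + 1
    cj <- (cells - 1) %/% nr + 1
    cbind(x = cj - stats::runif(sc$n_villages),
          y = ci - stats::runif(sc$n_villages))  # km units
  })
  x <- (seq_len(NC) - 0.5) / sub
  y <- (seq_len(NR) - 0.5) / sub
  X <- matrix(rep(x, each = NR), NR, NC)
  Y <- matrix(rep(y, times = NC), NR, NC)
  best_d <- matrix(Inf, NR, NC)
  best_id <- matrix(0L, NR, NC)
  for (k in seq_len(nrow(sites))) {
    d <- (X - sites[k, 1])^2 + (Y - sites[k, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_id[upd] <- k
  }
  es_cs <- sc$cell_size_m / sub
  org <- c(0, nr * sc$cell_size_m)
  village_tessellation(
    raster_layer(best_id, "village_id", "id", es_cs, org),
    sites = cbind(x = sites[, 1] * sc$cell_size_m,
                  y = org[2] - sites[, 2] * sc$cell_size_m))
}

#' Sample labeled classification points
#'
#' Emulates the expert point-labeling protocol with generator ground truth:
#' `n` points are sampled uniformly over non-masked feature cells, each
#' carrying the six classification features and its true class (0 rural,
#' 1 fringe, 2 urban).
#'
#' @param features A feature grid from [assemble_features()].
#' @param truth Ground-truth [zone_map()] on the same feature grid.
#' @param n Number of points (>= 30).
#' @param seed Integer seed.
#' @param balanced If `TRUE`, sample the same number of points per class
#'   instead of uniformly over space.
#' @return `data.frame` with cell row/col, the six features and `label`.
#' @export
generate_labeled_points <- function(features, truth, n, seed,
                                    balanced = FALSE) {
  stopifnot(inherits(features, "feature_grid"))
  if (n < 30) stop("need at least 30 labeled points")
  ok <- which(!features$mask & !is.na(truth$values))
  if (n > length(ok)) stop("n exceeds available unmasked cells")
  idx <- with_seed(seed, {
    if (balanced) {
      cls <- truth$values[ok]
      per <- ceiling(n / 3)
      sel <- unlist(lapply(0:2, function(z) {
        pool <- ok[cls == z]
        sample(pool, min(per, length(pool)))
      }))
      sample(sel, min(n, length(sel)))
    } else {
      sample(ok, n)
    }
  })
  nr <- nrow(truth$values)
  out <- data.frame(row = (idx - 1) %% nr + 1, col = (idx - 1) %/% nr + 1)
  for (nm in feature_names()) out[[nm]] <- features$features[[nm]][idx]
  out$label <- as.integer(truth$values[idx])
  out
}

#' Bundle archetype library
#'
#' Mean profiles of the seven recurring ES bundle classes on the normalized
#' `[0,1]` scale, in purification orientation (`TNp`/`TPp` are 1 minus the
#' normalized nitrogen/phosphorus export, so higher always means a better
#' service). The defaults encode the qualitative dominance patterns of the
#' seven bundles: near-urban trade-off bundles with high water yield and
#' aesthetics, a balanced synergistic bundle, carbon/habitat/aesthetics and
#' habitat/aesthetics bundles, a water purification bundle and a food
#' production bundle.
#'
#' @param archetypes Named numeric matrix (`k x 8`) of mean vectors in
#'   `[0,1]`, columns `FP, CS, WY, SC, TNp, TPp, HQ, LA`.
#' @param within_sd Per-archetype Gaussian noise scale.
#' @return Object of class `bundle_archetype_library`.
#' @export
bundle_archetype_library <- function(archetypes = NULL, within_sd = 0.08) {
  if (is.null(archetypes)) {
    archetypes <- rbind(
      key_tradeoffs      = c(0.10, 0.15, 0.90, 0.15, 0.20, 0.20, 0.15, 0.90),
      mild_tradeoffs     = c(0.25, 0.45, 0.80, 0.45, 0.50, 0.50, 0.45, 0.80),
      key_synergistic    = c(0.70, 0.75, 0.65, 0.70, 0.70, 0.70, 0.75, 0.65),
      cs_hq_la           = c(0.30, 0.85, 0.40, 0.55, 0.55, 0.55, 0.80, 0.80),
      hq_la              = c(0.25, 0.55, 0.40, 0.70, 0.55, 0.55, 0.85, 0.85),
      water_purification = c(0.40, 0.45, 0.50, 0.40, 0.90, 0.90, 0.50, 0.40),
      fp                 = c(0.90, 0.40, 0.35, 0.40, 0.40, 0.40, 0.35, 0.30))
    colnames(archetypes) <- bundle_indicator_names()
  }
  stopifnot(is.matrix(archetypes), ncol(archetypes) == 8,
            all(archetypes >= 0 & archetypes <= 1),
            !is.null(rownames(archetypes)),
            !anyDuplicated(rownames(archetypes)), within_sd >= 0)
  structure(list(archetypes = archetypes, within_sd = within_sd),
            class = "bundle_archetype_library")
}

#' Indicator names of the bundle space
#'
#' @return Character vector of the eight indicators in purification
#'   orientation (`TNp`, `TPp` = inverted nutrient export).
#' @export
bundle_indicator_names <- function() {
  c("FP", "CS", "WY", "SC", "TNp", "TPp", "HQ", "LA")
}

#' Draw a village ES matrix from planted bundle archetypes
#'
#' Rows are archetype means pushed away from the simplex centre by
#' `separation` (values scaled around 0.5 and clipped to `[0,1]`) plus
#' clipped Gaussian noise, with the ground-truth archetype retained —
#' the planted-truth input for testing bundle detection.
#'
#' @param library A [bundle_archetype_library()].
#' @param n_per_archetype Rows drawn per archetype (>= 2).
#' @param separation Scale factor applied to mean deviations from 0.5;
#'   larger values separate the archetype clouds further.
#' @param seed Integer seed.
#' @return `data.frame` with `village_id`, `archetype` and the eight
#'   indicator columns.
#' @export
generate_village_es_matrix <- function(library, n_per_archetype,
                                       separation = 1, seed = 1) {
  stopifnot(inherits(library, "bundle_archetype_library"))
  if (nrow(library$archetypes) == 0) stop("empty archetype library")
  if (n_per_archetype < 2) stop("need n_per_archetype >= 2")
  if (separation <= 0) stop("separation must be > 0")
  arcs <- library$archetypes
  k <- nrow(arcs); p <- ncol(arcs)
  mu <- clamp(0.5 + separation * (arcs - 0.5), lo = 0, hi = 1)
  with_seed(seed, {
    rows <- mu[rep(seq_len(k), each = n_per_archetype), , drop = FALSE] +
      matrix(stats::rnorm(k * n_per_archetype * p, sd = library$within_sd),
             k * n_per_archetype, p)
    rows <- clamp(rows, lo = 0, hi = 1)
    out <- data.frame(village_id = seq_len(k * n_per_archetype),
                      archetype = rep(rownames(arcs), each = n_per_archetype))
    for (jj in seq_len(p)) out[[colnames(arcs)[jj]]] <- rows[, jj]
    out
  })
}
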