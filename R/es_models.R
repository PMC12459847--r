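#' Ecosystem-service indicator names
#'
#' @return Character vector of the eight service layers: food production,
#'   carbon storage, water yield, soil conservation, nitrogen output,
#'   phosphorus output, habitat quality, landscape aesthetics.
#' @export
es_indicator_names <- function() {
  c("FP", "CS", "WY", "SC", "TN", "TP", "HQ", "LA")
}

# ---- default land-use-keyed parameter tables -------------------------------
# All defaults are synthetic placeholders on realistic scales, keyed by
# land-use code; real applications supply their own CSV tables.

#' Default crop-revision coefficients for food production
#'
#' The integrated revision coefficient `K_i` scales the standard climatic
#' production potential by land use (cropland near full potential, built-up
#' and water nil). Values are package defaults, not calibrated estimates.
#'
#' @return `data.frame` with `code`, `land_use`, `K_i`.
#' @export
default_revision_coefficients <- function() {
  lu <- land_use_codes()
  data.frame(code = unname(lu), land_use = names(lu),
             K_i = c(cropland = 0.85, forest = 0.20, grassland = 0.30,
                     wetland = 0.15, water = 0.00, builtup = 0.02,
                     bare = 0.05)[names(lu)])
}

#' Default carbon pool table
#'
#' Above-ground, below-ground, soil and dead-organic carbon densities
#' (t/ha) per land use; the total stock is their sum.
#'
#' @return `data.frame` with `code`, `land_use` and the four pools.
#' @export
default_carbon_pools <- function() {
  lu <- land_use_codes()
  pools <- rbind(
    cropland  = c(5.7, 15.2, 80.3, 1.0),
    forest    = c(42.0, 11.5, 120.0, 3.5),
    grassland = c(3.2, 8.6, 70.1, 0.8),
    wetland   = c(6.4, 10.2, 140.5, 1.2),
    water     = c(0.0, 0.0, 0.0, 0.0),
    builtup   = c(1.2, 0.5, 30.0, 0.1),
    bare      = c(0.3, 0.2, 20.0, 0.0))
  data.frame(code = unname(lu), land_use = names(lu),
             C_above = pools[names(lu), 1], C_below = pools[names(lu), 2],
             C_soil = pools[names(lu), 3], C_dead = pools[names(lu), 4])
}

#' Default USLE cover and practice factors
#'
#' @return `data.frame` with `code`, `land_use`, `C_f`, `P_f`.
#' @export
default_usle_cp <- function() {
  lu <- land_use_codes()
  data.frame(code = unname(lu), land_use = names(lu),
             C_f = c(cropland = 0.22, forest = 0.006, grassland = 0.04,
                     wetland = 0.01, water = 1.0, builtup = 1.0,
                     bare = 0.45)[names(lu)],
             P_f = c(cropland = 0.35, forest = 1.0, grassland = 1.0,
                     wetland = 1.0, water = 1.0, builtup = 1.0,
                     bare = 1.0)[names(lu)])
}

#' Default nutrient export coefficients
#'
#' Nitrogen and phosphorus export coefficients (kg/ha/a) per land use.
#'
#' @return `data.frame` with `code`, `land_use`, `pol_N`, `pol_P`.
#' @export
default_export_coefficients <- function() {
  lu <- land_use_codes()
  data.frame(code = unname(lu), land_use = names(lu),
             pol_N = c(cropland = 29.0, forest = 2.8, grassland = 4.0,
                       wetland = 1.8, water = 0.8, builtup = 13.0,
                       bare = 6.0)[names(lu)],
             pol_P = c(cropland = 1.05, forest = 0.09, grassland = 0.12,
                       wetland = 0.06, water = 0.03, builtup = 0.60,
                       bare = 0.25)[names(lu)])
}

#' Default habitat parameters
#'
#' Habitat suitability per land use and the threat set for the degradation
#' model: built-up and cropland cells act as threat sources with linear
#' distance decay.
#'
#' @param k Half-saturation constant of the habitat-quality response
#'   (default 0.5).
#' @return List with `suitability` data.frame (`code`, `land_use`, `H_j`),
#'   `threats` data.frame (`land_use`, `weight`, `max_dist_m`) and `k`.
#' @export
default_habitat_params <- function(k = 0.5) {
  if (k <= 0) stop("half-saturation constant k must be > 0")
  lu <- land_use_codes()
  list(
    suitability = data.frame(
      code = unname(lu), land_use = names(lu),
      H_j = c(cropland = 0.45, forest = 0.95, grassland = 0.75,
              wetland = 0.90, water = 0.85, builtup = 0.00,
              bare = 0.25)[names(lu)]),
    threats = data.frame(land_use = c("builtup", "cropland"),
                         weight = c(0.7, 0.3),
                         max_dist_m = c(8000, 3000)),
    k = k)
}

# ---- equations -------------------------------------------------------------

#' Food production from climate production potentials
#'
#' Computes the standard climatic production potential as the minimum of
#' the temperature-limited Miami potential
#' `WT = 30000 / (1 + exp(1.315 - 0.119 T))`, the precipitation-limited
#' potential `WR = 30000 (1 - exp(-0.000664 R))` and the
#' evapotranspiration-limited Thornthwaite-Memorial potential
#' `WV = 30000 (1 - exp(-0.0009695 (V - 20)))` with
#' `L = 300 + 25 T + 0.05 T^3` and
#' `V = 1.05 R / sqrt(1 + (1.05 R / L)^2)`, then scales it by the land-use
#' revision coefficient: `Y_i = W K_i` (kg/ha/a).
#'
#' `WR` and `WV` use the bounded saturating (multiplicative) form of the
#' Miami/Thornthwaite-Memorial family; `variant = "printed_division"`
#' reproduces a division form (`30000 / (1 - exp(...))`) found in some
#' transcriptions, which is unbounded and non-physical, for fidelity
#' testing only.
#'
#' @param temperature Mean annual temperature layer/matrix (deg C).
#' @param precipitation Annual precipitation layer/matrix (mm).
#' @param land_use Land-use code layer/matrix (or `NULL` for `K_i = 1`).
#' @param revision Revision-coefficient table (`code`, `K_i`).
#' @param variant `"multiplicative"` (default) or `"printed_division"`.
#' @return List with `FP` (matrix, kg/ha/a) and the potential components
#'   `WT`, `WR`, `WV`, `W`.
#' @export
food_production <- function(temperature, precipitation, land_use = NULL,
                            revision = default_revision_coefficients(),
                            variant = c("multiplicative", "printed_division")) {
  variant <- match.arg(variant)
  Tm <- if (inherits(temperature, "raster_layer")) temperature$values else temperature
  R <- if (inherits(precipitation, "raster_layer")) precipitation$values else precipitation
  if (any(!is.finite(Tm[!is.na(Tm)])) || any(!is.finite(R[!is.na(R)]))) {
    stop("non-finite climate inputs")
  }
  WT <- 30000 / (1 + exp(1.315 - 0.119 * Tm))
  L <- 300 + 25 * Tm + 0.05 * Tm^3
  V <- 1.05 * R / sqrt(1 + (1.05 * R / L)^2)
  if (variant == "multiplicative") {
    WR <- 30000 * (1 - exp(-0.000664 * R))
    WV <- 30000 * (1 - exp(-0.0009695 * (V - 20)))
  } else {
    WR <- 30000 / (1 - exp(-0.000664 * R))
    WV <- 30000 / (1 - exp(-0.0009695 * (V - 20)))
  }
  W <- pmin(WT, WR, WV)
  K <- 1
  if (!is.null(land_use)) {
    luv <- if (inherits(land_use, "raster_layer")) land_use$values else land_use
    miss <- setdiff(unique(luv[!is.na(luv)]), revision$code)
    if (length(miss)) stop("land-use code(s) missing from revision table: ",
                           paste(miss, collapse = ", "))
    K <- matrix(revision$K_i[match(luv, revision$code)], nrow(W), ncol(W))
  }
  FP <- clamp(W * K, lo = 0, warn_label = "food_production")
  list(FP = FP, WT = WT, WR = WR, WV = WV, W = W)
}

#' Soil conservation from USLE factors
#'
#' `SC = R_e K_e LS (1 - C_f P_f)` (t/km2), clamped at zero.
#'
#' @param R_e Rainfall erosivity.
#' @param K_e Soil erodibility.
#' @param LS Slope length-gradient factor.
#' @param C_f Vegetation cover factor in `[0, 1]`.
#' @param P_f Conservation practice factor in `[0, 1]`.
#' @return Matrix of soil conservation (t/km2).
#' @export
soil_conservation <- function(R_e, K_e, LS, C_f, P_f) {
  g <- function(x) if (inherits(x, "raster_layer")) x$values else x
  R_e <- g(R_e); K_e <- g(K_e); LS <- g(LS); C_f <- g(C_f); P_f <- g(P_f)
  for (nm in c("R_e", "K_e", "LS", "C_f", "P_f")) {
    v <- get(nm)
    if (any(v[!is.na(v)] < 0)) stop("negative USLE factor: ", nm)
  }
  clamp(R_e * K_e * LS * (1 - C_f * P_f), lo = 0, warn_label = "soil_conservation")
}

#' Water yield as precipitation excess
#'
#' `Y = (1 - AET/P) P`, which collapses to `max(P - AET, 0)` with the
#' clamp; `P = 0` yields 0.
#'
#' @param P Annual precipitation (mm).
#' @param AET Annual actual evapotranspiration (mm).
#' @param PET Optional potential evapotranspiration; stored by callers but
#'   unused by the yield formula.
#' @return Matrix of annual water yield (mm).
#' @export
water_yield <- function(P, AET, PET = NULL) {
  g <- function(x) if (inherits(x, "raster_layer")) x$values else x
  P <- g(P); AET <- g(AET)
  if (any(P[!is.na(P)] < 0) || any(AET[!is.na(AET)] < 0)) {
    stop("negative water-yield inputs")
  }
  pmax(P - AET, 0)
}

#' Carbon storage lookup
#'
#' Total carbon stock per cell as the sum of the four pools (above-ground,
#' below-ground, soil, dead organic matter) of its land use (t/ha).
#'
#' @param land_use Land-use code layer/matrix.
#' @param pools Carbon pool table (see [default_carbon_pools()]).
#' @return Matrix of total carbon density (t/ha).
#' @export
carbon_storage <- function(land_use, pools = default_carbon_pools()) {
  luv <- if (inherits(land_use, "raster_layer")) land_use$values else land_use
  miss <- setdiff(unique(luv[!is.na(luv)]), pools$code)
  if (length(miss)) stop("land-use code(s) missing from carbon table: ",
                         paste(miss, collapse = ", "))
  ctot <- pools$C_above + pools$C_below + pools$C_soil + pools$C_dead
  matrix(ctot[match(luv, pools$code)], nrow(luv), ncol(luv))
}

#' Nutrient export
#'
#' `ALV = HSS * pol`: the export coefficient of each cell corrected by its
#' hydrological sensitivity score. Purification capacity is inversely
#' proportional to the export magnitude.
#'
#' @param hss Hydrological sensitivity score layer/matrix (>= 0).
#' @param pol Nutrient export coefficient layer/matrix (kg/ha/a, >= 0).
#' @return Matrix of corrected nutrient output.
#' @export
nutrient_export <- function(hss, pol) {
  g <- function(x) if (inherits(x, "raster_layer")) x$values else x
  hss <- g(hss); pol <- g(pol)
  if (any(hss[!is.na(hss)] < 0) || any(pol[!is.na(pol)] < 0)) {
    stop("negative nutrient coefficients")
  }
  hss * pol
}

#' Habitat degradation from threat proximity
#'
#' Degradation of each cell is the normalised-weight sum over threat land
#' uses of a linear decay with distance to the nearest source cell:
#' `D(x) = sum_r w_r max(0, 1 - d_r(x) / max_dist_r)`, `D` in `[0, 1]`.
#'
#' @param land_use Land-use code [raster_layer()] (cell size is taken from
#'   it) or a plain matrix with `cell_size_m` supplied.
#' @param params Habitat parameter list (see [default_habitat_params()]).
#' @param cell_size_m Cell size when `land_use` is a plain matrix.
#' @return Matrix of degradation scores in `[0, 1]`.
#' @export
habitat_degradation <- function(land_use, params = default_habitat_params(),
                                cell_size_m = NULL) {
  if (inherits(land_use, "raster_layer")) {
    luv <- land_use$values
    cs <- land_use$cell_size_m
  } else {
    luv <- land_use
    if (is.null(cell_size_m)) stop("cell_size_m required for matrix input")
    cs <- cell_size_m
  }
  th <- params$threats
  if (any(th$max_dist_m <= 0)) stop("threat max distance must be > 0")
  w <- th$weight / sum(th$weight)
  codes <- land_use_codes()
  D <- matrix(0, nrow(luv), ncol(luv))
  for (r in seq_len(nrow(th))) {
    src <- !is.na(luv) & luv == codes[[th$land_use[r]]]
    if (!any(src)) next
    # distance (in cells) to nearest source: EBImage distance transform
    # measures distance to the nearest zero-valued pixel
    d <- EBImage::distmap(matrix(as.numeric(!src), nrow(luv), ncol(luv))) * cs
    D <- D + w[r] * pmax(0, 1 - d / th$max_dist_m[r])
  }
  clamp(D, lo = 0, hi = 1)
}

#' Habitat quality
#'
#' `Q = H_j (1 - D^2 / (D^2 + k^2))`: suitability of the land use damped
#' by degradation with half-saturation at `D = k`.
#'
#' @param land_use Land-use code layer/matrix.
#' @param D Degradation matrix in `[0, 1]` (from [habitat_degradation()]).
#' @param params Habitat parameter list with `suitability` and `k`.
#' @return Matrix of habitat quality in `[0, 1]`.
#' @export
habitat_quality <- function(land_use, D, params = default_habitat_params()) {
  if (params$k <= 0) stop("half-saturation constant k must be > 0")
  luv <- if (inherits(land_use, "raster_layer")) land_use$values else land_use
  Dm <- if (inherits(D, "raster_layer")) D$values else D
  st <- params$suitability
  miss <- setdiff(unique(luv[!is.na(luv)]), st$code)
  if (length(miss)) stop("land-use code(s) missing from suitability table: ",
                         paste(miss, collapse = ", "))
  H <- matrix(st$H_j[match(luv, st$code)], nrow(luv), ncol(luv))
  H * (1 - Dm^2 / (Dm^2 + params$k^2))
}

#' ES parameter bundle
#'
#' Collects every land-use-keyed parameter table the service equations
#' need; all arguments default to the package's synthetic tables.
#'
#' @param revision Food-production revision coefficients.
#' @param carbon Carbon pool table.
#' @param habitat Habitat parameter list.
#' @param fp_variant Food-production variant flag (see [food_production()]).
#' @return A list of class `es_params`.
#' @export
es_params <- function(revision = default_revision_coefficients(),
                      carbon = default_carbon_pools(),
                      habitat = default_habitat_params(),
                      fp_variant = "multiplicative") {
  structure(list(revision = revision, carbon = carbon, habitat = habitat,
                 fp_variant = fp_variant), class = "es_params")
}

#' Assemble the eight-service ES stack
#'
#' Computes FP, CS, WY, SC, TN, TP and HQ from the stack's input layers
#' and copies the landscape-aesthetics layer `la` through; all outputs
#' share the stack's grid and date tag.
#'
#' @param stack A [landscape_stack()] with layers `land_use`,
#'   `temperature`, `precipitation`, `aet`, `usle_R`, `usle_K`, `usle_LS`,
#'   `usle_Cf`, `usle_P`, `hss`, `pol_N`, `pol_P`, `la`.
#' @param params An [es_params()] bundle.
#' @return Object of class `es_stack`: named list of eight
#'   [raster_layer()]s plus `date_tag`.
#' @export
assemble_es_stack <- function(stack, params = es_params()) {
  stopifnot(inherits(stack, "landscape_stack"), inherits(params, "es_params"))
  need <- c("land_use", "temperature", "precipitation", "aet", "usle_R",
            "usle_K", "usle_LS", "usle_Cf", "usle_P", "hss", "pol_N",
            "pol_P", "la")
  miss <- setdiff(need, names(stack$layers))
  if (length(miss)) stop("missing input layer(s): ", paste(miss, collapse = ", "))
  ly <- stack$layers
  lu <- ly$land_use
  out <- list(
    FP = food_production(ly$temperature, ly$precipitation, lu,
                         params$revision, params$fp_variant)$FP,
    CS = carbon_storage(lu, params$carbon),
    WY = water_yield(ly$precipitation, ly$aet),
    SC = soil_conservation(ly$usle_R, ly$usle_K, ly$usle_LS,
                           ly$usle_Cf, ly$usle_P),
    TN = nutrient_export(ly$hss, ly$pol_N),
    TP = nutrient_export(ly$hss, ly$pol_P),
    HQ = habitat_quality(lu, habitat_degradation(lu, params$habitat),
                         params$habitat),
    LA = ly$la$values)
  units <- c(FP = "kg/ha/a", CS = "t/ha", WY = "mm", SC = "t/km2",
             TN = "kg/ha/a", TP = "kg/ha/a", HQ = "index", LA = "index")
  layers <- lapply(names(out), function(nm) {
    raster_layer(out[[nm]], name = nm, units = units[[nm]],
                 cell_size_m = lu$cell_size_m, origin = lu$origin)
  })
  names(layers) <- names(out)
  structure(list(date_tag = stack$date_tag, layers = layers),
            class = "es_stack")
}

#' @export
print.es_stack <- function(x, ...) {
  cat(sprintf("<es_stack '%s'> %s\n", x$date_tag,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}
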