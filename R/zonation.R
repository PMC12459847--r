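#' Names of the six classification features
#'
#' @return Character vector: population density, GDP density, PLAND
#'   (construction-land share), nighttime light, landscape-fragmentation
#'   entropy and POI urban-function score.
#' @export
feature_names <- function() {
  c("population_density", "gdp_density", "pland", "ntl",
    "fragmentation_w", "poi_function")
}

#' Mask large water bodies
#'
#' Flags connected water components whose area strictly exceeds
#' `min_area_km2`; smaller water (ponds, narrow channels) is retained.
#' Connectivity is 4-neighbour.
#'
#' @param stack A [landscape_stack()] containing a `land_use` layer.
#' @param min_area_km2 Area threshold in square kilometres (default 1).
#' @return Logical matrix on the stack grid, `TRUE` = masked.
#' @export
mask_water <- function(stack, min_area_km2 = 1) {
  stopifnot(inherits(stack, "landscape_stack"))
  lu <- stack$layers$land_use
  if (is.null(lu)) stop("missing land-use layer")
  wat <- !is.na(lu$values) & lu$values == land_use_codes()[["water"]]
  if (!any(wat)) return(matrix(FALSE, nrow(lu$values), ncol(lu$values)))
  lab <- EBImage::bwlabel(matrix(as.numeric(wat), nrow(wat), ncol(wat)))
  cell_km2 <- (lu$cell_size_m / 1000)^2
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes * cell_km2 > min_area_km2)
  matrix(lab %in% big, nrow(wat), ncol(wat))
}

#' Construction-land share (PLAND) of a window
#'
#' Percentage of the non-nodata area of a land-use window occupied by
#' construction (built-up) land.
#'
#' @param land_use A [raster_layer()] of land-use codes or a plain matrix.
#' @param rows,cols Optional window indices; default: whole layer.
#' @return Percentage in `[0, 100]`.
#' @export
compute_pland <- function(land_use, rows = NULL, cols = NULL) {
  v <- if (inherits(land_use, "raster_layer")) land_use$values else land_use
  if (!is.null(rows)) v <- v[rows, cols, drop = FALSE]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("window entirely nodata")
  100 * sum(v == land_use_codes()[["builtup"]]) / length(v)
}

#' Landscape-fragmentation entropy of a window
#'
#' Shannon entropy `W = -sum(X_n * ln X_n)` of the land-type proportions in
#' a window (nats), with `0 * ln 0 := 0`. Zero for a single land type,
#' maximal (`ln n`) at a uniform mixture of `n` types.
#'
#' @inheritParams compute_pland
#' @return Entropy in nats.
#' @export
compute_fragmentation <- function(land_use, rows = NULL, cols = NULL) {
  v <- if (inherits(land_use, "raster_layer")) land_use$values else land_use
  if (!is.null(rows)) v <- v[rows, cols, drop = FALSE]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("window entirely nodata")
  p <- tabulate(v) / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' POI kernel-density configuration
#'
#' @param weights Named non-negative weights per POI category, summing to 1
#'   (hierarchical-analysis weights; defaults to equal weights over the
#'   categories found in the data when `NULL`).
#' @param bandwidth_m Gaussian kernel bandwidth in metres (default 1000,
#'   one feature cell).
#' @return Object of class `poi_function_config`.
#' @export
poi_function_config <- function(weights = NULL, bandwidth_m = 1000) {
  if (bandwidth_m <= 0) stop("negative or zero kernel bandwidth")
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("POI weights must be non-negative")
    if (abs(sum(weights) - 1) > 1e-9) stop("POI weights must sum to 1")
  }
  structure(list(weights = weights, bandwidth_m = bandwidth_m),
            class = "poi_function_config")
}

#' POI urban-function assessment
#'
#' Gaussian kernel density of each POI category evaluated at the centres of
#' a feature grid, combined as the weighted total density and as per-type
#' shares `F_i = n_i w_i / sum(n_i w_i) * 100`. The cell feature used for
#' classification is the weighted total min-max rescaled to `[0, 100]`
#' across the grid (a share alone carries no density gradient).
#'
#' @param poi `data.frame` with `x`, `y`, `category`.
#' @param config A [poi_function_config()].
#' @param nr,nc Feature-grid dimensions.
#' @param cell_size_m Feature cell size (metres).
#' @param origin Grid top-left origin `c(x, y)`.
#' @return List with `feature` (rescaled percent matrix), `density`
#'   (weighted total density) and `shares` (named list of per-type `F_i`
#'   percent matrices).
#' @export
compute_poi_function <- function(poi, config, nr, nc, cell_size_m = 1000,
                                 origin = c(0, nr * cell_size_m)) {
  stopifnot(inherits(config, "poi_function_config"))
  h <- config$bandwidth_m
  cx <- origin[1] + (seq_len(nc) - 0.5) * cell_size_m
  cy <- origin[2] - (seq_len(nr) - 0.5) * cell_size_m
  cats <- sort(unique(as.character(poi$category)))
  if (length(cats) == 0) {
    zero <- matrix(0, nr, nc)
    return(list(feature = zero, density = zero, shares = list()))
  }
  w <- config$weights
  if (is.null(w)) w <- stats::setNames(rep(1 / length(cats), length(cats)), cats)
  if (!all(cats %in% names(w))) stop("POI category missing from weights")
  dens <- lapply(cats, function(cc) {
    pts <- poi[poi$category == cc, , drop = FALSE]
    m <- matrix(0, nr, nc)
    if (nrow(pts) == 0) return(m)
    # separable Gaussian kernel: outer product of axis distances
    kx <- exp(-outer(cx, pts$x, "-")^2 / (2 * h^2))  # nc x npts
    ky <- exp(-outer(cy, pts$y, "-")^2 / (2 * h^2))  # nr x npts
    (ky %*% t(kx)) / (2 * pi * h^2)
  })
  names(dens) <- cats
  weighted <- Reduce(`+`, Map(function(d, cc) d * w[[cc]], dens, cats))
  tot <- weighted
  shares <- lapply(cats, function(cc) {
    s <- dens[[cc]] * w[[cc]] / tot * 100
    s[tot == 0] <- 0
    s
  })
  names(shares) <- cats
  list(feature = minmax(weighted) * 100, density = weighted, shares = shares)
}

# aggregate a fine matrix to the feature grid by block mean / block apply
block_ids <- function(NR, NC, sub) {
  fi <- rep(ceiling(seq_len(NR) / sub), times = NC)
  fj <- rep(ceiling(seq_len(NC) / sub), each = NR)
  nrf <- ceiling(NR / sub)
  (fj - 1L) * nrf + fi  # column-major feature-cell id
}

block_mean <- function(m, sub, na_mask = NULL, nrf = NULL, ncf = NULL) {
  NR <- nrow(m); NC <- ncol(m)
  if (is.null(nrf)) nrf <- ceiling(NR / sub)
  if (is.null(ncf)) ncf <- ceiling(NC / sub)
  ids <- block_ids(NR, NC, sub)
  v <- as.vector(m)
  if (!is.null(na_mask)) v[as.vector(na_mask)] <- NA
  ok <- !is.na(v)
  s <- rep(NA_real_, nrf * ncf)
  cnt <- tabulate(ids[ok], nbins = nrf * ncf)
  sm <- rep(0, nrf * ncf)
  agg <- rowsum(v[ok], ids[ok])
  sm[as.integer(rownames(agg))] <- agg[, 1]
  s[cnt > 0] <- sm[cnt > 0] / cnt[cnt > 0]
  matrix(s, nrf, ncf)
}

#' Assemble the six-feature classification grid
#'
#' Computes all six 1-km features from a landscape stack: block means of
#' population density, GDP density and nighttime light; PLAND and
#' fragmentation entropy from the fine land-use mosaic; and the POI
#' urban-function score. Feature cells in which more than half of the fine
#' cells are masked carry nodata in every feature.
#'
#' @param stack A [landscape_stack()].
#' @param mask Logical fine-grid matrix from [mask_water()] (or `NULL`).
#' @param poi_config A [poi_function_config()].
#' @param feature_cell_m Feature cell size in metres (default 1000).
#' @return Object of class `feature_grid`: list of feature matrices, the
#'   feature-scale logical mask, cell size and origin.
#' @export
assemble_features <- function(stack, mask = NULL,
                              poi_config = poi_function_config(),
                              feature_cell_m = 1000) {
  stopifnot(inherits(stack, "landscape_stack"))
  lu <- stack$layers$land_use
  sub <- round(feature_cell_m / lu$cell_size_m)
  NR <- nrow(lu$values); NC <- ncol(lu$values)
  nrf <- ceiling(NR / sub); ncf <- ceiling(NC / sub)
  if (is.null(mask)) mask <- matrix(FALSE, NR, NC)
  fmask <- block_mean(mask * 1, sub) > 0.5
  fmask[is.na(fmask)] <- TRUE

  feats <- list()
  for (nm in c("population_density", "gdp_density", "ntl")) {
    ly <- stack$layers[[nm]]
    if (is.null(ly)) stop("missing layer: ", nm)
    stop_if_misaligned(lu, ly)
    feats[[nm]] <- block_mean(ly$values, sub, na_mask = mask, nrf, ncf)
  }
  built <- land_use_codes()[["builtup"]]
  luv <- lu$values
  luv[mask] <- NA
  feats$pland <- block_mean((luv == built) * 1, sub, nrf = nrf, ncf = ncf) * 100
  # fragmentation entropy per block from land-type counts
  ids <- block_ids(NR, NC, sub)
  ok <- !is.na(as.vector(luv))
  tab <- table(factor(ids[ok], levels = seq_len(nrf * ncf)),
               factor(as.vector(luv)[ok], levels = land_use_codes()))
  tab <- matrix(as.numeric(tab), nrf * ncf, length(land_use_codes()))
  tot <- rowSums(tab)
  p <- tab / ifelse(tot == 0, 1, tot)
  ent <- -rowSums(ifelse(p > 0, p * log(p), 0))
  ent[tot == 0] <- NA
  feats$fragmentation_w <- matrix(ent, nrf, ncf)
  feats$poi_function <- compute_poi_function(
    stack$poi, poi_config, nrf, ncf, feature_cell_m,
    origin = lu$origin)$feature

  for (nm in feature_names()) feats[[nm]][fmask] <- NA
  structure(list(features = feats[feature_names()], mask = fmask,
                 cell_size_m = feature_cell_m, origin = lu$origin),
            class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("<feature_grid> %d x %d cells, %d masked\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# ---- transitions -----------------------------------------------------------

#' Transition type codes
#'
#' @return Named integer vector of the transition typology codes.
#' @export
transition_codes <- function() {
  c(urban_maintenance = 1L, urban_expansion = 2L, fringe_maintenance = 3L,
    fringe_expansion = 4L, rural_retention = 5L, excluded = 6L)
}

#' Type zone transitions between two dates
#'
#' Five-class transition typology: urban maintained, fringe upgraded to
#' urban (urban expansion), fringe maintained, rural upgraded to fringe
#' (fringe expansion), rural retained. Downgrades (urban or fringe back to
#' rural, urban to fringe) are excluded as negligible and non-systematic.
#' Direct rural-to-urban jumps are not named by the five-class scheme;
#' by default they are treated as urban expansion, or excluded via
#' `rural_to_urban = "excluded"`.
#'
#' @param z0,z1 Aligned [zone_map()]s for the two dates.
#' @param rural_to_urban Either `"urban_expansion"` (default) or
#'   `"excluded"`.
#' @return A [raster_layer()] of [transition_codes()] (class
#'   `transition_map`), `NA` where either date is nodata.
#' @export
type_transitions <- function(z0, z1,
                             rural_to_urban = c("urban_expansion", "excluded")) {
  rural_to_urban <- match.arg(rural_to_urban)
  stop_if_misaligned(z0, z1, "zone maps")
  tc <- transition_codes()
  a <- z0$values; b <- z1$values
  out <- matrix(NA_integer_, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  key <- a * 10 + b
  map <- c(`22` = tc[["urban_maintenance"]], `12` = tc[["urban_expansion"]],
           `11` = tc[["fringe_maintenance"]], `1` = tc[["fringe_expansion"]],
           `0` = tc[["rural_retention"]], `21` = tc[["excluded"]],
           `20` = tc[["excluded"]], `10` = tc[["excluded"]],
           `2` = if (rural_to_urban == "urban_expansion")
             tc[["urban_expansion"]] else tc[["excluded"]])
  out[ok] <- map[as.character(key[ok])]
  tm <- raster_layer(out, name = "transitions", units = "class",
                     cell_size_m = z0$cell_size_m, origin = z0$origin)
  class(tm) <- c("transition_map", class(tm))
  tm
}

#' Zone transfer matrix between two dates
#'
#' Row-stochastic 3 x 3 matrix of transition shares over cells valid at
#' both dates (from-class rows, to-class columns), with absolute areas.
#'
#' @param z0,z1 Aligned [zone_map()]s.
#' @return List with `shares` (row-stochastic matrix), `counts` and
#'   `areas_km2`.
#' @export
transfer_matrix <- function(z0, z1) {
  stop_if_misaligned(z0, z1, "zone maps")
  ok <- !is.na(z0$values) & !is.na(z1$values)
  if (!any(ok)) stop("no jointly valid cells")
  lv <- c("rural", "fringe", "urban")
  cnt <- table(factor(z0$values[ok], levels = 0:2, labels = lv),
               factor(z1$values[ok], levels = 0:2, labels = lv))
  cnt <- matrix(as.numeric(cnt), 3, 3, dimnames = list(from = lv, to = lv))
  rs <- rowSums(cnt)
  shares <- cnt / ifelse(rs == 0, 1, rs)
  list(shares = shares, counts = cnt,
       areas_km2 = cnt * (z0$cell_size_m / 1000)^2)
}

#' Majority attribution of a categorical feature-scale layer to villages
#'
#' Assigns to each village the modal code of the feature-scale cells its
#' fine cells fall in, weighting by fine-cell counts; ties break toward the
#' lower code.
#'
#' @param villages A [village_tessellation()] (fine grid).
#' @param layer A categorical [raster_layer()] at the feature scale.
#' @return Named integer vector of codes per village id (`NA` when every
#'   covering cell is nodata).
#' @export
village_majority <- function(villages, layer) {
  idr <- villages$id_raster
  sub <- round(layer$cell_size_m / idr$cell_size_m)
  ids <- as.vector(idr$values)
  NR <- nrow(idr$values); NC <- ncol(idr$values)
  fi <- pmin(rep(ceiling(seq_len(NR) / sub), times = NC), nrow(layer$values))
  fj <- pmin(rep(ceiling(seq_len(NC) / sub), each = NR), ncol(layer$values))
  code <- layer$values[cbind(fi, fj)]
  out <- stats::setNames(rep(NA_integer_, length(villages$ids)),
                         villages$ids)
  ok <- !is.na(code)
  if (!any(ok)) return(out)
  tab <- table(ids[ok], code[ok])
  for (r in rownames(tab)) {
    counts <- tab[r, ]
    best <- names(counts)[counts == max(counts)]
    out[[r]] <- min(as.integer(best))  # tie -> lower code
  }
  out
}
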