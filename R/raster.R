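#' Grid raster layer
#'
#' A minimal planar raster: a numeric (or integer-coded categorical) matrix
#' with a name, units, cell size in metres and a grid origin. Row 1 is the
#' top (northernmost) row; cell `[i, j]` covers the half-open square
#' `[origin_x + (j-1)*cs, origin_x + j*cs) x (origin_y - i*cs, origin_y - (i-1)*cs]`
#' where `cs` is the cell size and `origin` the top-left corner. Missing
#' cells are `NA`.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param name Layer identifier.
#' @param units Free-text units.
#' @param cell_size_m Cell edge length in metres.
#' @param origin Numeric `c(x, y)` of the top-left grid corner.
#' @param categories Optional named integer vector of declared codes for a
#'   categorical layer; non-`NA` values outside this set are rejected.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, name, units = "", cell_size_m = 1000,
                         origin = c(0, 0), categories = NULL) {
  stopifnot(is.matrix(values), is.character(name), cell_size_m > 0,
            length(origin) == 2)
  if (!is.null(categories)) {
    bad <- setdiff(unique(values[!is.na(values)]), categories)
    if (length(bad) > 0) {
      stop(sprintf("layer '%s': undeclared categorical code(s): %s",
                   name, paste(bad, collapse = ", ")))
    }
  }
  v <- values[!is.na(values)]
  if (length(v) && any(!is.finite(v))) {
    stop(sprintf("layer '%s': non-finite values present", name))
  }
  structure(list(values = values, name = name, units = units,
                 cell_size_m = cell_size_m, origin = as.numeric(origin),
                 categories = categories),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer '%s'> %d x %d cells @ %g m, %d nodata\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size_m,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_layer <- function(x) dim(x$values)

# TRUE when two layers share grid, cell size and origin
rasters_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_misaligned <- function(a, b, what = "layers") {
  if (!rasters_aligned(a, b)) {
    stop(sprintf("misaligned %s: '%s' vs '%s'", what, a$name, b$name))
  }
  invisible(TRUE)
}

#' Coordinates of cell centres of a raster layer
#'
#' @param layer A [raster_layer()].
#' @return A list with matrices `x` and `y` of cell-centre coordinates
#'   (metres, same dimensions as the layer).
#' @keywords internal
cell_centers <- function(layer) {
  cs <- layer$cell_size_m
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  x <- matrix(rep(layer$origin[1] + (seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  y <- matrix(rep(layer$origin[2] - (seq_len(nr) - 0.5) * cs, times = nc), nr, nc)
  list(x = x, y = y)
}

#' Land-use codes used throughout the package
#'
#' Integer codes for the seven land-use categories.
#'
#' @return Named integer vector.
#' @export
land_use_codes <- function() {
  c(cropland = 1L, forest = 2L, grassland = 3L, wetland = 4L,
    water = 5L, builtup = 6L, bare = 7L)
}

#' Two-date landscape stack
#'
#' Bundles the aligned input layers and the POI point set for one date.
#' All layers share grid geometry; socio-economic layers generated at the
#' 1-km feature scale are stored refined to the common fine grid.
#'
#' @param date_tag Label such as `"t0"` or `"t1"`.
#' @param layers Named list of aligned [raster_layer()] objects; must
#'   include `land_use`.
#' @param poi `data.frame` with columns `x`, `y` (metres) and `category`.
#' @return Object of class `landscape_stack`.
#' @export
landscape_stack <- function(date_tag, layers, poi) {
  stopifnot(is.character(date_tag), is.list(layers), length(layers) > 0)
  if (is.null(layers$land_use)) stop("stack must contain a 'land_use' layer")
  ref <- layers[[1]]
  for (ly in layers) stop_if_misaligned(ref, ly, "stack layers")
  stopifnot(all(c("x", "y", "category") %in% names(poi)))
  structure(list(date_tag = date_tag, layers = layers, poi = poi),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack '%s'> %d layers (%s), %d POIs\n",
              x$date_tag, length(x$layers),
              paste(utils::head(names(x$layers), 6), collapse = ", "),
              nrow(x$poi)))
  invisible(x)
}

#' Categorical zone map (rural / fringe / urban)
#'
#' @param values Integer matrix with codes 0 (rural), 1 (fringe), 2 (urban)
#'   and `NA` for masked cells.
#' @param date_tag Date label.
#' @inheritParams raster_layer
#' @return Object of classes `zone_map` and `raster_layer`.
#' @export
zone_map <- function(values, date_tag, cell_size_m = 1000, origin = c(0, 0)) {
  bad <- setdiff(unique(values[!is.na(values)]), c(0, 1, 2))
  if (length(bad)) stop("zone map contains undeclared codes: ",
                        paste(bad, collapse = ", "))
  z <- raster_layer(values, name = paste0("zones_", date_tag),
                    units = "class", cell_size_m = cell_size_m, origin = origin)
  z$date_tag <- date_tag
  class(z) <- c("zone_map", class(z))
  z
}

#' Zone code labels
#' @return Named integer vector mapping labels to codes.
#' @export
zone_codes <- function() c(rural = 0L, fringe = 1L, urban = 2L)
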