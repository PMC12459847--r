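#' Write a raster layer to an ESRI ASCII grid file
#'
#' Plain-text `.asc` format readable by any GIS: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values from the top row down. Values are written
#' with full double precision so a write/read round trip is bit-identical.
#'
#' @param layer A [raster_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  v <- layer$values
  nodata <- -9999
  if (any(v[!is.na(v)] == nodata)) nodata <- -3.402823e+38
  out <- v
  out[is.na(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$origin[1]),
    sprintf("yllcorner %.10g", layer$origin[2] - nrow(v) * layer$cell_size_m),
    sprintf("cellsize %.10g", layer$cell_size_m),
    sprintf("NODATA_value %s", format(nodata, digits = 17))
  ), con)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a raster layer from an ESRI ASCII grid file
#'
#' @param path Input `.asc` file.
#' @param name Layer name to assign (defaults to the file stem).
#' @param units Units string to attach.
#' @return A [raster_layer()].
#' @export
read_raster <- function(path, name = NULL, units = "") {
  if (!file.exists(path)) stop("no such raster file: ", path)
  hdr_lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid body size mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  raster_layer(m, name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
               units = units, cell_size_m = hdr$cellsize,
               origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize))
}

#' Write a POI point set as GeoJSON
#'
#' @param poi `data.frame` with `x`, `y`, `category`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poi <- function(poi, path) {
  stopifnot(all(c("x", "y", "category") %in% names(poi)))
  feats <- lapply(seq_len(nrow(poi)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(poi$x[i], poi$y[i])),
         properties = list(category = as.character(poi$category[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a POI point set from GeoJSON
#'
#' @param path GeoJSON file of Point features with a `category` property.
#' @return `data.frame` with `x`, `y`, `category`.
#' @export
read_poi <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  rows <- lapply(g$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Point" ||
        length(f$geometry$coordinates) < 2) {
      stop("empty or non-point geometry in ", path)
    }
    data.frame(x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               category = as.character(f$properties$category))
  })
  do.call(rbind, rows)
}

#' Write a village tessellation as GeoJSON
#'
#' Each village is exported as a MultiPolygon made of its constituent grid
#' cells (axis-aligned squares), with the village id as a property. The
#' representation is lossless: reading it back reconstructs the id raster.
#'
#' @param villages A [village_tessellation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_villages <- function(villages, path) {
  stopifnot(inherits(villages, "village_tessellation"))
  idr <- villages$id_raster
  cs <- idr$cell_size_m
  ox <- idr$origin[1]; oy <- idr$origin[2]
  feats <- lapply(villages$ids, function(vid) {
    cells <- which(idr$values == vid, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(cells)), function(k) {
      i <- cells[k, 1]; j <- cells[k, 2]
      x0 <- ox + (j - 1) * cs; x1 <- x0 + cs
      y1 <- oy - (i - 1) * cs; y0 <- y1 - cs
      list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = polys),
         properties = list(village_id = vid))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats,
                            grid = list(nrows = nrow(idr$values),
                                        ncols = ncol(idr$values),
                                        cell_size_m = cs,
                                        origin = idr$origin)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a village tessellation from GeoJSON
#'
#' Inverse of [write_villages()]; validates that the village polygons are
#' pairwise non-overlapping and cover the grid.
#'
#' @param path GeoJSON file written by [write_villages()].
#' @return A [village_tessellation()].
#' @export
read_villages <- function(path) {
  g <- jsonlite::read_json(path)
  gr <- g$grid
  if (is.null(gr)) stop("missing grid metadata in ", path)
  nr <- gr$nrows; nc <- gr$ncols; cs <- gr$cell_size_m
  org <- as.numeric(unlist(gr$origin))
  idm <- matrix(NA_integer_, nr, nc)
  for (f in g$features) {
    vid <- f$properties$village_id
    for (poly in f$geometry$coordinates) {
      ring <- poly[[1]]
      if (length(ring) < 4) stop("empty geometry in ", path)
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      j <- round((min(xs) - org[1]) / cs) + 1
      i <- round((org[2] - max(ys)) / cs) + 1
      if (i < 1 || i > nr || j < 1 || j > nc) stop("cell outside grid in ", path)
      if (!is.na(idm[i, j]) && idm[i, j] != vid) {
        stop("overlapping village polygons in ", path)
      }
      idm[i, j] <- as.integer(vid)
    }
  }
  if (any(is.na(idm))) stop("village polygons do not cover the grid in ", path)
  village_tessellation(raster_layer(idm, "village_id", "id", cs, org))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos fail loudly. See
#' [pipeline_config()] for the full key set and defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
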