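# Raster data model: named layers (plain matrices) on a shared WGS84
# latitude/longitude grid. Cell-centre registration, north-up: row 1 is the
# northernmost row, column 1 the westernmost. Missing data are NA.

#' Create a raster stack on a geographic grid
#'
#' A `grid_stack` holds any number of equally shaped layers (matrices) on a
#' shared WGS84 latitude/longitude grid with square cells of `cellsize`
#' degrees. Registration is cell-centre, north-up: row 1 is the northernmost
#' row and column 1 the westernmost column. Missing values are `NA` and are
#' treated as shared across layers by operations that need a missing mask.
#'
#' @param west,north western and northern edge of the grid, decimal degrees.
#' @param cellsize cell size in decimal degrees (> 0).
#' @param nrow,ncol grid dimensions.
#' @param layers named list of `nrow` x `ncol` matrices (may be empty).
#' @return An object of class `grid_stack`.
#' @seealso [study_area_grid()], [read_grid()], [write_grid()]
#' @export
grid_stack <- function(west, north, cellsize, nrow, ncol, layers = list()) {
  stopifnot(is.numeric(west), is.numeric(north), cellsize > 0,
            nrow >= 1, ncol >= 1)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (length(layers)) {
    if (is.null(names(layers)) || any(!nzchar(names(layers))))
      stop_("all layers must be named")
    for (nm in names(layers)) {
      d <- dim(layers[[nm]])
      if (is.null(d) || d[1] != nrow || d[2] != ncol)
        stop_("layer '%s' does not have dimensions %d x %d", nm, nrow, ncol)
    }
  }
  structure(list(west = west, north = north, cellsize = cellsize,
                 nrow = nrow, ncol = ncol, crs = "WGS84", layers = layers),
            class = "grid_stack")
}

#' Empty grid covering a study area
#'
#' Builds the cell grid for a rectangular study area at a given resolution in
#' arc-seconds. The bounding box must divide evenly into whole cells.
#'
#' @param bbox numeric vector `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param resolution_arcsec cell size in arc-seconds (e.g. 30).
#' @return A `grid_stack` with no layers.
#' @examples
#' g <- study_area_grid(c(104, 110, 10, 16), 30)
#' n_cells(g)  # 518400
#' @export
study_area_grid <- function(bbox, resolution_arcsec) {
  if (length(bbox) != 4) stop_("bbox must be c(lon_min, lon_max, lat_min, lat_max)")
  lon_min <- bbox[1]; lon_max <- bbox[2]; lat_min <- bbox[3]; lat_max <- bbox[4]
  if (!(lon_max > lon_min && lat_max > lat_min))
    stop_("degenerate bbox: need lon_max > lon_min and lat_max > lat_min")
  cs <- resolution_arcsec / 3600
  nc <- (lon_max - lon_min) / cs
  nr <- (lat_max - lat_min) / cs
  if (abs(nc - round(nc)) > 1e-8 || abs(nr - round(nr)) > 1e-8)
    stop_("bbox does not divide evenly into %s arc-second cells", resolution_arcsec)
  grid_stack(west = lon_min, north = lat_max, cellsize = cs,
             nrow = round(nr), ncol = round(nc))
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d x %d cells (%.6g deg), WGS84\n",
              x$nrow, x$ncol, x$cellsize))
  cat(sprintf("  extent: %g to %g E, %g to %g N\n",
              x$west, x$west + x$ncol * x$cellsize,
              x$north - x$nrow * x$cellsize, x$north))
  if (length(x$layers))
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  else cat("  layers: (none)\n")
  invisible(x)
}

#' @export
`[[.grid_stack` <- function(x, name) x$layers[[name]]

#' @export
`[[<-.grid_stack` <- function(x, name, value) {
  if (is.null(value)) { x$layers[[name]] <- NULL; return(x) }
  d <- dim(value)
  if (is.null(d) || d[1] != x$nrow || d[2] != x$ncol)
    stop_("layer '%s' does not have dimensions %d x %d", name, x$nrow, x$ncol)
  x$layers[[name]] <- value
  x
}

#' Grid bookkeeping helpers
#'
#' `n_cells` returns the number of cells; `lon_centers`/`lat_centers` the
#' cell-centre coordinates per column/row; `layer_names` the layer names;
#' `missing_mask` the shared missing mask (a cell is missing if it is `NA`
#' in any of the named layers).
#'
#' @param gs a `grid_stack`.
#' @param layers layer names to combine for the mask; default all layers.
#' @return See description.
#' @export
n_cells <- function(gs) gs$nrow * gs$ncol

#' @rdname n_cells
#' @export
lon_centers <- function(gs) gs$west + (seq_len(gs$ncol) - 0.5) * gs$cellsize

#' @rdname n_cells
#' @export
lat_centers <- function(gs) gs$north - (seq_len(gs$nrow) - 0.5) * gs$cellsize

#' @rdname n_cells
#' @export
layer_names <- function(gs) names(gs$layers)

#' @rdname n_cells
#' @export
missing_mask <- function(gs, layers = NULL) {
  layers <- layers %||% names(gs$layers)
  m <- matrix(FALSE, gs$nrow, gs$ncol)
  for (nm in layers) {
    if (is.null(gs$layers[[nm]])) stop_("no layer named '%s'", nm)
    m <- m | is.na(gs$layers[[nm]])
  }
  m
}

# Matrices of cell-centre coordinates (same shape as layers).
cell_lon_matrix <- function(gs) matrix(lon_centers(gs), gs$nrow, gs$ncol, byrow = TRUE)
cell_lat_matrix <- function(gs) matrix(lat_centers(gs), gs$nrow, gs$ncol)

#' Read and write grids as ESRI ASCII rasters
#'
#' Each layer is stored as one plain-text `.asc` file (ESRI ASCII grid,
#' self-describing georeference, `NODATA_value` honoured), named
#' `<layer>.asc`. `read_grid` reads every `.asc` file in a directory back
#' into a single `grid_stack`, checking that all files share one grid.
#'
#' @param gs a `grid_stack`.
#' @param dir directory to write to / read from.
#' @param nodata value used to encode `NA` on disk.
#' @return `write_grid` returns the written file paths invisibly;
#'   `read_grid` returns a `grid_stack`.
#' @export
write_grid <- function(gs, dir, nodata = -9999) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(gs$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(gs$layers[[nm]], p, gs$west, gs$north - gs$nrow * gs$cellsize,
                     gs$cellsize, nodata)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_grid
#' @export
read_grid <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop_("no .asc files in '%s'", dir)
  gs <- NULL
  for (f in files) {
    g <- read_ascii_grid(f)
    nm <- sub("\\.asc$", "", basename(f))
    if (is.null(gs)) {
      gs <- grid_stack(g$west, g$north, g$cellsize, nrow(g$values), ncol(g$values))
    } else if (abs(g$west - gs$west) > 1e-9 || abs(g$north - gs$north) > 1e-9 ||
               abs(g$cellsize - gs$cellsize) > 1e-12 ||
               nrow(g$values) != gs$nrow || ncol(g$values) != gs$ncol) {
      stop_("layer '%s' is not on the same grid as the other layers", nm)
    }
    gs[[nm]] <- g$values
  }
  gs
}

write_ascii_grid <- function(m, path, xll, yll, cellsize, nodata = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.12g", cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  # rows already run north -> south, matching the .asc convention
  utils::write.table(format(mm, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
}

read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  m <- matrix(scan(path, skip = 6, quiet = TRUE), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(west = vals[["xllcorner"]],
       north = vals[["yllcorner"]] + nr * vals[["cellsize"]],
       cellsize = vals[["cellsize"]], values = m)
}

#' Rasterize GeoJSON polygons to a binary mask
#'
#' A cell is included when its centre falls inside a polygon, using the
#' even-odd (crossing-number) rule; holes are honoured. Accepts a path to a
#' GeoJSON file or an already parsed list (as from [jsonlite::read_json()]),
#' containing a FeatureCollection, Feature, Polygon or MultiPolygon.
#'
#' @param gs a `grid_stack` defining the target grid.
#' @param geojson file path or parsed GeoJSON list.
#' @return A logical `nrow x ncol` matrix.
#' @export
rasterize_polygons <- function(gs, geojson) {
  gj <- if (is.character(geojson)) jsonlite::read_json(geojson) else geojson
  rings <- collect_rings(gj)
  lon <- cell_lon_matrix(gs); lat <- cell_lat_matrix(gs)
  crossings <- matrix(0L, gs$nrow, gs$ncol)
  for (ring in rings) {
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    n <- length(xs)
    if (n < 3) next
    if (xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1  # drop closing vertex
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
      if (y1 == y2) next
      hit <- ((y1 > lat) != (y2 > lat)) &
        (lon < x1 + (lat - y1) * (x2 - x1) / (y2 - y1))
      crossings <- crossings + hit
    }
  }
  crossings %% 2L == 1L
}

collect_rings <- function(gj) {
  t <- gj[["type"]] %||% ""
  switch(t,
    FeatureCollection = do.call(c, lapply(gj$features, collect_rings)),
    Feature = collect_rings(gj$geometry),
    Polygon = gj$coordinates,
    MultiPolygon = do.call(c, gj$coordinates),
    GeometryCollection = do.call(c, lapply(gj$geometries, collect_rings)),
    stop_("unsupported GeoJSON type '%s'", t))
}
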