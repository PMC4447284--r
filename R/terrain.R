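# Geometric primitives on lat/lon grids: terrain slope, spherical cell
# areas, great-circle distances, D8 watershed labelling, point extraction.

EARTH_RADIUS_KM <- 6371.0088
M_PER_DEG <- 111320  # metres per degree of latitude (and of longitude at the equator)

#' Terrain slope from an elevation layer
#'
#' Horn's 8-neighbour finite-difference slope, in degrees. Horizontal
#' distances use a per-row metric conversion (1 deg latitude = 111,320 m,
#' 1 deg longitude = 111,320 * cos(latitude) m). Border cells use a clamped
#' (edge-replicated) neighbourhood; any missing neighbour makes the result
#' missing.
#'
#' @param gs a `grid_stack` containing an elevation layer in metres.
#' @param elevation name of the elevation layer.
#' @return A matrix of slopes in degrees.
#' @export
slope_from_elevation <- function(gs, elevation = "elevation") {
  z <- gs$layers[[elevation]]
  if (is.null(z)) stop_("no layer named '%s'", elevation)
  nr <- nrow(z); nc <- ncol(z)
  ri <- c(1, seq_len(nr), nr); ci <- c(1, seq_len(nc), nc)
  zp <- z[ri, ci, drop = FALSE]
  sel <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
  z_nw <- sel(0, 0); z_n <- sel(0, 1); z_ne <- sel(0, 2)
  z_w  <- sel(1, 0);                   z_e  <- sel(1, 2)
  z_sw <- sel(2, 0); z_s <- sel(2, 1); z_se <- sel(2, 2)
  dx_m <- gs$cellsize * M_PER_DEG * cos(lat_centers(gs) * pi / 180)  # per row
  dy_m <- gs$cellsize * M_PER_DEG
  dzdx <- ((z_ne + 2 * z_e + z_se) - (z_nw + 2 * z_w + z_sw)) / (8 * dx_m)
  dzdy <- ((z_sw + 2 * z_s + z_se) - (z_nw + 2 * z_n + z_ne)) / (8 * dy_m)
  out <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out[is.na(z)] <- NA_real_  # a missing cell has no slope of its own
  out
}

#' Spherical cell areas in km^2
#'
#' Area of each grid cell as a spherical zone slice,
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`, with
#' `R = 6371.0088` km. Exact for the sphere: row sums equal the closed-form
#' band area.
#'
#' @param gs a `grid_stack`.
#' @return A matrix of areas (km^2), constant within each row.
#' @export
cell_area_km2 <- function(gs) {
  cs <- gs$cellsize * pi / 180
  lat_top <- (gs$north - (seq_len(gs$nrow) - 1) * gs$cellsize) * pi / 180
  lat_bot <- lat_top - cs
  row_area <- EARTH_RADIUS_KM^2 * cs * (sin(lat_top) - sin(lat_bot))
  matrix(row_area, gs$nrow, gs$ncol)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized over
#' all four coordinate arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return Distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Label watershed basins by D8 steepest descent
#'
#' Every cell drains to its lowest of the 8 neighbours (ties broken by the
#' smallest neighbour index in row-major order); cells with no strictly
#' lower neighbour are sinks. All cells draining to the same sink share a
#' basin label; labels `1..k` are assigned to sinks in row-major order, so
#' the labelling is deterministic and forms a partition of the non-missing
#' cells. Adding a constant to the elevation does not change the result.
#'
#' @param gs a `grid_stack` with an elevation layer.
#' @param elevation name of the elevation layer.
#' @return An integer matrix of basin labels (`NA` where elevation is `NA`).
#' @export
label_basins <- function(gs, elevation = "elevation") {
  z <- gs$layers[[elevation]]
  if (is.null(z)) stop_("no layer named '%s'", elevation)
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  zv <- as.vector(z)                      # column-major
  # Neighbour offsets in row-major tie-break order: NW, N, NE, W, E, SW, S, SE
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  row_i <- rep(seq_len(nr), times = nc)
  col_i <- rep(seq_len(nc), each = nr)
  ptr <- seq_len(n)                       # default: self (sink)
  best <- zv                              # must be strictly lower to redirect
  for (k in seq_len(8)) {
    rr <- row_i + dr[k]; cc <- col_i + dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- rep(NA_integer_, n)
    nb[ok] <- (cc[ok] - 1) * nr + rr[ok]
    nz <- rep(NA_real_, n)
    nz[ok] <- zv[nb[ok]]
    take <- ok & !is.na(nz) & !is.na(best) & nz < best
    ptr[take] <- nb[take]
    best[take] <- nz[take]
  }
  ptr[is.na(zv)] <- NA_integer_
  # Pointer jumping until every cell points at its sink.
  repeat {
    nxt <- ptr
    live <- !is.na(ptr)
    nxt[live] <- ptr[ptr[live]]
    if (identical(nxt, ptr)) break
    ptr <- nxt
  }
  sinks <- which(!is.na(ptr) & ptr == seq_len(n))
  # Row-major order of sink cells for label assignment
  sink_rm <- (row_i[sinks] - 1) * nc + col_i[sinks]
  sinks <- sinks[order(sink_rm)]
  lab <- rep(NA_integer_, n)
  lab[sinks] <- seq_along(sinks)
  out <- rep(NA_integer_, n)
  live <- !is.na(ptr)
  out[live] <- lab[ptr[live]]
  matrix(out, nr, nc)
}

#' Extract layer values at points
#'
#' Nearest-cell-centre lookup. A point exactly on a cell edge or corner is
#' assigned deterministically to the cell whose centre lies to the
#' north-west. Points outside the grid raise an error naming the offending
#' point. Cells that are `NA` in a requested layer yield `NA` and set the
#' `missing` flag for that point.
#'
#' @param gs a `grid_stack`.
#' @param lon,lat point coordinates in decimal degrees.
#' @param layers layer names to extract; default all layers.
#' @return A data frame with `lon`, `lat`, `cell` (column-major cell index),
#'   one column per layer, and a logical `missing` column.
#' @export
extract_at_points <- function(gs, lon, lat, layers = NULL) {
  layers <- layers %||% names(gs$layers)
  east <- gs$west + gs$ncol * gs$cellsize
  south <- gs$north - gs$nrow * gs$cellsize
  bad <- lon < gs$west | lon > east | lat < south | lat > gs$north
  if (any(bad)) {
    i <- which(bad)[1]
    stop_("point %d (lon %g, lat %g) is outside the grid extent", i, lon[i], lat[i])
  }
  j <- ceiling((lon - gs$west) / gs$cellsize); j[j < 1] <- 1L  # west-edge points
  i <- ceiling((gs$north - lat) / gs$cellsize); i[i < 1] <- 1L # north-edge points
  cell <- (j - 1) * gs$nrow + i
  out <- data.frame(lon = lon, lat = lat, cell = as.integer(cell))
  miss <- rep(FALSE, length(lon))
  for (nm in layers) {
    lay <- gs$layers[[nm]]
    if (is.null(lay)) stop_("no layer named '%s'", nm)
    v <- lay[cell]
    out[[nm]] <- v
    miss <- miss | is.na(v)
  }
  out$missing <- miss
  out
}
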