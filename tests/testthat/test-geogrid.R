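# Grid data model, terrain geometry and point extraction.

test_that("study_area_grid cell bookkeeping is exact", {
  g <- study_area_grid(c(104, 110, 10, 16), 30)
  expect_equal(n_cells(g), 518400)
  expect_equal(c(g$nrow, g$ncol), c(720L, 720L))
  g2 <- study_area_grid(c(0, 1, 0, 1), 30)
  expect_equal(c(g2$nrow, g2$ncol), c(120L, 120L))
  expect_equal(study_area_grid(c(0, 1.25, 0, 1), 30)$ncol, 150L)
  expect_error(study_area_grid(c(0, 1.01, 0, 1), 30), "divide")
  expect_error(study_area_grid(c(1, 0, 0, 1), 30), "degenerate")
})

test_that("grid_stack enforces shared shape and supports layer access", {
  gs <- toy_stack(4, 5)
  gs[["a"]] <- matrix(1, 4, 5)
  expect_equal(gs[["a"]], matrix(1, 4, 5))
  expect_error({gs[["b"]] <- matrix(1, 3, 5)}, "dimensions")
  gs[["b"]] <- matrix(c(NA, rep(2, 19)), 4, 5)
  expect_equal(sum(missing_mask(gs)), 1)
})

test_that("slope is zero on flat terrain and analytic on a plane", {
  gs <- toy_stack(20, 20)
  gs[["elevation"]] <- matrix(500, 20, 20)
  expect_true(all(slope_from_elevation(gs) == 0))
  # northward gradient of 0.1 m per metre
  gs2 <- grid_stack(0, 1, 1 / 120, 60, 60)
  latm <- matrix(lat_centers(gs2), 60, 60)
  gs2[["elevation"]] <- latm * 111320 * 0.1
  sl <- slope_from_elevation(gs2)
  expect_equal(sl[30, 30], atan(0.1) * 180 / pi, tolerance = 1e-6)
})

test_that("slope matches an independent centered-difference oracle inland", {
  set.seed(11)
  nr <- 25; nc <- 25
  gs <- grid_stack(0, 1, 1 / nr, nr, nc)
  z <- matrix(cumsum(rnorm(nr * nc, sd = 5)), nr, nc)
  z <- (z + t(z)) / 2  # smooth-ish random surface
  gs[["elevation"]] <- z
  sl <- slope_from_elevation(gs)
  dy <- (1 / nr) * 111320
  dx <- (1 / nr) * 111320 * cos(lat_centers(gs) * pi / 180)
  for (i in seq(3, nr - 2, by = 5)) for (j in seq(3, nc - 2, by = 5)) {
    gx <- (z[i, j + 1] - z[i, j - 1]) / (2 * dx[i])
    gy <- (z[i + 1, j] - z[i - 1, j]) / (2 * dy)
    oracle <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    expect_lt(abs(sl[i, j] - oracle), 1)
  }
})

test_that("slope propagates missing neighbours and requires elevation", {
  gs <- toy_stack(6, 6)
  z <- matrix(runif(36, 0, 10), 6, 6); z[3, 3] <- NA
  gs[["elevation"]] <- z
  sl <- slope_from_elevation(gs)
  expect_true(all(is.na(sl[2:4, 2:4])))
  expect_false(is.na(sl[6, 6]))
  expect_error(slope_from_elevation(toy_stack(3, 3)), "elevation")
})

test_that("cell areas satisfy the spherical closed form", {
  g <- study_area_grid(c(104, 110, 10, 16), 120)
  a <- cell_area_km2(g)
  R <- 6371.0088
  closed <- R^2 * (6 * pi / 180) * (sin(16 * pi / 180) - sin(10 * pi / 180))
  expect_equal(sum(a), closed, tolerance = 1e-12)
  # any latitude band: row sums equal the zone slice area
  lat_top <- 16 - (seq_len(g$nrow) - 1) * g$cellsize
  band <- R^2 * (6 * pi / 180) *
    (sin(lat_top * pi / 180) - sin((lat_top - g$cellsize) * pi / 180))
  expect_equal(rowSums(a), band, tolerance = 1e-12)
  # 30-arcsec cell on the equator
  ge <- study_area_grid(c(0, 1, -0.5, 0.5), 30)
  expect_equal(cell_area_km2(ge)[60, 1], 0.8587, tolerance = 1e-3)
  # area strictly decreases away from the equator along a column
  col <- cell_area_km2(g)[, 1]
  expect_true(all(diff(col) > 0))  # rows run 16N -> 10N, area grows toward equator
})

test_that("haversine distance has the right scale, symmetry and oracle", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371.0088 / 180, tolerance = 1e-4)
  set.seed(3)
  lon <- runif(20, -180, 180); lat <- runif(20, -80, 80)
  lon2 <- runif(20, -180, 180); lat2 <- runif(20, -80, 80)
  expect_equal(haversine_km(lon, lat, lon2, lat2),
               haversine_km(lon2, lat2, lon, lat))
  skip_if_not_installed("geosphere")
  oracle <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                     r = 6371.0088)
  expect_equal(haversine_km(lon, lat, lon2, lat2), oracle, tolerance = 1e-9)
})

test_that("basin labelling partitions the grid and finds bowls", {
  nr <- 10; nc <- 10
  gs <- toy_stack(nr, nc)
  xx <- colmat(nr, nc); yy <- rowmat(nr, nc)
  gs[["elevation"]] <- (xx - 5)^2 + (yy - 5)^2
  b <- label_basins(gs)
  expect_equal(sort(unique(as.vector(b))), 1L)
  # two bowls separated by a ridge, checked against an exhaustive descent oracle
  z <- pmin((xx - 3)^2 + (yy - 3)^2, (xx - 8)^2 + (yy - 8)^2)
  gs[["elevation"]] <- z
  b2 <- label_basins(gs)
  expect_equal(length(unique(as.vector(b2))), 2)
  descend <- function(i, j) {  # independent oracle: follow lowest neighbour
    repeat {
      best <- c(i, j); bz <- z[i, j]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && z[ii, jj] < bz) {
          bz <- z[ii, jj]; best <- c(ii, jj)
        }
      }
      if (all(best == c(i, j))) return(best)
      i <- best[1]; j <- best[2]
    }
  }
  for (i in c(1, 4, 7, 10)) for (j in c(2, 5, 9)) {
    sink_o <- descend(i, j)
    expect_equal(b2[i, j], b2[sink_o[1], sink_o[2]])
  }
  # partition: every non-missing cell labelled exactly once
  expect_true(all(!is.na(b2)))
  # invariance to adding a constant
  gs[["elevation"]] <- z + 1234.5
  expect_identical(label_basins(gs), b2)
})

test_that("point extraction uses nearest centre with a NW corner tie-break", {
  gs <- grid_stack(0, 1, 0.5, 2, 2,
                   layers = list(v = matrix(c(1, 3, 2, 4), 2, 2)))
  expect_equal(extract_at_points(gs, 0.25, 0.75, "v")$v, 1)  # exact centre
  expect_equal(extract_at_points(gs, 0.75, 0.25, "v")$v, 4)
  # corner point: deterministic tie-break to the cell centred north-west
  expect_equal(extract_at_points(gs, 0.5, 0.5, "v")$v, 1)
  # masked cell flags missing instead of returning a number
  gs[["v"]][1, 1] <- NA
  ex <- extract_at_points(gs, 0.25, 0.75, "v")
  expect_true(is.na(ex$v) && ex$missing)
  expect_error(extract_at_points(gs, 1.5, 0.5, "v"), "outside")
})

test_that("ascii grid round-trip preserves values, georeference and NA", {
  gs <- toy_stack(6, 7)
  set.seed(4)
  m <- matrix(round(runif(42, -5, 5), 4), 6, 7); m[2, 3] <- NA
  gs[["x"]] <- m
  gs[["y"]] <- m * 2
  dir <- withr::local_tempdir()
  write_grid(gs, dir)
  back <- read_grid(dir)
  expect_equal(back[["x"]], m, tolerance = 1e-9)
  expect_equal(back[["y"]], m * 2, tolerance = 1e-9)
  expect_equal(back$west, gs$west)
  expect_equal(back$cellsize, gs$cellsize)
})

test_that("geojson polygons rasterize by cell-centre with even-odd holes", {
  gs <- toy_stack(10, 10)
  square <- list(type = "Polygon", coordinates = list(
    list(list(0.2, 0.2), list(0.8, 0.2), list(0.8, 0.8), list(0.2, 0.8),
         list(0.2, 0.2)),
    # hole
    list(list(0.4, 0.4), list(0.6, 0.4), list(0.6, 0.6), list(0.4, 0.6),
         list(0.4, 0.4))))
  m <- rasterize_polygons(gs, square)
  lon <- nichesplit:::cell_lon_matrix(gs); lat <- nichesplit:::cell_lat_matrix(gs)
  inside <- lon > 0.2 & lon < 0.8 & lat > 0.2 & lat < 0.8 &
    !(lon > 0.4 & lon < 0.6 & lat > 0.4 & lat < 0.6)
  expect_equal(m, inside)
})
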