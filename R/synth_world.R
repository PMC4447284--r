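# Synthetic landscapes with known ground truth: correlated low-rank climate
# layers (Gaussian random fields), elevation, niche-driven presence sites,
# forest and protected-area masks.

#' Specification of a synthetic world
#'
#' Collects every tunable of the landscape generator. Defaults describe a
#' 1 degree x 1 degree tropical-highland study area at 30 arc-second
#' resolution with 19 correlated climate layers of latent rank 3, two
#' region clusters (a smaller "north" with 11 presence sites and a larger
#' "south" with 20), half forest cover and a handful of protected discs.
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param resolution arc-seconds per cell.
#' @param n_layers number of climate layers (named `bio1..bioN`).
#' @param latent_rank number of independent spatial factors mixed into the
#'   layers.
#' @param noise_sd SD of the independent per-layer noise.
#' @param length_scale Gaussian-kernel smoothing length in cells.
#' @param niches named list of per-cluster niche definitions; each a list
#'   with `axes` (predictor layer names), `optimum_q` (quantiles of each
#'   axis at which the optimum sits), `breadth_sd` (niche breadth as a
#'   multiple of each axis' SD), `height` (logistic steepness: the linear
#'   predictor at the optimum), `n_presence`, and `lineages` (labels cycled
#'   over that cluster's sites).
#' @param true_threshold suitability defining the true binary range.
#' @param min_presence_km minimum great-circle separation between presence
#'   cells within a cluster, so that presences are distinct sites (the
#'   1 km site-deduplication downstream leaves them untouched).
#' @param forest_fraction fraction of cells covered by forest (0-1).
#' @param n_protected_discs number of protected-area discs.
#' @param protected_radius_km disc radius in km.
#' @param seed integer RNG seed; every generated object is a pure function
#'   of the spec (including this seed).
#' @return A list of class `world_spec`.
#' @export
world_spec <- function(bbox = c(107, 108, 11.5, 12.5), resolution = 30,
                       n_layers = 19, latent_rank = 3, noise_sd = 1e-3,
                       length_scale = 15,
                       niches = list(
                         north = list(axes = "PC1", optimum_q = 1.0,
                                      breadth_sd = 0.7, height = 10,
                                      n_presence = 11,
                                      lineages = c("1", "2", "3")),
                         south = list(axes = "PC1", optimum_q = 0.0,
                                      breadth_sd = 1.0, height = 10,
                                      n_presence = 20,
                                      lineages = c("4", "5", "6", "7", "8", "9"))),
                       true_threshold = 0.5, min_presence_km = 1.5,
                       forest_fraction = 0.5, n_protected_discs = 8,
                       protected_radius_km = 10, seed = 20150601) {
  if (!(bbox[2] > bbox[1] && bbox[4] > bbox[3]))
    stop_("degenerate bbox")
  if (latent_rank > n_layers) stop_("latent_rank must be <= n_layers")
  if (forest_fraction < 0 || forest_fraction > 1)
    stop_("forest_fraction must be in [0, 1]")
  cs <- resolution / 3600
  if (abs((bbox[2] - bbox[1]) / cs - round((bbox[2] - bbox[1]) / cs)) > 1e-8 ||
      abs((bbox[4] - bbox[3]) / cs - round((bbox[4] - bbox[3]) / cs)) > 1e-8)
    stop_("bbox does not divide evenly at %s arc-seconds", resolution)
  structure(list(bbox = bbox, resolution = resolution, n_layers = n_layers,
                 latent_rank = latent_rank, noise_sd = noise_sd,
                 length_scale = length_scale, niches = niches,
                 true_threshold = true_threshold,
                 min_presence_km = min_presence_km,
                 forest_fraction = forest_fraction,
                 n_protected_discs = n_protected_discs,
                 protected_radius_km = protected_radius_km, seed = seed),
            class = "world_spec")
}

# Smoothed standardized Gaussian random field (spectrally simple
# convolution smoothing of white noise, separable Gaussian kernel).
gaussian_field <- function(nr, nc, length_scale) {
  W <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (length_scale <= 0) return((W - mean(W)) / stats::sd(W))
  kmat <- function(n) {
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * length_scale^2))
    K / rowSums(K)
  }
  f <- kmat(nr) %*% W %*% t(kmat(nc))
  (f - mean(f)) / stats::sd(f)
}

#' Generate correlated climate layers and elevation
#'
#' Draws `latent_rank` independent smooth Gaussian random fields, mixes
#' them linearly into `n_layers` climate layers (`bio1..bioN`, plus small
#' independent noise of SD `noise_sd`), and adds a smooth `elevation` layer
#' in metres. Deterministic for a given spec (same seed twice gives
#' bit-identical stacks).
#'
#' @param spec a [world_spec()].
#' @return A `grid_stack` with layers `bio1..bioN` and `elevation`.
#' @export
make_climate_stack <- function(spec) {
  gs <- study_area_grid(spec$bbox, spec$resolution)
  nr <- gs$nrow; nc <- gs$ncol
  with_seed(derive_seed(spec$seed, 101), {
    Z <- lapply(seq_len(spec$latent_rank), function(i)
      gaussian_field(nr, nc, spec$length_scale))
    A <- matrix(stats::rnorm(spec$n_layers * spec$latent_rank),
                spec$n_layers, spec$latent_rank)
    for (l in seq_len(spec$n_layers)) {
      lay <- matrix(0, nr, nc)
      for (k in seq_len(spec$latent_rank)) lay <- lay + A[l, k] * Z[[k]]
      lay <- lay + spec$noise_sd * matrix(stats::rnorm(nr * nc), nr, nc)
      gs[[paste0("bio", l)]] <- lay
    }
    gs[["elevation"]] <- 800 + 400 * gaussian_field(nr, nc, spec$length_scale)
  })
  gs
}

#' True niches and presence sites
#'
#' Defines, per cluster, a true suitability surface as the logistic of a
#' quadratic form in the named predictor axes:
#' `S = plogis(height * (1 - sum_i ((x_i - opt_i) / breadth_i)^2))`,
#' so S equals `plogis(height)` at the optimum and 0.5 on the niche-ellipse
#' boundary. Presence cells are drawn without replacement with probability
#' proportional to suitability; site coordinates are the cell centres. The
#' true binary range is the union of per-cluster surfaces at the spec's
#' `true_threshold`.
#'
#' @param predictor_stack a `grid_stack` holding the axes named in the
#'   niche definitions (e.g. PCs from [project_pca()]).
#' @param spec a [world_spec()].
#' @return A list: `suitability` (named list of matrices), `sites` (data
#'   frame `site, lon, lat, lineage, cluster, cell`), `true_range` (logical
#'   matrix), `truth` (realized niche parameters per cluster).
#' @export
make_niche_and_presences <- function(predictor_stack, spec) {
  gs <- predictor_stack
  lon <- cell_lon_matrix(gs); lat <- cell_lat_matrix(gs)
  suit <- list(); truth <- list(); sites <- NULL
  for (g in seq_along(spec$niches)) {
    nm <- names(spec$niches)[g]
    ni <- spec$niches[[g]]
    vals <- lapply(ni$axes, function(ax) {
      lay <- gs$layers[[ax]]
      if (is.null(lay)) stop_("niche axis '%s' not present in stack", ax)
      lay
    })
    opt <- mapply(function(v, q) stats::quantile(v, q, na.rm = TRUE),
                  vals, ni$optimum_q)
    brd <- mapply(function(v, b) b * stats::sd(v, na.rm = TRUE),
                  vals, ni$breadth_sd)
    qf <- 0
    for (i in seq_along(vals)) qf <- qf + ((vals[[i]] - opt[i]) / brd[i])^2
    S <- stats::plogis(ni$height * (1 - qf))
    # sampling weights on the log scale: proportional to S but stable when
    # breadth -> 0 underflows S itself (point-mass niches)
    logS <- stats::plogis(ni$height * (1 - qf), log.p = TRUE)
    Wt <- exp(logS - max(logS, na.rm = TRUE))
    suit[[nm]] <- S
    truth[[nm]] <- list(axes = ni$axes, optimum = unname(opt),
                        breadth = unname(brd), height = ni$height)
    pos <- which(!is.na(Wt) & Wt > 0)
    if (ni$n_presence > length(pos))
      stop_("cluster '%s': %d presences requested but only %d cells with "
            %+% "positive suitability", nm, ni$n_presence, length(pos))
    min_km <- spec$min_presence_km %||% 0
    cells <- with_seed(derive_seed(spec$seed, 102, g), {
      # sequential draw without replacement, cell probability proportional
      # to suitability, excluding cells closer than min_presence_km to an
      # already drawn presence (presences are distinct sites)
      avail <- pos
      picked <- integer(0)
      for (d in seq_len(ni$n_presence)) {
        if (!length(avail))
          stop_("cluster '%s': ran out of cells %g km apart after %d presences",
                nm, min_km, length(picked))
        c1 <- avail[sample.int(length(avail), 1, prob = Wt[avail])]
        picked <- c(picked, c1)
        if (min_km > 0)
          avail <- avail[haversine_km(lon[avail], lat[avail],
                                      lon[c1], lat[c1]) > min_km]
        else avail <- setdiff(avail, c1)
      }
      picked
    })
    lineages <- rep_len(ni$lineages %||% nm, ni$n_presence)
    sites <- rbind(sites, data.frame(
      lon = lon[cells], lat = lat[cells],
      lineage = lineages, cluster = nm, cell = cells))
  }
  sites <- cbind(site = seq_len(nrow(sites)), sites)
  true_range <- Reduce(`|`, lapply(suit, function(S)
    !is.na(S) & S >= spec$true_threshold))
  list(suitability = suit, sites = sites, true_range = true_range,
       truth = truth)
}

`%+%` <- function(a, b) paste0(a, b)

#' Forest and protected-area masks
#'
#' Forest is a smooth random field thresholded at the quantile that covers
#' `forest_fraction` of the cells; the protected mask is the union of
#' `n_protected_discs` great-circle discs of radius `protected_radius_km`
#' centred at uniform random cells.
#'
#' @param gs a `grid_stack` (defines the grid).
#' @param spec a [world_spec()].
#' @return A list with logical matrices `forest` and `protected`.
#' @export
make_masks <- function(gs, spec) {
  nr <- gs$nrow; nc <- gs$ncol
  lon <- cell_lon_matrix(gs); lat <- cell_lat_matrix(gs)
  with_seed(derive_seed(spec$seed, 103), {
    f <- gaussian_field(nr, nc, spec$length_scale)
    forest <- if (spec$forest_fraction >= 1) matrix(TRUE, nr, nc)
              else if (spec$forest_fraction <= 0) matrix(FALSE, nr, nc)
              else f >= stats::quantile(f, 1 - spec$forest_fraction)
    protected <- matrix(FALSE, nr, nc)
    if (spec$n_protected_discs > 0) {
      centers <- sample.int(nr * nc, spec$n_protected_discs)
      for (ct in centers)
        protected <- protected |
          (haversine_km(lon, lat, lon[ct], lat[ct]) <= spec$protected_radius_km)
    }
    list(forest = forest, protected = protected)
  })
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running the whole generation chain: climate stack,
#' terrain slope, climate PCA (8 components), predictor stack, true niches
#' and presence sites, forest/protected masks, watershed basins and cell
#' areas. Everything is a pure function of the spec.
#'
#' @param spec a [world_spec()].
#' @param k_pca number of climate principal components.
#' @return A list of class `synthetic_world` with elements `spec`,
#'   `climate` (stack), `pca`, `predictors` (stack of PCs + slope),
#'   `suitability`, `sites`, `true_range`, `truth`, `forest`, `protected`,
#'   `basins`, `area_km2`.
#' @export
simulate_world <- function(spec = world_spec(), k_pca = 8) {
  climate <- make_climate_stack(spec)
  climate[["slope"]] <- slope_from_elevation(climate)
  pca <- fit_pca(climate, k = min(k_pca, spec$n_layers))
  predictors <- project_pca(climate, pca, passthrough = "slope")
  np <- make_niche_and_presences(predictors, spec)
  masks <- make_masks(climate, spec)
  basins <- label_basins(climate)
  structure(list(spec = spec, climate = climate, pca = pca,
                 predictors = predictors, suitability = np$suitability,
                 sites = np$sites, true_range = np$true_range,
                 truth = np$truth, forest = masks$forest,
                 protected = masks$protected, basins = basins,
                 area_km2 = cell_area_km2(climate)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d climate layers (rank %d)\n",
              x$climate$nrow, x$climate$ncol, x$spec$n_layers,
              x$spec$latent_rank))
  cat(sprintf("  clusters: %s; %d sites; true range %d cells\n",
              paste(names(x$spec$niches), collapse = ", "), nrow(x$sites),
              sum(x$true_range)))
  invisible(x)
}

#' Write the synthetic world's pipeline inputs to disk
#'
#' Emits the plain-text artefacts a real analysis would start from: one
#' `.asc` raster per climate/terrain layer plus masks and basin labels, and
#' a `sites.csv` occurrence table (`lon,lat,lineage,cluster`).
#'
#' @param world a `synthetic_world`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gs <- world$climate
  gs[["forest"]] <- world$forest * 1
  gs[["protected"]] <- world$protected * 1
  gs[["basins"]] <- world$basins * 1
  write_grid(gs, file.path(dir, "stack"))
  utils::write.csv(world$sites[, c("lon", "lat", "lineage", "cluster")],
                   file.path(dir, "sites.csv"), row.names = FALSE)
  invisible(dir)
}
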