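# The full niche-modelling protocol: site deduplication, per-region model
# fitting, replicated leave-out-one-third ROC evaluation, max(sens+spec)
# thresholding, merging of regional ranges and overlay area accounting.

#' Deduplicate occurrence points into sites
#'
#' Single-linkage agglomeration of occurrence points at a distance radius
#' (default 1 km): any chain of points with successive great-circle
#' distances at or below the radius collapses into one site whose
#' coordinates are the centroid of its members. Lineage and region-cluster
#' labels are carried over from the first member of each site (a warning is
#' given if members disagree).
#'
#' @param points data frame with columns `lon`, `lat` and optionally
#'   `lineage` and `cluster`.
#' @param radius_km linkage radius in km.
#' @return A data frame with columns `site`, `lon`, `lat`, `n_points`, plus
#'   `lineage`/`cluster` when present in the input.
#' @export
cluster_sites <- function(points, radius_km = 1.0) {
  if (!NROW(points)) stop_("no occurrence points supplied")
  n <- nrow(points)
  memb <- if (n == 1) 1L else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d[i, j] <- d[j, i] <- haversine_km(points$lon[i], points$lat[i],
                                         points$lon[j], points$lat[j])
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    stats::cutree(hc, h = radius_km)
  }
  out <- do.call(rbind, lapply(sort(unique(memb)), function(k) {
    idx <- which(memb == k)
    row <- data.frame(site = k, lon = mean(points$lon[idx]),
                      lat = mean(points$lat[idx]), n_points = length(idx))
    for (col in intersect(c("lineage", "cluster"), names(points))) {
      vals <- unique(points[[col]][idx])
      if (length(vals) > 1)
        warning(sprintf("site %d mixes %s labels: %s", k, col,
                        paste(vals, collapse = ", ")), call. = FALSE)
      row[[col]] <- points[[col]][idx[1]]
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Sample background cells away from presence sites
#'
#' Draws `n` cells uniformly without replacement from the non-missing grid
#' cells whose centres lie at least `min_km` from every presence site.
#'
#' @param gs a `grid_stack`.
#' @param sites data frame with `lon`/`lat` of presence sites.
#' @param n number of background cells (default 1000).
#' @param min_km exclusion radius around sites, km (default 5).
#' @param seed optional RNG seed for a reproducible draw.
#' @param layers layers defining the missing mask (default: all layers).
#' @param eligible optional precomputed vector of eligible cell indices
#'   (as returned in the `eligible` attribute), to avoid recomputing
#'   distances across repeated draws with the same sites.
#' @return A data frame `cell`, `lon`, `lat`; the eligible index vector is
#'   attached as attribute `eligible`.
#' @export
sample_background <- function(gs, sites, n = 1000, min_km = 5.0, seed = NULL,
                              layers = NULL, eligible = NULL) {
  if (is.null(eligible)) {
    ok <- !missing_mask(gs, layers = layers)
    lon <- cell_lon_matrix(gs); lat <- cell_lat_matrix(gs)
    far <- matrix(TRUE, gs$nrow, gs$ncol)
    for (i in seq_len(nrow(sites)))
      far <- far & (haversine_km(lon, lat, sites$lon[i], sites$lat[i]) >= min_km)
    eligible <- which(ok & far)
  }
  if (length(eligible) < n)
    stop_("only %d eligible background cells (need %d)", length(eligible), n)
  cells <- with_seed(seed, sample(eligible, n, replace = FALSE))
  lon <- cell_lon_matrix(gs); lat <- cell_lat_matrix(gs)
  structure(data.frame(cell = cells, lon = lon[cells], lat = lat[cells]),
            eligible = eligible)
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' `(concordant pairs + 0.5 * ties) / (n_presence * n_background)`:
#' the probability that a random presence outscores a random background
#' point.
#'
#' @param presence,background numeric score vectors (both non-empty).
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(presence, background) {
  np <- length(presence); nb <- length(background)
  if (!np || !nb) stop_("both score sets must be non-empty")
  r <- rank(c(presence, background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans the unique observed scores as candidate thresholds, predicting
#' suitable when `score >= t`, and returns the candidate maximizing
#' sensitivity (true positive rate) plus specificity (true negative rate).
#' Ties are broken toward the smallest threshold, i.e. the most inclusive
#' predicted range.
#'
#' @param presence,background numeric score vectors.
#' @return The selected threshold.
#' @export
select_threshold <- function(presence, background) {
  if (!length(presence) || !length(background))
    stop_("both score sets must be non-empty")
  cand <- sort(unique(c(presence, background)))
  ss <- vapply(cand, function(t)
    mean(presence >= t) + mean(background < t), 0)
  cand[which.max(ss)]  # which.max takes the first (smallest) maximizer
}

# Predictor matrix at site locations (errors if any site hits missing cells).
site_predictors <- function(gs, sites, predictors) {
  ex <- extract_at_points(gs, sites$lon, sites$lat, layers = predictors)
  if (any(ex$missing))
    stop_("%d site(s) fall on missing predictor cells", sum(ex$missing))
  as.matrix(ex[, predictors, drop = FALSE])
}

# Predictor matrix at background cells.
bg_predictors <- function(gs, bg, predictors) {
  X <- sapply(predictors, function(nm) gs$layers[[nm]][bg$cell])
  matrix(X, nrow = nrow(bg), dimnames = list(NULL, predictors))
}

#' Replicated leave-out-one-third evaluation of a regional niche model
#'
#' For each replicate a random third of the sites (test size
#' `max(1, round(n/3))`) is held out, the model is refitted on the
#' remaining sites against a fixed training background, and scored on the
#' held-out sites against a fresh background draw of `n_background` cells.
#' The per-replicate AUC and max(sens+spec) threshold are recorded and
#' their medians reported.
#'
#' @param sites data frame of sites (`lon`, `lat`), at least 3 rows.
#' @param gs predictor `grid_stack` (PC layers + slope).
#' @param predictors predictor layer names; default all layers of `gs`.
#' @param reps number of replicates (default 50).
#' @param holdout fraction of sites held out per replicate (default 1/3).
#' @param n_background background cells per draw (default 1000).
#' @param min_km background exclusion radius, km.
#' @param lambda regularization multiplier for [maxent()].
#' @param seed seed controlling splits and background draws.
#' @param keep_surfaces also predict every replicate model across the full
#'   grid and return the cellwise median surface (used by [enm()]).
#' @return An object of class `enm_eval`: per-replicate `auc` and
#'   `threshold` vectors, their medians, the configuration, and (with
#'   `keep_surfaces`) `median_surface`.
#' @export
evaluate_enm <- function(sites, gs, predictors = NULL, reps = 50,
                         holdout = 1 / 3, n_background = 1000, min_km = 5,
                         lambda = 1, seed = NULL, keep_surfaces = FALSE) {
  n <- nrow(sites)
  if (n < 3) stop_("need at least 3 sites to evaluate (got %d)", n)
  predictors <- predictors %||% names(gs$layers)
  seed <- seed %||% with_seed(NULL, sample.int(2^31 - 2, 1))
  train_bg <- sample_background(gs, sites, n = n_background, min_km = min_km,
                                seed = derive_seed(seed, 1), layers = predictors)
  eligible <- attr(train_bg, "eligible")
  Xb_train <- bg_predictors(gs, train_bg, predictors)
  Xs <- site_predictors(gs, sites, predictors)
  n_test <- max(1L, round(n * holdout))
  auc <- thr <- numeric(reps)
  surfs <- if (keep_surfaces) array(NA_real_, c(gs$nrow, gs$ncol, reps))
  for (r in seq_len(reps)) {
    test_idx <- with_seed(derive_seed(seed, 2, r),
                          sample.int(n, n_test, replace = FALSE))
    train_idx <- setdiff(seq_len(n), test_idx)
    # presence samples join the fitting background (standard maxent
    # behaviour; keeps the presence feature mean inside the background
    # feature hull so the penalized likelihood stays bounded)
    fit <- maxent(Xs[train_idx, , drop = FALSE],
                  rbind(Xb_train, Xs[train_idx, , drop = FALSE]),
                  lambda = lambda)
    fresh <- sample_background(gs, sites, n = n_background, min_km = min_km,
                               seed = derive_seed(seed, 3, r),
                               layers = predictors, eligible = eligible)
    sc_p <- predict(fit, Xs[test_idx, , drop = FALSE])
    sc_b <- predict(fit, bg_predictors(gs, fresh, predictors))
    auc[r] <- roc_auc(sc_p, sc_b)
    thr[r] <- select_threshold(sc_p, sc_b)
    if (keep_surfaces) surfs[, , r] <- predict(fit, gs)
  }
  structure(list(auc = auc, threshold = thr,
                 median_auc = stats::median(auc),
                 median_threshold = stats::median(thr),
                 median_surface = if (keep_surfaces)
                   apply(surfs, c(1, 2), stats::median),
                 reps = reps, holdout = holdout, n_sites = n,
                 n_train = n - n_test, n_test = n_test, seed = seed),
            class = "enm_eval")
}

#' @export
print.enm_eval <- function(x, ...) {
  cat(sprintf("<enm_eval> %d replicates, %d sites (train %d / test %d)\n",
              x$reps, x$n_sites, x$n_train, x$n_test))
  cat(sprintf("  median AUC %.3f (range %.3f-%.3f); median threshold %.3f\n",
              x$median_auc, min(x$auc), max(x$auc), x$median_threshold))
  invisible(x)
}

#' Fit, evaluate and merge regional niche models
#'
#' The central fitting function of the package. Sites are split by their
#' region-cluster label; for each region the model is evaluated by
#' replicated leave-out-one-third splits ([evaluate_enm()]) and the
#' region's continuous suitability surface is, by default, the cellwise
#' median of the replicate surfaces ("median results"), thresholded at the
#' region's median max(sens+spec) threshold - replicate surfaces and
#' replicate thresholds share one output scale. `surface = "refit"`
#' instead predicts from a single model refitted on all of the region's
#' sites (also always returned in `models`). The merged continuous surface
#' is the cellwise maximum of the regional surfaces and the merged binary
#' range is the union of the regional binary ranges.
#'
#' @param sites site data frame (`lon`, `lat`, and `cluster` unless
#'   `cluster_col` is `NULL` or absent, in which case a single region is
#'   fitted).
#' @param gs predictor `grid_stack`.
#' @param predictors predictor layer names; default all layers of `gs`.
#' @param cluster_col name of the region-cluster column.
#' @param reps,holdout,n_background,min_km,lambda see [evaluate_enm()].
#' @param surface how the final per-region surface is produced (see
#'   Description).
#' @param seed master seed (per-region streams are derived from it).
#' @return An object of class `enm`: per-region `models` (full-data
#'   refits), `eval`, `suitability` (matrices), `threshold`, `binary`;
#'   plus `merged` (suitability matrix) and `merged_binary`.
#' @export
enm <- function(sites, gs, predictors = NULL, cluster_col = "cluster",
                reps = 50, holdout = 1 / 3, n_background = 1000, min_km = 5,
                lambda = 1, surface = c("replicate_median", "refit"),
                seed = NULL) {
  cl <- match.call()
  surface <- match.arg(surface)
  predictors <- predictors %||% names(gs$layers)
  seed <- seed %||% with_seed(NULL, sample.int(2^31 - 2, 1))
  regions <- if (!is.null(cluster_col) && cluster_col %in% names(sites))
    split(sites, sites[[cluster_col]]) else list(all = sites)
  small <- names(regions)[vapply(regions, nrow, 0L) < 3]
  if (length(small))
    stop_("region(s) below the 3-site minimum: %s", paste(small, collapse = ", "))
  models <- eval <- suit <- bin <- list()
  thr <- numeric(0)
  for (g in seq_along(regions)) {
    nm <- names(regions)[g]
    reg_sites <- regions[[g]]
    reg_seed <- derive_seed(seed, 10 + g)
    ev <- evaluate_enm(reg_sites, gs, predictors, reps = reps,
                       holdout = holdout, n_background = n_background,
                       min_km = min_km, lambda = lambda, seed = reg_seed,
                       keep_surfaces = surface == "replicate_median")
    bg <- sample_background(gs, reg_sites, n = n_background, min_km = min_km,
                            seed = derive_seed(reg_seed, 4), layers = predictors)
    Xs_reg <- site_predictors(gs, reg_sites, predictors)
    fit <- maxent(Xs_reg, rbind(bg_predictors(gs, bg, predictors), Xs_reg),
                  lambda = lambda)
    S <- if (surface == "replicate_median") ev$median_surface
         else predict(fit, gs)
    models[[nm]] <- fit
    eval[[nm]] <- ev
    suit[[nm]] <- S
    thr[nm] <- ev$median_threshold
    bin[[nm]] <- !is.na(S) & S >= thr[nm]
  }
  merged <- Reduce(pmax, suit)
  merged_bin <- Reduce(`|`, bin)
  structure(list(models = models, eval = eval, suitability = suit,
                 threshold = thr, binary = bin, merged = merged,
                 merged_binary = merged_bin, regions = names(regions),
                 predictors = predictors, seed = seed, call = cl),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("<enm> %d region(s): %s\n", length(x$regions),
              paste(x$regions, collapse = ", ")))
  for (nm in x$regions)
    cat(sprintf("  %s: %d sites, median AUC %.3f, threshold %.3f\n", nm,
                x$eval[[nm]]$n_sites, x$eval[[nm]]$median_auc, x$threshold[nm]))
  cat(sprintf("  merged binary range: %d cells\n", sum(x$merged_binary)))
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$regions, function(nm) {
    ev <- object$eval[[nm]]
    data.frame(region = nm, n_sites = ev$n_sites, reps = ev$reps,
               median_auc = ev$median_auc, median_threshold = ev$median_threshold,
               range_cells = sum(object$binary[[nm]]))
  }))
  structure(list(table = tab, merged_cells = sum(object$merged_binary)),
            class = "summary.enm")
}

#' @export
print.summary.enm <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("merged binary range: %d cells\n", x$merged_cells))
  invisible(x)
}

#' @export
plot.enm <- function(x, which = c("merged", "binary"), ...) {
  which <- match.arg(which)
  m <- if (which == "merged") x$merged else x$merged_binary * 1
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("%s suitability", which), ...)
  invisible(x)
}

#' Jaccard index of two binary masks
#'
#' @param a,b logical matrices/vectors of equal length.
#' @return `|a & b| / |a | b|` (1 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  u <- sum(a | b, na.rm = TRUE)
  if (u == 0) return(1)
  sum(a & b, na.rm = TRUE) / u
}

#' Account a predicted range against forest, protection and basin overlays
#'
#' Sums spherical cell areas over the predicted range and its intersections
#' with a forest mask and a protected-area mask, overall and per watershed
#' basin. Percentages follow the conventional denominators: forest and
#' protected percentages are relative to the suitable area, and the
#' forested-protected percentage is relative to the suitable forested area.
#' Basins whose suitable area exceeds `basin_cutoff_km2` are flagged.
#'
#' @param range logical matrix of the (merged) binary range.
#' @param forest,protected logical overlay masks on the same grid.
#' @param basins integer basin-label matrix (as from [label_basins()]).
#' @param area cell-area matrix in km^2 (as from [cell_area_km2()]).
#' @param basin_cutoff_km2 flagging cutoff for per-basin suitable area.
#' @return An object of class `range_account`: `areas_km2` (suitable,
#'   suitable_forest, suitable_protected, suitable_forest_protected),
#'   `percent` (forest_of_suitable, protected_of_suitable,
#'   protected_of_forested), and `basins` (per-basin table sorted by
#'   suitable area, with `over_cutoff` flags).
#' @export
range_account <- function(range, forest, protected, basins, area,
                          basin_cutoff_km2 = 100) {
  dims <- dim(range)
  for (lay in list(forest, protected, basins, area))
    if (!identical(dim(lay), dims))
      stop_("overlay layers are not co-registered with the range")
  range <- !is.na(range) & range
  forest <- !is.na(forest) & forest
  protected <- !is.na(protected) & protected
  a <- function(mask) sum(area[mask])
  suit <- a(range)
  sf <- a(range & forest)
  sp <- a(range & protected)
  sfp <- a(range & forest & protected)
  pct <- function(num, den) if (den > 0) 100 * num / den else {
    warning("empty denominator; percentage reported as 0", call. = FALSE); 0
  }
  percent <- c(forest_of_suitable = pct(sf, suit),
               protected_of_suitable = pct(sp, suit),
               protected_of_forested = pct(sfp, sf))
  labs <- sort(unique(basins[!is.na(basins) & range]))
  btab <- do.call(rbind, lapply(labs, function(b) {
    inb <- !is.na(basins) & basins == b
    data.frame(basin = b,
               suitable_km2 = a(range & inb),
               suitable_forest_km2 = a(range & forest & inb),
               suitable_protected_km2 = a(range & protected & inb),
               suitable_forest_protected_km2 = a(range & forest & protected & inb))
  }))
  if (is.null(btab))
    btab <- data.frame(basin = integer(0), suitable_km2 = numeric(0),
                       suitable_forest_km2 = numeric(0),
                       suitable_protected_km2 = numeric(0),
                       suitable_forest_protected_km2 = numeric(0))
  btab <- btab[order(-btab$suitable_km2), , drop = FALSE]
  rownames(btab) <- NULL
  btab$over_cutoff <- btab$suitable_km2 > basin_cutoff_km2
  structure(list(areas_km2 = c(suitable = suit, suitable_forest = sf,
                               suitable_protected = sp,
                               suitable_forest_protected = sfp),
                 percent = percent, basins = btab,
                 basin_cutoff_km2 = basin_cutoff_km2),
            class = "range_account")
}

#' @export
print.range_account <- function(x, ...) {
  a <- x$areas_km2; p <- x$percent
  cat(sprintf("<range_account> suitable area: %.0f km2\n", a["suitable"]))
  cat(sprintf("  forested: %.0f km2 (%.1f%% of suitable)\n",
              a["suitable_forest"], p["forest_of_suitable"]))
  cat(sprintf("  protected: %.0f km2 (%.1f%% of suitable; %.1f%% of forested)\n",
              a["suitable_protected"], p["protected_of_suitable"],
              p["protected_of_forested"]))
  nover <- sum(x$basins$over_cutoff)
  cat(sprintf("  %d basin(s) intersect the range; %d exceed %g km2\n",
              nrow(x$basins), nover, x$basin_cutoff_km2))
  invisible(x)
}

#' Climate conditions at occurrence sites
#'
#' Extracts elevation, temperature seasonality, annual precipitation and
#' precipitation seasonality (bio4 / bio12 / bio15 naming convention) at
#' each site for lineage-wise summaries.
#'
#' @param sites site data frame (`lon`, `lat`, optional `lineage`).
#' @param gs `grid_stack` holding the climate layers.
#' @param layers named character vector mapping output names to layer names.
#' @return A data frame of per-site values (plus `lineage` when present).
#' @export
site_climate_summary <- function(sites, gs,
    layers = c(elevation = "elevation", temp_seasonality = "bio4",
               annual_precip = "bio12", precip_seasonality = "bio15")) {
  miss <- setdiff(unname(layers), names(gs$layers))
  if (length(miss)) stop_("missing layer(s): %s", paste(miss, collapse = ", "))
  ex <- extract_at_points(gs, sites$lon, sites$lat, layers = unname(layers))
  out <- ex[, c("lon", "lat", unname(layers))]
  names(out) <- c("lon", "lat", names(layers))
  if ("lineage" %in% names(sites)) out$lineage <- sites$lineage
  out
}
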