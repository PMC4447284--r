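# End-to-end orchestration: one config, one master seed, one report.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default: 1,000 background
#' points at least 5 km from sites, 50 leave-out-one-third replicates,
#' lambda = 1, 8 climate principal components, a 3% p-distance cutoff, a
#' 100 km2 basin cutoff and alpha = 0.05. Round-trips losslessly through
#' JSON via [config_to_json()] / [config_from_json()].
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param world a [world_spec()] driving synthetic input generation (set
#'   `stack_dir`/`sites_csv` instead to run from files on disk).
#' @param stack_dir,sites_csv optional paths to a directory of `.asc`
#'   layers and an occurrence CSV (`lon,lat,lineage,cluster`).
#' @param n_background,min_km,reps,holdout,lambda,k_pca,site_radius_km
#'   niche-modelling tunables (see [enm()], [cluster_sites()]).
#' @param p_cutoff p-distance clustering cutoff (proportion).
#' @param basin_cutoff_km2 basin flagging cutoff.
#' @param alpha significance level for the morphometric tests.
#' @param tree a [lineage_tree_spec()] for sequence simulation.
#' @param traits a [trait_spec()] for trait simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, world = world_spec(), stack_dir = NULL,
                       sites_csv = NULL, n_background = 1000, min_km = 5,
                       reps = 50, holdout = 1 / 3, lambda = 1, k_pca = 8,
                       site_radius_km = 1, p_cutoff = 0.03,
                       basin_cutoff_km2 = 100, alpha = 0.05,
                       tree = lineage_tree_spec(), traits = trait_spec()) {
  structure(list(seed = seed, world = world, stack_dir = stack_dir,
                 sites_csv = sites_csv, n_background = n_background,
                 min_km = min_km, reps = reps, holdout = holdout,
                 lambda = lambda, k_pca = k_pca,
                 site_radius_km = site_radius_km, p_cutoff = p_cutoff,
                 basin_cutoff_km2 = basin_cutoff_km2, alpha = alpha,
                 tree = tree, traits = traits),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
config_to_json <- function(config, path) {
  obj <- unclass(config)
  obj$world <- unclass(obj$world)
  obj$tree <- unclass(obj$tree)[c("newick", "seq_length", "n_per_lineage",
                                  "within_branch")]
  obj$traits <- unclass(obj$traits)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
config_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  world <- do.call(world_spec, o$world[setdiff(names(o$world), character(0))])
  tree <- lineage_tree_spec(newick = o$tree$newick,
                            seq_length = o$tree$seq_length,
                            n_per_lineage = o$tree$n_per_lineage,
                            within_branch = o$tree$within_branch)
  traits <- trait_spec(lineages = o$traits$lineages,
                       svl_mean = o$traits$svl_mean,
                       svl_sd = o$traits$svl_sd,
                       allometry = as.data.frame(o$traits$allometry),
                       offsets = if (!is.null(o$traits$offsets))
                         as.data.frame(o$traits$offsets) else NULL)
  run_config(seed = o$seed, world = world, stack_dir = o$stack_dir,
             sites_csv = o$sites_csv, n_background = o$n_background,
             min_km = o$min_km, reps = o$reps, holdout = o$holdout,
             lambda = o$lambda, k_pca = o$k_pca,
             site_radius_km = o$site_radius_km, p_cutoff = o$p_cutoff,
             basin_cutoff_km2 = o$basin_cutoff_km2, alpha = o$alpha,
             tree = tree, traits = traits)
}

#' Run the full pipeline from a configuration
#'
#' Executes, in order: input generation (or loading), terrain slope,
#' climate PCA and projection, per-region niche modelling with replicated
#' evaluation and threshold merge, range/overlay accounting, sequence
#' simulation with p-distance screening, and trait simulation with the
#' diagnosability matrix. Identical config + seed produces an identical
#' report; when `out_dir` is given, artefacts are written there and their
#' md5 checksums recorded in the report.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for artefacts.
#' @return A list of class `run_report` with per-stage results and a
#'   `summary` of headline numbers.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  for (p in c(config$stack_dir, config$sites_csv))
    if (!is.null(p) && !file.exists(p)) stop_("input path does not exist: %s", p)
  seed <- config$seed
  if (!is.null(config$stack_dir)) {
    climate <- read_grid(config$stack_dir)
    sites_raw <- utils::read.csv(config$sites_csv, stringsAsFactors = FALSE)
    if (!all(c("lon", "lat") %in% names(sites_raw)))
      stop_("sites CSV must contain lon and lat columns")
    climate[["slope"]] <- slope_from_elevation(climate)
    pca <- fit_pca(climate, k = config$k_pca)
    predictors <- project_pca(climate, pca, passthrough = "slope")
    world <- list(climate = climate, pca = pca, predictors = predictors,
                  basins = label_basins(climate),
                  area_km2 = cell_area_km2(climate),
                  forest = climate[["forest"]] > 0,
                  protected = climate[["protected"]] > 0)
    sites <- cluster_sites(sites_raw, radius_km = config$site_radius_km)
    true_range <- NULL
  } else {
    ws <- config$world
    ws$seed <- derive_seed(seed, 1)
    world <- simulate_world(ws, k_pca = config$k_pca)
    sites <- cluster_sites(world$sites, radius_km = config$site_radius_km)
    true_range <- world$true_range
  }
  fit <- enm(sites, world$predictors, cluster_col = "cluster",
             reps = config$reps, holdout = config$holdout,
             n_background = config$n_background, min_km = config$min_km,
             lambda = config$lambda, seed = derive_seed(seed, 2))
  account <- range_account(fit$merged_binary, world$forest, world$protected,
                           world$basins, world$area_km2,
                           basin_cutoff_km2 = config$basin_cutoff_km2)
  seqs <- simulate_sequences(config$tree, seed = derive_seed(seed, 3))
  pd <- p_distance_matrix(seqs)
  divergence <- group_divergence(pd)
  clusters <- threshold_cluster(pd, cutoff = config$p_cutoff)
  traits <- simulate_traits(config$traits, seed = derive_seed(seed, 4))
  diag <- diagnosability_matrix(traits, alpha = config$alpha)
  summary <- list(
    n_sites = nrow(sites),
    median_auc = vapply(fit$eval, function(e) e$median_auc, 0),
    threshold = fit$threshold,
    suitable_km2 = unname(account$areas_km2["suitable"]),
    forest_pct = unname(account$percent["forest_of_suitable"]),
    protected_pct = unname(account$percent["protected_of_suitable"]),
    jaccard_true = if (!is.null(true_range))
      jaccard_index(fit$merged_binary, true_range) else NA_real_,
    among_p_range = divergence$among_range,
    within_p_max = divergence$within_range[2],
    n_candidate_lineages = length(unique(clusters)))
  checksums <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    write_ascii_grid(fit$merged, file.path(out_dir, "suitability.asc"),
                     world$climate$west,
                     world$climate$north - world$climate$nrow * world$climate$cellsize,
                     world$climate$cellsize)
    write_ascii_grid(fit$merged_binary * 1, file.path(out_dir, "range.asc"),
                     world$climate$west,
                     world$climate$north - world$climate$nrow * world$climate$cellsize,
                     world$climate$cellsize)
    utils::write.csv(account$basins, file.path(out_dir, "basins.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(id = names(pd$lineage %||%
                                             rownames(pd$distance)),
                                round(100 * pd$distance, 2)),
                     file.path(out_dir, "p_distances.csv"), row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    checksums <- tools::md5sum(files)
    names(checksums) <- basename(files)
  }
  structure(list(config = config, sites = sites, enm = fit,
                 account = account, divergence = divergence,
                 clusters = clusters, diagnosability = diag,
                 summary = summary, checksums = checksums),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("<run_report>\n")
  cat(sprintf("  sites: %d; regions: %s\n", s$n_sites,
              paste(sprintf("%s (AUC %.3f, t %.3f)", names(s$median_auc),
                            s$median_auc, s$threshold), collapse = "; ")))
  cat(sprintf("  suitable %0.f km2; %.1f%% forested; %.1f%% protected\n",
              s$suitable_km2, s$forest_pct, s$protected_pct))
  if (is.finite(s$jaccard_true))
    cat(sprintf("  Jaccard vs true range: %.3f\n", s$jaccard_true))
  cat(sprintf("  16S divergence: among %.2f-%.2f%%, within max %.2f%%; %d candidate lineages\n",
              100 * s$among_p_range[1], 100 * s$among_p_range[2],
              100 * s$within_p_max, s$n_candidate_lineages))
  invisible(x)
}
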