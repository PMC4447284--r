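# Principal components of the climate layers over all non-missing study-area
# cells. Bioclim-style variables have incommensurate units, so the PCA is on
# the correlation matrix (each layer standardized to mean 0, SD 1).

#' Fit a principal-components model to climate layers
#'
#' Standardizes each named layer over the non-missing cells, eigendecomposes
#' the correlation matrix and retains either a fixed number of components
#' `k` (default 8) or the smallest number reaching `variance_target`. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making results platform-reproducible.
#'
#' @param gs a `grid_stack`.
#' @param layers layer names to include (at least 2). Default: all layers
#'   whose name starts with `"bio"`.
#' @param k number of components to retain.
#' @param variance_target if given, overrides `k`: retain the smallest
#'   number of components whose variance fractions sum to at least this.
#' @return An object of class `climate_pca` with elements `layers`, `center`,
#'   `scale`, `loadings` (layers x components, orthonormal columns),
#'   `variance_fraction` (all components), `k`.
#' @export
fit_pca <- function(gs, layers = NULL, k = 8, variance_target = NULL) {
  layers <- layers %||% grep("^bio", names(gs$layers), value = TRUE)
  if (length(layers) < 2) stop_("need at least 2 layers for a PCA")
  X <- sapply(layers, function(nm) {
    lay <- gs$layers[[nm]]
    if (is.null(lay)) stop_("no layer named '%s'", nm)
    as.vector(lay)
  })
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < length(layers)) stop_("too few non-missing cells for a PCA")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop_("layer '%s' is constant and cannot be standardized",
          layers[which(scl == 0)[1]])
  Xs <- scale(X, center = ctr, scale = scl)
  C <- crossprod(Xs) / (nrow(Xs) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  # deterministic sign: largest |loading| per component is positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  frac <- ev / sum(ev)
  if (!is.null(variance_target)) {
    k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
    if (is.na(k)) k <- length(frac)
  }
  k <- min(k, length(frac))
  dimnames(V) <- list(layers, paste0("PC", seq_along(frac)))
  structure(list(layers = layers, center = ctr, scale = scl,
                 loadings = V, variance_fraction = frac, k = as.integer(k)),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat(sprintf("<climate_pca> %d layers, %d components retained\n",
              length(x$layers), x$k))
  cat(sprintf("  variance explained by retained components: %.2f%%\n",
              100 * sum(x$variance_fraction[seq_len(x$k)])))
  invisible(x)
}

#' Project a stack onto fitted principal components
#'
#' Computes `PC_i = sum_j loading_ji * standardized layer_j` cellwise for
#' the retained components and returns a new `grid_stack` of PC layers,
#' optionally passing through additional predictor layers (terrain slope by
#' default, when present). Missing cells propagate.
#'
#' @param gs a `grid_stack` containing all layers of the model.
#' @param model a `climate_pca` from [fit_pca()].
#' @param k number of components to produce (default: the model's `k`).
#' @param passthrough layer names copied through unchanged if present.
#' @return A `grid_stack` with layers `PC1..PCk` (+ passthrough layers).
#' @export
project_pca <- function(gs, model, k = model$k, passthrough = "slope") {
  X <- sapply(model$layers, function(nm) {
    lay <- gs$layers[[nm]]
    if (is.null(lay)) stop_("layer '%s' required by the PCA model is missing", nm)
    as.vector(lay)
  })
  Xs <- scale(X, center = model$center, scale = model$scale)
  S <- Xs %*% model$loadings[, seq_len(k), drop = FALSE]
  out <- grid_stack(gs$west, gs$north, gs$cellsize, gs$nrow, gs$ncol)
  for (j in seq_len(k))
    out[[paste0("PC", j)]] <- matrix(S[, j], gs$nrow, gs$ncol)
  for (nm in intersect(passthrough, names(gs$layers)))
    out[[nm]] <- gs$layers[[nm]]
  out
}

#' Serialize / restore a climate PCA model as JSON
#'
#' @param model a `climate_pca`.
#' @param path file path.
#' @return `pca_to_json` writes and returns `path` invisibly;
#'   `pca_from_json` returns a `climate_pca`.
#' @export
pca_to_json <- function(model, path) {
  obj <- list(layers = model$layers, center = unname(model$center),
              scale = unname(model$scale),
              loadings = unname(model$loadings),
              variance_fraction = model$variance_fraction, k = model$k)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pca_to_json
#' @export
pca_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(o$loadings)
  dimnames(L) <- list(o$layers, paste0("PC", seq_len(ncol(L))))
  structure(list(layers = o$layers,
                 center = stats::setNames(o$center, o$layers),
                 scale = stats::setNames(o$scale, o$layers),
                 loadings = L, variance_fraction = o$variance_fraction,
                 k = as.integer(o$k)),
            class = "climate_pca")
}
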