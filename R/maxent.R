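# Penalized maximum-entropy presence/background niche model.
#
# The model puts a Gibbs distribution r(x) = exp(eta(x)) / Z over the
# background cells, eta(x) = sum_j w_j f_j(x), and maximizes the penalized
# presence log-likelihood
#
#   (1/m) sum_presence eta(x_i) - log sum_B exp(eta(x)) - sum_j beta_j |w_j|
#
# which is concave; at the optimum the KKT conditions bound the gap between
# presence and model feature means by beta_j, with equality on active
# features. The user-facing suitability is the logistic transform
# S(x) = e^H r(x) / (1 + e^H r(x)), H the entropy of r over the background,
# so that a completely uninformative model scores 0.5 everywhere.

#' Build a maxent feature set from background predictors
#'
#' Feature classes depend on the presence sample size `m`: fewer than 10
#' presences use linear features only; 10-14 add quadratic; 15 or more add
#' hinge features on a grid of `hinge_knots` knots per predictor. Every
#' feature is rescaled to `[0, 1]` over the background; features constant on
#' the background are dropped with a warning.
#'
#' @param background numeric matrix (cells x predictors) of predictor values
#'   at background cells; column names are the predictor names.
#' @param m number of presence records the model will be fitted to.
#' @param hinge_knots number of hinge knots per predictor (the knot at the
#'   predictor maximum is degenerate and never produces a feature).
#' @return An object of class `maxent_features`.
#' @export
maxent_features <- function(background, m, hinge_knots = 31) {
  background <- as.matrix(background)
  if (nrow(background) < 2) stop_("need at least 2 background cells")
  if (any(!is.finite(background))) stop_("background predictors must be finite")
  p <- ncol(background)
  preds <- colnames(background) %||% paste0("x", seq_len(p))
  colnames(background) <- preds
  classes <- if (m < 10) "linear"
             else if (m < 15) c("linear", "quadratic")
             else c("linear", "quadratic", "hinge")
  pred_min <- apply(background, 2, min)
  pred_max <- apply(background, 2, max)
  def <- list()
  for (j in seq_len(p)) {
    def[[length(def) + 1]] <- list(pred = j, type = "linear", knot = NA_real_)
    if ("quadratic" %in% classes)
      def[[length(def) + 1]] <- list(pred = j, type = "quadratic", knot = NA_real_)
    if ("hinge" %in% classes && pred_max[j] > pred_min[j]) {
      knots <- seq(pred_min[j], pred_max[j], length.out = hinge_knots)
      knots <- knots[-length(knots)]  # hinge at the max is identically zero
      for (k in knots)
        def[[length(def) + 1]] <- list(pred = j, type = "hinge", knot = k)
    }
  }
  fs <- structure(list(predictors = preds, pred_min = pred_min,
                       pred_max = pred_max, def = def, classes = classes),
                  class = "maxent_features")
  Fraw <- eval_features_raw(fs, background)
  fmin <- apply(Fraw, 2, min)
  fmax <- apply(Fraw, 2, max)
  keep <- fmax - fmin > 0
  if (!any(keep)) stop_("all features are constant on the background")
  if (any(!keep))
    warning(sprintf("dropping %d feature(s) constant on the background",
                    sum(!keep)), call. = FALSE)
  fs$def <- fs$def[keep]
  fs$f_min <- fmin[keep]
  fs$f_max <- fmax[keep]
  Fb <- scale_features(fs, Fraw[, keep, drop = FALSE])
  fs$s <- apply(Fb, 2, stats::sd)
  fs$names <- vapply(fs$def, function(d) {
    if (d$type == "hinge")
      sprintf("hinge(%s,%.6g)", preds[d$pred], d$knot)
    else sprintf("%s(%s)", d$type, preds[d$pred])
  }, "")
  fs
}

eval_features_raw <- function(fs, X) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(X), length(fs$def))
  for (j in seq_along(fs$def)) {
    d <- fs$def[[j]]
    x <- X[, d$pred]
    out[, j] <- switch(d$type,
      linear = x,
      quadratic = x^2,
      hinge = pmax(0, x - d$knot))
  }
  out
}

scale_features <- function(fs, Fraw, clamp = FALSE) {
  Fsc <- sweep(sweep(Fraw, 2, fs$f_min), 2, fs$f_max - fs$f_min, "/")
  if (clamp) { Fsc[Fsc < 0] <- 0; Fsc[Fsc > 1] <- 1 }
  Fsc
}

# Scaled (and optionally clamped) feature matrix for a predictor matrix.
feature_matrix <- function(fs, X, clamp = FALSE) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    miss <- setdiff(fs$predictors, colnames(X))
    if (length(miss)) stop_("missing predictor(s): %s", paste(miss, collapse = ", "))
    X <- X[, fs$predictors, drop = FALSE]
  } else if (ncol(X) != length(fs$predictors)) {
    stop_("predictor matrix has %d columns; model expects %d",
          ncol(X), length(fs$predictors))
  }
  scale_features(fs, eval_features_raw(fs, X), clamp = clamp)
}

#' @export
print.maxent_features <- function(x, ...) {
  cat(sprintf("<maxent_features> %d features over %d predictors (classes: %s)\n",
              length(x$def), length(x$predictors),
              paste(x$classes, collapse = "+")))
  invisible(x)
}

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

#' Fit a penalized maximum-entropy niche model
#'
#' Maximizes the L1-penalized presence log-likelihood over the background by
#' accelerated proximal gradient descent (with adaptive step size and
#' restarts), followed by an active-set quasi-Newton polish, to a relative
#' objective change below `tol`. Per-feature penalties default to the
#' schedule `beta_j = lambda * s_j / sqrt(m)` (floored at 1e-4), with `s_j`
#' the background standard deviation of the scaled feature.
#'
#' @param x numeric matrix (presences x predictors) of predictor values at
#'   presence cells.
#' @param background numeric matrix (cells x predictors) at background cells.
#' @param lambda overall regularization multiplier (> 0).
#' @param features a `maxent_features` object; built from the background and
#'   `nrow(x)` when `NULL`.
#' @param beta optional explicit per-feature penalties overriding the
#'   `lambda` schedule (recycled to the number of features).
#' @param max_iter iteration cap for the proximal-gradient phase.
#' @param tol relative objective-change convergence tolerance.
#' @return An object of class `maxent` with components including
#'   `coefficients` (named weights), `beta`, `features`, `logZ`, `entropy`,
#'   `raw_bg` (the fitted distribution over background cells),
#'   `presence_mean` / `model_mean` (scaled feature means), and `kkt`
#'   (maximum stationarity violation).
#' @examples
#' set.seed(1)
#' bg <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' pr <- matrix(rnorm(40, mean = 1, sd = 0.5), ncol = 2,
#'              dimnames = list(NULL, c("a", "b")))
#' m <- maxent(pr, bg)
#' range(predict(m, bg))
#' @export
maxent <- function(x, background, lambda = 1, features = NULL, beta = NULL,
                   max_iter = 10000, tol = 1e-8) {
  cl <- match.call()
  x <- as.matrix(x); background <- as.matrix(background)
  m <- nrow(x)
  if (m == 0) stop_("no presence records")
  if (any(!is.finite(x))) stop_("presence predictors must be finite")
  if (is.null(features)) features <- maxent_features(background, m)
  fs <- features
  Fp <- feature_matrix(fs, x)
  Fb <- feature_matrix(fs, background)
  J <- ncol(Fb); n_bg <- nrow(Fb)
  if (is.null(beta)) beta <- pmax(lambda * fs$s / sqrt(m), 1e-4)
  beta <- rep_len(beta, J)
  fbar_p <- colMeans(Fp)

  smooth_obj <- function(w) {
    eta <- drop(Fb %*% w); M <- max(eta)
    v <- -sum(fbar_p * w) + M + log(sum(exp(eta - M)))
    if (!is.finite(v)) stop_("non-finite objective during fit")
    v
  }
  smooth_grad <- function(w) {
    eta <- drop(Fb %*% w); M <- max(eta)
    r <- exp(eta - M); r <- r / sum(r)
    drop(crossprod(Fb, r)) - fbar_p
  }
  pen_obj <- function(w) smooth_obj(w) + sum(beta * abs(w))

  fista <- function(w0, iters, tol) {
    w <- w0; y <- w0; tk <- 1; L <- 1
    F_prev <- pen_obj(w)
    for (it in seq_len(iters)) {
      g <- smooth_grad(y); fy <- smooth_obj(y)
      repeat {
        w_new <- soft_threshold(y - g / L, beta / L)
        d <- w_new - y
        if (smooth_obj(w_new) <= fy + sum(g * d) + L / 2 * sum(d * d) + 1e-12)
          break
        L <- L * 2
        if (L > 1e16) break
      }
      F_new <- pen_obj(w_new)
      if (F_new > F_prev + 1e-15) {    # restart acceleration from last accepted w
        y <- w; tk <- 1
      } else {
        t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
        y <- w_new + ((tk - 1) / t_new) * (w_new - w)
        tk <- t_new
        conv <- abs(F_prev - F_new) <= tol * max(1, abs(F_new))
        w <- w_new; F_prev <- F_new
        if (conv && it > 5) return(list(w = w, iter = it, converged = TRUE))
      }
      L <- max(L / 1.5, 1e-8)
    }
    list(w = w, iter = iters, converged = FALSE)
  }

  polish <- function(w) {
    # active coordinates, plus inactive ones whose KKT bound is violated
    # (they belong in the active set; their sign is the descent direction)
    g <- smooth_grad(w)
    A <- which(w != 0 | abs(g) > beta)
    if (!length(A)) return(w)
    s <- ifelse(w[A] != 0, sign(w[A]), -sign(g[A]))
    fn <- function(wa) { ww <- w; ww[A] <- wa; smooth_obj(ww) + sum(beta[A] * s * wa) }
    gr <- function(wa) { ww <- w; ww[A] <- wa; smooth_grad(ww)[A] + beta[A] * s }
    o <- try(stats::optim(w[A], fn, gr, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-15)),
             silent = TRUE)
    if (inherits(o, "try-error")) return(w)
    w2 <- w; w2[A] <- o$par
    if (pen_obj(w2) <= pen_obj(w) + 1e-12) w2 else w
  }

  kkt_gap <- function(w) {
    g <- smooth_grad(w)
    act <- w != 0
    v <- numeric(J)
    v[act] <- abs(g[act] + beta[act] * sign(w[act]))
    v[!act] <- pmax(0, abs(g[!act]) - beta[!act])
    v
  }

  res <- fista(rep(0, J), max_iter, tol)
  w <- res$w; iters <- res$iter
  ftol <- tol
  for (round in 1:12) {
    w <- polish(w)
    w[abs(w) < 1e-12] <- 0
    if (max(kkt_gap(w)) < 1e-7) break
    ftol <- ftol / 100
    res <- fista(w, 3000, ftol)
    w <- res$w; iters <- iters + res$iter
  }

  eta_b <- drop(Fb %*% w)
  logZ <- {
    M <- max(eta_b); M + log(sum(exp(eta_b - M)))
  }
  r <- exp(eta_b - logZ)
  H <- -sum(r * log(r))
  model_mean <- drop(crossprod(Fb, r))
  names(w) <- fs$names
  structure(list(coefficients = w, beta = stats::setNames(beta, fs$names),
                 lambda = lambda, features = fs,
                 logZ = logZ, entropy = H, raw_bg = r,
                 presence_mean = stats::setNames(fbar_p, fs$names),
                 model_mean = stats::setNames(model_mean, fs$names),
                 m = m, n_bg = n_bg, iterations = iters,
                 kkt = max(kkt_gap(w)), converged = res$converged,
                 call = cl),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("<maxent> %d presences vs %d background cells, %d features (%s)\n",
              x$m, x$n_bg, length(x$coefficients),
              paste(x$features$classes, collapse = "+")))
  cat(sprintf("  nonzero weights: %d; entropy H = %.4f; max KKT gap = %.2e\n",
              sum(x$coefficients != 0), x$entropy, x$kkt))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  w <- object$coefficients
  act <- w[w != 0]
  structure(list(model = object,
                 active = act[order(-abs(act))],
                 gap = abs(object$presence_mean - object$model_mean)),
            class = "summary.maxent")
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  if (length(x$active)) {
    cat("  largest active weights:\n")
    print(utils::head(round(x$active, 4), 10))
  }
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$coefficients

#' Check the stationarity (KKT) conditions of a fitted maxent model
#'
#' At the optimum of the penalized likelihood the gap between presence and
#' model feature means is bounded by the penalty: `|gap_j| <= beta_j`, with
#' equality on features carrying nonzero weight. Returns the per-feature gap
#' table and the maximum violation.
#'
#' @param model a fitted `maxent`.
#' @return A list with `table` (feature, weight, gap, beta) and
#'   `max_violation`.
#' @export
kkt_check <- function(model) {
  gap <- model$presence_mean - model$model_mean
  w <- model$coefficients; b <- model$beta
  act <- w != 0
  viol <- ifelse(act, abs(abs(gap) - b), pmax(0, abs(gap) - b))
  list(table = data.frame(feature = names(w), weight = unname(w),
                          gap = unname(gap), beta = unname(b),
                          active = unname(act)),
       max_violation = max(viol))
}

#' Predict suitability from a fitted maxent model
#'
#' @param object a fitted `maxent`.
#' @param newdata a numeric matrix / data frame of predictor values (columns
#'   named as at fit time), or a `grid_stack` containing the predictor
#'   layers.
#' @param type `"logistic"` (default; suitability in (0,1)), `"raw"`
#'   (normalized Gibbs density over the training background), `"link"` (the
#'   linear predictor eta), or `"cumulative"` (percentile of raw among
#'   background cells, 0-100).
#' @param clamp clamp scaled features into the training `[0, 1]` range
#'   (standard maxent extrapolation behaviour).
#' @param ... unused.
#' @return A numeric vector, or a matrix when `newdata` is a `grid_stack`.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("logistic", "raw", "link", "cumulative"),
                           clamp = TRUE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "grid_stack")) {
    gs <- newdata
    X <- sapply(object$features$predictors, function(nm) {
      lay <- gs$layers[[nm]]
      if (is.null(lay)) stop_("predictor layer '%s' missing from stack", nm)
      as.vector(lay)
    })
    ok <- stats::complete.cases(X)
    out <- rep(NA_real_, nrow(X))
    if (any(ok))
      out[ok] <- predict(object, X[ok, , drop = FALSE], type = type, clamp = clamp)
    return(matrix(out, gs$nrow, gs$ncol))
  }
  Fm <- feature_matrix(object$features, newdata, clamp = clamp)
  eta <- drop(Fm %*% object$coefficients)
  if (type == "link") return(eta)
  raw <- exp(eta - object$logZ)
  if (type == "raw") return(raw)
  if (type == "cumulative") {
    ec <- stats::ecdf(object$raw_bg)
    return(100 * ec(raw))
  }
  # e^H r / (1 + e^H r) computed in log space for stability
  stats::plogis(object$entropy + eta - object$logZ)
}
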