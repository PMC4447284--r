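# Morphometric diagnosability statistics: varimax-rotated PCA with a
# loading screen, ANCOVA (SVL as covariate) with Tukey HSD, ratio-based
# nonparametric comparisons, a normality gate routing traits between the
# two, and the pairwise lineage diagnosability matrix.

#' The standard measurement set
#'
#' The 14 external measurements (mm) used throughout: snout-vent length
#' (SVL), head length (HDL), head width (HDW), snout length (SNT), eye
#' diameter (EYE), interorbital distance (IOD), tympanum diameter (TMP),
#' tympanum-eye distance (TEY), tibia length (TIB), manus length (ML), pes
#' length (PL), and the pectoral (PEC), femoral (FEM) and humeral (HUM)
#' gland diameters.
#'
#' @format A character vector of length 14.
#' @export
MEASUREMENTS <- c("SVL", "HDL", "HDW", "SNT", "EYE", "IOD", "TMP",
                  "TEY", "TIB", "ML", "PL", "PEC", "FEM", "HUM")

#' Varimax-rotated principal components of morphometric variables
#'
#' PCA on the correlation matrix of the (complete-case) measurements,
#' followed by an orthogonal varimax rotation of the first `n_factors`
#' loadings. ML and PL are excluded by default (frequently unmeasurable on
#' poorly preserved specimens). Variables with any rotated loading above
#' `cutoff` in magnitude are flagged as high-contribution variables.
#' Communalities (row sums of squared loadings) are invariant under the
#' rotation.
#'
#' @param data data frame of measurements.
#' @param variables variables to include; default all measurements except
#'   ML and PL.
#' @param n_factors number of factors to rotate (default 2).
#' @param cutoff absolute-loading flag threshold (default 0.80).
#' @param normalize Kaiser-normalize rows during rotation (default FALSE:
#'   the plain varimax criterion).
#' @return An object of class `rotated_pca`: `loadings` (unrotated),
#'   `rotated`, `rotation` (orthogonal matrix), `variance_fraction` (per
#'   retained factor, of total variance), `communality`, `flagged`,
#'   `n_used` (complete cases).
#' @export
pca_varimax <- function(data, variables = setdiff(MEASUREMENTS, c("ML", "PL")),
                        n_factors = 2, cutoff = 0.80, normalize = FALSE) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop_("missing variable(s): %s", paste(miss, collapse = ", "))
  if (n_factors > length(variables))
    stop_("n_factors (%d) exceeds the number of variables (%d)",
          n_factors, length(variables))
  X <- as.matrix(data[, variables, drop = FALSE])
  cc <- stats::complete.cases(X)
  if (sum(!cc))
    message(sprintf("dropping %d incomplete specimen(s) (listwise deletion)",
                    sum(!cc)))
  X <- X[cc, , drop = FALSE]
  if (nrow(X) <= n_factors) stop_("too few complete cases")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop_("variable '%s' is constant", variables[sds == 0][1])
  C <- stats::cor(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_factors)]), n_factors)
  dimnames(L) <- list(variables, paste0("Factor", seq_len(n_factors)))
  for (j in seq_len(n_factors)) {          # deterministic sign
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  if (n_factors > 1) {
    R <- varimax_rotation(L, normalize = normalize, eps = 1e-8)
    Lr <- L %*% R
  } else {
    R <- matrix(1, 1, 1)
    Lr <- L
  }
  dimnames(Lr) <- dimnames(L)
  structure(list(loadings = L, rotated = Lr, rotation = R,
                 variance_fraction = ev[seq_len(n_factors)] / length(variables),
                 variance_fraction_rotated = colSums(Lr^2) / length(variables),
                 communality = rowSums(L^2),
                 flagged = variables[apply(abs(Lr) > cutoff, 1, any)],
                 cutoff = cutoff, n_used = nrow(X)),
            class = "rotated_pca")
}

#' @export
print.rotated_pca <- function(x, ...) {
  cat(sprintf("<rotated_pca> %d variables, %d factors, %d specimens\n",
              nrow(x$rotated), ncol(x$rotated), x$n_used))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", ")))
  cat(sprintf("  |loading| > %.2f: %s\n", x$cutoff,
              if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "(none)"))
  invisible(x)
}

# Classical varimax by pairwise planar rotations (Kaiser's angle formula),
# maximizing sum_factors [mean(loading^4) - mean(loading^2)^2]. Sweeps over
# column pairs until the criterion improves by less than `eps`. The
# closed-form angle handles symmetric configurations where gradient-free
# stationary points trap SVD-style updates.
varimax_rotation <- function(L, normalize = FALSE, eps = 1e-8,
                             max_sweeps = 200) {
  p <- nrow(L); k <- ncol(L)
  h <- sqrt(rowSums(L^2))
  Z <- if (normalize) L / h else L
  R <- diag(k)
  crit <- function(B) sum(apply(B^2, 2, function(cc) mean(cc^2) - mean(cc)^2))
  old <- crit(Z %*% R)
  for (s in seq_len(max_sweeps)) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      B <- Z %*% R
      x <- B[, i]; y <- B[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      num <- sum(2 * u * v) - 2 * sum(u) * sum(v) / p
      den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) < 1e-15) next
      G <- diag(k)
      G[i, i] <- cos(phi); G[j, j] <- cos(phi)
      G[j, i] <- sin(phi); G[i, j] <- -sin(phi)
      R <- R %*% G
    }
    new <- crit(Z %*% R)
    if (new - old < eps) break
    old <- new
  }
  R
}

# Tukey-Kramer pairwise comparisons of group terms in a fitted linear
# model (adjusted means under a common slope when a covariate is present).
tukey_pairwise <- function(fit, data, group, alpha = 0.05) {
  g <- factor(data[[group]])
  lev <- levels(g)
  k <- length(lev)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- stats::df.residual(fit)
  # coefficient index of each group level under treatment contrasts
  idx <- stats::setNames(match(paste0("g", lev), names(cf)), lev)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pp) {
    ci <- rep(0, length(cf))
    if (!is.na(idx[pp[1]])) ci[idx[pp[1]]] <- 1
    if (!is.na(idx[pp[2]])) ci[idx[pp[2]]] <- -1
    est <- sum(ci * cf)
    se <- sqrt(drop(t(ci) %*% V %*% ci))
    if (se == 0) {
      p <- if (abs(est) < 1e-12) 1 else 0
    } else {
      q <- sqrt(2) * abs(est) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    data.frame(group1 = pp[1], group2 = pp[2], estimate = est, se = se,
               p_adj = p)
  }))
  out$significant <- out$p_adj < alpha
  out
}

#' ANCOVA with Tukey HSD pairwise comparisons
#'
#' Fits the common-slope linear model `trait ~ covariate + group`, reports
#' the group F-test (Type I, covariate entered first) and Tukey HSD
#' (Tukey-Kramer for unequal group sizes) comparisons of the
#' covariate-adjusted group means via the studentized-range distribution.
#' With `covariate = NULL` this reduces to a one-way ANOVA with Tukey HSD
#' (how body size itself is compared).
#'
#' @param data data frame.
#' @param trait response variable name.
#' @param covariate covariate name (default `"SVL"`), or `NULL` for plain
#'   ANOVA.
#' @param group grouping variable name (default `"lineage"`).
#' @param alpha significance level for flagging pairs.
#' @return An object of class `ancova_tukey`: `F`, `p`, `df`, `pairwise`
#'   table, the fitted model, and metadata.
#' @export
ancova_tukey <- function(data, trait, covariate = "SVL", group = "lineage",
                         alpha = 0.05) {
  cols <- c(trait, covariate, group)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data.frame(y = data[[trait]][cc], g = factor(data[[group]][cc]))
  if (!is.null(covariate)) d$cov <- data[[covariate]][cc]
  tab <- table(d$g)
  if (length(tab) < 2) stop_("need at least 2 groups")
  if (any(tab < 2)) stop_("every group needs at least 2 complete cases")
  fit <- if (is.null(covariate)) stats::lm(y ~ g, data = d)
         else stats::lm(y ~ cov + g, data = d)
  an <- stats::anova(fit)
  gi <- match("g", rownames(an))
  ss_g <- an[gi, "Sum Sq"]; ms_e <- an["Residuals", "Mean Sq"]
  if (ss_g < 1e-12) {            # no group signal at all (incl. 0/0 case)
    Fv <- 0; pv <- 1
  } else {
    Fv <- an[gi, "F value"]; pv <- an[gi, "Pr(>F)"]
    if (!is.finite(Fv)) { Fv <- Inf; pv <- 0 }  # perfect separation, zero error
  }
  pw <- tukey_pairwise(fit, d, "g", alpha = alpha)
  structure(list(F = Fv, p = pv,
                 df = c(an[gi, "Df"], an["Residuals", "Df"]),
                 pairwise = pw, fit = fit, trait = trait,
                 covariate = covariate, group = group, alpha = alpha,
                 n = nrow(d)),
            class = "ancova_tukey")
}

#' @export
print.ancova_tukey <- function(x, ...) {
  kind <- if (is.null(x$covariate)) "ANOVA" else
    sprintf("ANCOVA (covariate %s)", x$covariate)
  cat(sprintf("<ancova_tukey> %s: %s, F(%d,%d) = %.3g, p = %.3g\n",
              x$trait, kind, x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  %d/%d Tukey HSD pairs significant at alpha = %g\n",
              sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' Ratio-based nonparametric comparisons
#'
#' Removes the effect of body size by the ratio `trait / covariate`, then
#' runs a Kruskal-Wallis test (tie-corrected, chi-squared approximation
#' with k-1 df) across groups and two-sided pairwise Wilcoxon rank-sum
#' tests (normal approximation with continuity correction).
#'
#' @inheritParams ancova_tukey
#' @return An object of class `ratio_npar`: `H` (Kruskal-Wallis
#'   chi-squared), `p`, `df`, `pairwise` table, `undefined` flag (all
#'   values tied in every group).
#' @export
ratio_nonparametric <- function(data, trait, covariate = "SVL",
                                group = "lineage", alpha = 0.05) {
  cols <- c(trait, covariate, group)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  ratio <- d[[trait]] / d[[covariate]]
  g <- factor(d[[group]])
  if (nlevels(g) < 2) stop_("need at least 2 groups")
  if (length(unique(ratio)) == 1) {
    warning("all ratios tied; Kruskal-Wallis statistic undefined", call. = FALSE)
    return(structure(list(H = NA_real_, p = NA_real_, df = nlevels(g) - 1,
                          pairwise = NULL, undefined = TRUE, trait = trait,
                          alpha = alpha),
                     class = "ratio_npar"))
  }
  kw <- stats::kruskal.test(ratio, g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pp) {
    a <- ratio[g == pp[1]]; b <- ratio[g == pp[2]]
    p <- if (length(unique(c(a, b))) == 1) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                          correct = TRUE)$p.value)
    data.frame(group1 = pp[1], group2 = pp[2], p = p)
  }))
  pw$significant <- pw$p < alpha
  structure(list(H = unname(kw$statistic), p = kw$p.value,
                 df = unname(kw$parameter), pairwise = pw, undefined = FALSE,
                 trait = trait, alpha = alpha),
            class = "ratio_npar")
}

#' @export
print.ratio_npar <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<ratio_npar> %s/SVL: undefined (all values tied)\n", x$trait))
    return(invisible(x))
  }
  cat(sprintf("<ratio_npar> %s ratio: Kruskal-Wallis chi2(%d) = %.3g, p = %.3g\n",
              x$trait, x$df, x$H, x$p))
  cat(sprintf("  %d/%d pairwise Wilcoxon tests significant at alpha = %g\n",
              sum(x$pairwise$significant), nrow(x$pairwise), x$alpha))
  invisible(x)
}

# D'Agostino-Belanger-D'Agostino K2 omnibus normality statistic.
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8) stop_("K2 approximation requires n >= 8 (got %d)", n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_("zero variance: normality test undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * asinh(Y / alpha)
  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  list(K2 = K2, Zg1 = Zg1, Zg2 = Zg2,
       p = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Normality gate for routing traits between parametric and rank tests
#'
#' D'Agostino K2 omnibus test (skewness + kurtosis) at level `alpha`,
#' intended for covariate-adjusted residuals. Requires `n >= 8` (the
#' chi-squared approximation is invalid below that).
#'
#' @param values numeric vector (typically residuals of `trait ~ SVL`).
#' @param alpha significance level (default 0.05).
#' @return A list with `decision` (`"normal"` / `"non-normal"`), `K2` and
#'   `p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  r <- dagostino_k2(values)
  list(decision = if (r$p < alpha) "non-normal" else "normal",
       K2 = r$K2, p = r$p)
}

#' Pairwise lineage diagnosability matrix
#'
#' For each trait: SVL is compared by one-way ANOVA with Tukey HSD (no
#' covariate); every other trait is first routed by [normality_gate()] on
#' the residuals of `trait ~ SVL` - normal traits go through ANCOVA with
#' Tukey HSD, non-normal traits through ratio-based Kruskal-Wallis with
#' pairwise Wilcoxon tests. A trait appears in cell (i, j) when its
#' pairwise test between lineages i and j is significant at `alpha`. The
#' matrix is symmetric in content and printed lower-triangular.
#'
#' @param data trait data frame (must contain `SVL` and the grouping
#'   column).
#' @param traits traits to test (default: all measurements present except
#'   ML and PL; SVL always included first).
#' @param group grouping variable name.
#' @param alpha significance level.
#' @return An object of class `diagnosability`: `matrix` (character, traits
#'   per cell), `routes` (per-trait test route), and per-trait test
#'   objects in `tests`.
#' @export
diagnosability_matrix <- function(data, traits = NULL, group = "lineage",
                                  alpha = 0.05) {
  traits <- traits %||% intersect(setdiff(MEASUREMENTS, c("ML", "PL")),
                                  names(data))
  traits <- union("SVL", traits)
  lev <- levels(factor(data[[group]]))
  k <- length(lev)
  cellmat <- matrix("", k, k, dimnames = list(lev, lev))
  routes <- character(0)
  tests <- list()
  add_pairs <- function(cellmat, pw, trait) {
    for (r in seq_len(nrow(pw))) if (pw$significant[r]) {
      i <- pw$group1[r]; j <- pw$group2[r]
      for (cell in list(c(i, j), c(j, i))) {
        cur <- cellmat[cell[1], cell[2]]
        cellmat[cell[1], cell[2]] <-
          if (nzchar(cur)) paste(cur, trait, sep = ", ") else trait
      }
    }
    cellmat
  }
  for (tr in traits) {
    if (tr == "SVL") {
      res <- ancova_tukey(data, "SVL", covariate = NULL, group = group,
                          alpha = alpha)
      routes[tr] <- "anova"
      tests[[tr]] <- res
      cellmat <- add_pairs(cellmat, res$pairwise, "SVL")
      next
    }
    cc <- stats::complete.cases(data[, c(tr, "SVL", group)])
    resid <- stats::residuals(stats::lm(data[[tr]][cc] ~ data$SVL[cc]))
    gate <- normality_gate(resid, alpha = alpha)
    if (gate$decision == "normal") {
      res <- ancova_tukey(data, tr, covariate = "SVL", group = group,
                          alpha = alpha)
      routes[tr] <- "ancova"
      cellmat <- add_pairs(cellmat, res$pairwise, tr)
    } else {
      res <- ratio_nonparametric(data, tr, covariate = "SVL", group = group,
                                 alpha = alpha)
      routes[tr] <- "ratio"
      if (!res$undefined)
        cellmat <- add_pairs(cellmat, res$pairwise, tr)
    }
    tests[[tr]] <- res
  }
  structure(list(matrix = cellmat, routes = routes, tests = tests,
                 alpha = alpha, group = group),
            class = "diagnosability")
}

#' @export
print.diagnosability <- function(x, ...) {
  m <- x$matrix
  lower <- m
  lower[upper.tri(lower, diag = TRUE)] <- ""
  cat(sprintf("<diagnosability> %d lineages, alpha = %g\n", nrow(m), x$alpha))
  cat("  routes:", paste(sprintf("%s=%s", names(x$routes), x$routes),
                         collapse = ", "), "\n")
  print(as.data.frame(lower), right = FALSE)
  invisible(x)
}

#' Simple regression screen for call covariates
#'
#' Ordinary least-squares regression of a response on one predictor,
#' reporting the coefficient of determination, the overall F statistic
#' (df 1, n-2) and its two-sided p-value - the standard screen for
#' size- or temperature-dependence of acoustic parameters.
#'
#' @param data data frame.
#' @param response,predictor column names.
#' @return A list with `r_squared`, `F`, `p`, `n`, `slope`, `intercept`.
#' @export
covariate_screen <- function(data, response, predictor) {
  d <- data[stats::complete.cases(data[, c(response, predictor)]), ]
  n <- nrow(d)
  if (n < 3) stop_("need at least 3 complete pairs")
  x <- d[[predictor]]; y <- d[[response]]
  if (stats::var(x) == 0) stop_("predictor '%s' has zero variance", predictor)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  Fv <- unname(s$fstatistic[1])
  list(r_squared = s$r.squared, F = Fv,
       p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE), n = n,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
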