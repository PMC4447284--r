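# Morphometric statistics: rotated PCA, ANCOVA/Tukey, rank tests, the
# normality gate and the diagnosability matrix.

test_that("rank-1 data loads entirely on one factor with identity rotation", {
  set.seed(1)
  base <- rnorm(30, 25, 3)
  d <- data.frame(SVL = base, HDW = 2 * base, TIB = -base)
  p <- pca_varimax(d, variables = c("SVL", "HDW", "TIB"), n_factors = 1)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-10)
  expect_equal(abs(p$rotated), abs(p$loadings), tolerance = 1e-10)
})

test_that("varimax rotates symmetric loadings to the axes (grid-search oracle)", {
  L <- rbind(c(0.7, 0.7), c(0.7, -0.7))
  R <- nichesplit:::varimax_rotation(L)
  rot <- L %*% R
  # grid-search oracle over planar rotation angles
  crit <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    B <- L %*% R
    sum(apply(B^2, 2, function(col) mean(col^2) - mean(col)^2))
  }
  th <- seq(0, pi / 2, length.out = 20001)
  best <- th[which.max(vapply(th, crit, 0))]
  Rb <- matrix(c(cos(best), sin(best), -sin(best), cos(best)), 2, 2)
  oracle <- L %*% Rb
  expect_equal(sort(abs(as.vector(rot))), sort(abs(as.vector(oracle))),
               tolerance = 1e-4)
  expect_equal(max(abs(rot)), 0.7 * sqrt(2), tolerance = 1e-6)
  expect_equal(sort(round(abs(as.vector(rot)), 4)), c(0, 0, 0.9899, 0.9899))
})

test_that("rotation is orthogonal and preserves communalities", {
  sp <- trait_spec()
  d <- simulate_traits(sp, n_per_lineage = 8, seed = 11)
  p <- pca_varimax(d, n_factors = 2)
  expect_equal(crossprod(p$rotation), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rowSums(p$rotated^2), p$communality, tolerance = 1e-8,
               ignore_attr = TRUE)
  # agreement with the reference implementation away from degenerate points
  vm <- stats::varimax(p$loadings, normalize = FALSE, eps = 1e-10)
  ref <- p$loadings %*% vm$rotmat
  # compare loadings up to column order and sign (not identified)
  expect_equal(sort(abs(as.vector(p$rotated))), sort(abs(as.vector(ref))),
               tolerance = 1e-5)
  expect_error(pca_varimax(d, n_factors = 40), "exceeds")
  # body-size-dominated data: factor 1 carries most variance and flags SVL
  expect_gt(p$variance_fraction[1], 0.5)
  expect_true("SVL" %in% rownames(p$rotated))
})

test_that("listwise deletion drops incomplete specimens with a message", {
  d <- simulate_traits(trait_spec(), n_per_lineage = 6, seed = 2)
  d$HDW[3] <- NA
  expect_message(p <- pca_varimax(d, n_factors = 2), "1 incomplete")
  expect_equal(p$n_used, nrow(d) - 1)
})

test_that("ancova detects no group effect in purely allometric data", {
  set.seed(4)
  svl <- rnorm(60, 25, 3)
  d <- data.frame(SVL = svl, HDW = 2 + 0.5 * svl,
                  lineage = rep(c("a", "b", "c"), each = 20))
  r <- suppressWarnings(ancova_tukey(d, "HDW"))  # noise-free fit warnings
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_false(any(r$pairwise$significant))
})

test_that("a planted offset is recovered exactly as the adjusted difference", {
  set.seed(5)
  svl <- rnorm(40, 25, 3)
  d <- data.frame(SVL = svl, HDW = 2 + 0.5 * svl +
                    rep(c(0, 1), each = 20),
                  lineage = rep(c("a", "b"), each = 20))
  r <- suppressWarnings(ancova_tukey(d, "HDW"))  # noise-free fit warnings
  est <- r$pairwise$estimate[1]
  expect_equal(abs(est), 1, tolerance = 1e-10)
  expect_true(is.infinite(r$F) || r$F > 1e10)  # noise-free separation
})

test_that("group F matches a full-vs-reduced RSS oracle on random data", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 72
    d <- data.frame(SVL = rnorm(n, 25, 2),
                    lineage = sample(letters[1:4], n, TRUE))
    d$HDW <- 1 + 0.4 * d$SVL + 0.3 * (d$lineage == "b") + rnorm(n, 0, 0.3)
    r <- ancova_tukey(d, "HDW")
    full <- stats::lm(HDW ~ SVL + lineage, d)
    red <- stats::lm(HDW ~ SVL, d)
    k <- length(unique(d$lineage))
    F_oracle <- ((sum(stats::residuals(red)^2) - sum(stats::residuals(full)^2)) /
                   (k - 1)) / (sum(stats::residuals(full)^2) / (n - k - 1))
    expect_equal(r$F, F_oracle, tolerance = 1e-8)
  }
})

test_that("the two-group studentized range reduces to sqrt(2) * z", {
  q <- stats::qtukey(0.95, nmeans = 2, df = 1e7)
  expect_equal(q, sqrt(2) * 1.95996, tolerance = 1e-4)
  # two-group Tukey p equals the pooled t-test p
  set.seed(6)
  d <- data.frame(SVL = rnorm(30, 25, 2), lineage = rep(c("a", "b"), 15))
  d$HDW <- 0.4 * d$SVL + rnorm(30, 0, 0.5)
  r <- ancova_tukey(d, "HDW")
  fit <- stats::lm(HDW ~ SVL + lineage, d)
  p_t <- summary(fit)$coefficients["lineageb", "Pr(>|t|)"]
  expect_equal(r$pairwise$p_adj, p_t, tolerance = 1e-8)
})

test_that("tukey matches the emmeans adjusted comparisons", {
  skip_if_not_installed("emmeans")
  set.seed(7)
  n <- 60
  d <- data.frame(SVL = rnorm(n, 25, 2),
                  lineage = sample(c("a", "b", "c"), n, TRUE))
  d$HDW <- 0.4 * d$SVL + 0.5 * (d$lineage == "c") + rnorm(n, 0, 0.4)
  r <- ancova_tukey(d, "HDW")
  fit <- stats::lm(HDW ~ cov + g,
                   data = data.frame(HDW = d$HDW, cov = d$SVL,
                                     g = factor(d$lineage)))
  em <- summary(emmeans::emmeans(fit, pairwise ~ g, adjust = "tukey")$contrasts)
  expect_equal(sort(r$pairwise$p_adj), sort(em$p.value), tolerance = 1e-6)
})

test_that("kruskal-wallis reproduces the hand-ranked example H = 2.4", {
  d <- data.frame(SVL = 1, TIB = c(1, 2, 3, 4),
                  lineage = c("a", "a", "b", "b"))
  r <- ratio_nonparametric(d, "TIB")
  expect_equal(r$H, 2.4)   # 12/(n(n+1)) * sum R_i^2/n_i - 3(n+1)
  # identical groups give H = 0
  d0 <- data.frame(SVL = 1, TIB = rep(c(1, 2, 3), 2),
                   lineage = rep(c("a", "b"), each = 3))
  expect_equal(ratio_nonparametric(d0, "TIB")$H, 0)
  # rank statistic: invariant under strictly monotone transforms
  set.seed(8)
  d2 <- data.frame(SVL = 1, TIB = runif(30),
                   lineage = sample(c("a", "b", "c"), 30, TRUE))
  h1 <- ratio_nonparametric(d2, "TIB")$H
  d3 <- d2; d3$TIB <- exp(5 * d3$TIB)
  expect_equal(ratio_nonparametric(d3, "TIB")$H, h1)
  # fully tied data is undefined and flagged
  d4 <- data.frame(SVL = 1, TIB = 1, lineage = rep(c("a", "b"), 5))
  expect_warning(r4 <- ratio_nonparametric(d4, "TIB"), "tied")
  expect_true(r4$undefined)
})

test_that("the normality gate reproduces the frozen scipy oracle and decides", {
  x <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
         10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584,
         10.132061, 12.254482, 10.935019, 8.281415, 10.737502, 8.082235,
         11.756901, 9.900148, 9.630275, 8.638141, 12.445083, 9.690941,
         9.143344, 9.295733, 11.064618, 10.730888, 10.825465, 10.861642,
         14.283295, 9.18717, 8.975515, 8.372455, 11.231959, 12.257945,
         9.772105, 8.319687, 8.351038, 11.301186)
  g <- normality_gate(x)
  expect_equal(g$K2, 0.11548162717787923, tolerance = 1e-8)
  expect_equal(g$p, 0.9438945603787778, tolerance = 1e-8)
  expect_equal(g$decision, "normal")
  # large simulated samples decide correctly at a fixed seed
  set.seed(10)
  expect_equal(normality_gate(rnorm(500))$decision, "normal")
  expect_equal(normality_gate(rexp(500))$decision, "non-normal")
  expect_error(normality_gate(rnorm(5)), "n >= 8")
  expect_error(normality_gate(rep(3, 20)), "variance")
})

test_that("diagnosability recovers planted effects and stays empty on nulls", {
  # lineage-class design: SVL split and one trait offset
  off <- data.frame(lineage = c("3", "6", "9"), trait = "HDW", offset = 1.5)
  sp <- trait_spec(svl_mean = rep(c(22, 22, 22, 29, 29, 29, 22, 29, 22)),
                   svl_sd = 1, offsets = off)
  d <- simulate_traits(sp, n_per_lineage = 12, seed = 77)
  dm <- diagnosability_matrix(d, traits = c("SVL", "HDW"))
  m <- dm$matrix
  # symmetric content
  expect_identical(m, t(m))
  big <- c("4", "5", "6", "8")  # SVL mean 29
  small <- setdiff(rownames(m), big)
  svl_hits <- outer(rownames(m), colnames(m), Vectorize(function(i, j)
    grepl("SVL", m[i, j])))
  planted_svl <- outer(rownames(m) %in% big, colnames(m) %in% big, "!=")
  sens_svl <- sum(svl_hits & planted_svl) / sum(planted_svl)
  expect_gte(sens_svl, 0.95)
  hdw_hits <- outer(rownames(m), colnames(m), Vectorize(function(i, j)
    grepl("HDW", m[i, j])))
  off_l <- c("3", "6", "9")
  planted_hdw <- outer(rownames(m) %in% off_l, colnames(m) %in% off_l, "!=")
  expect_gte(sum(hdw_hits & planted_hdw) / sum(planted_hdw), 0.95)
})

test_that("a lineage shifted only in SVL shows SVL in every one of its cells", {
  sp <- trait_spec(lineages = c("A", "B", "C"),
                   svl_mean = c(20, 20, 30), svl_sd = 0.8)
  d <- simulate_traits(sp, n_per_lineage = 12, seed = 13)
  dm <- diagnosability_matrix(d, traits = c("SVL", "EYE"))
  m <- dm$matrix
  expect_true(grepl("SVL", m["A", "C"]))
  expect_true(grepl("SVL", m["B", "C"]))
})

test_that("regression screen matches the normal-equations oracle", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  r <- suppressWarnings(covariate_screen(d, "y", "x"))  # perfect-fit warning
  expect_equal(r$r_squared, 1)
  set.seed(12)
  d2 <- data.frame(x = rnorm(40, 25, 3))
  d2$y <- 3 + 0.2 * d2$x + rnorm(40, 0, 0.5)
  r2 <- covariate_screen(d2, "y", "x")
  X <- cbind(1, d2$x)
  beta <- solve(crossprod(X), crossprod(X, d2$y))
  res <- d2$y - X %*% beta
  r2_oracle <- 1 - sum(res^2) / sum((d2$y - mean(d2$y))^2)
  expect_equal(r2$r_squared, r2_oracle, tolerance = 1e-10)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  F_oracle <- r2_oracle / (1 - r2_oracle) * (40 - 2)
  expect_equal(r2$F, F_oracle, tolerance = 1e-8)
  expect_error(covariate_screen(data.frame(x = c(1, 1, 1), y = 1:3), "y", "x"),
               "variance")
})
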