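# The synthetic-data generators: determinism, known-truth structure,
# closed-form sequence expectations and allometric traits.

test_that("climate stacks are deterministic and low-rank as specified", {
  sp <- small_world_spec()
  a <- make_climate_stack(sp)
  b <- make_climate_stack(sp)
  expect_identical(a$layers, b$layers)
  expect_equal(length(grep("^bio", names(a$layers))), 19)
  p <- fit_pca(a, k = 5)
  expect_gte(sum(p$variance_fraction[1:3]), 0.99)
  # a different seed gives a different world
  c2 <- make_climate_stack(small_world_spec(seed = 99))
  expect_false(identical(a$layers$bio1, c2$layers$bio1))
  expect_error(world_spec(bbox = c(1, 0, 0, 1)), "degenerate")
  expect_error(world_spec(latent_rank = 25), "latent_rank")
  expect_error(world_spec(forest_fraction = 1.2), "forest_fraction")
})

test_that("single-layer stack has one component at 100%", {
  sp <- small_world_spec(n_layers = 2, latent_rank = 1, noise_sd = 0)
  st <- make_climate_stack(sp)
  p <- fit_pca(st, k = 2)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("point-mass niches put all presences at the argmax cell", {
  sp <- small_world_spec(min_presence_km = 0)
  sp$niches <- list(solo = list(axes = "PC1", optimum_q = 0.5,
                                breadth_sd = 1e-9, height = 10,
                                n_presence = 1, lineages = "1"))
  st <- make_climate_stack(sp)
  pca <- fit_pca(st, k = 3)
  pred <- project_pca(st, pca)
  np <- make_niche_and_presences(pred, sp)
  S <- np$suitability$solo
  best <- which(S == max(S))
  expect_true(np$sites$cell %in% best)
})

test_that("uniform suitability draws presences uniformly (chi-squared)", {
  sp <- small_world_spec(min_presence_km = 0)
  sp$niches <- list(flat = list(axes = "PC1", optimum_q = 0.5,
                                breadth_sd = 1e9, height = 0,
                                n_presence = 400, lineages = "1"))
  st <- make_climate_stack(sp)
  pred <- project_pca(st, fit_pca(st, k = 3))
  np <- make_niche_and_presences(pred, sp)
  expect_true(all(abs(np$suitability$flat - 0.5) < 1e-12))
  # bin drawn cells into 9 blocks; direct chi-squared against uniform
  nr <- pred$nrow
  row <- (np$sites$cell - 1) %% nr + 1
  col <- (np$sites$cell - 1) %/% nr + 1
  bin <- 3 * (pmin(floor((row - 1) / (nr / 3)), 2)) +
    pmin(floor((col - 1) / (pred$ncol / 3)), 2) + 1
  obs <- tabulate(bin, 9)
  chi2 <- sum((obs - mean(obs))^2 / mean(obs))
  expect_gt(stats::pchisq(chi2, df = 8, lower.tail = FALSE), 0.01)
})

test_that("disjoint cluster niches give spatially disjoint presence sets", {
  w <- simulate_world(small_world_spec())
  cells_n <- w$sites$cell[w$sites$cluster == "north"]
  cells_s <- w$sites$cell[w$sites$cluster == "south"]
  expect_length(intersect(cells_n, cells_s), 0)
  # presence sampling error path: more presences than positive cells
  sp <- small_world_spec()
  sp$niches$north$n_presence <- 1e7
  st <- make_climate_stack(sp)
  pred <- project_pca(st, fit_pca(st, k = 3))
  expect_error(make_niche_and_presences(pred, sp), "presences|ran out")
})

test_that("presences within a cluster are farther apart than the site radius", {
  w <- simulate_world(small_world_spec())
  for (cl in unique(w$sites$cluster)) {
    s <- w$sites[w$sites$cluster == cl, ]
    d <- c()
    for (i in seq_len(nrow(s) - 1))
      d <- c(d, haversine_km(s$lon[i], s$lat[i],
                             s$lon[(i + 1):nrow(s)], s$lat[(i + 1):nrow(s)]))
    expect_gt(min(d), 1.5)
  }
})

test_that("mask generation hits the forest fraction and disc count", {
  sp <- small_world_spec(forest_fraction = 0.5)
  st <- make_climate_stack(sp)
  m <- make_masks(st, sp)
  frac <- mean(m$forest)
  expect_gte(frac, 0.48); expect_lte(frac, 0.52)
  expect_true(any(m$protected))
  m1 <- make_masks(st, small_world_spec(forest_fraction = 1))
  expect_true(all(m1$forest))
  m0 <- make_masks(st, small_world_spec(n_protected_discs = 0))
  expect_false(any(m0$protected))
})

test_that("JC69 sequence simulation obeys the closed-form expectations", {
  # t = 0: identical tips
  sp0 <- lineage_tree_spec(newick = "(A:0,B:0);", seq_length = 300,
                           n_per_lineage = 1, within_branch = 0)
  s0 <- simulate_sequences(sp0, seed = 1)
  expect_equal(p_distance(s0$seqs[1], s0$seqs[2])$distance, 0)
  # saturation: long branches approach 0.75
  spInf <- lineage_tree_spec(newick = "(A:40,B:40);", seq_length = 4000,
                             n_per_lineage = 1, within_branch = 0)
  sInf <- simulate_sequences(spInf, seed = 2)
  expect_equal(p_distance(sInf$seqs[1], sInf$seqs[2])$distance, 0.75,
               tolerance = 0.03)
  expect_equal(jc69_expected_p(1e9), 0.75)
  expect_equal(jc69_expected_p(0), 0)
  # t = 0.05: mean observed p over 200 replicate pairs of 500 bp within 3 SE
  spt <- lineage_tree_spec(newick = "(A:0.025,B:0.025);", seq_length = 500,
                           n_per_lineage = 1, within_branch = 0)
  p_hat <- vapply(1:200, function(i) {
    s <- simulate_sequences(spt, seed = i)
    p_distance(s$seqs[1], s$seqs[2])$distance
  }, 0)
  p_exp <- jc69_expected_p(0.05)
  se <- sqrt(p_exp * (1 - p_exp) / (500 * 200))
  expect_lt(abs(mean(p_hat) - p_exp), 3 * se)
  suppressWarnings(expect_error(lineage_tree_spec(newick = "((A:1,B:"),
                                "newick"))
  expect_error(lineage_tree_spec(seq_length = 0), "positive")
})

test_that("lineage expansion produces labelled tip clusters deterministically", {
  sp <- lineage_tree_spec(seq_length = 120)
  s1 <- simulate_sequences(sp, seed = 5)
  s2 <- simulate_sequences(sp, seed = 5)
  expect_identical(s1$seqs, s2$seqs)
  expect_equal(length(s1$seqs), 27)  # 9 lineages x 3 samples
  expect_equal(sort(unique(s1$lineage)), paste0("L", 1:9))
  expect_true(all(nchar(s1$seqs) == 120))
})

test_that("trait tables are allometric, deterministic and validated", {
  sp <- trait_spec()
  t1 <- simulate_traits(sp, n_per_lineage = 5, seed = 3)
  t2 <- simulate_traits(sp, n_per_lineage = 5, seed = 3)
  expect_identical(t1, t2)
  expect_true(all(MEASUREMENTS %in% names(t1)))
  expect_equal(nrow(t1), 45)
  expect_true(all(t1$sex == "m"))
  # zero residual SD makes every trait exactly linear in SVL
  sp0 <- trait_spec(allometry = transform(default_allometry(), sd = 0))
  t0 <- simulate_traits(sp0, n_per_lineage = 4, seed = 1)
  expect_equal(t0$HDL, 0.38 * t0$SVL, tolerance = 1e-12)
  expect_equal(t0$TIB, 0.48 * t0$SVL, tolerance = 1e-12)
  expect_error(trait_spec(svl_sd = -1), "non-negative")
  # planted SVL separation is detectable by a two-sample t-test
  sp2 <- trait_spec(lineages = c("a", "b"), svl_mean = c(20, 30), svl_sd = 1)
  tt <- simulate_traits(sp2, n_per_lineage = 10, seed = 9)
  pt <- stats::t.test(SVL ~ lineage, data = tt)$p.value
  expect_lt(pt, 1e-6)
})
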