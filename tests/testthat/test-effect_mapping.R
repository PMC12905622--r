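# default synthetic cohort on a small mesh, shared across blocks
sim_small <- function(seed = 1, ...) {
  cfg <- cohort_sim_config(seed = seed, icosphere_level = 2, ...)
  simulate_cohort_maps(ico2, make_pattern(ico2), cfg)
}

test_that("delta maps subtract OFF from ON with the synchronization sign convention", {
  on <- matrix(rnorm(5 * 42), 5, dimnames = list(paste0("s", 1:5), NULL))
  d0 <- delta_maps(on, on)
  expect_true(all(d0$deltas == 0))
  d1 <- delta_maps(on + 1, on)
  expect_equal(unname(d1$deltas), matrix(1, 5, 42),
               tolerance = 1e-12)  # ON > OFF: synchronization is positive

  off_bad <- on[1:4, ]
  rownames(off_bad)[1] <- "zz"
  expect_error(delta_maps(on, off_bad), "unmatched")

  # generator round-trip: ON - OFF returns the injected fields exactly
  sim <- sim_small()
  rt <- delta_maps(sim$on, sim$off)
  expect_equal(rt$deltas, sim$deltas$deltas, tolerance = 1e-12)
})

test_that("group t-map has df n-1, masks degenerate vertices, and is calibrated", {
  sim <- sim_small()
  tm <- group_t_map(sim$deltas)
  expect_equal(tm$df, 14)
  expect_true(all(tm$p$values[tm$p$mask] > 0 & tm$p$values[tm$p$mask] <= 1))

  d <- sim$deltas$deltas
  d[, 3] <- 5  # identical nonzero delta across subjects: zero variance
  tm2 <- group_t_map(delta_map_set(d))
  expect_false(tm2$t$mask[3])

  # type-I calibration at alpha = 0.05 under a pure-noise null
  set.seed(99)
  rates <- replicate(50, {
    dn <- matrix(rnorm(15 * 162), 15)
    tmn <- group_t_map(delta_map_set(dn))
    mean(tmn$p$values < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("subgroup t-maps split, mirror, and isolate a responder-only effect", {
  sim <- sim_small(subgroup_effect = TRUE)
  labels <- sim$truth$responder
  expect_gte(sum(labels), 3)
  expect_gte(sum(!labels), 3)

  both <- subgroup_t_maps(sim$deltas, labels)
  flipped <- subgroup_t_maps(sim$deltas, !labels)
  expect_equal(both$responders$t$values, flipped$non_responders$t$values)

  all_resp <- subgroup_t_maps(sim$deltas, rep(TRUE, 15))
  expect_equal(all_resp$responders$t$values, group_t_map(sim$deltas)$t$values)
  expect_null(all_resp$non_responders)

  pat <- sim$pattern$map$values
  # responders express the planted pattern; non-responders are pure noise.
  # responder outcomes are all above the cohort mean, so their expected
  # delta is positive where the pattern is: t-map tracks +pattern
  r_t <- both$responders$t$values
  n_t <- both$non_responders$t$values
  expect_gt(cor(r_t, pat), 0.5)
  expect_lt(abs(cor(n_t, pat)), 0.2)

  expect_error(subgroup_t_maps(sim$deltas, c(rep(TRUE, 13), FALSE, FALSE)),
               "fewer than 3")
})

test_that("ROI selection follows the largest-cluster / peak-t rules", {
  n <- ico2$n_vertices
  tval <- rep(0.1, n)
  pval <- rep(0.9, n)
  # plant a 10-vertex and a 3-vertex suprathreshold cluster, well separated;
  # BFS order from vertex 1 keeps any prefix connected
  bfs <- 1L
  queue <- 1L
  while (length(bfs) < 10) {
    v <- queue[1]; queue <- queue[-1]
    new <- setdiff(ico2$adjacency[[v]], bfs)
    bfs <- c(bfs, new); queue <- c(queue, new)
  }
  c10 <- bfs[1:10]
  near <- unique(c(c10, unlist(ico2$adjacency[c10])))
  far <- setdiff(seq_len(n), near)
  anchor <- far[which.max(vapply(far, function(v)
    min(colSums((t(ico2$coords[c10, ]) - ico2$coords[v, ])^2)), 1))]
  c3 <- c(anchor, ico2$adjacency[[anchor]][1:2])
  tval[c10] <- 3; tval[c3] <- 6
  pval[c(c10, c3)] <- 0.01
  tm <- scalar_map(tval, kind = "t"); pm <- scalar_map(pval, kind = "p")
  roi <- select_roi(tm, pm, ico2)
  expect_setequal(roi$roi_vertices, c10)
  expect_equal(roi$sign, "synchronisation")

  # equal sizes: the peak-|t| cluster wins
  tval2 <- tval; tval2[c10] <- 0.1; pval2 <- pval; pval2[c10] <- 0.9
  c3b <- c10[1:3]
  tval2[c3b] <- 3.1; pval2[c3b] <- 0.01
  tval2[c3] <- 4.0
  roi2 <- select_roi(scalar_map(tval2, kind = "t"),
                     scalar_map(pval2, kind = "p"), ico2)
  expect_setequal(roi2$roi_vertices, c3)

  # negative-sign clusters are labelled suppression
  roi3 <- select_roi(scalar_map(-tval, kind = "t"),
                     scalar_map(pval, kind = "p"), ico2)
  expect_equal(roi3$sign, "suppression")

  expect_warning(empty <- select_roi(scalar_map(rep(0.1, n), kind = "t"),
                                     scalar_map(rep(0.9, n), kind = "p"), ico2),
                 "survive")
  expect_length(empty$roi_vertices, 0)
})

test_that("ROI from a planted blob overlaps the blob (Dice >= 0.5)", {
  set.seed(21)
  n <- ico2$n_vertices
  d2 <- colSums((t(ico2$coords) - ico2$coords[10, ])^2)
  blob_t <- 6 * exp(-d2 / (2 * 25^2))
  dice <- replicate(10, {
    tval <- blob_t + rnorm(n)
    pval <- 2 * pt(-abs(tval), df = 14)
    roi <- select_roi(scalar_map(tval, kind = "t"),
                      scalar_map(pval, kind = "p"), ico2)
    truth <- which(blob_t > qt(0.975, 14))
    2 * length(intersect(roi$roi_vertices, truth)) /
      (length(roi$roi_vertices) + length(truth))
  })
  expect_true(all(dice >= 0.5))
})

test_that("ROI-outcome correlation applies the explicit Bonferroni cap", {
  sim <- sim_small()
  roi <- seq_len(20)
  res <- roi_outcome_correlation(sim$deltas, roi, sim$outcomes,
                                 m_comparisons = 4)
  expect_equal(res$p_bonferroni, min(1, 4 * res$p_raw))
  expect_equal(res$m_comparisons, 4)

  # monotone outcomes: rho = 1
  md <- rowMeans(sim$deltas$deltas[, roi])
  res2 <- roi_outcome_correlation(sim$deltas, roi, md)
  expect_equal(res2$rho, 1)
  expect_equal(roi_outcome_correlation(sim$deltas, roi, -md)$rho, -1)

  # a large raw p caps at exactly 1
  set.seed(2)
  for (k in 1:20) {
    y <- rnorm(15)
    r <- roi_outcome_correlation(sim$deltas, roi, y, m_comparisons = 4)
    expect_equal(r$p_bonferroni, min(1, 4 * r$p_raw))
  }
  expect_error(roi_outcome_correlation(sim$deltas, integer(0), sim$outcomes),
               "empty")
})

test_that("R-map hits affine relationships and masks degeneracies", {
  sim <- sim_small()
  d <- sim$deltas$deltas
  d[, 7] <- 2 * sim$outcomes + 5
  rm <- r_map(delta_map_set(d), sim$outcomes)
  expect_equal(rm$map$values[7], 1)
  expect_true(all(abs(rm$map$values[rm$map$mask]) <= 1))
  expect_equal(rm$n_subjects, 15)

  d[, 8] <- 3  # constant across subjects
  rm2 <- r_map(delta_map_set(d), sim$outcomes)
  expect_false(rm2$map$mask[8])

  expect_error(r_map(sim$deltas, rep(1, 15)), "zero variance")

  # planted pattern: sign of r matches sign of the pattern at its peaks
  pat <- sim$pattern$map$values
  rm3 <- r_map(sim$deltas, sim$outcomes)
  peaks <- order(abs(pat), decreasing = TRUE)[1:20]
  expect_true(all(sign(rm3$map$values[peaks]) == sign(pat[peaks])))

  # Spearman R-maps are invariant to monotone outcome transforms
  rm4 <- r_map(sim$deltas, exp(sim$outcomes / 50))
  expect_equal(rm4$map$values, rm3$map$values)
})

test_that("R-map of outcome-independent noise is centred at zero", {
  set.seed(5)
  mean_r <- replicate(20, {
    d <- matrix(rnorm(15 * 100), 15)
    y <- rnorm(15)
    mean(r_map(delta_map_set(d), y)$map$values)
  })
  expect_lt(abs(mean(mean_r)), 0.03)
})

test_that("spatial similarity is a correlation with pairwise masking", {
  sim <- sim_small()
  rm <- r_map(sim$deltas, sim$outcomes)
  v <- rm$map$values
  expect_equal(spatial_similarity(3 * v, rm), 1)
  expect_equal(spatial_similarity(-v, rm), -1)
  set.seed(8)
  x <- sim$deltas$deltas[1, ]
  expect_equal(spatial_similarity(0.3 * x + 7, rm),
               spatial_similarity(x, rm), tolerance = 1e-12)

  small <- scalar_map(v, mask = c(rep(TRUE, 5), rep(FALSE, length(v) - 5)),
                      kind = "delta")
  expect_error(spatial_similarity(small, rm), "fewer than 10")
})

test_that("one-sided Spearman test matches a brute-force permutation oracle", {
  expect_equal(spearman_one_sided(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  rev <- spearman_one_sided(1:6, 6:1)
  expect_equal(rev$rho, -1)
  expect_gt(rev$p_one_sided, 0.95)

  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    approx <- spearman_one_sided(x, y, p_method = "t")
    exact <- spearman_one_sided(x, y, p_method = "exact")
    expect_equal(approx$rho, exact$rho)
    expect_lt(abs(approx$p_one_sided - exact$p_one_sided), 0.03)

    # independent oracle: direct enumeration over all 8! rank permutations
    rx <- rank(x); ry <- rank(y)
    perms <- expand.grid(rep(list(1:8), 8))
    perms <- as.matrix(perms[apply(perms, 1, anyDuplicated) == 0, ])
    rhos <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    expect_equal(exact$p_one_sided, mean(rhos >= exact$rho - 1e-12))
  }
  expect_error(spearman_one_sided(rep(1, 6), 1:6), "constant")
})

test_that("cross-validation is seeded, deterministic, and leak-free", {
  sim <- sim_small()
  k1 <- cross_validate(sim$deltas, sim$outcomes, "kfold", k = 4, seed = 11)
  k2 <- cross_validate(sim$deltas, sim$outcomes, "kfold", k = 4, seed = 11)
  expect_identical(k1$fold_assignment, k2$fold_assignment)
  expect_identical(k1$rho, k2$rho)
  expect_identical(k1$similarity, k2$similarity)
  expect_true(all(table(k1$fold_assignment) %in% c(3, 4)))
  expect_error(cross_validate(sim$deltas, sim$outcomes, "kfold", k = 4),
               "seed")

  # leakage: perturbing the held-out subject leaves its training R-map
  # bit-identical
  loo1 <- cross_validate(sim$deltas, sim$outcomes, "loo", store_rmaps = TRUE)
  pert <- sim$deltas
  pert$deltas[3, ] <- pert$deltas[3, ] * 100 + 7
  out_pert <- sim$outcomes
  out_pert[3] <- -999
  loo2 <- cross_validate(delta_map_set(pert$deltas), out_pert, "loo",
                         store_rmaps = TRUE)
  expect_identical(loo1$train_rmaps[[3]]$map$values,
                   loo2$train_rmaps[[3]]$map$values)
  # and the other held-out subjects' similarities are unchanged when only
  # subject 3's outcome changes (their training sets exclude outcomes of
  # held-out subjects only through the R-map)
  loo3 <- cross_validate(sim$deltas, sim$outcomes, "loo")
  expect_equal(loo1$similarity, loo3$similarity)
})

test_that("cross-validated rho is invariant to monotone outcome transforms", {
  sim <- sim_small()
  a <- cross_validate(sim$deltas, sim$outcomes, "kfold", k = 4, seed = 3,
                      sim_method = "spearman")
  b <- cross_validate(sim$deltas, 10 + exp(sim$outcomes / 60), "kfold",
                      k = 4, seed = 3, sim_method = "spearman")
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_one_sided, b$p_one_sided)
})

test_that("the noiseless cohort saturates the R-map to a sign map", {
  cfg <- cohort_sim_config(seed = 5, noise_sd = 0, icosphere_level = 2)
  sim <- simulate_cohort_maps(ico2, make_pattern(ico2), cfg)
  rm <- r_map(sim$deltas, sim$outcomes)
  expect_equal(abs(rm$map$values[rm$map$mask]),
               rep(1, sum(rm$map$mask)), tolerance = 1e-12)
  expect_equal(sign(rm$map$values), sign(sim$pattern$map$values))

  loo <- cross_validate(sim$deltas, sim$outcomes, "loo")
  co <- sim$outcomes - mean(sim$outcomes)
  # similarities collapse to a * sign(centred outcome)
  sims <- round(loo$similarity, 8)
  expect_length(unique(sims), 2)
  expect_equal(sign(sims), sign(co))
  # tie-averaged rank correlation equals the independently computed bound
  rho_tied <- cor(rank(sims), rank(sim$outcomes))
  expect_equal(rho_tied, cor(rank(sign(co)), rank(sim$outcomes)),
               tolerance = 1e-12)
  expect_gt(rho_tied, 0.8)
})
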