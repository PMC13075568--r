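test_that("fisher_z closed forms and monotonicity", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(-0.37), -fisher_z(0.37))
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-10)
  expect_equal(fisher_z(0.5), 0.549306144334, tolerance = 1e-10)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_warning(zc <- fisher_z(1), "clipped")
  expect_true(is.finite(zc))
})

test_that("dice_score hand cases and conventions", {
  m <- c(0.9, 0.5, 0.1, 0)
  expect_equal(dice_score(m, m), 1)
  expect_equal(dice_score(c(1, 0, 0, 0), c(0, 0, 1, 1)), 0)
  # worked example: thresholds 0.2 and 0.1 give (1,1,0,0) and (1,0,1,1)
  A <- c(1.0, 0.3, 0.1, 0)
  B <- c(0.5, 0.05, 0.4, 0.2)
  expect_equal(dice_score(A, B), 0.4)
  expect_warning(d0 <- dice_score(c(-1, -2), c(1, 2)), "positive")
  expect_equal(d0, 0)
  # absolute-value convention thresholds |map|
  expect_equal(dice_score(c(-1, 0.1), c(-1, 0.1), use_abs = TRUE), 1)
})

test_that("similarity_confusion: self-similarity, oracle, hemisphere masks", {
  set.seed(91)
  maps <- matrix(rnorm(4 * 20), 4)
  sim <- similarity_confusion(maps, maps)
  expect_equal(diag(sim$dice), rep(1, 4))
  expect_equal(apply(sim$fisher_z, 1, which.max), 1:4)
  expect_equal(sim$match$cap_id, 1:4)
  expect_equal(sim$match$rsn_id, 1:4)

  # loop-free vs per-pair recomputation on random sets
  for (rep in 1:5) {
    A <- matrix(rnorm(3 * 15), 3); B <- matrix(rnorm(5 * 15), 5)
    sm <- similarity_confusion(A, B)
    for (i in 1:3) for (j in 1:5) {
      expect_equal(sm$fisher_z[i, j], atanh(cor(A[i, ], B[j, ])),
                   tolerance = 1e-10)
      expect_equal(sm$dice[i, j], dice_score(A[i, ], B[j, ]))
    }
  }

  # hemisphere-restricted similarity of a left-dominant map against its
  # bilateral partner (same spatial core) exceeds the whole-map value
  core <- rnorm(20)
  cap_left <- c(1.7 * core, 0.3 * core)   # left-dominant
  rsn_bi <- c(core, core)                 # bilateral partner
  masks <- list(left = rep(c(TRUE, FALSE), each = 20),
                right = rep(c(FALSE, TRUE), each = 20))
  mt <- data.frame(cap_id = c(1, 1), rsn_id = c(1, 1),
                   hemisphere = c("left", NA))
  sm2 <- suppressWarnings(
    similarity_confusion(matrix(cap_left, 1), matrix(rsn_bi, 1),
                         match_table = mt, hemisphere_masks = masks))
  expect_gt(sm2$match$pair_z[1], sm2$match$pair_z[2])

  expect_error(similarity_confusion(maps, maps,
                                    match_table = data.frame(cap_id = 9,
                                                             rsn_id = 1)),
               "missing")
})

test_that("permutation test: exact bound, exchangeable null, conventions", {
  # identity relabelings are permitted, so with few RSNs the observed mean is
  # tied (never strictly beaten) by some null draws; with 9 RSNs and 5
  # matched pairs a permutation fixing all five matched columns is never
  # drawn in 999 tries at this seed, so the premise of the exact bound holds
  set.seed(92)
  sim <- matrix(rnorm(5 * 9), 5)
  sim[cbind(1:5, 1:5)] <- sim[cbind(1:5, 1:5)] + 10
  mt <- data.frame(cap_id = 1:5, rsn_id = 1:5)
  pt <- permutation_match_test(sim, mt, n_perm = 999, seed = 2)
  expect_lt(max(pt$null_mean), pt$observed_mean)   # premise verified
  expect_equal(pt$p_mean, 1 / 1000)

  flat <- matrix(3, 4, 4)
  ptf <- permutation_match_test(flat, data.frame(cap_id = 1:4, rsn_id = 1:4),
                                n_perm = 500, seed = 3)
  expect_equal(ptf$p_mean, 1)

  expect_error(permutation_match_test(sim, mt, n_perm = 50), "unstable")
  expect_error(permutation_match_test(sim[, 1, drop = FALSE],
                                      data.frame(cap_id = 1, rsn_id = 1),
                                      n_perm = 500), "RSNs")
})

test_that("symmetry index: forced cases and null behaviour", {
  mp <- default_mirror_pairs(20)
  v <- rnorm(10)
  sym <- c(v, v)[order(c(mp$roi_left, mp$roi_right))]
  expect_equal(symmetry_index(sym, mp), 1)
  anti <- numeric(20); anti[mp$roi_left] <- v; anti[mp$roi_right] <- -v
  expect_equal(symmetry_index(anti, mp), -1)

  # i.i.d. maps: mean index ~ -1/(R - 1) (sample-centering bias), so use
  # enough ROIs that |mean| stays under 0.05
  mp60 <- default_mirror_pairs(60)
  set.seed(93)
  idx <- replicate(1000, symmetry_index(rnorm(60), mp60))
  expect_lt(abs(mean(idx)), 0.05)

  expect_error(symmetry_index(rnorm(3), data.frame(roi_left = 1,
                                                   roi_right = 2)),
               "bijection")
})

test_that("leave-one-out consistency matches a naive loop", {
  set.seed(94)
  base <- rnorm(25)
  M <- rbind(base + rnorm(25, sd = 0.1),
             base + rnorm(25, sd = 0.1),
             base + rnorm(25, sd = 0.1),
             rnorm(25))                     # participant 4 off-template
  r <- loo_consistency(M)
  expect_gt(min(r[1:3, 1]), 0.8)
  expect_lt(abs(r[4, 1]), 0.5)
  for (p in 1:4)
    expect_equal(r[p, 1], cor(M[p, ], colMeans(M[-p, ])))

  ident <- matrix(rep(base, 3), 3, byrow = TRUE)
  expect_equal(as.numeric(loo_consistency(ident)), rep(1, 3))
  expect_error(loo_consistency(ident[1:2, ]), "participants")
})

test_that("mixed model recovers planted pattern/group effects", {
  set.seed(95)
  n <- 20
  grid <- expand.grid(participant = 1:n, pattern = c("CAP", "RSN"),
                      group = c("SM", "HO", "Other"))
  eff <- c(SM = 0.4, HO = 0.2, Other = 0)[as.character(grid$group)] +
    c(CAP = 0.3, RSN = 0)[as.character(grid$pattern)]
  part <- rnorm(n, sd = 0.05)[grid$participant]
  grid$z <- 1 + eff + part + rnorm(nrow(grid), sd = 0.05)
  fit <- consistency_mixed_model(grid)
  fx <- fit$fixed
  expect_lt(fx["patternRSN", "p"], 0.01)
  expect_lt(fx["groupHO", "p"], 0.01)      # SM vs HO
  expect_lt(fx["groupOther", "p"], 0.01)   # SM vs Other
  expect_lt(fx["patternRSN", "Estimate"], 0)
  expect_lt(fx["groupOther", "Estimate"], fx["groupHO", "Estimate"])

  # random-intercept sd recovered within 50% at a larger participant sd
  set.seed(96)
  n2 <- 30
  g2 <- expand.grid(participant = 1:n2, pattern = c("CAP", "RSN"),
                    group = c("SM", "HO", "Other"), rep = 1:4)
  g2$z <- rnorm(n2, sd = 0.3)[g2$participant] + rnorm(nrow(g2), sd = 0.1)
  f2 <- consistency_mixed_model(g2)
  expect_gt(f2$random_intercept_sd, 0.15)
  expect_lt(f2$random_intercept_sd, 0.45)

  # identical values everywhere: no significant contrasts (singular fit ok)
  g3 <- grid; g3$z <- 1
  f3 <- consistency_mixed_model(g3)
  expect_true(all(f3$fixed[-1L, "p"] > 0.9, na.rm = TRUE))
})

test_that("beta/consistency correlation: forced and null cases", {
  set.seed(97)
  np <- 8; k <- 3; R <- 40
  loo <- matrix(runif(np * k, 0.2, 0.9), np)
  group <- matrix(rnorm(k * R), k)
  betas <- array(0, c(np, k, R))
  for (j in 1:k) {
    mask <- order(group[j, ], decreasing = TRUE)[1:2]
    for (p in 1:np) betas[p, j, ] <- 0
    for (p in 1:np) betas[p, j, mask] <- loo[p, j]    # proportional
  }
  bc <- beta_consistency_correlation(betas, group, loo, mask_frac = 0.05)
  expect_equal(bc$r, 1, tolerance = 1e-10)

  # independent betas and consistencies: calibrated type-I error
  set.seed(98)
  sig <- 0L
  for (rep in 1:500) {
    b <- matrix(rnorm(24), 8)
    l <- matrix(rnorm(24), 8)
    ct <- cor.test(as.numeric(b), as.numeric(l))
    if (ct$p.value < 0.05) sig <- sig + 1L
  }
  expect_lt(sig / 500, 0.08)

  # hand 4-point dataset against closed-form r
  b4 <- array(c(1, 2, 3, 4), c(4, 1, 1))
  g4 <- matrix(1, 1, 1)
  l4 <- matrix(c(1.2, 1.9, 3.4, 3.8), 4)
  bc4 <- beta_consistency_correlation(b4, g4, l4, mask_frac = 1)
  expect_equal(bc4$r, cor(c(1, 2, 3, 4), c(1.2, 1.9, 3.4, 3.8)))
})

test_that("temporal correspondence: identity pair, null mean, planted pair", {
  set.seed(99)
  Tn <- 300
  env <- matrix(rnorm(6 * Tn), 6)
  caps <- env[1:4, ] + matrix(rnorm(4 * Tn, sd = 0.05), 4)
  tcres <- temporal_correspondence(
    list(caps), list(env),
    match_table = data.frame(cap_id = 1:4, rsn_id = 1:4),
    n_perm = 500, seed = 1)
  expect_gt(min(diag(tcres$z_mean[, 1:4])), 2)
  expect_lt(tcres$test$p_mean, 0.01)

  # independent series: mean z near zero across 100 participants
  zs <- replicate(100, {
    a <- matrix(rnorm(Tn), 1); b <- matrix(rnorm(Tn), 1)
    atanh(cor(a[1, ], b[1, ]))
  })
  expect_lt(abs(mean(zs)), 0.05)

  # planted cohort: one CAP's time course drives one IC envelope
  set.seed(100)
  parts <- lapply(1:4, function(p) {
    drive <- rnorm(Tn)
    caps_p <- rbind(drive, rnorm(Tn), rnorm(Tn))
    env_p <- rbind(rnorm(Tn), 0.8 * drive + 0.6 * rnorm(Tn))
    list(caps = caps_p, env = env_p)
  })
  res <- temporal_correspondence(lapply(parts, `[[`, "caps"),
                                 lapply(parts, `[[`, "env"),
                                 n_perm = 500, seed = 2)
  matched_z <- res$z_mean[1, 2]
  expect_true(all(matched_z > res$z_mean[-1, ]))
  expect_equal(res$match$rsn_id[res$match$cap_id == 1], 2)
})
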