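test_that("templates honour symmetry structure and determinism", {
  tpl <- make_templates(40, 6, seed = 3)
  mp <- tpl$mirror_pairs

  bil <- which(tpl$mirror_spec == "bilateral")
  for (j in bil)
    expect_equal(tpl$templates[j, mp$roi_left],
                 tpl$templates[j, mp$roi_right])
  expect_equal(symmetry_index(tpl$templates[bil[1L], ], mp), 1)

  ld <- which(tpl$mirror_spec == "left-dominant")[1L]
  mirrored <- capnet:::mirror_map(tpl$templates[ld, ], mp)
  expect_gte(cor(mirrored, tpl$templates[ld + 1L, ]), 0.8)

  expect_true(all(apply(tpl$templates, 1L, sd) > 0))
  expect_identical(tpl$templates, make_templates(40, 6, seed = 3)$templates)
  expect_false(identical(tpl$templates,
                         make_templates(40, 6, seed = 4)$templates))
})

test_that("degenerate bilateral template is exactly mirror-symmetric", {
  tpl <- make_templates(4, 1, mirror_spec = "bilateral", seed = 1)
  mp <- tpl$mirror_pairs
  expect_equal(tpl$templates[1L, mp$roi_left], tpl$templates[1L, mp$roi_right])
  expect_equal(symmetry_index(tpl$templates[1L, ], mp), 1)
})

test_that("hierarchy: parents are normalized child sums and dominate siblings", {
  tpl <- make_templates(60, 6, hierarchy_depth = 1L, seed = 7)
  expect_length(tpl$hierarchy, 3L)
  for (p in seq_along(tpl$hierarchy)) {
    ch <- tpl$hierarchy[[p]]
    v <- colSums(tpl$templates[ch, ])
    expect_equal(tpl$parents[p, ], v / sqrt(sum(v^2)))
    r_sib <- cor(tpl$templates[ch[1L], ], tpl$templates[ch[2L], ])
    r_par1 <- cor(tpl$templates[ch[1L], ], tpl$parents[p, ])
    r_par2 <- cor(tpl$templates[ch[2L], ], tpl$parents[p, ])
    expect_lt(r_sib, r_par1)
    expect_lt(r_sib, r_par2)
  }
})

test_that("broken mirror tables are rejected with a clear message", {
  bad <- data.frame(roi_left = c(1, 2), roi_right = c(3, 3))
  expect_error(make_templates(4, 2, mirror_pairs = bad), "bijection")
  expect_error(make_templates(5, 2), "even")
})

test_that("state sequences: degenerate case, determinism, dwell target", {
  one <- simulate_state_sequence(2, 100, occ_rates = 1, mean_dwell_ms = 50,
                                 seed = 1)
  expect_true(all(one$labels == 1L))
  expect_equal(nrow(compute_runs(one$labels, 100)$runs), 1L)

  a <- simulate_state_sequence(60, 250, rep(0.7, 6), 80, seed = 5)
  b <- simulate_state_sequence(60, 250, rep(0.7, 6), 80, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_length(a$labels, 60 * 250)
  expect_true(all(a$labels %in% 1:6))

  # design point: 80 ms dwell at 250 Hz, 600 s -> empirical mean in [72, 88]
  st <- suppressWarnings(
    simulate_state_sequence(600, 250, rep(0.7, 6), 80, seed = 2))
  dwell_ms <- mean(rle(st$labels)$lengths) * 1000 / 250
  expect_gte(dwell_ms, 72)
  expect_lte(dwell_ms, 88)
})

test_that("over-committed rates warn and renormalize", {
  expect_warning(simulate_state_sequence(10, 250, rep(0.9, 20), 80, seed = 1),
                 "occupancy")
  es <- expected_state_stats(rep(0.7, 6), 80, 250)
  expect_equal(sum(es$run_share), 1)
  # rates scale to fill the recording: total rate = 1 / mean dwell
  expect_equal(sum(es$occurrence_rate_hz), 1 / 0.08)
})

test_that("noiseless envelopes reproduce the active template frame-by-frame", {
  tpl <- make_templates(30, 3, seed = 2)
  st <- simulate_state_sequence(4, 250, rep(0.7, 3), 80, seed = 2)
  co <- simulate_roi_envelopes(tpl, st, snr = Inf, n_participants = 1,
                               participant_sigma_by_group =
                                 c(SM = 0, HO = 0, Other = 0), seed = 9)
  lab <- co$states[[1L]]$labels
  # interior frames of each run carry a clean scaled copy of the template
  a <- capnet:::half_cosine_activation(lab)
  keep <- a > 0.2
  rr <- capnet:::row_cor(t(co$env[[1L]][, keep]),
                         tpl$templates)
  expect_true(all(rr[cbind(seq_len(sum(keep)), lab[keep])] > 0.99))
})

test_that("cohorts are reproducible and carry full ground truth", {
  tpl <- make_templates(20, 3, seed = 1)
  st <- simulate_state_sequence(3, 100, rep(0.7, 3), 80, seed = 1)
  c1 <- simulate_roi_envelopes(tpl, st, snr = 0.5, n_participants = 3,
                               seed = 4)
  c2 <- simulate_roi_envelopes(tpl, st, snr = 0.5, n_participants = 3,
                               seed = 4)
  expect_identical(c1$env, c2$env)
  expect_identical(c1$states[[2L]]$labels, c2$states[[2L]]$labels)
  expect_length(c1$env, 3L)
  expect_length(c1$participant_templates, 3L)
  # participants share template identities but not exact loadings
  expect_gt(cor(c1$participant_templates[[1L]][3L, ], tpl$templates[3L, ]),
            0.7)
  expect_false(identical(c1$participant_templates[[1L]],
                         c1$participant_templates[[2L]]))
})

test_that("lead fields are full row rank and dimension-checked", {
  lf <- make_lead_field(32, 400, seed = 1)
  expect_equal(qr(lf$L)$rank, 32L)
  expect_error(make_lead_field(10, 10), "underdetermined")
})

test_that("sensor EEG obeys the forward identity in the noiseless limit", {
  tpl <- make_templates(40, 2, seed = 6)
  st <- simulate_state_sequence(2, 250, rep(0.7, 2), 80, seed = 6)
  lf <- make_lead_field(8, 40, seed = 6)
  ss <- simulate_sensor_eeg(lf, tpl, st, snr = Inf, seed = 6)
  expect_equal(ss$phi, lf$L %*% ss$sources, tolerance = 1e-12)
  expect_equal(ss$carrier_hz, 10)
})

test_that("envelope pipeline tracks the planted modulation on true sources", {
  tpl <- make_templates(40, 2, seed = 8)
  # slow fixed-length dwells (1 s) keep AM sidebands inside the alpha band
  st <- simulate_state_sequence(20, 250, rep(0.7, 2), 1000, seed = 8,
                                dwell_dist = "fixed")
  lf <- make_lead_field(8, 40, seed = 8)
  ss <- simulate_sensor_eeg(lf, tpl, st, snr = Inf, seed = 8)
  env <- hilbert_envelope(bandpass_alpha(ss$sources, 250))
  trim <- 250
  keep <- (trim + 1L):(ncol(env) - trim)
  # per-source RMS error against the known modulator, relative to its scale
  err <- sqrt(rowMeans((env[, keep] - ss$modulators[, keep])^2))
  expect_lt(median(err / sqrt(rowMeans(ss$modulators[, keep]^2))), 0.05)
})
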