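# CAP-RSN correspondence statistics ------------------------------------------

#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`; values with `|r| >= 1` are clipped to `+-(1 - 1e-7)` with
#' a warning.
#'
#' @param r correlation value(s).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clipped before Fisher transform", call. = FALSE)
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Dice overlap of thresholded spatial maps
#'
#' Each signed map is binarized at `threshold_frac` of its own maximum
#' (positive values by default; `use_abs = TRUE` thresholds `|map|` at a
#' fraction of `max |map|`), then `dice = 2 |A & B| / (|A| + |B|)`. An empty
#' binarized map yields 0 with a warning.
#'
#' @param mapA,mapB numeric vectors of equal length.
#' @param threshold_frac fraction of the per-map maximum (default 0.2).
#' @param use_abs threshold absolute values instead of positive values.
#' @return dice score in `[0, 1]`.
#' @export
dice_score <- function(mapA, mapB, threshold_frac = 0.2, use_abs = FALSE) {
  stopifnot(length(mapA) == length(mapB))
  bin <- function(m) {
    v <- if (use_abs) abs(m) else m
    mx <- max(v)
    if (mx <= 0) {
      warning("map has no positive values; binarized map empty",
              call. = FALSE)
      return(rep(FALSE, length(m)))
    }
    v >= threshold_frac * mx
  }
  a <- bin(mapA); b <- bin(mapB)
  denom <- sum(a) + sum(b)
  if (denom == 0L) {
    warning("both binarized maps empty; dice defined 0", call. = FALSE)
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Optimal one-to-one CAP-RSN matching
#'
#' Hungarian-style assignment maximizing total Fisher-z spatial correlation
#' (absolute value optionally), standing in for the visual matching used on
#' real data. Rectangular matrices are matched on the smaller dimension.
#'
#' @param cap_maps n_cap x R matrix.
#' @param rsn_maps n_rsn x R matrix.
#' @param use_abs match on `|r|` (default TRUE).
#' @return data.frame `cap_id`, `rsn_id`, `r`.
#' @export
match_maps <- function(cap_maps, rsn_maps, use_abs = TRUE) {
  rr <- row_cor(cap_maps, rsn_maps)
  score <- fisher_z(if (use_abs) abs(rr) else rr)
  flip <- nrow(score) > ncol(score)
  sc <- if (flip) t(score) else score
  sol <- clue::solve_LSAP(sc - min(sc) + 1e-9, maximum = TRUE)
  i <- seq_along(sol)
  out <- if (flip) data.frame(cap_id = as.integer(sol), rsn_id = i)
         else data.frame(cap_id = i, rsn_id = as.integer(sol))
  out$r <- rr[cbind(out$cap_id, out$rsn_id)]
  out[order(out$cap_id), , drop = FALSE]
}

#' CAP x RSN similarity confusion matrices
#'
#' Computes the full matrix of Fisher-z spatial correlations and of dice
#' scores between all CAP and RSN maps. Matched pairs come from
#' `match_table` (columns `cap_id`, `rsn_id`, optional `hemisphere` with
#' values `"left"`/`"right"` restricting that pair's similarity to one
#' hemisphere mask) or, when omitted, from [match_maps()]. One-to-two
#' matches are expressed as two hemisphere-tagged rows.
#'
#' @param cap_maps n_cap x R matrix.
#' @param rsn_maps n_rsn x R matrix in the same ROI space.
#' @param match_table optional data.frame of matched pairs.
#' @param hemisphere_masks optional list with logical vectors `left` and
#'   `right` over the ROI space (required for hemisphere-tagged pairs).
#' @param threshold_frac dice threshold fraction.
#' @return object of class `capnet_similarity`: `fisher_z` and `dice`
#'   matrices (n_cap x n_rsn), `match` (the table, with per-pair values
#'   `pair_z` and `pair_dice`), `metrics` tag.
#' @export
similarity_confusion <- function(cap_maps, rsn_maps, match_table = NULL,
                                 hemisphere_masks = NULL,
                                 threshold_frac = 0.2) {
  assert_matrix(cap_maps, "cap_maps")
  assert_matrix(rsn_maps, "rsn_maps")
  if (ncol(cap_maps) != ncol(rsn_maps))
    stop_capnet("maps live in different ROI spaces")
  zmat <- fisher_z(row_cor(cap_maps, rsn_maps))
  dmat <- matrix(0, nrow(cap_maps), nrow(rsn_maps))
  for (i in seq_len(nrow(cap_maps))) for (j in seq_len(nrow(rsn_maps)))
    dmat[i, j] <- dice_score(cap_maps[i, ], rsn_maps[j, ], threshold_frac)
  if (is.null(match_table)) {
    match_table <- match_maps(cap_maps, rsn_maps)
    match_table$hemisphere <- NA_character_
  } else {
    match_table <- as.data.frame(match_table)
    if (!all(c("cap_id", "rsn_id") %in% names(match_table)))
      stop_capnet("match table needs `cap_id` and `rsn_id`")
    if (is.null(match_table$hemisphere))
      match_table$hemisphere <- NA_character_
    if (any(match_table$cap_id > nrow(cap_maps)) ||
        any(match_table$rsn_id > nrow(rsn_maps)))
      stop_capnet("match table references missing CAP/RSN ids")
  }
  pz <- pd <- numeric(nrow(match_table))
  for (m in seq_len(nrow(match_table))) {
    ci <- match_table$cap_id[m]; ri <- match_table$rsn_id[m]
    hemi <- match_table$hemisphere[m]
    if (!is.na(hemi)) {
      if (is.null(hemisphere_masks))
        stop_capnet("hemisphere-tagged pair but no hemisphere_masks given")
      mask <- hemisphere_masks[[hemi]]
      a <- cap_maps[ci, mask]; b <- rsn_maps[ri, mask]
      pz[m] <- fisher_z(stats::cor(a, b))
      pd[m] <- dice_score(a, b, threshold_frac)
    } else {
      pz[m] <- zmat[ci, ri]
      pd[m] <- dmat[ci, ri]
    }
  }
  match_table$pair_z <- pz
  match_table$pair_dice <- pd
  structure(list(fisher_z = zmat, dice = dmat, match = match_table,
                 threshold_frac = threshold_frac),
            class = "capnet_similarity")
}

#' Permutation test of matched-pair similarity
#'
#' Null distribution built by relabeling RSN columns uniformly at random
#' (identity permitted) `n_perm` times and recomputing the mean similarity
#' over the fixed matched mask. `p = (1 + #{null >= observed}) /
#' (1 + n_perm)`; per-pair p-values use the same permutation draws and are
#' reported raw and Bonferroni-corrected over matched pairs.
#'
#' @param sim matrix of similarity values (n_cap x n_rsn), or a
#'   [similarity_confusion()] result (its Fisher-z matrix is used unless
#'   `metric = "dice"`).
#' @param match_table data.frame with `cap_id`, `rsn_id` (taken from `sim`
#'   when it is a `capnet_similarity`).
#' @param n_perm number of permutations (>= 100; default 100000).
#' @param seed integer seed.
#' @param metric which stored matrix to use for `capnet_similarity` input.
#' @return list: `observed_mean`, `p_mean`, per-pair data.frame (`pair_p`,
#'   `pair_p_bonferroni`), `n_perm`.
#' @export
permutation_match_test <- function(sim, match_table = NULL, n_perm = 100000L,
                                   seed = 1L,
                                   metric = c("fisher_z", "dice")) {
  metric <- match.arg(metric)
  if (inherits(sim, "capnet_similarity")) {
    if (is.null(match_table)) match_table <- sim$match
    sim <- sim[[metric]]
  }
  assert_matrix(sim, "sim")
  if (ncol(sim) < 2L) stop_capnet("need >= 2 RSNs to permute")
  if (n_perm < 100L) stop_capnet("n_perm < 100 gives unstable p-values")
  if (is.null(match_table)) stop_capnet("match_table required")
  ci <- match_table$cap_id; ri <- match_table$rsn_id
  obs_pairs <- sim[cbind(ci, ri)]
  obs_mean <- mean(obs_pairs)
  n_rsn <- ncol(sim)
  null_mean <- numeric(n_perm)
  null_ge_pair <- integer(length(ci))
  with_seed(derive_seed(seed, "permutation"), {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_rsn)
      vals <- sim[cbind(ci, perm[ri])]
      null_mean[b] <- mean(vals)
      null_ge_pair <- null_ge_pair + (vals >= obs_pairs)
    }
  })
  p_mean <- (1 + sum(null_mean >= obs_mean)) / (1 + n_perm)
  pair_p <- (1 + null_ge_pair) / (1 + n_perm)
  pairs <- data.frame(cap_id = ci, rsn_id = ri, observed = obs_pairs,
                      pair_p = pair_p,
                      pair_p_bonferroni = pmin(1, pair_p * length(ci)))
  list(observed_mean = obs_mean, p_mean = p_mean, pairs = pairs,
       null_mean = null_mean, n_perm = n_perm)
}

#' Hemispheric symmetry index
#'
#' Pearson correlation between a spatial map and its hemisphere-swapped copy
#' over mirror-paired ROIs. For a unilateral pair, pass one member as `map`
#' and its partner as `partner`: the index is then the correlation between
#' the partner and the mirrored map.
#'
#' @param map numeric vector over the mirror-paired ROI space.
#' @param mirror_pairs bijection table (`roi_left`, `roi_right`).
#' @param partner optional partner map for unilateral pairs.
#' @return correlation in `[-1, 1]`.
#' @export
symmetry_index <- function(map, mirror_pairs, partner = NULL) {
  mp <- validate_mirror_pairs(mirror_pairs, length(map))
  mirrored <- mirror_map(map, mp)
  ref <- if (is.null(partner)) map else partner
  stats::cor(ref, mirrored)
}

#' Leave-one-out inter-participant consistency
#'
#' For each participant and CAP, the Pearson correlation between the
#' participant's map and the mean map of all other participants possessing
#' that CAP. Missing maps (participant lacks the CAP) give `NA`.
#'
#' @param participant_maps participant x R matrix for one CAP, or a
#'   participant x k x R array for all CAPs.
#' @return matrix participant x k of correlations (a 1-column matrix for
#'   matrix input).
#' @export
loo_consistency <- function(participant_maps) {
  if (is.matrix(participant_maps))
    participant_maps <- array(participant_maps,
                              c(nrow(participant_maps), 1L,
                                ncol(participant_maps)))
  np <- dim(participant_maps)[1L]
  k <- dim(participant_maps)[2L]
  if (np < 3L) stop_capnet("need >= 3 participants")
  out <- matrix(NA_real_, np, k)
  for (j in seq_len(k)) {
    M <- participant_maps[, j, ]       # np x R
    have <- which(stats::complete.cases(M))
    if (length(have) < 3L) next
    for (p in have) {
      others <- setdiff(have, p)
      out[p, j] <- stats::cor(M[p, ], colMeans(M[others, , drop = FALSE]))
    }
  }
  out
}

#' Mixed-effect model of consistency scores
#'
#' Fits `z ~ pattern * group + (1 | participant)` by REML (lme4) on
#' Fisher-z consistency values and reports fixed-effect contrasts of
#' interest: CAP vs RSN, and the SM/HO/Other gradient, with Wald p-values.
#' A singular fit falls back to a fixed-effects-only linear model (logged).
#'
#' @param z_scores data.frame with columns `z`, `pattern` (CAP/RSN),
#'   `group` (SM/HO/Other), `participant`.
#' @param interaction include the pattern:group interaction (default FALSE).
#' @return list: `fit`, `fixed` (coefficient table with p-values),
#'   `singular` flag, `random_intercept_sd`.
#' @export
consistency_mixed_model <- function(z_scores, interaction = FALSE) {
  d <- as.data.frame(z_scores)
  stopifnot(all(c("z", "pattern", "group", "participant") %in% names(d)))
  d$pattern <- factor(d$pattern)
  d$group <- factor(d$group, levels = intersect(c("SM", "HO", "Other"),
                                                unique(as.character(d$group))))
  if (nlevels(d$pattern) < 1L || nlevels(d$group) < 2L)
    stop_capnet("need >= 2 levels per factor")
  form <- if (nlevels(d$pattern) > 1L) {
    if (interaction) z ~ pattern * group + (1 | participant)
    else z ~ pattern + group + (1 | participant)
  } else z ~ group + (1 | participant)
  if (stats::sd(d$z) == 0) {
    # constant response carries no evidence for any contrast
    co <- data.frame(Estimate = 0, `Std. Error` = NA_real_,
                     `t value` = NA_real_, p = 1, check.names = FALSE,
                     row.names = "(Intercept)")
    return(list(fit = NULL, fixed = co, singular = TRUE,
                random_intercept_sd = 0))
  }
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE))), error = function(e) NULL)
  co_try <- if (is.null(fit)) NULL else
    tryCatch(as.data.frame(summary(fit)$coefficients),
             error = function(e) NULL)
  if (is.null(fit) || is.null(co_try)) {
    # degenerate data (e.g. constant response): fixed-effects-only fallback
    capnet_log("mixed fit failed; falling back to fixed effects only")
    ffit <- stats::lm(lme4::nobars(form), data = d)
    co <- as.data.frame(summary(ffit)$coefficients)
    names(co)[4L] <- "p"
    return(list(fit = ffit, fixed = co, singular = TRUE,
                random_intercept_sd = NA_real_))
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    capnet_log("singular mixed fit; falling back to fixed effects only")
    ffit <- stats::lm(lme4::nobars(form), data = d)
    co <- as.data.frame(summary(ffit)$coefficients)
    names(co)[4L] <- "p"
    vc <- as.data.frame(lme4::VarCorr(fit))
    return(list(fit = ffit, fixed = co, singular = TRUE,
                random_intercept_sd = vc$sdcor[vc$grp == "participant"][1L]))
  }
  co <- as.data.frame(summary(fit)$coefficients)
  # Wald p-values on the t statistics (normal approximation)
  co$p <- 2 * stats::pnorm(-abs(co[["t value"]]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit, fixed = co, singular = FALSE,
       random_intercept_sd = vc$sdcor[vc$grp == "participant"][1L])
}

#' Beta-magnitude vs consistency correlation
#'
#' For each participant and component: mean beta inside the top-`mask_frac`
#' region of the group map; correlated against the LOO consistency scores
#' across all pooled (participant, component) observations.
#'
#' @param participant_beta_maps participant x k x R array of beta maps.
#' @param group_maps k x R matrix of group beta maps.
#' @param loo_scores participant x k matrix from [loo_consistency()].
#' @param mask_frac top fraction of the group map defining the mask
#'   (default 0.05).
#' @return list: `r`, `p`, `n`, and the pooled data.frame.
#' @export
beta_consistency_correlation <- function(participant_beta_maps, group_maps,
                                         loo_scores, mask_frac = 0.05) {
  np <- dim(participant_beta_maps)[1L]
  k <- dim(participant_beta_maps)[2L]
  R <- dim(participant_beta_maps)[3L]
  stopifnot(nrow(group_maps) == k, ncol(group_maps) == R)
  n_mask <- max(1L, ceiling(mask_frac * R))
  rows <- list()
  for (j in seq_len(k)) {
    mask <- order(group_maps[j, ], decreasing = TRUE)[seq_len(n_mask)]
    for (p in seq_len(np)) {
      b <- mean(participant_beta_maps[p, j, mask])
      rows[[length(rows) + 1L]] <-
        data.frame(participant = p, component = j, mean_beta = b,
                   consistency = loo_scores[p, j])
    }
  }
  d <- do.call(rbind, rows)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3L || stats::sd(d$mean_beta) == 0 ||
      stats::sd(d$consistency) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(d), data = d))
  ct <- stats::cor.test(d$mean_beta, d$consistency)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d), data = d)
}

#' Temporal correspondence between CAP time courses and IC envelopes
#'
#' Per participant, Pearson correlation over time between every CAP time
#' course and every component envelope; Fisher-z transformed and averaged
#' across participants; permutation null as in [permutation_match_test()].
#'
#' @param cap_tc_by_participant list of k x T matrices.
#' @param ic_env_by_participant list of components x T matrices (same T per
#'   participant).
#' @param match_table data.frame `cap_id`, `rsn_id` (component); if NULL the
#'   optimal assignment on the averaged z matrix is used.
#' @param n_perm permutations for the significance test (default 10000).
#' @param seed integer seed.
#' @return list: `z_mean` (k x components averaged Fisher-z matrix), `test`
#'   (permutation result), `match`.
#' @export
temporal_correspondence <- function(cap_tc_by_participant,
                                    ic_env_by_participant,
                                    match_table = NULL, n_perm = 10000L,
                                    seed = 1L) {
  np <- length(cap_tc_by_participant)
  stopifnot(np == length(ic_env_by_participant), np >= 1L)
  acc <- NULL
  for (p in seq_len(np)) {
    ct <- cap_tc_by_participant[[p]]
    ie <- ic_env_by_participant[[p]]
    if (ncol(ct) != ncol(ie))
      stop_capnet("participant %d: time axes differ (%d vs %d)",
                  p, ncol(ct), ncol(ie))
    ok <- stats::complete.cases(t(ct))
    z <- fisher_z(row_cor(ct[, ok, drop = FALSE], ie[, ok, drop = FALSE]))
    acc <- if (is.null(acc)) z else acc + z
  }
  z_mean <- acc / np
  if (is.null(match_table)) {
    flip <- nrow(z_mean) > ncol(z_mean)
    sc <- if (flip) t(z_mean) else z_mean
    sol <- clue::solve_LSAP(sc - min(sc) + 1e-9, maximum = TRUE)
    match_table <- if (flip)
      data.frame(cap_id = as.integer(sol), rsn_id = seq_along(sol))
    else data.frame(cap_id = seq_along(sol), rsn_id = as.integer(sol))
  }
  test <- permutation_match_test(z_mean, match_table, n_perm = n_perm,
                                 seed = seed)
  list(z_mean = z_mean, test = test, match = match_table)
}
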