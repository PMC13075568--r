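# CAP temporal metrics: occurrences, lifetimes, time courses, group tests ----

#' Run-length encode a label series into occurrences
#'
#' An occurrence of a CAP is a maximal run of consecutive frames with the
#' same label (single-frame runs count; use `min_run = 2` to exclude them).
#' Occurrence rate is the run count divided by the recording duration (Hz);
#' lifetime is the run length in ms.
#'
#' @param labels integer (or factor) label series.
#' @param fs sampling rate in Hz.
#' @param participant participant id recorded in the table.
#' @param min_run minimum run length (frames) for a run to count (default 1).
#' @return object of class `capnet_runs`: `runs` (data.frame participant,
#'   cap_id, start_frame, run_length_frames, lifetime_ms) and `summary`
#'   (data.frame cap_id, n_occurrences, occurrence_rate_hz,
#'   mean_lifetime_ms; caps with zero runs get rate 0 and lifetime `NA`).
#' @export
compute_runs <- function(labels, fs, participant = 1L, min_run = 1L) {
  stopifnot(length(labels) >= 1L, fs > 0)
  r <- rle(as.integer(labels))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  runs <- data.frame(participant = participant,
                     cap_id = r$values,
                     start_frame = start,
                     run_length_frames = r$lengths,
                     lifetime_ms = r$lengths * 1000 / fs)
  runs <- runs[runs$run_length_frames >= min_run, , drop = FALSE]
  duration_s <- length(labels) / fs
  caps <- seq_len(max(as.integer(labels)))
  summ <- do.call(rbind, lapply(caps, function(j) {
    rj <- runs[runs$cap_id == j, , drop = FALSE]
    data.frame(cap_id = j, n_occurrences = nrow(rj),
               occurrence_rate_hz = nrow(rj) / duration_s,
               mean_lifetime_ms = if (nrow(rj)) mean(rj$lifetime_ms) else NA_real_)
  }))
  structure(list(runs = runs, summary = summ, fs = fs,
                 duration_s = duration_s, participant = participant),
            class = "capnet_runs")
}

#' Per-participant temporal metrics for a cohort of label series
#'
#' @param labels_by_participant list of label series.
#' @param fs sampling rate in Hz.
#' @param min_run as in [compute_runs()].
#' @return data.frame (participant, cap_id, occurrence_rate_hz,
#'   mean_lifetime_ms).
#' @export
cohort_run_metrics <- function(labels_by_participant, fs, min_run = 1L) {
  out <- lapply(seq_along(labels_by_participant), function(p) {
    s <- compute_runs(labels_by_participant[[p]], fs, participant = p,
                      min_run = min_run)$summary
    cbind(participant = p, s)
  })
  do.call(rbind, out)
}

#' CAP time courses
#'
#' Spatial Pearson correlation between each group CAP map and the z-scored
#' ROI frame, at every timeframe. Frames with zero spatial variance get `NA`.
#'
#' @param group_maps k x R matrix of CAP maps.
#' @param frames a [zscore_rois()] result or a bare R x T matrix.
#' @return k x T matrix of correlations in `[-1, 1]` (`NA` for degenerate
#'   frames).
#' @export
cap_time_courses <- function(group_maps, frames) {
  Z <- if (inherits(frames, "capnet_frames")) frames$Z else frames
  assert_matrix(group_maps, "group_maps")
  if (nrow(group_maps) < 1L || ncol(group_maps) != nrow(Z))
    stop_capnet("ROI spaces differ: maps have %d ROIs, frames %d",
                ncol(group_maps), nrow(Z))
  Gc <- group_maps - rowMeans(group_maps)
  Gc <- Gc / sqrt(rowSums(Gc^2))
  Fc <- Z - rep(colMeans(Z), each = nrow(Z))
  nrm <- sqrt(colSums(Fc^2))
  tc <- Gc %*% Fc
  tc <- sweep(tc, 2L, nrm, "/")
  tc[, nrm == 0] <- NA_real_
  tc
}

#' Group statistical tests on temporal metrics
#'
#' One-way ANOVA across CAPs on natural-log-transformed per-participant
#' metric values, followed by post-hoc pairwise t-tests with Bonferroni
#' correction over all `k (k - 1) / 2` CAP pairs (190 at k = 20). Zero or
#' missing values are excluded from the log transform with a warning.
#'
#' @param metrics data.frame with columns `participant`, `cap_id`, and the
#'   metric named by `value_col`.
#' @param value_col metric column, e.g. `"occurrence_rate_hz"` or
#'   `"mean_lifetime_ms"`.
#' @return list with `anova` (data.frame F, df, p), `pairwise` (k x k matrix
#'   of Bonferroni-corrected p-values, capped at 1), `n_pairs`,
#'   `bonferroni_factor`.
#' @export
temporal_group_tests <- function(metrics, value_col = "occurrence_rate_hz") {
  stopifnot(value_col %in% names(metrics))
  v <- metrics[[value_col]]
  keep <- !is.na(v) & v > 0
  if (any(!keep))
    warning(sprintf("%d non-positive/missing values excluded from log tests",
                    sum(!keep)), call. = FALSE)
  d <- data.frame(y = log(v[keep]),
                  cap = factor(metrics$cap_id[keep]),
                  participant = metrics$participant[keep])
  k <- nlevels(d$cap)
  if (k < 2L) stop_capnet("need >= 2 CAPs")
  cnt <- table(d$cap)
  if (any(cnt < 2L))
    capnet_log("caps with < 2 participants excluded pairwise: %s",
               paste(names(cnt)[cnt < 2L], collapse = ", "))
  fit <- stats::aov(y ~ cap, data = d)
  an <- summary(fit)[[1L]]
  n_pairs <- (k * (k - 1L)) %/% 2L
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(d$cap), levels(d$cap)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    yi <- d$y[d$cap == levels(d$cap)[i]]
    yj <- d$y[d$cap == levels(d$cap)[j]]
    if (length(yi) < 2L || length(yj) < 2L) next
    # essentially-constant data carry no evidence against the null
    p <- tryCatch(stats::t.test(yi, yj)$p.value, error = function(e) 1)
    pw[i, j] <- pw[j, i] <- min(1, p * n_pairs)
  }
  list(anova = data.frame(F = an[["F value"]][1L],
                          df1 = an[["Df"]][1L], df2 = an[["Df"]][2L],
                          p = an[["Pr(>F)"]][1L]),
       pairwise = pw, n_pairs = n_pairs, bonferroni_factor = n_pairs)
}
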