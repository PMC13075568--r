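# Correlation-distance k-means CAP clustering --------------------------------
#
# Frames (timepoints) are clustered with distance 1 - Pearson r between their
# ROI vectors. On row-standardized frames this is spherical k-means: rows are
# centred and scaled to unit norm, similarity is the dot product, and the
# centroid update (normalized mean of member rows) is the exact maximizer of
# within-cluster similarity, so Lloyd iterations monotonically decrease the
# objective sum(1 - r(frame, centroid)).

# Center rows and scale to unit Euclidean norm.
unitize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop_capnet("frames with zero spatial variance: %s",
                paste(utils::head(bad, 5L), collapse = ", "))
  x / nrm
}

kmeanspp_init <- function(Xu, k) {
  n <- nrow(Xu)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- (1 - as.numeric(Xu %*% Xu[centers[1L], ]))^2
  if (k > 1L) for (j in 2:k) {
    tot <- sum(d2)
    centers[j] <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    dn <- (1 - as.numeric(Xu %*% Xu[centers[j], ]))^2
    d2 <- pmin(d2, dn)
  }
  Xu[centers, , drop = FALSE]
}

lloyd_correlation <- function(Xu, C, max_iter) {
  n <- nrow(Xu)
  k <- nrow(C)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    sim <- Xu %*% t(C)                  # n x k
    new_labels <- max.col(sim, ties.method = "first")
    # re-seed emptied clusters from the farthest frame
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.min(sim[cbind(seq_len(n), new_labels)])
      capnet_log("cluster %d emptied; re-seeded from frame %d", j, far)
      new_labels[far] <- j
      sim[far, j] <- 1
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    Cn <- rowsum(Xu, labels)
    Cn <- Cn - rowMeans(Cn)
    C <- Cn / sqrt(rowSums(Cn^2))
    if (converged && it > 1L) break
  }
  sim <- Xu %*% t(C)
  obj <- sum(1 - sim[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = C, objective = obj, iterations = it)
}

#' Correlation-distance k-means
#'
#' Clusters the rows of `frames` with distance `1 - cor(frame, centroid)`,
#' k-means++-style seeding in correlation distance, Lloyd iterations on
#' row-standardized frames, and the best of `n_init` restarts by total
#' within-cluster distance. Deterministic under a fixed seed.
#'
#' @param frames N x R matrix (frames in rows); every row needs nonzero
#'   variance.
#' @param k number of clusters (< N).
#' @param n_init random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param seed integer seed.
#' @return object of class `capnet_kmeans`: integer `labels` (length N),
#'   `centroids` (k x R, unit-norm rows), `objective`, `config`.
#' @export
kmeans_correlation <- function(frames, k, n_init = 10L, max_iter = 300L,
                               seed = 1L) {
  assert_matrix(frames, "frames")
  if (nrow(frames) <= k) stop_capnet("need more frames than clusters")
  Xu <- unitize_rows(frames)
  best <- NULL
  with_seed(derive_seed(seed, "kmeans"), {
    for (init in seq_len(n_init)) {
      C0 <- kmeanspp_init(Xu, k)
      fit <- lloyd_correlation(Xu, C0, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  structure(list(labels = best$labels, centroids = best$centroids,
                 objective = best$objective,
                 config = list(k = k, n_init = n_init, max_iter = max_iter,
                               seed = seed, distance = "correlation",
                               init = "kmeans++")),
            class = "capnet_kmeans")
}

# Total within-cluster correlation distance of a labeling (shared objective,
# also used by the brute-force oracle in tests).
correlation_objective <- function(frames, labels, k = max(labels)) {
  Xu <- unitize_rows(frames)
  obj <- 0
  for (j in seq_len(k)) {
    m <- Xu[labels == j, , drop = FALSE]
    if (nrow(m) == 0L) next
    cj <- colSums(m)
    cj <- cj - mean(cj)
    nj <- sqrt(sum(cj^2))
    obj <- obj + nrow(m) - if (nj > 0) sum(m %*% cj) / nj else 0
  }
  obj
}

#' Build participant- and group-level CAP maps
#'
#' The participant-level map of a CAP is the mean of that participant's
#' frames labeled to it (`map_frames` may live at a finer spatial resolution
#' than the clustering frames, e.g. source space vs ROI space); the
#' group-level map averages the participant maps over participants that
#' possess the CAP (>= 1 frame). Participants lacking a CAP are recorded
#' absent (`NA` rows), not zero.
#'
#' @param labels integer frame labels (length N, values in 1..k).
#' @param map_frames N x R_map matrix, time-aligned with `labels`.
#' @param participant_index integer/factor participant id per frame.
#' @param k number of CAPs (default `max(labels)`).
#' @return object of class `capnet_caps`: `participant_maps` (participant x
#'   k x R_map array, `NA` where absent), `group_maps` (k x R_map),
#'   `counts` (participant x k frame counts), `k`, `participants`.
#' @export
build_cap_maps <- function(labels, map_frames, participant_index,
                           k = max(labels)) {
  assert_matrix(map_frames, "map_frames")
  stopifnot(length(labels) == nrow(map_frames),
            length(participant_index) == nrow(map_frames))
  parts <- unique(participant_index)
  R <- ncol(map_frames)
  pm <- array(NA_real_, c(length(parts), k, R),
              dimnames = list(as.character(parts), NULL, NULL))
  counts <- matrix(0L, length(parts), k,
                   dimnames = list(as.character(parts), NULL))
  for (pi in seq_along(parts)) {
    inp <- participant_index == parts[pi]
    lab_p <- labels[inp]
    sums <- rowsum(map_frames[inp, , drop = FALSE], lab_p)  # drops empties
    full <- matrix(0, k, R)
    full[as.integer(rownames(sums)), ] <- sums
    nn <- tabulate(lab_p, k)
    counts[pi, ] <- nn
    has <- nn > 0L
    pm[pi, has, ] <- full[has, , drop = FALSE] / nn[has]
  }
  gm <- matrix(NA_real_, k, R)
  for (j in seq_len(k)) {
    have <- which(counts[, j] > 0L)
    if (length(have))
      gm[j, ] <- colMeans(matrix(pm[have, j, ], nrow = length(have)))
  }
  structure(list(participant_maps = pm, group_maps = gm, counts = counts,
                 k = k, participants = parts), class = "capnet_caps")
}
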