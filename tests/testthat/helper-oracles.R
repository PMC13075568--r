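# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (different algorithms, plain loops) so they can
# serve as second implementations.

# Run-length encoder by explicit boundary scan (no rle()).
rle_oracle <- function(labels, fs) {
  labels <- as.integer(labels)
  n <- length(labels)
  starts <- c(1L, which(labels[-1L] != labels[-n]) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  runs <- data.frame(cap_id = labels[starts], start_frame = starts,
                     run_length_frames = ends - starts + 1L)
  duration_s <- n / fs
  caps <- seq_len(max(labels))
  data.frame(
    cap_id = caps,
    n_occurrences = vapply(caps, function(j) sum(runs$cap_id == j),
                           integer(1L)),
    occurrence_rate_hz = vapply(caps, function(j)
      sum(runs$cap_id == j) / duration_s, numeric(1L)),
    mean_lifetime_ms = vapply(caps, function(j) {
      lens <- runs$run_length_frames[runs$cap_id == j]
      if (length(lens)) mean(lens) * 1000 / fs else NA_real_
    }, numeric(1L)))
}

# Exhaustive 2-partition minimizer of the correlation-k-means objective.
brute_force_kmeans2 <- function(frames) {
  n <- nrow(frames)
  Xu <- frames - rowMeans(frames)
  Xu <- Xu / sqrt(rowSums(Xu^2))
  part_obj <- function(members) {
    obj <- 0
    for (grp in list(members, setdiff(seq_len(n), members))) {
      m <- Xu[grp, , drop = FALSE]
      cj <- colSums(m)
      cj <- cj - mean(cj)
      nj <- sqrt(sum(cj^2))
      obj <- obj + nrow(m) - if (nj > 0) sum(m %*% cj) / nj else 0
    }
    obj
  }
  best <- Inf
  # frame 1 fixed in cluster 1 to halve the enumeration
  for (code in 0:(2^(n - 1L) - 1L)) {
    members <- c(1L, which(bitwAnd(code, 2^(seq_len(n - 1L) - 1L)) > 0) + 1L)
    if (length(members) == n) next
    best <- min(best, part_obj(members))
  }
  best
}

# Direct GCV evaluation forming A(lambda) explicitly (no eigenbasis).
gcv_brute <- function(L, phi, grid) {
  G <- L %*% t(L)
  n <- nrow(G)
  vals <- vapply(grid, function(lam) {
    A <- G %*% solve(G + diag(lam, n))
    r <- (diag(n) - A) %*% phi
    n * sum(r^2) / sum(diag(diag(n) - A))^2
  }, numeric(1L))
  grid[which.min(vals)]
}

# Optimal-assignment matched absolute correlations between two sets of row
# series/maps.
matched_abs_cor <- function(recovered, truth) {
  cc <- abs(suppressWarnings(stats::cor(t(recovered), t(truth))))
  sol <- clue::solve_LSAP(cc, maximum = TRUE)
  cc[cbind(seq_along(sol), as.integer(sol))]
}

# Match group maps to templates by optimal assignment; returns per-template
# absolute correlations and the template id assigned to each cluster.
match_to_templates <- function(maps, templates) {
  cm <- suppressWarnings(stats::cor(t(maps), t(templates)))
  sol <- as.integer(clue::solve_LSAP(abs(cm), maximum = TRUE))
  list(abs_cor = abs(cm[cbind(seq_len(nrow(maps)), sol)]),
       template_of_cluster = sol)
}
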