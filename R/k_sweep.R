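# k-sweep, overlap graph, seed stability -------------------------------------

#' Cluster the same frames at several k values
#'
#' Independent [kmeans_correlation()] runs over a shared frame set, one per
#' requested k, each with a derived seed recorded in its config.
#'
#' @param frames N x R matrix.
#' @param k_values ascending integer vector (default 10:20).
#' @param seed master seed.
#' @param n_init,max_iter forwarded to [kmeans_correlation()].
#' @return named list of `capnet_kmeans` fits, one per k.
#' @export
sweep_k <- function(frames, k_values = 10:20, seed = 1L, n_init = 10L,
                    max_iter = 300L) {
  if (is.unsorted(k_values)) stop_capnet("`k_values` must be ascending")
  fits <- lapply(k_values, function(k)
    kmeans_correlation(frames, k, n_init = n_init, max_iter = max_iter,
                       seed = derive_seed(seed, paste0("k", k))))
  names(fits) <- as.character(k_values)
  fits
}

#' Timeframe-overlap graph across consecutive k values
#'
#' For each consecutive pair of labelings (adjacent entries of the supplied
#' list), the edge from CAP `a` at the lower k to CAP `b` at the higher k is
#' weighted by the fraction of `a`'s frames labeled `b` at the higher k, so
#' outgoing weights from every node sum to 1. The full graph is stored; a
#' display threshold applies only at export.
#'
#' @param labelings_by_k named list of integer label vectors over the same
#'   frames (names are the k values, ascending).
#' @return object of class `capnet_overlap_graph`: data.frame `edges`
#'   (`k_from`, `cap_from`, `k_to`, `cap_to`, `weight`).
#' @export
overlap_graph <- function(labelings_by_k) {
  if (is.null(names(labelings_by_k)))
    names(labelings_by_k) <- seq_along(labelings_by_k)
  kv <- names(labelings_by_k)
  n <- length(labelings_by_k[[1L]])
  edges <- list()
  for (i in seq_len(length(labelings_by_k) - 1L)) {
    la <- labelings_by_k[[i]]
    lb <- labelings_by_k[[i + 1L]]
    if (length(la) != n || length(lb) != n)
      stop_capnet("labelings cover different frame counts")
    tab <- table(la, lb)
    w <- tab / rowSums(tab)
    idx <- which(tab > 0, arr.ind = TRUE)
    edges[[i]] <- data.frame(
      k_from = kv[i],
      cap_from = as.integer(rownames(tab))[idx[, 1L]],
      k_to = kv[i + 1L],
      cap_to = as.integer(colnames(tab))[idx[, 2L]],
      weight = w[idx])
  }
  structure(list(edges = do.call(rbind, edges)),
            class = "capnet_overlap_graph")
}

#' Export an overlap graph as an edge list
#'
#' Tab-delimited columns `k_from`, `cap_from`, `k_to`, `cap_to`, `weight`;
#' edges below `display_threshold` are filtered at export only.
#'
#' @param graph a [overlap_graph()] result.
#' @param path output file.
#' @param display_threshold minimum weight to export (default 0.1, matching
#'   the usual display convention).
#' @return `path`, invisibly.
#' @export
write_overlap_edges <- function(graph, path, display_threshold = 0.1) {
  e <- graph$edges[graph$edges$weight >= display_threshold, , drop = FALSE]
  data.table::fwrite(e, path, sep = "\t")
  invisible(path)
}

#' Seed stability of the clustering
#'
#' Repeats the clustering with different seeds, matches cluster maps across
#' runs to the first run by optimal assignment on correlation, and reports
#' per-CAP minimum and mean cross-run map correlations.
#'
#' @param frames N x R matrix.
#' @param k number of clusters.
#' @param n_runs number of repeated runs (default 5).
#' @param seeds optional explicit seeds (length `n_runs`).
#' @param n_init forwarded to [kmeans_correlation()].
#' @return list: `stability` data.frame (`cap_id`, `min_cor`, `mean_cor`),
#'   `fits`, `matched_centroids` (list of k x R matrices aligned to run 1).
#' @export
seed_stability <- function(frames, k, n_runs = 5L, seeds = NULL,
                           n_init = 10L) {
  if (n_runs < 2L) stop_capnet("need n_runs >= 2")
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  fits <- lapply(seeds, function(s)
    kmeans_correlation(frames, k, n_init = n_init, seed = s))
  ref <- fits[[1L]]$centroids
  aligned <- vector("list", n_runs)
  aligned[[1L]] <- ref
  for (r in 2:n_runs) {
    rr <- row_cor(ref, fits[[r]]$centroids)
    sol <- clue::solve_LSAP(abs(rr), maximum = TRUE)
    aligned[[r]] <- fits[[r]]$centroids[as.integer(sol), , drop = FALSE]
  }
  stab <- do.call(rbind, lapply(seq_len(k), function(j) {
    cors <- vapply(2:n_runs, function(r)
      abs(stats::cor(ref[j, ], aligned[[r]][j, ])), numeric(1L))
    data.frame(cap_id = j, min_cor = min(cors), mean_cor = mean(cors))
  }))
  list(stability = stab, fits = fits, matched_centroids = aligned)
}
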