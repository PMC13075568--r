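# Synthetic spatial templates ------------------------------------------------
#
# The generator plants a known set of spatial activation templates over ROIs
# with the structural features the downstream analysis is sensitive to:
# hemispheric mirror symmetry (bilateral templates and left/right-dominant
# pairs), a functional-group label per template (SM / HO / Other) carrying a
# variability gradient, and an optional parent/child hierarchy in which each
# parent is the normalized sum of its two children (used by k-sweep tests).
# No published generative model exists for this kind of data; all
# distributional choices here are stand-ins and are documented as such.

#' Default mirror-pair table
#'
#' Pairs ROI `i` in the left hemisphere (first half of the index range) with
#' ROI `i + n_roi/2` in the right hemisphere.
#'
#' @param n_roi even number of ROIs.
#' @return data.frame with columns `roi_left`, `roi_right`.
#' @export
default_mirror_pairs <- function(n_roi) {
  if (n_roi %% 2L != 0L) stop_capnet("`n_roi` must be even")
  data.frame(roi_left = seq_len(n_roi %/% 2L),
             roi_right = seq_len(n_roi %/% 2L) + n_roi %/% 2L)
}

validate_mirror_pairs <- function(mirror_pairs, n_roi) {
  mp <- as.data.frame(mirror_pairs)
  if (!all(c("roi_left", "roi_right") %in% names(mp)))
    stop_capnet("mirror table needs columns `roi_left` and `roi_right`")
  ids <- c(mp$roi_left, mp$roi_right)
  if (anyDuplicated(ids) || !setequal(ids, seq_len(n_roi)))
    stop_capnet(paste("mirror table is not a bijection between hemispheres:",
                      "every ROI 1..%d must appear exactly once"), n_roi)
  mp
}

# Swap values between mirror-paired ROIs.
mirror_map <- function(x, mirror_pairs) {
  out <- x
  out[mirror_pairs$roi_left] <- x[mirror_pairs$roi_right]
  out[mirror_pairs$roi_right] <- x[mirror_pairs$roi_left]
  out
}

# Smooth, centered, unit-norm random pattern over `n` indices.
smooth_pattern <- function(n, width = 4) {
  z <- stats::rnorm(n + 6L * width)
  k <- stats::dnorm(seq(-3L * width, 3L * width), sd = width)
  v <- stats::filter(z, k / sum(k), sides = 2L)
  v <- as.numeric(v)[(3L * width + 1L):(3L * width + n)]
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Generate a planted template set
#'
#' Builds `k_true` spatial templates over `n_roi` ROIs. Templates are derived
#' from mutually orthogonal smooth half-hemisphere "cores": a bilateral
#' template copies its core symmetrically into both hemispheres; a
#' left/right-dominant pair applies opposite hemisphere weightings
#' `(1 + dominance, 1 - dominance)` to a shared bilateral core, so mirroring
#' one member reproduces the other exactly. With `hierarchy_depth = 1`,
#' consecutive templates are grouped into sibling pairs (one left-, one
#' right-dominant) and each parent is the normalized sum of its two children.
#'
#' @param n_roi even ROI count, consistent with `mirror_pairs`.
#' @param k_true number of templates (>= 2 unless explicitly degenerate).
#' @param mirror_pairs left/right pairing table (default hemispheric halves).
#' @param hierarchy_depth 0 for a flat set, 1 for sibling pairs under parents
#'   (requires even `k_true`).
#' @param seed integer seed; the same seed reproduces the set bit-for-bit.
#' @param mirror_spec per-template `"bilateral"`, `"left-dominant"` or
#'   `"right-dominant"`; defaults to unilateral pairs for the first half of
#'   templates and bilateral for the rest (hierarchy mode forces pairs).
#' @param group_label per-template `"SM"`, `"HO"` or `"Other"`; default splits
#'   roughly 45/40/15 percent in that order.
#' @param dominance hemisphere weighting asymmetry in (0, 1) for unilateral
#'   templates; 0.7 gives sibling correlation ~0.34 and child-parent ~0.82.
#' @return object of class `capnet_templates` with fields `templates`
#'   (k x R), `group_label`, `mirror_spec`, `hierarchy` (list of child index
#'   vectors named by parent row of `parents`), `parents`, `mirror_pairs`.
#' @export
make_templates <- function(n_roi, k_true,
                           mirror_pairs = default_mirror_pairs(n_roi),
                           hierarchy_depth = 0L, seed = 1L,
                           mirror_spec = NULL, group_label = NULL,
                           dominance = 0.7) {
  if (n_roi %% 2L != 0L) stop_capnet("`n_roi` must be even")
  if (k_true < 1L) stop_capnet("`k_true` must be >= 1")
  mp <- validate_mirror_pairs(mirror_pairs, n_roi)
  if (hierarchy_depth > 0L && k_true %% 2L != 0L)
    stop_capnet("hierarchy mode requires an even `k_true`")

  if (is.null(mirror_spec)) {
    if (hierarchy_depth > 0L) {
      mirror_spec <- rep(c("left-dominant", "right-dominant"), k_true %/% 2L)
    } else {
      n_uni <- 2L * (k_true %/% 4L)
      mirror_spec <- c(rep(c("left-dominant", "right-dominant"), n_uni %/% 2L),
                       rep("bilateral", k_true - n_uni))
    }
  }
  stopifnot(length(mirror_spec) == k_true)
  if (is.null(group_label)) {
    n_sm <- max(1L, round(0.45 * k_true))
    n_ho <- max(1L, round(0.40 * k_true))
    group_label <- rep(c("SM", "HO", "Other"),
                       c(n_sm, n_ho, max(0L, k_true - n_sm - n_ho)))[seq_len(k_true)]
  }

  n_half <- n_roi %/% 2L
  # number of independent cores: one per bilateral template / unilateral pair
  is_uni <- mirror_spec != "bilateral"
  core_of <- integer(k_true)
  nc <- 0L
  i <- 1L
  while (i <= k_true) {
    nc <- nc + 1L
    if (is_uni[i] && i < k_true && is_uni[i + 1L]) {
      core_of[c(i, i + 1L)] <- nc
      i <- i + 2L
    } else {
      core_of[i] <- nc
      i <- i + 1L
    }
  }

  tpl <- with_seed(derive_seed(seed, "templates"), {
    cores <- matrix(0, nc, n_half)
    for (j in seq_len(nc)) {
      v <- smooth_pattern(n_half)
      if (j > 1L) { # Gram-Schmidt against earlier cores
        prev <- cores[seq_len(j - 1L), , drop = FALSE]
        v <- v - as.numeric(t(prev) %*% (prev %*% v))
        v <- v - mean(v)
        v <- v / sqrt(sum(v^2))
      }
      cores[j, ] <- v
    }
    T <- matrix(0, k_true, n_roi)
    for (t in seq_len(k_true)) {
      full <- numeric(n_roi)
      full[mp$roi_left] <- cores[core_of[t], ]
      full[mp$roi_right] <- cores[core_of[t], ]
      w <- rep(1, n_roi)
      if (mirror_spec[t] == "left-dominant") {
        w[mp$roi_left] <- 1 + dominance; w[mp$roi_right] <- 1 - dominance
      } else if (mirror_spec[t] == "right-dominant") {
        w[mp$roi_left] <- 1 - dominance; w[mp$roi_right] <- 1 + dominance
      }
      T[t, ] <- full * w
    }
    T / sqrt(rowSums(T^2))
  })

  hierarchy <- list()
  parents <- NULL
  if (hierarchy_depth > 0L) {
    np <- k_true %/% 2L
    parents <- matrix(0, np, n_roi)
    for (p in seq_len(np)) {
      ch <- c(2L * p - 1L, 2L * p)
      hierarchy[[as.character(p)]] <- ch
      v <- colSums(tpl[ch, , drop = FALSE])
      parents[p, ] <- v / sqrt(sum(v^2))
    }
  }

  structure(list(templates = tpl, group_label = group_label,
                 mirror_spec = mirror_spec, hierarchy = hierarchy,
                 parents = parents, mirror_pairs = mp, seed = seed),
            class = "capnet_templates")
}
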