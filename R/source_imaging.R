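# Minimum-norm source imaging ------------------------------------------------
#
# The inverse model is the classical Tikhonov-regularized minimum-norm
# estimate S(t) = L' (L L' + lambda(t) I)^-1 phi(t), with lambda chosen per
# timeframe by generalized cross-validation (Golub-Heath-Wahba statistic on
# the sensor-space residual) and a 3-SD outlier repair of the lambda series.

as_lead_field <- function(lead_field) {
  L <- if (inherits(lead_field, "capnet_leadfield")) lead_field$L else lead_field
  assert_matrix(L, "lead_field")
  L
}

#' Minimum-norm inverse estimate
#'
#' Computes `S = L' (L L' + lambda I)^-1 phi` for one sensor frame or a
#' sensors x frames matrix (one shared `lambda`, or one per frame).
#'
#' @param lead_field lead-field matrix or [make_lead_field()] object.
#' @param sensor_frame numeric vector (one frame) or matrix
#'   (sensors x frames).
#' @param lambda regularization parameter(s), >= 0; at 0 the Gram matrix
#'   `L L'` must be invertible.
#' @return source vector (or sources x frames matrix).
#' @export
mne_inverse <- function(lead_field, sensor_frame, lambda) {
  L <- as_lead_field(lead_field)
  phi <- if (is.matrix(sensor_frame)) sensor_frame else
    matrix(sensor_frame, ncol = 1L)
  if (nrow(phi) != nrow(L))
    stop_capnet("sensor frame has %d rows, lead field %d", nrow(phi), nrow(L))
  stopifnot(all(lambda >= 0))
  G <- tcrossprod(L)
  n <- nrow(G)
  solve_one <- function(lam, b) {
    A <- G + diag(lam, n)
    x <- tryCatch(solve(A, b), error = function(e)
      stop_capnet(paste("singular system at lambda = %g: L L' is rank",
                        "deficient (rank %d < %d sensors)"),
                  lam, qr(G)$rank, n))
    crossprod(L, x)
  }
  if (length(lambda) == 1L) {
    out <- solve_one(lambda, phi)
  } else {
    if (length(lambda) != ncol(phi))
      stop_capnet("need one lambda per frame")
    # per-frame regularization, solved jointly in the eigenbasis of L L'
    eg <- eigen(G, symmetric = TRUE)
    if (any(lambda == 0) && min(eg$values) < max(eg$values) * 1e-12)
      stop_capnet("singular system at lambda = 0: L L' is rank deficient")
    b <- crossprod(eg$vectors, phi)
    x <- eg$vectors %*% (b / outer(eg$values, lambda, "+"))
    out <- crossprod(L, x)
  }
  if (is.matrix(sensor_frame)) out else as.numeric(out)
}

#' Default GCV lambda grid
#'
#' 30 log-spaced points over `[1e-6, 1e2]` times the mean eigenvalue of
#' `L L'`.
#'
#' @param lead_field lead field.
#' @param n_grid number of grid points.
#' @return ascending numeric vector.
#' @export
default_lambda_grid <- function(lead_field, n_grid = 30L) {
  L <- as_lead_field(lead_field)
  scale <- mean(diag(tcrossprod(L)))   # mean eigenvalue = mean diagonal
  exp(seq(log(1e-6 * scale), log(1e2 * scale), length.out = n_grid))
}

#' Select lambda by generalized cross-validation
#'
#' Evaluates `GCV(lambda) = n * ||(I - A) phi||^2 / trace(I - A)^2` with
#' `A = L L' (L L' + lambda I)^-1` over a grid and returns the minimizer;
#' ties break toward the smaller lambda. Grid points with
#' `trace(I - A) = 0` are skipped with a warning.
#'
#' @param lead_field lead field.
#' @param sensor_frame one sensor frame (vector) or sensors x frames matrix
#'   (selection is independent per frame).
#' @param lambda_grid ascending positive grid; default
#'   [default_lambda_grid()].
#' @return selected lambda (scalar, or vector with one value per frame).
#' @export
gcv_select_lambda <- function(lead_field, sensor_frame,
                              lambda_grid = default_lambda_grid(lead_field)) {
  L <- as_lead_field(lead_field)
  stopifnot(length(lambda_grid) >= 1L, !is.unsorted(lambda_grid))
  phi <- if (is.matrix(sensor_frame)) sensor_frame else
    matrix(sensor_frame, ncol = 1L)
  G <- tcrossprod(L)
  eg <- eigen(G, symmetric = TRUE)
  n <- nrow(G)
  # In the eigenbasis, I - A(lambda) = diag(lambda / (d_i + lambda)).
  b <- crossprod(eg$vectors, phi)      # n x frames
  gmat <- matrix(Inf, length(lambda_grid), ncol(phi))
  for (li in seq_along(lambda_grid)) {
    w <- lambda_grid[li] / (eg$values + lambda_grid[li])
    tr <- sum(w)
    if (tr == 0) {
      warning(sprintf("trace(I - A) = 0 at lambda = %g; grid point skipped",
                      lambda_grid[li]), call. = FALSE)
      next
    }
    gmat[li, ] <- n * colSums((w * b)^2) / tr^2
  }
  if (all(!is.finite(gmat))) stop_capnet("no usable lambda grid point")
  # which.min takes the first (= smallest lambda) on ties
  sel <- lambda_grid[apply(gmat, 2L, which.min)]
  if (is.matrix(sensor_frame)) sel else sel[[1L]]
}

#' Repair outliers in a lambda series
#'
#' Flags values beyond `n_sd` standard deviations of the whole-series mean
#' and replaces them by linear interpolation between the nearest non-outlier
#' neighbours (nearest valid value at the edges). A constant series (sd 0)
#' passes through unchanged. Statistics are computed on raw lambda by
#' default, or on `log10(lambda)` with `on_log = TRUE`.
#'
#' @param lambda_series positive numeric vector (length >= 3).
#' @param n_sd outlier threshold in standard deviations (default 3).
#' @param on_log compute the outlier statistics on `log10(lambda)`.
#' @return list with `lambda` (repaired series) and `outlier` (logical mask
#'   of replaced positions).
#' @export
regularize_lambda_series <- function(lambda_series, n_sd = 3,
                                     on_log = FALSE) {
  x <- as.numeric(lambda_series)
  if (length(x) < 3L) stop_capnet("lambda series must have length >= 3")
  stat <- if (on_log) log10(x) else x
  s <- stats::sd(stat)
  if (s == 0) return(list(lambda = x, outlier = rep(FALSE, length(x))))
  out <- abs(stat - mean(stat)) > n_sd * s
  if (all(out)) stop_capnet("all lambda values flagged as outliers")
  if (any(out)) {
    good <- which(!out)
    x[out] <- stats::approx(good, x[good], xout = which(out),
                            rule = 2)$y
  }
  list(lambda = x, outlier = out)
}

#' Write / read a lambda series as two-column delimited text
#'
#' @param lambda numeric series.
#' @param path output file.
#' @return `path`, invisibly (writer); numeric vector (reader).
#' @export
write_lambda_series <- function(lambda, path) {
  data.table::fwrite(data.table::data.table(frame_index = seq_along(lambda),
                                            lambda = lambda),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_lambda_series
#' @export
read_lambda_series <- function(path) {
  data.table::fread(path, sep = "\t")$lambda
}
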