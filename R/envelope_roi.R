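# Band-limiting, Hilbert envelopes, ROI reduction ----------------------------
#
# No IIR-filter package ships with the target environment, so the classical
# Butterworth bandpass design (analog prototype -> lowpass-to-bandpass
# transform -> bilinear transform) and reflection-padded forward-backward
# filtering are implemented here directly. The recursions themselves run
# through stats::filter (compiled), so multichannel minutes-long series
# filter in milliseconds.

# Polynomial coefficients (descending powers) from roots, real part taken
# after pairing conjugates.
poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p) * root
  Re(p)
}

#' Design a digital Butterworth bandpass filter
#'
#' Order-`order/2` analog Butterworth prototype, lowpass-to-bandpass
#' transformed (doubling the order to `order`) and discretized with the
#' bilinear transform with frequency prewarping. Gain is normalized to 1 at
#' the geometric-mean centre frequency.
#'
#' @param band numeric length-2 passband edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order total bandpass order (even; default 4).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(band, fs, order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2)
    stop_capnet("band edge %g Hz is at or above Nyquist (%g Hz)",
                band[2], fs / 2)
  if (order %% 2L != 0L) stop_capnet("bandpass order must be even")
  n <- order %/% 2L
  # prewarped analog edges
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog lowpass prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each pole p gives roots of s^2 - p*bw*s + w0^2
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((p * bw)^2 / 4 - w0^2 + 0i)
    p_bp <- c(p_bp, p * bw / 2 + disc, p * bw / 2 - disc)
  }
  # bilinear transform
  zp <- (1 + p_bp / (2 * fs)) / (1 - p_bp / (2 * fs))
  zz <- c(rep(1, n), rep(-1, n))   # analog zeros at 0 and infinity
  a <- poly_from_roots(zp)
  b <- poly_from_roots(zz)
  # unit gain at the centre frequency
  wc <- 2 * pi * sqrt(prod(band)) / fs
  z1 <- exp(-1i * wc * (seq_along(b) - 1L))
  gain <- abs(sum(b * z1) / sum(a * z1))
  list(b = b / gain, a = a)
}

iir_filter <- function(x, b, a) {
  # direct-form: y = (b * x) followed by the recursive part of a
  y <- stats::filter(c(rep(0, length(b) - 1L), x), b, sides = 1L)
  y <- y[-seq_len(length(b) - 1L)]
  as.numeric(stats::filter(y, -a[-1L], method = "recursive"))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection padding at
#' both ends, giving zero phase distortion and squared magnitude response.
#'
#' @param x numeric vector.
#' @param b,a filter coefficients from [butter_bandpass()].
#' @param padlen reflection pad length (default `min(length(x) - 1, 3 * 10 *
#'   order)`).
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_iir <- function(x, b, a,
                         padlen = min(length(x) - 1L,
                                      30L * (length(a) - 1L))) {
  n <- length(x)
  if (n <= padlen) padlen <- n - 1L
  pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  y <- iir_filter(c(pre, x, post), b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[padlen + seq_len(n)]
}

#' Bandpass filter multichannel data to the alpha band
#'
#' Zero-phase 4th-order Butterworth bandpass, per channel (row).
#'
#' @param ts channels x time numeric matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz (`fs > 2 * band[2]`).
#' @param band passband in Hz, default `c(8, 12)`.
#' @param order filter order, default 4.
#' @return matrix of the same shape.
#' @export
bandpass_alpha <- function(ts, fs, band = c(8, 12), order = 4L) {
  vec <- !is.matrix(ts)
  if (vec) ts <- matrix(ts, nrow = 1L)
  assert_matrix(ts, "ts")
  co <- butter_bandpass(band, fs, order)
  out <- t(apply(ts, 1L, filtfilt_iir, b = co$b, a = co$a))
  if (vec) as.numeric(out) else out
}

#' Instantaneous amplitude via the Hilbert transform
#'
#' Magnitude of the analytic signal of each channel (row).
#'
#' @param ts channels x time matrix or numeric vector.
#' @return nonnegative matrix (or vector) of instantaneous amplitudes.
#' @export
hilbert_envelope <- function(ts) Mod(analytic_signal(ts))

#' @rdname hilbert_envelope
#' @export
analytic_signal <- function(ts) {
  vec <- !is.matrix(ts)
  if (vec) ts <- matrix(ts, nrow = 1L)
  assert_matrix(ts, "ts")
  n <- ncol(ts)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  X <- t(stats::mvfft(t(ts)))
  A <- t(stats::mvfft(t(X * rep(h, each = nrow(ts))), inverse = TRUE)) / n
  if (vec) A[1L, ] else A
}

#' Read an atlas membership table
#'
#' Tab-delimited text with header `node_id<TAB>roi_id`.
#'
#' @param path file path.
#' @return data.frame with integer columns `node_id`, `roi_id`.
#' @export
read_atlas_membership <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("node_id", "roi_id") %in% names(m)))
    stop_capnet("membership table needs columns `node_id` and `roi_id`")
  m
}

#' Read a mirror-pair table (`roi_left<TAB>roi_right`)
#'
#' @param path file path.
#' @return data.frame with columns `roi_left`, `roi_right`.
#' @export
read_mirror_pairs <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("roi_left", "roi_right") %in% names(m)))
    stop_capnet("mirror table needs columns `roi_left` and `roi_right`")
  m
}

#' Average source series into ROI series
#'
#' ROI value at a frame is the arithmetic mean of its member nodes. Nodes
#' absent from the membership table are ignored (count logged); an ROI with
#' zero members is an error.
#'
#' @param source_env sources x time matrix.
#' @param membership data.frame with `node_id` (row index into `source_env`)
#'   and `roi_id`.
#' @return ROI x time matrix with ROI ids as row names.
#' @export
roi_reduce <- function(source_env, membership) {
  assert_matrix(source_env, "source_env")
  membership <- as.data.frame(membership)
  if (anyDuplicated(membership$node_id))
    stop_capnet("nodes mapped to more than one ROI: %s",
                paste(utils::head(unique(
                  membership$node_id[duplicated(membership$node_id)]), 5L),
                  collapse = ", "))
  rois <- sort(unique(membership$roi_id))
  counts <- table(factor(membership$roi_id, levels = rois))
  if (any(counts == 0L))
    stop_capnet("ROI with zero member nodes: %s",
                paste(rois[counts == 0L], collapse = ", "))
  unassigned <- nrow(source_env) - nrow(membership)
  if (unassigned > 0L)
    capnet_log("%d source nodes unassigned to any ROI; ignored", unassigned)
  sub <- source_env[membership$node_id, , drop = FALSE]
  out <- rowsum(sub, group = membership$roi_id, reorder = TRUE)
  out / as.numeric(counts)
}

#' Z-score ROI envelope series
#'
#' Default convention standardizes each ROI across time within participant
#' (equal ROI weighting; sample sd with `n - 1`). The alternative reading,
#' per frame across ROIs, is selectable with `axis = "frame"`.
#'
#' @param roi_env ROI x time matrix.
#' @param fs sampling rate in Hz (metadata).
#' @param participant participant identifier (metadata).
#' @param axis `"time"` (per ROI across time, default) or `"frame"` (per
#'   frame across ROIs).
#' @return object of class `capnet_frames` with matrix `Z` (ROI x time),
#'   `fs`, `participant`, `axis`.
#' @export
zscore_rois <- function(roi_env, fs = NA_real_, participant = NA,
                        axis = c("time", "frame")) {
  assert_matrix(roi_env, "roi_env")
  axis <- match.arg(axis)
  if (axis == "time") {
    s <- apply(roi_env, 1L, stats::sd)
    if (any(s == 0))
      stop_capnet("zero-variance ROI series: %s",
                  paste(utils::head(which(s == 0), 5L), collapse = ", "))
    Z <- (roi_env - rowMeans(roi_env)) / s
  } else {
    s <- apply(roi_env, 2L, stats::sd)
    if (any(s == 0))
      stop_capnet("zero-variance frames: %s",
                  paste(utils::head(which(s == 0), 5L), collapse = ", "))
    Z <- t((t(roi_env) - colMeans(roi_env)) / s)
  }
  structure(list(Z = Z, fs = fs, participant = participant, axis = axis),
            class = "capnet_frames")
}
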