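# Time-averaged RSN estimation: STFT, time-frequency ICA, envelope regression
#
# RSNs are estimated the classical way: non-overlapping 1-s STFT windows give
# complex spectral series at 1 Hz spacing; the alpha bins are complex-averaged
# per window; all participants' window series are concatenated and unmixed by
# ICA. The environment ships no ICA package, so both a complex fixed-point
# FastICA (kurtosis-type contrast on complex data) and a real FastICA applied
# to stacked real/imaginary channels are implemented here; the recovery tests
# gate both.

#' Short-time Fourier spectral series
#'
#' Per-channel z-scoring, then discrete Fourier coefficients of consecutive
#' non-overlapping rectangular windows. Window length `window_s` seconds with
#' 1/window_s Hz bin spacing; bins up to `max_hz` are retained. A trailing
#' partial window is dropped (logged).
#'
#' @param eeg channels x time matrix.
#' @param fs sampling rate in Hz (>= `2 * max_hz`).
#' @param window_s window length in seconds (default 1).
#' @param max_hz highest retained bin (default 100).
#' @param zscore z-score channels across time first (default TRUE).
#' @return object of class `capnet_spectra`: complex array `coef`
#'   (channels x bins x windows), `freqs_hz`, `fs`, `window_s`.
#' @export
stft_spectral_series <- function(eeg, fs, window_s = 1, max_hz = 100,
                                 zscore = TRUE) {
  assert_matrix(eeg, "eeg")
  if (fs < 2 * max_hz)
    stop_capnet("fs = %g Hz cannot resolve %g Hz", fs, max_hz)
  wlen <- round(fs * window_s)
  n_win <- ncol(eeg) %/% wlen
  if (n_win < 2L) stop_capnet("need at least 2 whole windows")
  if (ncol(eeg) %% wlen != 0L)
    capnet_log("dropping trailing partial window (%d frames)",
               ncol(eeg) %% wlen)
  if (zscore) {
    s <- apply(eeg, 1L, stats::sd)
    if (any(s == 0)) stop_capnet("zero-variance channel")
    eeg <- (eeg - rowMeans(eeg)) / s
  }
  freqs <- seq(0, max_hz, by = 1 / window_s)
  bins <- round(freqs * window_s) + 1L
  coef <- array(complex(real = 0), c(nrow(eeg), length(freqs), n_win))
  for (w in seq_len(n_win)) {
    seg <- eeg[, (w - 1L) * wlen + seq_len(wlen), drop = FALSE]
    Fw <- stats::mvfft(t(seg))          # wlen x channels
    coef[, , w] <- t(Fw[bins, , drop = FALSE])
  }
  structure(list(coef = coef, freqs_hz = freqs, fs = fs,
                 window_s = window_s), class = "capnet_spectra")
}

#' Average complex spectral coefficients over a band
#'
#' Arithmetic mean of the complex coefficients over the inclusive bin range
#' (8..12 Hz by default).
#'
#' @param spec a [stft_spectral_series()] result.
#' @param band inclusive frequency range in Hz.
#' @return complex channels x windows matrix.
#' @export
alpha_band_average <- function(spec, band = c(8, 12)) {
  sel <- which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
  if (length(sel) == 0L) stop_capnet("no frequency bins inside the band")
  out <- spec$coef[, sel[1L], , drop = TRUE]
  if (length(sel) > 1L) {
    acc <- apply(spec$coef[, sel, , drop = FALSE], c(1L, 3L), sum)
    out <- acc / length(sel)
  }
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(spec$coef)[1L])
  out
}

# Symmetric decorrelation W <- (W W^H)^{-1/2} W (works for real and complex).
sym_decorrelate <- function(W) {
  S <- W %*% Conj(t(W))
  e <- eigen(S, symmetric = TRUE)
  iv <- e$vectors %*% diag(1 / sqrt(pmax(Re(e$values), 1e-12)),
                           nrow(W)) %*% Conj(t(e$vectors))
  iv %*% W
}

# Real symmetric FastICA with tanh contrast on pre-whitened data X (c x n).
fastica_real <- function(X, n_comp, max_iter = 500L, tol = 1e-9) {
  W <- matrix(stats::rnorm(n_comp * nrow(X)), n_comp)
  W <- sym_decorrelate(W)
  n <- ncol(X)
  for (it in seq_len(max_iter)) {
    U <- W %*% X
    G <- tanh(U)
    W1 <- (G %*% t(X)) / n - diag(rowMeans(1 - G^2), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

# Complex fixed-point FastICA (Bingham & Hyvarinen 2000) with the kurtosis
# contrast G(y) = y^2/2 (g(y) = y), suited to the super-Gaussian amplitude
# structure of spectral envelope sources, on pre-whitened complex X (c x n).
fastica_complex <- function(X, n_comp, max_iter = 500L, tol = 1e-9) {
  C <- nrow(X)
  W <- matrix(complex(real = stats::rnorm(n_comp * C),
                      imaginary = stats::rnorm(n_comp * C)), n_comp)
  W <- sym_decorrelate(W)
  n <- ncol(X)
  for (it in seq_len(max_iter)) {
    U <- W %*% X                       # components x n
    y2 <- Mod(U)^2
    # w <- E{ x conj(w^H x) g } - E{ g + |w^H x|^2 g' } w, g(y) = y
    W1 <- (Conj(U) * y2) %*% t(X) / n -
      diag(rowMeans(2 * y2), n_comp) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * Conj(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

whiten <- function(X, n_comp) {
  mu <- rowMeans(X)
  Xc <- X - mu
  Cv <- Xc %*% Conj(t(Xc)) / ncol(Xc)
  e <- eigen(Cv, symmetric = TRUE)
  pos <- Re(e$values) > max(Re(e$values)) * 1e-10
  r <- sum(pos)
  if (r < n_comp) {
    warning(sprintf("rank %d after whitening < %d components; reduced",
                    r, n_comp), call. = FALSE)
    n_comp <- r
  }
  K <- diag(1 / sqrt(Re(e$values[seq_len(n_comp)])), n_comp) %*%
    Conj(t(e$vectors[, seq_len(n_comp), drop = FALSE]))
  list(K = K, X = K %*% Xc, mu = mu, n_comp = n_comp)
}

#' Group temporal ICA on concatenated spectral series
#'
#' Concatenates per-participant complex (channels x windows) series along the
#' window axis and unmixes them. `method = "complex"` (default) runs the
#' complex fixed-point FastICA; `method = "stacked"` stacks real and
#' imaginary parts as separate real channels and runs real FastICA with a
#' tanh contrast. Deterministic under a fixed seed.
#'
#' @param series_by_participant list of complex channels x windows matrices
#'   (a single matrix is accepted).
#' @param n_components number of components (<= channels; default 48 capped
#'   at the channel count).
#' @param seed integer seed.
#' @param method `"complex"` or `"stacked"`.
#' @param retained_components optional integer ids of components treated as
#'   neuronal downstream (default all).
#' @return object of class `capnet_ica`: demixing `W` (components x
#'   channels, acting on centred data), mixing `A`, component window series
#'   `S`, `method`, `retained`.
#' @export
group_temporal_ica <- function(series_by_participant, n_components = 48L,
                               seed = 1L, method = c("complex", "stacked"),
                               retained_components = NULL) {
  method <- match.arg(method)
  if (is.matrix(series_by_participant))
    series_by_participant <- list(series_by_participant)
  X <- do.call(cbind, series_by_participant)
  C <- nrow(X)
  # the stacked route sees 2C real channels, the complex route C
  n_components <- min(n_components, if (method == "stacked") 2L * C else C)
  if (ncol(X) <= n_components)
    stop_capnet("need more windows (%d) than components (%d)",
                ncol(X), n_components)

  with_seed(derive_seed(seed, "ica"), {
    if (method == "stacked") {
      Xr <- rbind(Re(X), Im(X))
      wh <- whiten(Xr, min(n_components, nrow(Xr)))
      Wu <- fastica_real(Re(wh$X), wh$n_comp)
    } else {
      wh <- whiten(X, n_components)
      Wu <- fastica_complex(wh$X, wh$n_comp)
    }
    W <- Wu %*% wh$K                   # components x (stacked) channels
    # fix sign/phase: largest-|.| weight made real positive
    for (i in seq_len(nrow(W))) {
      j <- which.max(Mod(W[i, ]))
      ph <- W[i, j] / Mod(W[i, j])
      W[i, ] <- W[i, ] / ph
    }
    A <- Conj(t(W)) %*% solve(W %*% Conj(t(W)))  # right pseudo-inverse
    S <- W %*% (if (method == "stacked") rbind(Re(X), Im(X)) - rowMeans(rbind(Re(X), Im(X))) else X - rowMeans(X))
    retained <- if (is.null(retained_components)) seq_len(nrow(W)) else
      as.integer(retained_components)
    structure(list(W = W, A = A, S = S, method = method,
                   n_channels = C, retained = retained, seed = seed),
              class = "capnet_ica")
  })
}

#' Project time-domain data through the ICA demixing matrix
#'
#' For a real demixing matrix, returns `W %*% ts`. For a complex demixing
#' matrix (complex ICA, or a stacked model interpreted as complex weights),
#' the analytic signal of `ts` is projected and the complex component series
#' returned; its modulus is the component envelope.
#'
#' @param alpha_eeg channels x time matrix (alpha-band, time domain).
#' @param model a [group_temporal_ica()] result, or a bare demixing matrix.
#' @return components x time matrix (complex if `W` is complex).
#' @export
ic_time_courses <- function(alpha_eeg, model) {
  W <- if (inherits(model, "capnet_ica")) ica_complex_demixing(model) else model
  assert_matrix(Re(alpha_eeg), "alpha_eeg")
  if (ncol(W) != nrow(alpha_eeg))
    stop_capnet("demixing matrix has %d channels, data has %d",
                ncol(W), nrow(alpha_eeg))
  if (is.complex(W)) W %*% analytic_signal(alpha_eeg) else W %*% alpha_eeg
}

# Complex component-space demixing matrix over the original channels.
ica_complex_demixing <- function(model) {
  W <- model$W
  if (model$method == "stacked" && ncol(W) == 2L * model$n_channels) {
    C <- model$n_channels
    # component = u . Re(x) + v . Im(x) = Re((u - i v)^H-free form); project
    # the analytic signal with u - i v to carry phase.
    W <- W[, seq_len(C), drop = FALSE] - 1i * W[, C + seq_len(C), drop = FALSE]
  }
  W
}

#' Component envelopes, z-scored
#'
#' Convenience wrapper: demix, take instantaneous amplitude, z-score each
#' component across time.
#'
#' @inheritParams ic_time_courses
#' @return components x time matrix of z-scored envelopes.
#' @export
ic_envelopes_z <- function(alpha_eeg, model) {
  tc <- ic_time_courses(alpha_eeg, model)
  env <- if (is.complex(tc)) Mod(tc) else hilbert_envelope(tc)
  s <- apply(env, 1L, stats::sd)
  s[s == 0] <- 1
  (env - rowMeans(env)) / s
}

#' Per-dipole envelope regression beta maps
#'
#' Ordinary least squares per dipole: the dipole envelope z-series is
#' regressed on all component envelope z-series plus an intercept. With
#' collinear regressors the minimum-norm (pseudo-inverse) solution is used
#' and the condition number logged.
#'
#' @param dipole_env_z sources x time matrix (responses).
#' @param ic_env_z components x time matrix (regressors).
#' @return components x sources beta matrix (intercept dropped).
#' @export
regress_rsn_maps <- function(dipole_env_z, ic_env_z) {
  assert_matrix(dipole_env_z, "dipole_env_z")
  assert_matrix(ic_env_z, "ic_env_z")
  Tn <- ncol(dipole_env_z)
  if (ncol(ic_env_z) != Tn) stop_capnet("time axes differ")
  if (Tn <= nrow(ic_env_z) + 1L)
    stop_capnet("need T > components + 1")
  X <- cbind(1, t(ic_env_z))           # T x (K+1)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    sv <- svd(X)
    capnet_log("collinear regressors; min-norm solution, condition %g",
               sv$d[1L] / sv$d[max(which(sv$d > sv$d[1L] * 1e-12))])
    dinv <- ifelse(sv$d > sv$d[1L] * 1e-12, 1 / sv$d, 0)
    B <- sv$v %*% (dinv * (t(sv$u) %*% t(dipole_env_z)))
  } else {
    B <- qr.coef(qx, t(dipole_env_z))
  }
  B[-1L, , drop = FALSE]               # components x sources
}

#' Average participant-level maps into group maps
#'
#' @param maps list of equally sized matrices (one per participant).
#' @return elementwise unweighted mean matrix.
#' @export
group_average <- function(maps) {
  stopifnot(length(maps) >= 1L)
  Reduce(`+`, maps) / length(maps)
}
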