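# Synthetic cohorts -----------------------------------------------------------
#
# Envelope mode plants, per participant, frame(t) = baseline +
# a(t) * template_p[state(t)] + noise, where a(t) is a half-cosine bump over
# each state run (no hard onsets), template_p is the participant's perturbed
# copy of the group template (perturbation sd set by the template's
# functional-group label, giving the SM < HO < Other variability gradient),
# and noise is spatially smoothed Gaussian scaled to the requested SNR
# (template-signal variance / noise variance).

half_cosine_activation <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  a <- numeric(length(labels))
  start <- 1L
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    a[start:ends[i]] <- sin(pi * (seq_len(len) - 0.5) / len)
    start <- ends[i] + 1L
  }
  a
}

# Gaussian smoothing matrix over ROI index (unit row sums).
roi_smoother <- function(n_roi, width) {
  if (width <= 0) return(diag(n_roi))
  d <- abs(outer(seq_len(n_roi), seq_len(n_roi), "-"))
  K <- exp(-0.5 * (d / width)^2)
  K / rowSums(K)
}

perturb_templates <- function(templates, sigma_by_template, noise_width = 4) {
  tpl <- templates$templates
  out <- tpl
  for (t in seq_len(nrow(tpl))) {
    if (sigma_by_template[t] <= 0) next
    eta <- smooth_pattern(ncol(tpl))     # centered, unit norm
    v <- tpl[t, ] + sigma_by_template[t] * eta / stats::sd(eta) * stats::sd(tpl[t, ])
    out[t, ] <- v / sqrt(sum(v^2))
  }
  out
}

#' Simulate a multi-participant ROI-envelope cohort
#'
#' Generates per-participant ROI x time envelope data containing the planted
#' templates, with participant-specific template perturbations and a fresh
#' state sequence per participant drawn from the configuration of `states`.
#'
#' @param templates a [make_templates()] result.
#' @param states a [simulate_state_sequence()] result; its configuration
#'   (rates, dwell, fs, duration) is redrawn per participant with derived
#'   seeds.
#' @param snr template-signal variance / noise variance, > 0 (`Inf` allowed
#'   for the noiseless limit).
#' @param participant_sigma_by_group named perturbation scales for the
#'   `"SM"`, `"HO"` and `"Other"` groups (fraction of template sd).
#' @param n_participants cohort size (>= 2 for group analyses).
#' @param seed master seed; the same seed reproduces the cohort bit-for-bit.
#' @param baseline constant envelope offset (removed by z-scoring).
#' @param noise_width Gaussian width (in ROI indices) of spatial noise
#'   smoothing.
#' @return object of class `capnet_cohort` with `env` (list of ROI x time
#'   matrices), `states` (list of `capnet_states`), `templates`,
#'   `participant_templates` (list of perturbed k x R matrices) and `config`.
#' @export
simulate_roi_envelopes <- function(templates, states, snr = 0.5,
                                   participant_sigma_by_group =
                                     c(SM = 0.05, HO = 0.15, Other = 0.3),
                                   n_participants = 8L, seed = 1L,
                                   baseline = 1, noise_width = 3) {
  stopifnot(snr > 0, n_participants >= 1L)
  tpl <- templates$templates
  k <- nrow(tpl)
  R <- ncol(tpl)
  sigma_by_template <-
    unname(participant_sigma_by_group[templates$group_label])
  sigma_by_template[is.na(sigma_by_template)] <- 0
  Ksm <- roi_smoother(R, noise_width)

  env <- vector("list", n_participants)
  st <- vector("list", n_participants)
  ptpl <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    pseed <- derive_seed(seed, sprintf("participant%03d", p))
    st[[p]] <- simulate_state_sequence(states$duration_s, states$fs,
                                       states$config$occ_rates,
                                       states$config$mean_dwell_ms,
                                       seed = pseed,
                                       dwell_dist =
                                         states$config$dwell_dist %||% "geometric")
    ptpl[[p]] <- with_seed(derive_seed(pseed, "perturb"),
                           perturb_templates(templates, sigma_by_template))
    env[[p]] <- with_seed(derive_seed(pseed, "envelope"), {
      lab <- st[[p]]$labels
      a <- half_cosine_activation(lab)
      signal <- ptpl[[p]][lab, , drop = FALSE] * a   # T x R
      sig_var <- stats::var(as.numeric(signal))
      if (is.finite(snr)) {
        noise <- Ksm %*% matrix(stats::rnorm(R * length(lab)), R)
        noise <- noise * sqrt(sig_var / snr / stats::var(as.numeric(noise)))
      } else noise <- 0
      baseline + t(signal) + noise                   # R x T
    })
  }
  structure(list(env = env, states = st, templates = templates,
                 participant_templates = ptpl,
                 config = list(snr = snr,
                               participant_sigma_by_group = participant_sigma_by_group,
                               n_participants = n_participants, seed = seed,
                               baseline = baseline, noise_width = noise_width,
                               mode = "envelope")),
            class = "capnet_cohort")
}

#' Generate a random full-row-rank lead field
#'
#' Draws a Gaussian `n_sensors x n_sources` gain matrix with smoothing over
#' the source index (neighbouring sources project similarly). The system is
#' underdetermined (`n_sensors < n_sources`) as in EEG source imaging. A
#' rank-deficient draw (numerically impossible in practice) is regenerated
#' with a new derived seed and logged.
#'
#' @param n_sensors,n_sources dimensions, `n_sensors < n_sources`.
#' @param seed integer seed.
#' @param smooth_width source-index smoothing width.
#' @return object of class `capnet_leadfield` with matrix `L`.
#' @export
make_lead_field <- function(n_sensors, n_sources, seed = 1L,
                            smooth_width = 3) {
  if (n_sensors >= n_sources)
    stop_capnet("lead field must be underdetermined (n_sensors < n_sources)")
  Ksm <- roi_smoother(n_sources, smooth_width)
  for (attempt in 0:4) {
    L <- with_seed(derive_seed(seed, paste0("leadfield", attempt)), {
      matrix(stats::rnorm(n_sensors * n_sources), n_sensors) %*% Ksm
    })
    if (qr(L)$rank == n_sensors)
      return(structure(list(L = L, seed = seed), class = "capnet_leadfield"))
    capnet_log("rank-deficient lead field draw, regenerating (attempt %d)",
               attempt + 1L)
  }
  stop_capnet("could not generate a full-row-rank lead field")
}

#' Simulate sensor-level oscillatory EEG (oscillation mode)
#'
#' Source `j` carries an alpha-range sinusoid with random phase whose
#' amplitude is modulated by the planted activation:
#' `m_j(t) = max(baseline + a(t) * gain * template[state(t), j], floor)`, and
#' sensors record `L %*% S(t)` plus white sensor noise at the requested SNR.
#' Ground-truth sources and modulators are returned alongside for oracle
#' comparisons.
#'
#' @param lead_field a [make_lead_field()] result with `n_sources` columns
#'   equal to the template ROI count.
#' @param templates,states as in [simulate_roi_envelopes()].
#' @param carrier_band frequency range in Hz; the carrier sits at its centre.
#' @param snr sensor-signal variance / sensor-noise variance.
#' @param seed integer seed.
#' @param mod_gain modulation depth applied to template loadings.
#' @return object of class `capnet_sensor_series`: `phi` (sensors x T),
#'   `sources` (sources x T), `modulators` (sources x T), `fs`, `carrier_hz`.
#' @export
simulate_sensor_eeg <- function(lead_field, templates, states,
                                carrier_band = c(8, 12), snr = 10,
                                seed = 1L, mod_gain = 4) {
  L <- lead_field$L
  tpl <- templates$templates
  if (ncol(L) != ncol(tpl))
    stop_capnet("lead field has %d sources but templates have %d ROIs",
                ncol(L), ncol(tpl))
  fs <- states$fs
  lab <- states$labels
  n <- length(lab)
  f0 <- mean(carrier_band)
  out <- with_seed(derive_seed(seed, "sensor_eeg"), {
    a <- half_cosine_activation(lab)
    modulators <- t(tpl[lab, , drop = FALSE] * (a * mod_gain))  # sources x T
    modulators <- pmax(1 + modulators, 0.05)
    phase <- stats::runif(ncol(L), 0, 2 * pi)
    tt <- (seq_len(n) - 1L) / fs
    carrier <- cos(outer(phase, 2 * pi * f0 * tt, "+"))
    S <- modulators * carrier
    phi <- L %*% S
    if (is.finite(snr)) {
      noise <- matrix(stats::rnorm(length(phi)), nrow(phi))
      noise <- noise * sqrt(stats::var(as.numeric(phi)) / snr /
                              stats::var(as.numeric(noise)))
      phi <- phi + noise
    }
    list(phi = phi, sources = S, modulators = modulators)
  })
  structure(c(out, list(fs = fs, carrier_hz = f0, states = states,
                        templates = templates, seed = seed)),
            class = "capnet_sensor_series")
}
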