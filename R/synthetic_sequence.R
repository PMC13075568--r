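# Synthetic brain-state sequences --------------------------------------------

#' Simulate a semi-Markov state sequence
#'
#' Draws an alternating sequence of states and geometric dwell times. The
#' next state is drawn with probability proportional to its configured
#' occurrence rate, excluding the current state (so runs are maximal by
#' construction and the dwell distribution is exactly the configured
#' geometric; see the methods vignette). Dwells are geometric on frames with
#' the configured mean, so per-frame exit is memoryless.
#'
#' Because states are exclusive and cover every frame, configured rates only
#' set relative selection weights: if the implied occupancy
#' `sum(rate_i * dwell_i)` differs from 1 the weights renormalize, with a
#' warning when occupancy exceeds 1. Use [expected_state_stats()] for the
#' resulting ground-truth expectations.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param occ_rates per-state target occurrence rates in Hz (length k).
#' @param mean_dwell_ms per-state mean dwell in milliseconds (recycled).
#' @param seed integer seed.
#' @param dwell_dist `"geometric"` (default) or `"fixed"` (every run has
#'   exactly the configured mean length, rounded to frames).
#' @return object of class `capnet_states`: integer `labels` (one per frame),
#'   `fs`, `duration_s`, and the generating `config`.
#' @export
simulate_state_sequence <- function(duration_s, fs, occ_rates,
                                    mean_dwell_ms = 80, seed = 1L,
                                    dwell_dist = c("geometric", "fixed")) {
  dwell_dist <- match.arg(dwell_dist)
  k <- length(occ_rates)
  stopifnot(k >= 1L, all(occ_rates > 0), duration_s > 0, fs > 0)
  mean_dwell_ms <- rep_len(mean_dwell_ms, k)
  mean_frames <- fs * mean_dwell_ms / 1000
  if (any(mean_frames < 1))
    stop_capnet("mean dwell below one frame at fs = %g Hz", fs)
  occupancy <- sum(occ_rates * mean_dwell_ms / 1000)
  if (occupancy > 1)
    warning(sprintf(paste("configured rates imply occupancy %.2f > 1;",
                          "states are exclusive so rates renormalize"),
                    occupancy), call. = FALSE)

  n_frames <- round(fs * duration_s)
  p <- occ_rates / sum(occ_rates)
  labels <- with_seed(derive_seed(seed, "states"), {
    out <- integer(n_frames)
    filled <- 0L
    cur <- 0L
    while (filled < n_frames) {
      if (k == 1L) {
        nxt <- 1L
      } else {
        w <- p
        if (cur > 0L) w[cur] <- 0
        nxt <- sample.int(k, 1L, prob = w)
      }
      dwell <- if (dwell_dist == "fixed") max(1L, round(mean_frames[nxt]))
      else stats::rgeom(1L, prob = 1 / mean_frames[nxt]) + 1L
      take <- min(dwell, n_frames - filled)
      out[filled + seq_len(take)] <- nxt
      filled <- filled + take
      cur <- nxt
    }
    out
  })
  structure(list(labels = labels, fs = fs, duration_s = duration_s,
                 config = list(occ_rates = occ_rates,
                               mean_dwell_ms = mean_dwell_ms, seed = seed,
                               dwell_dist = dwell_dist)),
            class = "capnet_states")
}

#' Ground-truth expectations of a state-sequence configuration
#'
#' Computes the planted per-state expectations implied by the generator
#' model: selection weights `p = occ_rates / sum(occ_rates)`; run share of
#' the embedded no-repeat chain `pi_i` proportional to `p_i (1 - p_i)`; mean
#' dwell `m_i` frames; occurrence rate `rate_i = pi_i / sum_j(pi_j m_j / fs)`.
#'
#' @param occ_rates per-state rates in Hz.
#' @param mean_dwell_ms per-state mean dwell in ms.
#' @param fs sampling rate in Hz.
#' @return data.frame with `state`, `run_share`, `occurrence_rate_hz`,
#'   `mean_lifetime_ms`.
#' @export
expected_state_stats <- function(occ_rates, mean_dwell_ms, fs) {
  k <- length(occ_rates)
  p <- occ_rates / sum(occ_rates)
  mean_dwell_ms <- rep_len(mean_dwell_ms, k)
  m <- fs * mean_dwell_ms / 1000
  pi_i <- if (k == 1L) 1 else p * (1 - p) / sum(p * (1 - p))
  mean_cycle_s <- sum(pi_i * m) / fs
  data.frame(state = seq_len(k), run_share = pi_i,
             occurrence_rate_hz = pi_i / mean_cycle_s,
             mean_lifetime_ms = mean_dwell_ms)
}
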