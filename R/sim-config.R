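#' Configuration for the imaging-session forward model
#'
#' Bundles every tunable of the calcium-imaging simulator. Defaults mirror the
#' recording conditions the analysis assumes: three 15-min sessions imaged at
#' 20 Hz, 24 one-second mechanical stimuli per session at random intervals, and
#' a GCaMP6s-like indicator with second-scale transients. Session lengths are
#' freely reducible (all analysis windows are expressed in seconds), which is
#' how the test-suite keeps problem sizes small.
#'
#' The simulated signal for neuron \eqn{i} is
#' \deqn{f_i(t) = F \left(1 + c_i(t)\right) + d(t) + \epsilon_i(t)}
#' where \eqn{c_i(t)} is a calcium activity trace composed of a tonic level,
#' Poisson background spiking convolved with a double-exponential indicator
#' kernel, and a deterministic evoked transient per stimulus (positive for
#' planted activated neurons, negative for inactivated ones; scaled by
#' `opto_gain_session2` in session 2), \eqn{d(t)} is a slow sinusoidal drift
#' and \eqn{\epsilon} is white Gaussian noise. A background-overlap trace
#' (shared low-pass-filtered noise plus an offset) accompanies every ROI so the
#' slow-baseline definition (percentile of ROI + background) is exercised
#' nontrivially.
#'
#' @param n_neurons number of simulated ROIs.
#' @param frame_rate imaging rate, Hz.
#' @param session_length session duration, s.
#' @param n_sessions number of sessions (optogenetic gain acts on session 2).
#' @param n_stimuli_per_session stimuli per session.
#' @param stimulus_duration stimulus length, s.
#' @param min_interval,max_interval bounds of the uniform inter-stimulus
#'   interval, s (onset-to-onset gap minus stimulus duration).
#' @param fraction_activated,fraction_inactivated planted population fractions;
#'   the non-responsive fraction is the remainder.
#' @param evoked_amplitude peak evoked dF/F0 of activated neurons.
#' @param opto_gain_session2 multiplicative gain applied to evoked transients
#'   in session 2.
#' @param indicator_rise_tau,indicator_decay_tau indicator kernel time
#'   constants, s.
#' @param baseline_rate background spike rate, Hz.
#' @param spike_amplitude dF/F0 transient amplitude per background spike.
#' @param tonic_dff tonic calcium-related dF/F0 level; caps how deep
#'   inactivated neurons can be suppressed.
#' @param f_base mean baseline fluorescence, arbitrary units.
#' @param noise_sd white-noise SD, fluorescence units.
#' @param drift_amplitude slow-drift amplitude, fluorescence units.
#' @param background_level,background_sd offset and SD of the simulated
#'   background-overlap trace, fluorescence units.
#' @param withdrawal_threshold population-activity threshold above which a
#'   trial is flagged as a behavioural withdrawal.
#' @param withdrawal_noise_sd trial-to-trial noise on the withdrawal score.
#' @param seed integer RNG seed; identical configs and seeds give bit-identical
#'   simulations.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 100,
                       frame_rate = 20,
                       session_length = 900,
                       n_sessions = 3,
                       n_stimuli_per_session = 24,
                       stimulus_duration = 1,
                       min_interval = 5,
                       max_interval = 15,
                       fraction_activated = 0.40,
                       fraction_inactivated = 0.25,
                       evoked_amplitude = 0.5,
                       opto_gain_session2 = 1.5,
                       indicator_rise_tau = 0.2,
                       indicator_decay_tau = 1.6,
                       baseline_rate = 0.2,
                       spike_amplitude = 0.2,
                       tonic_dff = 0.3,
                       f_base = 1.0,
                       noise_sd = 0.05,
                       drift_amplitude = 0.05,
                       background_level = 0.3,
                       background_sd = 0.03,
                       withdrawal_threshold = NULL,
                       withdrawal_noise_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_neurons = as.integer(n_neurons), frame_rate = frame_rate,
    session_length = session_length, n_sessions = as.integer(n_sessions),
    n_stimuli_per_session = as.integer(n_stimuli_per_session),
    stimulus_duration = stimulus_duration,
    min_interval = min_interval, max_interval = max_interval,
    fraction_activated = fraction_activated,
    fraction_inactivated = fraction_inactivated,
    fraction_nonresponsive = 1 - fraction_activated - fraction_inactivated,
    evoked_amplitude = evoked_amplitude,
    opto_gain_session2 = opto_gain_session2,
    indicator_rise_tau = indicator_rise_tau,
    indicator_decay_tau = indicator_decay_tau,
    baseline_rate = baseline_rate, spike_amplitude = spike_amplitude,
    tonic_dff = tonic_dff, f_base = f_base,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    background_level = background_level, background_sd = background_sd,
    withdrawal_threshold = withdrawal_threshold,
    withdrawal_noise_sd = withdrawal_noise_sd,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_neurons >= 1, cfg$frame_rate > 0, cfg$session_length > 0,
            cfg$n_sessions >= 1, cfg$n_stimuli_per_session >= 1,
            cfg$stimulus_duration > 0)
  if (cfg$fraction_activated < 0 || cfg$fraction_inactivated < 0 ||
      cfg$fraction_nonresponsive < -1e-12)
    stop("population fractions must be non-negative and sum to at most 1")
  if (cfg$min_interval < 0 || cfg$max_interval < cfg$min_interval)
    stop("need 0 <= min_interval <= max_interval")
  taus <- c(cfg$indicator_rise_tau, cfg$indicator_decay_tau)
  if (any(taus <= 0) || cfg$indicator_decay_tau <= cfg$indicator_rise_tau)
    stop("indicator taus must be positive with decay > rise")
  if (cfg$noise_sd < 0 || cfg$drift_amplitude < 0 || cfg$background_sd < 0)
    stop("noise parameters must be >= 0")
  # feasibility of the stimulus schedule (post-window margin checked at
  # simulation time, where the alignment window is known)
  need <- cfg$n_stimuli_per_session *
    (cfg$stimulus_duration + cfg$min_interval)
  if (need > cfg$session_length)
    stop("infeasible stimulus schedule: ", cfg$n_stimuli_per_session,
         " stimuli do not fit into ", cfg$session_length, " s")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_neurons, " neurons, ", x$n_sessions, " x ",
      x$session_length, " s @ ", x$frame_rate, " Hz, ",
      x$n_stimuli_per_session, " stimuli/session\n", sep = "")
  cat("  fractions act/inact/none: ",
      sprintf("%.2f/%.2f/%.2f", x$fraction_activated, x$fraction_inactivated,
              x$fraction_nonresponsive),
      ", evoked amplitude ", x$evoked_amplitude,
      ", opto gain (s2) ", x$opto_gain_session2, "\n", sep = "")
  invisible(x)
}
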