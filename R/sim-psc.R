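#' Configure and simulate paired voltage-clamp PSC recordings
#'
#' `psc_sim()` describes a compound postsynaptic-current experiment recorded
#' at two holding potentials: near -50 mV (between the glutamate and GABA
#' reversal potentials, where IPSCs appear as outward currents) and at -92 mV
#' (the GABA-A equilibrium potential, where only the EPSC remains).
#' `simulate_psc_recording()` renders the trial set: every trial contains an
#' inward EPSC (biexponential kernel) at the stimulus time; -50 mV trials
#' additionally contain, with probability `ipsc_release_probability`, an
#' outward feedforward IPSC at the planted latency after the EPSC onset.
#'
#' @param epsc_amplitude_pa,ipsc_amplitude_pa peak amplitudes (positive
#'   numbers; the EPSC is rendered inward/negative, the IPSC outward/positive).
#' @param epsc_rise_ms,epsc_decay_ms,ipsc_rise_ms,ipsc_decay_ms biexponential
#'   kernel time constants.
#' @param ipsc_latency_ms planted onset-to-onset latency between EPSC and
#'   feedforward IPSC (must be > 0).
#' @param ipsc_release_probability per-trial probability that the disynaptic
#'   IPSC is released.
#' @param epsc_scale_minus50 driving-force scaling of the EPSC at -50 mV
#'   relative to -92 mV.
#' @param n_trials trials per holding potential.
#' @param stim_time_s stimulus time within the trial.
#' @param trial_length_s trial duration.
#' @param sampling_rate Hz.
#' @param noise_sd_pa white current noise SD.
#' @param seed RNG seed.
#' @return `psc_sim()`: a validated config of class `psc_sim`.
#' @export
psc_sim <- function(epsc_amplitude_pa = 100, ipsc_amplitude_pa = 50,
                    epsc_rise_ms = 0.3, epsc_decay_ms = 4,
                    ipsc_rise_ms = 0.3, ipsc_decay_ms = 8,
                    ipsc_latency_ms = 3, ipsc_release_probability = 0.7,
                    epsc_scale_minus50 = 0.6,
                    n_trials = 10, stim_time_s = 0.05, trial_length_s = 0.25,
                    sampling_rate = 20000, noise_sd_pa = 0, seed = 1L) {
  if (ipsc_latency_ms <= 0) stop("ipsc_latency_ms must be > 0")
  if (ipsc_release_probability < 0 || ipsc_release_probability > 1)
    stop("ipsc_release_probability must be in [0, 1]")
  stopifnot(epsc_amplitude_pa >= 0, ipsc_amplitude_pa >= 0, n_trials >= 1,
            epsc_rise_ms > 0, epsc_decay_ms > epsc_rise_ms,
            ipsc_rise_ms > 0, ipsc_decay_ms > ipsc_rise_ms,
            noise_sd_pa >= 0)
  structure(as.list(environment()), class = "psc_sim")
}

#' @rdname psc_sim
#' @param psc a `psc_sim` configuration.
#' @return `simulate_psc_recording()`: object of class `psc_trial_set` with
#'   `trials_minus50` and `trials_minus92` (trial x sample matrices, pA),
#'   `time` (s), `stim_time_s`, `sampling_rate` and a `planted` list
#'   (IPSC latency, amplitude, per-trial release indicator).
#' @export
simulate_psc_recording <- function(psc) {
  stopifnot(inherits(psc, "psc_sim"))
  set.seed(as.integer(psc$seed))
  fs <- psc$sampling_rate
  dt <- 1 / fs
  tt <- seq(0, psc$trial_length_s - dt, by = dt)
  n_samp <- length(tt)
  i_stim <- round(psc$stim_time_s * fs) + 1L

  epsc <- biexp_kernel(tt, psc$epsc_rise_ms / 1000, psc$epsc_decay_ms / 1000,
                       psc$epsc_amplitude_pa)
  ipsc <- biexp_kernel(tt, psc$ipsc_rise_ms / 1000, psc$ipsc_decay_ms / 1000,
                       psc$ipsc_amplitude_pa)
  lat_samp <- round(psc$ipsc_latency_ms / 1000 * fs)

  place <- function(kern, at) {
    out <- numeric(n_samp)
    idx <- at:n_samp
    out[idx] <- kern[seq_along(idx)]
    out
  }
  epsc_m92 <- -place(epsc, i_stim)
  epsc_m50 <- psc$epsc_scale_minus50 * epsc_m92
  ipsc_m50 <- place(ipsc, i_stim + lat_samp)

  released <- runif(psc$n_trials) < psc$ipsc_release_probability
  m92 <- matrix(rep(epsc_m92, each = psc$n_trials), nrow = psc$n_trials)
  m50 <- matrix(rep(epsc_m50, each = psc$n_trials), nrow = psc$n_trials) +
    outer(as.numeric(released), ipsc_m50)
  if (psc$noise_sd_pa > 0) {
    m92 <- m92 + matrix(rnorm(length(m92), sd = psc$noise_sd_pa),
                        nrow = psc$n_trials)
    m50 <- m50 + matrix(rnorm(length(m50), sd = psc$noise_sd_pa),
                        nrow = psc$n_trials)
  }
  structure(list(trials_minus50 = m50, trials_minus92 = m92, time = tt,
                 stim_time_s = psc$stim_time_s, sampling_rate = fs,
                 planted = list(ipsc_latency_ms = psc$ipsc_latency_ms,
                                ipsc_amplitude_pa = psc$ipsc_amplitude_pa,
                                released = released),
                 config = psc),
            class = "psc_trial_set")
}

## biexponential kernel normalised to the requested peak amplitude
biexp_kernel <- function(tt, tau_rise, tau_decay, amplitude) {
  k <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  pk <- max(k)
  if (pk <= 0) return(k * 0)
  k / pk * amplitude
}
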