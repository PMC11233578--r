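#' Simulate current-clamp sweep sets with planted intrinsic parameters
#'
#' Generates idealised 1-s current-step sweeps (default protocol -50 to +50 pA
#' in 10 pA increments at 20 kHz) from a passive-membrane model with optional
#' sag and stereotyped action potentials, for validating the intrinsic-feature
#' extractors. Subthreshold sweeps follow
#' \deqn{V(t) = V_{rest} + I R_{in} (1 - e^{-t/\tau})}
#' plus, for hyperpolarising steps, a sag bump (Gaussian, centred 0.2 s into
#' the step) whose depth is planted, so that the planted sag ratio is
#' \eqn{|IR_{in}| / (|IR_{in}| + d_{sag})} in closed form. Suprathreshold
#' sweeps insert stereotyped spikes: a quarter-sine upstroke from the planted
#' threshold voltage (maximum dV/dt well above the 50 V/s detection criterion),
#' a half-cosine downstroke reaching the afterhyperpolarisation minimum at the
#' planted latency after threshold, and an exponential recovery. The two
#' archetypes differ the way layer-1 interneuron classes do: `"SBC"`-like
#' cells fire early atop a pronounced depolarising hump, `"NGF"`-like cells
#' fire late with a small hump.
#'
#' @param archetype `"NGF"` or `"SBC"`; chooses the default planted parameters.
#' @param planted named list overriding any planted parameter:
#'   `rin_mohm`, `tau_ms`, `sag_depth_mv`, `v_rest_mv`, `rheobase_pa`,
#'   `spike_latency_s` (first AP peak relative to step onset), `ahp_latency_s`
#'   (threshold to AHP minimum), `ahp_depth_mv`, `ap_amplitude_mv`, `hump_mv`.
#' @param current_steps injected currents, pA.
#' @param sampling_rate Hz.
#' @param noise_sd_mv Gaussian voltage noise SD (0 = noiseless).
#' @param seed RNG seed (only used when `noise_sd_mv > 0`).
#' @return Object of class `sweep_set`: `time` (s), `sweeps` (sample x sweep
#'   matrix, mV), `current_steps` (pA), `sampling_rate`, `step_onset_s`,
#'   `step_dur_s`, `archetype` and the `planted` parameter list (including the
#'   implied closed-form `sag_ratio`).
#' @export
simulate_voltage_sweeps <- function(archetype = c("NGF", "SBC"),
                                    planted = list(),
                                    current_steps = seq(-50, 50, by = 10),
                                    sampling_rate = 20000,
                                    noise_sd_mv = 0,
                                    seed = 1L) {
  archetype <- match.arg(archetype)
  p <- sweep_archetype_defaults(archetype)
  p[names(planted)] <- planted
  if (p$rin_mohm <= 0 || p$tau_ms <= 0)
    stop("non-physical parameters: Rin and tau must be > 0")
  if (p$sag_depth_mv < 0 || p$ahp_latency_s <= 0 || p$spike_latency_s <= 0)
    stop("non-physical parameters: sag depth and latencies must be >= 0")

  fs <- sampling_rate
  dt <- 1 / fs
  step_onset <- 0.2
  step_dur <- 1
  total <- step_onset + step_dur + 0.3
  tt <- seq(0, total - dt, by = dt)
  n_samp <- length(tt)
  ts <- tt - step_onset                  # time relative to step onset
  in_step <- ts >= 0 & ts < step_dur
  tau_s <- p$tau_ms / 1000

  set.seed(as.integer(seed))
  sweeps <- matrix(NA_real_, n_samp, length(current_steps))
  for (j in seq_along(current_steps)) {
    I <- current_steps[j]
    ss <- I * p$rin_mohm * 1e-3          # steady-state deflection, mV
    v <- rep(p$v_rest_mv, n_samp)
    rise <- ifelse(in_step, 1 - exp(-ts / tau_s), 0)
    post <- ts >= step_dur
    relax <- ifelse(post, exp(-(ts - step_dur) / tau_s), 0)
    v <- v + ss * (rise + relax * (1 - exp(-step_dur / tau_s)))
    if (I < 0 && p$sag_depth_mv > 0) {
      # sag: extra undershoot peaking 0.2 s into the step, gone by 0.4 s
      bump <- exp(-((ts - 0.2)^2) / (2 * 0.04^2)) * in_step
      v <- v - p$sag_depth_mv * bump * abs(I) / 50
    }
    if (I >= p$rheobase_pa) {
      v <- insert_spikes(v, tt, ts, p, I, fs, step_onset, step_dur, tau_s)
    }
    sweeps[, j] <- v
  }
  if (noise_sd_mv > 0)
    sweeps <- sweeps + matrix(rnorm(length(sweeps), sd = noise_sd_mv),
                              nrow = n_samp)

  ss50 <- 50 * p$rin_mohm * 1e-3
  p$sag_ratio <- ss50 / (ss50 + p$sag_depth_mv)
  structure(list(time = tt, sweeps = sweeps, current_steps = current_steps,
                 sampling_rate = fs, step_onset_s = step_onset,
                 step_dur_s = step_dur, archetype = archetype, planted = p),
            class = "sweep_set")
}

sweep_archetype_defaults <- function(archetype) {
  if (archetype == "NGF") {
    # late-spiking, small hump, slow AHP
    list(rin_mohm = 250, tau_ms = 20, sag_depth_mv = 1.5, v_rest_mv = -65,
         rheobase_pa = 40, spike_latency_s = 0.40, ahp_latency_s = 0.015,
         ahp_depth_mv = 10, ap_amplitude_mv = 65, hump_mv = 1.5)
  } else {
    # early-spiking atop a depolarising hump, fast AHP
    list(rin_mohm = 350, tau_ms = 15, sag_depth_mv = 2.5, v_rest_mv = -65,
         rheobase_pa = 40, spike_latency_s = 0.04, ahp_latency_s = 0.006,
         ahp_depth_mv = 8, ap_amplitude_mv = 70, hump_mv = 6)
  }
}

## Insert stereotyped spikes (and the archetype's depolarising hump) into a
## suprathreshold sweep. The first 50 V/s crossing lands on the first upstroke
## sample, whose voltage is exactly the planted threshold.
insert_spikes <- function(v, tt, ts, p, I, fs, step_onset, step_dur, tau_s) {
  dt <- 1 / fs
  ss <- I * p$rin_mohm * 1e-3
  plateau <- p$v_rest_mv + ss
  v_thr <- plateau + p$hump_mv
  rise_t <- 5e-4                         # AP upstroke duration, s
  n_extra <- floor((I - p$rheobase_pa) / 10)
  peak_times <- p$spike_latency_s + 0.1 * (0:n_extra)
  peak_times <- peak_times[peak_times < step_dur - 0.05]

  in_step <- ts >= 0 & ts < step_dur
  t_on1 <- peak_times[1] - rise_t
  late <- p$spike_latency_s >= 0.35
  if (late) {
    # delayed-spiking archetype: the depolarising hump is an early transient,
    # peaking at 0.15 s and decayed again by the 0.3-s reference point
    v <- v + p$hump_mv * exp(-((ts - 0.15)^2) / (2 * 0.04^2)) * in_step
  }
  # narrow ramp carrying the trajectory to threshold at the first spike onset
  base_at_on <- p$v_rest_mv + ss * (1 - exp(-t_on1 / tau_s)) +
    if (late) p$hump_mv * exp(-((t_on1 - 0.15)^2) / (2 * 0.04^2)) else 0
  bump_amp <- v_thr - base_at_on
  bump_sd <- max(0.008, min(0.02, t_on1 / 2.5))
  v <- v + bump_amp * exp(-((ts - t_on1)^2) / (2 * bump_sd^2)) * in_step

  for (tp in peak_times) {
    t_on <- tp - rise_t
    i_on <- which.min(abs(ts - t_on))
    i_peak <- i_on + round(rise_t / dt)
    i_min <- i_on + round(p$ahp_latency_s / dt)
    if (i_min >= length(v)) next
    v_peak <- v_thr + p$ap_amplitude_mv
    v_min <- v_thr - p$ahp_depth_mv
    up <- i_on:i_peak
    v[up] <- v_thr + (v_peak - v_thr) *
      sin(pi / 2 * (up - i_on) / (i_peak - i_on))
    dn <- i_peak:i_min
    v[dn] <- v_min + (v_peak - v_min) *
      (cos(pi * (dn - i_peak) / (i_min - i_peak)) + 1) / 2
    rec <- (i_min + 1):min(length(v), i_min + round(0.08 / dt))
    base <- p$v_rest_mv + ss * (1 - exp(-ts[rec] / tau_s))
    v[rec] <- base + (v_min - base[1]) * exp(-(ts[rec] - ts[i_min]) / 0.02)
  }
  v
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", x$archetype, "-like archetype, ",
      length(x$current_steps), " sweeps (",
      min(x$current_steps), "..", max(x$current_steps), " pA) @ ",
      x$sampling_rate / 1000, " kHz\n", sep = "")
  invisible(x)
}
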