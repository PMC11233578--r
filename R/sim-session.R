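#' Simulate a multi-session calcium-imaging data set with planted ground truth
#'
#' Forward model emulating CNMF-style extracted traces recorded while 1-s
#' mechanical stimuli are delivered at random intervals. Each neuron carries a
#' planted class (`activated`, `inactivated`, `nonresponsive`): activated
#' neurons receive a deterministic positive evoked transient per stimulus
#' (stimulus boxcar convolved with the indicator kernel, peak-normalised to the
#' planted amplitude), inactivated neurons a negative transient bounded by the
#' tonic calcium level plus a suppression of background spiking during the
#' stimulus, and non-responsive neurons nothing but stationary background
#' activity. Evoked transients in session 2 are scaled by
#' `opto_gain_session2`, emulating optogenetic recruitment of a modulatory
#' projection. Per-trial withdrawal flags are set by thresholding the noisy
#' summed activated-population response.
#'
#' @param config a [sim_config()].
#' @return An object of class `session_set`: list with `sessions` (per session,
#'   `f` and `background` neuron-by-frame matrices), `events` (data.frame with
#'   `session`, `onset_frame`, `duration_frames`, `withdrawal`, `opto`),
#'   `frame_rate`, `ml_coordinate_um`, `ground_truth` (planted class and
#'   amplitude per neuron) and the generating `config`.
#' @seealso [compute_dff()], [responsiveness_test()], [run_pipeline()]
#' @export
simulate_session_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  fr <- config$frame_rate
  dt <- 1 / fr
  n_frames <- round(config$session_length * fr)
  n <- config$n_neurons

  ## planted classes, amplitudes, positions
  n_act <- round(n * config$fraction_activated)
  n_inact <- round(n * config$fraction_inactivated)
  classes <- sample(rep(c("activated", "inactivated", "nonresponsive"),
                        c(n_act, n_inact, n - n_act - n_inact)))
  amp <- numeric(n)
  act <- classes == "activated"
  inact <- classes == "inactivated"
  amp[act] <- config$evoked_amplitude * runif(sum(act), 0.9, 1.1)
  amp[inact] <- -pmin(config$evoked_amplitude * runif(sum(inact), 0.9, 1.1),
                      0.8 * config$tonic_dff)
  # a zero planted amplitude is no response at all (the null case)
  classes[amp == 0] <- "nonresponsive"
  act <- classes == "activated"
  inact <- classes == "inactivated"
  ml <- runif(n, 0, 900)

  ## indicator kernel (sampled) and peak-normalised evoked waveform
  kern_t <- seq(0, 6 * config$indicator_decay_tau, by = dt)
  kern <- exp(-kern_t / config$indicator_decay_tau) -
    exp(-kern_t / config$indicator_rise_tau)
  kern_peak <- max(kern)
  dur_frames <- max(1L, round(config$stimulus_duration * fr))
  single_box <- c(rep(1, dur_frames), rep(0, length(kern)))
  evoked_unit <- causal_conv(single_box, kern)
  evoked_peak <- max(evoked_unit)

  a_d <- exp(-dt / config$indicator_decay_tau)
  a_r <- exp(-dt / config$indicator_rise_tau)

  sessions <- vector("list", config$n_sessions)
  events <- vector("list", config$n_sessions)
  thr <- config$withdrawal_threshold
  if (is.null(thr)) thr <- config$evoked_amplitude

  for (s in seq_len(config$n_sessions)) {
    onsets <- schedule_onsets(config, n_frames)
    gain <- if (s == 2L) config$opto_gain_session2 else 1
    opto <- s == 2L

    stim_on <- numeric(n_frames)   # 1 during stimulus frames
    supp_on <- numeric(n_frames)   # 1 during suppression window (stim + 1 s)
    for (o in onsets) {
      stim_on[o:min(n_frames, o + dur_frames - 1L)] <- 1
      supp_on[o:min(n_frames, o + dur_frames + fr - 1L)] <- 1
    }
    evoked_shape <- causal_conv(stim_on, kern) / evoked_peak

    ## background spiking: Poisson, suppressed around stimuli for inactivated
    lam <- config$baseline_rate * dt
    spikes <- matrix(rpois(n_frames * n, lam), nrow = n_frames, ncol = n)
    if (any(inact) && lam > 0) {
      sup_idx <- which(supp_on > 0)
      spikes[sup_idx, inact] <- 0L
    }
    ## double-exponential convolution via two one-pole recursions
    conv <- stats::filter(spikes, a_d, method = "recursive") -
      stats::filter(spikes, a_r, method = "recursive")
    conv <- conv * (config$spike_amplitude / kern_peak)

    evoked <- outer(evoked_shape, amp * gain)          # frames x neurons
    calcium <- config$tonic_dff + conv + evoked

    phase <- runif(n, 0, 2 * pi)
    tvec <- seq_len(n_frames) * dt
    drift <- config$drift_amplitude *
      sin(outer(tvec, rep(2 * pi / 200, n)) + rep(phase, each = n_frames))
    noise <- matrix(rnorm(n_frames * n, sd = config$noise_sd),
                    nrow = n_frames)
    f <- config$f_base * (1 + calcium) + drift + noise

    ## background overlap: offset + shared low-pass noise
    shared <- as.numeric(stats::filter(rnorm(n_frames), 0.95,
                                       method = "recursive"))
    if (sd(shared) > 0) shared <- shared / sd(shared) * config$background_sd
    bg_row <- config$background_level * config$f_base + shared
    background <- matrix(rep(bg_row, n), nrow = n_frames)

    ## withdrawal per trial from the noisy summed activated response
    base_score <- if (any(act)) mean(amp[act]) * gain else 0
    wd <- base_score + rnorm(length(onsets), sd = config$withdrawal_noise_sd) > thr

    sessions[[s]] <- list(f = t(f), background = t(background))
    events[[s]] <- data.frame(session = s, onset_frame = onsets,
                              duration_frames = dur_frames,
                              withdrawal = wd, opto = opto)
  }

  structure(list(
    sessions = sessions,
    events = do.call(rbind, events),
    frame_rate = fr,
    ml_coordinate_um = ml,
    ground_truth = data.frame(neuron = seq_len(n), class = classes,
                              amplitude = amp),
    config = config), class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat("<session_set> ", nrow(x$sessions[[1]]$f), " neurons, ",
      length(x$sessions), " sessions of ", ncol(x$sessions[[1]]$f),
      " frames @ ", x$frame_rate, " Hz, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

## Causal discrete convolution, output truncated to length(x).
causal_conv <- function(x, kern) {
  out <- stats::convolve(x, rev(kern), type = "open")
  out[seq_along(x)]
}

## Draw a feasible stimulus schedule: minimum gaps plus uniform jitter,
## rescaled into the available slack so a drawn schedule is never infeasible.
schedule_onsets <- function(config, n_frames) {
  fr <- config$frame_rate
  k <- config$n_stimuli_per_session
  pre_margin <- 2                       # s before the first onset
  post_margin <- 5.5                    # s: full 5-s post window must fit
  dur <- config$stimulus_duration
  slack <- config$session_length - pre_margin - post_margin -
    k * (dur + config$min_interval)
  if (slack < 0)
    stop("infeasible stimulus schedule: ", k, " stimuli with minimum gap ",
         config$min_interval, " s do not fit into ", config$session_length,
         " s with alignment margins")
  extra <- runif(k, 0, config$max_interval - config$min_interval)
  if (sum(extra) > slack && sum(extra) > 0)
    extra <- extra * slack / sum(extra)
  gaps <- config$min_interval + extra
  onset_s <- pre_margin + cumsum(gaps) + dur * (seq_len(k) - 1)
  sort(round(onset_s * fr)) + 1L
}
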