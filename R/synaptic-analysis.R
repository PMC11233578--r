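#' Detect a PSC onset by fractional-peak crossing
#'
#' On a 3-kHz low-pass-filtered copy of the (baseline-subtracted) trace, the
#' onset is the first sample after the stimulus at which the current in the
#' requested direction exceeds `frac` (default 5%) of its peak, searching
#' back from the peak so that later noise excursions cannot pre-empt it.
#'
#' @param trace current trace, pA (baseline-subtracted).
#' @param time time axis, s.
#' @param stim_time_s search start, s.
#' @param sampling_rate Hz.
#' @param direction `"inward"` (negative peak) or `"outward"`.
#' @param frac fraction of peak defining the onset.
#' @param search_window_s how far past the stimulus to search for the peak.
#' @return list: `onset_s`, `i_onset`, `peak`, `i_peak`; errors when no
#'   clear peak exists.
#' @export
detect_psc_onset <- function(trace, time, stim_time_s, sampling_rate,
                             direction = c("inward", "outward"),
                             frac = 0.05, search_window_s = 0.05) {
  direction <- match.arg(direction)
  tf <- lowpass_trace(trace, sampling_rate)
  sgn <- if (direction == "inward") -1 else 1
  y <- sgn * tf
  sel <- which(time >= stim_time_s & time <= stim_time_s + search_window_s)
  if (!length(sel)) stop("stimulus window outside trace")
  i_peak <- sel[which.max(y[sel])]
  peak <- y[i_peak]
  base_sd <- sd(y[time < stim_time_s])
  if (peak <= 5 * base_sd || peak <= 0)
    stop("undetectable PSC onset: no peak above noise")
  # last sample before the peak still below frac * peak (the search may step
  # a little before the stimulus: zero-phase filtering smears the rise back)
  pre <- which(time >= stim_time_s - 0.002)
  pre <- pre[pre <= i_peak]
  below <- pre[y[pre] < frac * peak]
  if (!length(below)) stop("undetectable PSC onset: no sub-threshold samples")
  i_on <- max(below) + 1L
  peak_raw <- max(sgn * trace[sel])        # amplitude read off the raw trace
  list(onset_s = time[i_on], i_onset = i_on, peak = sgn * peak_raw,
       i_peak = i_peak)
}

## linear initial slope over `slope_window_s` from a detected onset (pA/ms)
initial_slope <- function(trace, time, i_onset, sampling_rate,
                          slope_window_s = 0.001) {
  idx <- i_onset:min(length(trace), i_onset + round(slope_window_s *
                                                      sampling_rate))
  coef(lm(trace[idx] ~ time[idx]))[[2]] / 1000
}

#' Isolate the feedforward IPSC by initial-slope scaled subtraction
#'
#' The averaged pure EPSC (recorded at the GABA-A equilibrium potential,
#' -92 mV) is scaled so that its initial slope matches the initial slope of
#' the averaged compound PSC recorded near -50 mV, then subtracted; the
#' outward residual is the feedforward IPSC. Onsets are located by
#' fractional-peak crossing ([detect_psc_onset()]), the latency is the IPSC
#' onset minus the EPSC onset.
#'
#' @param trial_set a `psc_trial_set` (see [simulate_psc_recording()]).
#' @param slope_window_s window of the initial-slope linear fit, s.
#' @param frac onset fraction-of-peak criterion.
#' @return object of class `ff_ipsc_result`: `isolated_trace`,
#'   `scale_factor`, `epsc_onset_s`, `ipsc_onset_s`, `latency_ms`,
#'   `amplitude_pa`, `excluded` (FALSE here; see [apply_exclusion_rules()]),
#'   `exclusion_reason`.
#' @export
isolate_ff_ipsc <- function(trial_set, slope_window_s = 5e-4, frac = 0.05) {
  fs <- trial_set$sampling_rate
  tt <- trial_set$time
  stim <- trial_set$stim_time_s
  base <- tt < stim
  avg50 <- colMeans(trial_set$trials_minus50)
  avg92 <- colMeans(trial_set$trials_minus92)
  avg50 <- avg50 - mean(avg50[base])
  avg92 <- avg92 - mean(avg92[base])

  on92 <- detect_psc_onset(avg92, tt, stim, fs, "inward", frac)
  on50 <- detect_psc_onset(avg50, tt, stim, fs, "inward", frac)
  s92 <- initial_slope(avg92, tt, on92$i_onset, fs, slope_window_s)
  s50 <- initial_slope(avg50, tt, on50$i_onset, fs, slope_window_s)
  if (s92 == 0) stop("flat pure EPSC: cannot scale")
  scale <- s50 / s92
  ff <- avg50 - scale * avg92

  ipsc_on <- try(detect_psc_onset(ff, tt, on50$onset_s, fs, "outward", frac),
                 silent = TRUE)
  if (inherits(ipsc_on, "try-error")) {
    return(structure(list(isolated_trace = ff, scale_factor = scale,
                          epsc_onset_s = on50$onset_s, ipsc_onset_s = NA_real_,
                          latency_ms = NA_real_, amplitude_pa = NA_real_,
                          excluded = FALSE, exclusion_reason = "none",
                          time = tt), class = "ff_ipsc_result"))
  }
  structure(list(isolated_trace = ff, scale_factor = scale,
                 epsc_onset_s = on50$onset_s, ipsc_onset_s = ipsc_on$onset_s,
                 latency_ms = 1000 * (ipsc_on$onset_s - on50$onset_s),
                 amplitude_pa = ipsc_on$peak,
                 excluded = FALSE, exclusion_reason = "none",
                 time = tt), class = "ff_ipsc_result")
}

#' Apply the antidromic-contamination exclusion rules
#'
#' A recording is excluded when (a) an apparent outward IPSC is present in
#' 100% of the -50 mV trials (antidromic activation is reliable and
#' temporally precise, feedforward release is not), or (b) the
#' EPSC-to-IPSC latency is shorter than 1 ms. Per-trial outward events are
#' detected as excursions above `sd_mult` baseline SDs within a search
#' window after the EPSC onset.
#'
#' @param trial_set the `psc_trial_set`.
#' @param ff_result an [isolate_ff_ipsc()] result.
#' @param sd_mult per-trial detection threshold, baseline SDs.
#' @param search_window_s `c(from, to)` relative to the EPSC onset, s.
#' @param min_latency_ms exclusion bound on the latency.
#' @return the `ff_ipsc_result` updated with `excluded`, `exclusion_reason`
#'   (`outward_incidence_100`, `latency_below_1ms` or `none`) and
#'   `outward_incidence`.
#' @export
apply_exclusion_rules <- function(trial_set, ff_result, sd_mult = 3,
                                  search_window_s = c(0.001, 0.020),
                                  min_latency_ms = 1) {
  tt <- trial_set$time
  on <- ff_result$epsc_onset_s
  sel <- tt >= on + search_window_s[1] & tt <= on + search_window_s[2]
  base <- tt < trial_set$stim_time_s
  m50 <- trial_set$trials_minus50
  outward <- apply(m50, 1, function(tr) {
    tr <- tr - mean(tr[base])
    max(tr[sel]) > sd_mult * max(sd(tr[base]), 1e-12)
  })
  incidence <- mean(outward)
  ff_result$outward_incidence <- incidence
  if (incidence == 1) {
    ff_result$excluded <- TRUE
    ff_result$exclusion_reason <- "outward_incidence_100"
  } else if (is.finite(ff_result$latency_ms) &&
             ff_result$latency_ms < min_latency_ms) {
    ff_result$excluded <- TRUE
    ff_result$exclusion_reason <- "latency_below_1ms"
  }
  ff_result
}

#' Inward synaptic charge
#'
#' Trapezoidal time-integral of the inward (negative) component of a
#' baseline-subtracted current trace over a window; outward current does not
#' contribute. Reported positive, in picocoulombs (pA x s = pC).
#'
#' @param trace current, pA (baseline-subtracted).
#' @param time s.
#' @param window `c(from, to)`, s.
#' @return list: `inward_charge_pc`, `window`.
#' @export
inward_charge <- function(trace, time, window) {
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 2) stop("integration window outside trace")
  q <- -pracma::trapz(time[sel], pmin(trace[sel], 0))
  list(inward_charge_pc = q, window = window)
}

#' Spiking probability per condition
#'
#' @param outcomes logical spike outcomes, one per trial.
#' @param condition condition label per trial (e.g. before / during_opto /
#'   after).
#' @return data.frame: `condition`, `n_trials`, `n_spikes`, `probability`
#'   (percent).
#' @export
spike_probability <- function(outcomes, condition) {
  stopifnot(length(outcomes) == length(condition))
  if (!length(outcomes)) stop("zero trials")
  agg <- tapply(outcomes, condition, function(x) c(n = length(x),
                                                   k = sum(x)))
  out <- do.call(rbind, lapply(names(agg), function(cn) {
    data.frame(condition = cn, n_trials = agg[[cn]]["n"],
               n_spikes = agg[[cn]]["k"],
               probability = 100 * agg[[cn]]["k"] / agg[[cn]]["n"])
  }))
  rownames(out) <- NULL
  out
}

#' Connectivity percentages per cell type
#'
#' Two-decimal percentage of connected over tested cells, the convention of
#' connectivity summaries (21 of 58 -> 36.21%).
#'
#' @param counts data.frame with `cell_type`, `connected`, `tested`.
#' @return the input with a `percent` column.
#' @export
connectivity_summary <- function(counts) {
  stopifnot(all(c("cell_type", "connected", "tested") %in% names(counts)))
  if (any(counts$tested == 0)) stop("tested count of zero")
  if (any(counts$connected > counts$tested | counts$connected < 0))
    stop("connected counts must lie in [0, tested]")
  counts$percent <- round(100 * counts$connected / counts$tested, 2)
  counts
}
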