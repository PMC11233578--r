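#' Low-pass filter a voltage trace like the acquisition chain
#'
#' Zero-phase 4th-order Butterworth low-pass (default 3 kHz cut-off, the
#' hardware filter setting the derivative criterion assumes). Returns the
#' input unchanged when the cut-off is at or above Nyquist.
#'
#' @param v voltage trace, mV.
#' @param sampling_rate Hz.
#' @param cutoff Hz.
#' @return filtered trace.
#' @export
lowpass_trace <- function(v, sampling_rate, cutoff = 3000) {
  if (cutoff >= sampling_rate / 2) return(v)
  bf <- signal::butter(4, cutoff / (sampling_rate / 2), type = "low")
  # pad with the edge values so filter start-up transients stay outside
  npad <- min(length(v), ceiling(0.02 * sampling_rate))
  padded <- c(rep(v[1], npad), v, rep(v[length(v)], npad))
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(npad + 1):(npad + length(v))]
}

## deflection of a sweep relative to its pre-step baseline
sweep_deflection <- function(sweep_set, j) {
  v <- sweep_set$sweeps[, j]
  ts <- sweep_set$time - sweep_set$step_onset_s
  base <- median(v[ts < 0])
  list(v = v, ts = ts, defl = v - base)
}

#' Input resistance from subthreshold current steps
#'
#' Slope of the median steady-state voltage deflection (last 0.3 s of the
#' 1-s step, relative to the pre-step baseline) against injected current,
#' over the +/-30 pA subthreshold sweeps. Sweeps containing action potentials
#' are excluded.
#'
#' @param sweep_set a `sweep_set` (see [simulate_voltage_sweeps()]).
#' @param max_abs_current only sweeps with `|I|` at or below this (pA) enter
#'   the fit.
#' @return input resistance, megaohms.
#' @export
input_resistance <- function(sweep_set, max_abs_current = 30) {
  keep <- which(abs(sweep_set$current_steps) <= max_abs_current &
                  sweep_set$current_steps != 0)
  keep <- keep[!vapply(keep, function(j) sweep_has_spikes(sweep_set, j),
                       logical(1))]
  if (length(keep) < 2) stop("need at least 2 non-spiking subthreshold sweeps")
  defl <- vapply(keep, function(j) {
    d <- sweep_deflection(sweep_set, j)
    median(d$defl[d$ts >= sweep_set$step_dur_s - 0.3 &
                    d$ts < sweep_set$step_dur_s])
  }, numeric(1))
  I <- sweep_set$current_steps[keep]
  slope <- coef(lm(defl ~ I))[["I"]]       # mV / pA = GOhm
  slope * 1000
}

sweep_has_spikes <- function(sweep_set, j) {
  nrow(detect_aps(sweep_set$sweeps[, j], sweep_set$sampling_rate)) > 0
}

#' Membrane time constant from the -50 pA step
#'
#' Single-exponential least-squares fit,
#' \eqn{V(t) = V_\infty + A e^{-t/\tau}}, over the first 0.1 s of the voltage
#' relaxation after step onset. Initialised from a log-linear regression; a
#' non-convergent or degenerate fit is an error.
#'
#' @param sweep_set a `sweep_set`.
#' @param current step current to use, pA (default -50).
#' @param fit_range fit window from step onset, s.
#' @return time constant, ms.
#' @export
membrane_time_constant <- function(sweep_set, current = -50,
                                   fit_range = 0.1) {
  j <- which(sweep_set$current_steps == current)
  if (!length(j)) stop("no sweep at ", current, " pA")
  d <- sweep_deflection(sweep_set, j[1])
  sel <- d$ts >= 0 & d$ts < fit_range
  tt <- d$ts[sel]
  y <- d$defl[sel]
  y_inf <- mean(d$defl[d$ts >= fit_range - 0.02 & d$ts < fit_range])
  s0 <- sign(y[1] - y_inf)                  # relaxation direction
  r <- s0 * (y - y_inf)                     # decays from |A| toward 0
  if (max(r) <= 0 || sd(y) == 0) stop("degenerate trace: no relaxation to fit")
  ok <- r > 0.02 * max(r)
  if (sum(ok) < 10) stop("degenerate trace: no relaxation to fit")
  lf <- lm(log(r[ok]) ~ tt[ok])
  tau0 <- -1 / coef(lf)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- fit_range / 5
  fit <- try(nls(y ~ vinf + a * exp(-tt / tau),
                 start = list(vinf = y_inf, a = -y_inf, tau = tau0),
                 control = stats::nls.control(maxiter = 200,
                                              scaleOffset = 1)),
             silent = TRUE)
  if (inherits(fit, "try-error")) stop("exponential fit did not converge")
  tau <- coef(fit)[["tau"]]
  if (tau <= 0) stop("non-physical fitted time constant")
  tau * 1000
}

#' Sag ratio from the -50 pA step
#'
#' Median steady-state deflection over the last 0.3 s of the step divided by
#' the minimum deflection in the first 0.3 s (both relative to the pre-step
#' baseline). 1 means no sag; smaller values mean a deeper Ih-like sag.
#'
#' @param sweep_set a `sweep_set`.
#' @param current hyperpolarising step current, pA.
#' @return sag ratio (dimensionless, in (0, 1] for physiological traces).
#' @export
sag_ratio <- function(sweep_set, current = -50) {
  j <- which(sweep_set$current_steps == current)
  if (!length(j)) stop("no hyperpolarising sweep at ", current, " pA")
  d <- sweep_deflection(sweep_set, j[1])
  ss <- median(d$defl[d$ts >= sweep_set$step_dur_s - 0.3 &
                        d$ts < sweep_set$step_dur_s])
  mn <- min(d$defl[d$ts >= 0 & d$ts < 0.3])
  if (mn == 0) stop("zero deflection: sag undefined")
  ss / mn
}

#' Detect action potentials by the dV/dt threshold criterion
#'
#' dV/dt is computed by central differences on a 3-kHz low-pass-filtered copy
#' of the trace. Each spike's threshold is the voltage at the first upward
#' crossing of `dvdt_threshold` (default 50 V/s); its peak is the raw-trace
#' maximum within 5 ms of threshold; amplitude is peak minus threshold.
#' Crossings within a 2-ms refractory window of a previous spike are merged.
#'
#' @param v voltage sweep, mV.
#' @param sampling_rate Hz (>= 10 kHz recommended).
#' @param dvdt_threshold V/s.
#' @return data.frame with one row per spike: `i_threshold`, `i_peak`
#'   (sample indices), `v_threshold`, `v_peak`, `amplitude` (mV).
#' @export
detect_aps <- function(v, sampling_rate, dvdt_threshold = 50) {
  vf <- lowpass_trace(v, sampling_rate)
  n <- length(v)
  dvdt <- c(0, (vf[3:n] - vf[1:(n - 2)]) * sampling_rate / 2, 0) / 1000 # V/s
  up <- which(dvdt[-1] >= dvdt_threshold & dvdt[-n] < dvdt_threshold) + 1L
  if (!length(up))
    return(data.frame(i_threshold = integer(0), i_peak = integer(0),
                      v_threshold = numeric(0), v_peak = numeric(0),
                      amplitude = numeric(0)))
  refrac <- round(0.002 * sampling_rate)
  keep <- up[c(TRUE, diff(up) > refrac)]
  win <- round(0.005 * sampling_rate)
  out <- lapply(keep, function(i) {
    seg <- i:min(n, i + win)
    ip <- seg[which.max(v[seg])]
    data.frame(i_threshold = i, i_peak = ip, v_threshold = v[i],
               v_peak = v[ip], amplitude = v[ip] - v[i])
  })
  do.call(rbind, out)
}

#' First-spike latency
#'
#' Time from step onset to the peak of the first action potential.
#'
#' @param sweep_set a `sweep_set`.
#' @param j sweep index.
#' @return latency, s; `NA` if the sweep has no spikes.
#' @export
first_spike_latency <- function(sweep_set, j) {
  sp <- detect_aps(sweep_set$sweeps[, j], sweep_set$sampling_rate)
  if (!nrow(sp)) return(NA_real_)
  sweep_set$time[sp$i_peak[1]] - sweep_set$step_onset_s
}

#' First afterhyperpolarisation latency
#'
#' Time from the first spike's threshold crossing to the post-spike voltage
#' minimum, searched up to the next spike's threshold (or the end of the
#' current step). Flags (errors) when the AHP is truncated, i.e. the minimum
#' sits on the search-window boundary.
#'
#' @param sweep_set a `sweep_set`.
#' @param j sweep index.
#' @param spikes optional precomputed [detect_aps()] table.
#' @return latency, s.
#' @export
first_ahp_latency <- function(sweep_set, j, spikes = NULL) {
  v <- sweep_set$sweeps[, j]
  fs <- sweep_set$sampling_rate
  if (is.null(spikes)) spikes <- detect_aps(v, fs)
  if (!nrow(spikes)) stop("no spikes in sweep")
  i_thr <- spikes$i_threshold[1]
  i_end <- if (nrow(spikes) > 1) spikes$i_threshold[2] - 1L else
    round((sweep_set$step_onset_s + sweep_set$step_dur_s) * fs)
  i_end <- min(i_end, length(v))
  seg <- spikes$i_peak[1]:i_end
  i_min <- seg[which.min(v[seg])]
  if (i_min == i_end) stop("truncated AHP: no minimum before window end")
  (i_min - i_thr) / fs
}

#' Depolarising-hump amplitude (both rule variants)
#'
#' Two definitions, matching the two layer-1 interneuron firing phenotypes:
#' for early-spiking cells (single-bouquet-like) the hump is the first-AP
#' threshold minus the potential 0.3 s after step onset; for delayed-spiking
#' cells (neurogliaform-like) it is the maximal potential in the first 0.3 s
#' minus the potential at 0.3 s. Both are returned; `value` holds the
#' class-appropriate one when a hint is given.
#'
#' @param sweep_set a `sweep_set`.
#' @param j near-threshold sweep index (lowest step that elicits a spike; see
#'   [near_threshold_sweep()]).
#' @param cell_class_hint optional `"pNGF"` or `"pSBC"`.
#' @return list with `ngf_rule`, `sbc_rule` (mV; `sbc_rule` is `NA` with a
#'   warning when the sweep has no spike) and `value`.
#' @export
hump_amplitude <- function(sweep_set, j, cell_class_hint = NULL) {
  v <- sweep_set$sweeps[, j]
  fs <- sweep_set$sampling_rate
  ts <- sweep_set$time - sweep_set$step_onset_s
  i_03 <- which.min(abs(ts - 0.3))
  v_03 <- v[i_03]
  early <- ts >= 0 & ts < 0.3
  spikes <- detect_aps(v, fs)
  # exclude AP waveforms from the early-window maximum
  vmax_src <- v
  if (nrow(spikes)) {
    for (r in seq_len(nrow(spikes))) {
      cut <- spikes$i_threshold[r]:min(length(v),
                                       spikes$i_peak[r] + round(0.01 * fs))
      vmax_src[cut] <- NA
    }
  }
  ngf <- max(vmax_src[early], na.rm = TRUE) - v_03
  sbc <- if (nrow(spikes)) spikes$v_threshold[1] - v_03 else {
    warning("no spike in sweep: early-spiking hump rule undefined")
    NA_real_
  }
  value <- if (is.null(cell_class_hint)) NA_real_
           else if (cell_class_hint == "pNGF") ngf else sbc
  list(ngf_rule = ngf, sbc_rule = sbc, value = value)
}

#' Lowest current step eliciting at least one spike
#'
#' @param sweep_set a `sweep_set`.
#' @return sweep index.
#' @export
near_threshold_sweep <- function(sweep_set) {
  ord <- order(sweep_set$current_steps)
  for (j in ord) {
    if (sweep_set$current_steps[j] > 0 && sweep_has_spikes(sweep_set, j))
      return(j)
  }
  stop("no suprathreshold sweep found")
}

#' Extract the full intrinsic-feature set of one cell
#'
#' @param sweep_set a `sweep_set`.
#' @return object of class `ephys_feature_set` with `input_resistance` (MOhm),
#'   `membrane_tau` (ms), `sag_ratio`, `first_spike_latency` (s),
#'   `ap_threshold` (mV), `ap_amplitude` (mV), `hump_ngf_rule`,
#'   `hump_sbc_rule` (mV), `first_ahp_latency` (s).
#' @export
ephys_features <- function(sweep_set) {
  j <- near_threshold_sweep(sweep_set)
  spikes <- detect_aps(sweep_set$sweeps[, j], sweep_set$sampling_rate)
  hump <- hump_amplitude(sweep_set, j)
  structure(list(
    input_resistance = input_resistance(sweep_set),
    membrane_tau = membrane_time_constant(sweep_set),
    sag_ratio = sag_ratio(sweep_set),
    first_spike_latency = first_spike_latency(sweep_set, j),
    ap_threshold = spikes$v_threshold[1],
    ap_amplitude = spikes$amplitude[1],
    hump_ngf_rule = hump$ngf_rule,
    hump_sbc_rule = hump$sbc_rule,
    first_ahp_latency = first_ahp_latency(sweep_set, j, spikes)),
    class = "ephys_feature_set")
}

#' Classify a layer-1 interneuron from its spike-timing features
#'
#' Deterministic rule on (first spike latency, first AHP latency): delayed
#' firing or a slow AHP indicates a neurogliaform-like cell, early firing
#' with a fast AHP a single-bouquet-like cell. Values exactly on a boundary
#' tie-break toward `pNGF` with a warning. When both cut-offs are `NULL`, a
#' two-component Gaussian mixture on the log latencies is fitted instead and
#' the longer-latency component is labelled `pNGF`.
#'
#' @param features an `ephys_feature_set` (or list with
#'   `first_spike_latency`, `first_ahp_latency`, s).
#' @param spike_latency_cut,ahp_latency_cut decision thresholds, s.
#' @return list of class `cell_class_call`: `cell_class` (`pNGF`, `pSBC` or
#'   `other`), `features_used`, `rule`.
#' @export
classify_l1_interneuron <- function(features, spike_latency_cut = 0.1,
                                    ahp_latency_cut = 0.012) {
  lat <- features$first_spike_latency
  ahp <- features$first_ahp_latency
  used <- c(first_spike_latency = lat, first_ahp_latency = ahp)
  if (is.null(lat) || is.null(ahp) || any(!is.finite(used))) {
    return(structure(list(cell_class = "other", features_used = used,
                          rule = "missing feature"),
                     class = "cell_class_call"))
  }
  if (is.null(spike_latency_cut) && is.null(ahp_latency_cut)) {
    stop("Gaussian-mixture classification needs a population; ",
         "use classify_l1_population()")
  }
  on_boundary <- lat == spike_latency_cut || ahp == ahp_latency_cut
  if (on_boundary)
    warning("feature exactly on the decision boundary; tie-break to pNGF")
  cls <- if (lat >= spike_latency_cut || ahp >= ahp_latency_cut)
    "pNGF" else "pSBC"
  structure(list(cell_class = cls, features_used = used,
                 rule = sprintf("thresholds (latency >= %g s | AHP >= %g s)",
                                spike_latency_cut, ahp_latency_cut)),
            class = "cell_class_call")
}

#' Population-level Gaussian-mixture fallback classification
#'
#' Used when no numeric decision boundary is configured: fits a two-component
#' Gaussian mixture to the log spike/AHP latencies of all cells and labels
#' the longer-spike-latency component `pNGF`.
#'
#' @param feature_list list of `ephys_feature_set` objects.
#' @return character vector of class calls.
#' @export
classify_l1_population <- function(feature_list) {
  lat <- vapply(feature_list, `[[`, numeric(1), "first_spike_latency")
  ahp <- vapply(feature_list, `[[`, numeric(1), "first_ahp_latency")
  x <- cbind(log(lat), log(ahp))
  fit <- mclust::Mclust(x, G = 2, verbose = FALSE)
  mu_lat <- fit$parameters$mean[1, ]
  ngf_comp <- which.max(mu_lat)
  ifelse(fit$classification == ngf_comp, "pNGF", "pSBC")
}

#' @export
print.ephys_feature_set <- function(x, ...) {
  cat(sprintf(paste0("<ephys_feature_set> Rin %.1f MOhm, tau %.1f ms, ",
                     "sag %.3f\n  first spike %.1f ms, AP %0.1f mV from ",
                     "%.1f mV, AHP latency %.1f ms\n"),
              x$input_resistance, x$membrane_tau, x$sag_ratio,
              1000 * x$first_spike_latency, x$ap_amplitude, x$ap_threshold,
              1000 * x$first_ahp_latency))
  invisible(x)
}
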