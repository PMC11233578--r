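#' Parameters for dF/F0 computation
#'
#' @param baseline_pre_window width of the event-local baseline window
#'   (mean fluorescence before each stimulus onset), s.
#' @param percentile percentile used for the slow baseline f0.
#' @param percentile_window width of the moving window for f0, s.
#' @param percentile_centering `"centered"` (default) or `"trailing"` moving
#'   window for f0.
#' @param smoothing_sigma Gaussian smoothing SD for visualisation, s. Never
#'   applied before quantitative statistics.
#' @param pre,post alignment window around each stimulus onset, s.
#' @return list of class `dff_params`.
#' @export
dff_params <- function(baseline_pre_window = 0.5, percentile = 8,
                       percentile_window = 1,
                       percentile_centering = c("centered", "trailing"),
                       smoothing_sigma = 0.1, pre = 1, post = 5) {
  stopifnot(percentile > 0, percentile < 100, percentile_window > 0,
            baseline_pre_window > 0, pre >= 0, post > 0,
            smoothing_sigma >= 0)
  structure(list(baseline_pre_window = baseline_pre_window,
                 percentile = percentile,
                 percentile_window = percentile_window,
                 percentile_centering = match.arg(percentile_centering),
                 smoothing_sigma = smoothing_sigma, pre = pre, post = post),
            class = "dff_params")
}

#' Running-percentile slow baseline
#'
#' Per-frame q-th percentile of a trace over a moving window, the slow
#' baseline f0 of the dF/F0 definition (computed on the sum of ROI and
#' overlapping-background fluorescence). The window is centred by default
#' (half-width `floor(w/2)` frames on each side) and truncated at the trace
#' edges; percentiles interpolate linearly between order statistics
#' (`stats::quantile` type 7), so a brute-force sort-and-index oracle matches
#' exactly.
#'
#' @param f_total numeric trace (typically ROI + background fluorescence).
#' @param window window width, s.
#' @param q percentile in (0, 100).
#' @param frame_rate frames per second.
#' @param centering `"centered"` or `"trailing"`.
#' @return numeric trace of per-frame baselines, same length as `f_total`.
#' @export
running_percentile_baseline <- function(f_total, window, q, frame_rate,
                                        centering = "centered") {
  if (length(f_total) == 0) stop("empty trace")
  if (any(!is.finite(f_total))) stop("trace must be finite")
  w_frames <- round(window * frame_rate)
  if (w_frames < 2) stop("percentile window must span at least 2 frames")
  if (centering == "centered") {
    halfwin <- w_frames %/% 2
    .run_percentile_cpp(f_total, halfwin, q)
  } else {
    # trailing window: percentile of [i - w + 1, i]
    n <- length(f_total)
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - w_frames + 1L)
      unname(quantile(f_total[lo:i], q / 100, type = 7))
    }, numeric(1))
  }
}

#' Compute per-event dF/F0 segments
#'
#' Implements \eqn{\Delta F/F_0 = (f_i - f_{b,i}) / f_{0,i}} framewise:
#' `f_b` is the mean ROI fluorescence over `baseline_pre_window` seconds
#' preceding each stimulus onset, and `f_0` the running percentile of the sum
#' of ROI and background fluorescence ([running_percentile_baseline()]).
#' Segments are cut to `[-pre, +post)` around each onset. A segment in which
#' `f_0 <= 0` anywhere is flagged invalid and excluded from the returned
#' matrix; events whose alignment window extends beyond the session are
#' dropped with a warning.
#'
#' @param f ROI fluorescence trace.
#' @param background estimated overlapping-background trace (same length).
#' @param onsets event onset frames (1-based).
#' @param params a [dff_params()].
#' @param frame_rate frames per second.
#' @return list with `segments` (valid-trial x frame dF/F0 matrix),
#'   `time_axis` (s, onset at 0), `valid` (per retained event), `dropped`
#'   (onsets without a full window), and `f0` (the slow baseline trace).
#' @export
compute_dff <- function(f, background, onsets, params = dff_params(),
                        frame_rate) {
  stopifnot(length(f) == length(background))
  n <- length(f)
  f0 <- running_percentile_baseline(f + background,
                                    params$percentile_window,
                                    params$percentile, frame_rate,
                                    params$percentile_centering)
  pre_f <- round(params$pre * frame_rate)
  post_f <- round(params$post * frame_rate)
  base_f <- round(params$baseline_pre_window * frame_rate)

  full <- onsets - max(pre_f, base_f) >= 1 & onsets + post_f - 1 <= n
  dropped <- onsets[!full]
  if (length(dropped))
    warning(length(dropped), " event(s) too close to the session edge dropped")
  onsets <- onsets[full]
  if (!length(onsets)) stop("no events with a full alignment window")

  segs <- matrix(NA_real_, length(onsets), pre_f + post_f)
  valid <- logical(length(onsets))
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    f_b <- mean(f[(o - base_f):(o - 1)])
    idx <- (o - pre_f):(o + post_f - 1)           # half-open [t, t + dt)
    seg_f0 <- f0[idx]
    valid[k] <- all(seg_f0 > 0)
    if (valid[k]) segs[k, ] <- (f[idx] - f_b) / seg_f0
  }
  if (!all(valid))
    warning(sum(!valid), " segment(s) with non-positive f0 excluded")
  list(segments = segs[valid, , drop = FALSE],
       time_axis = (seq_len(pre_f + post_f) - pre_f - 1) / frame_rate,
       valid = valid, dropped = dropped, f0 = f0,
       onsets_used = onsets[valid])
}

#' Stack dF/F0 segments into a stimulus-aligned response
#'
#' @param dff result of [compute_dff()].
#' @param neuron_id,session_id identifiers carried along.
#' @return object of class `aligned_response`: `dff` (trial x frame matrix),
#'   `time_axis` (s, onset at frame with t = 0), ids.
#' @export
align_to_events <- function(dff, neuron_id = NA, session_id = NA) {
  structure(list(dff = dff$segments, time_axis = dff$time_axis,
                 neuron_id = neuron_id, session_id = session_id),
            class = "aligned_response")
}

#' Gaussian smoothing for visualisation
#'
#' Convolution with a normalised Gaussian kernel (reflected boundaries).
#' Intended for display only; quantitative statistics in this package operate
#' on unsmoothed traces.
#'
#' @param trace numeric vector.
#' @param sigma kernel SD, s; `0` returns the input unchanged.
#' @param frame_rate frames per second.
#' @return smoothed trace, same length.
#' @export
gaussian_smooth <- function(trace, sigma, frame_rate) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(trace)
  sig_f <- sigma * frame_rate
  half <- max(1L, ceiling(4 * sig_f))
  x <- (-half):half
  kern <- exp(-x^2 / (2 * sig_f^2))
  kern <- kern / sum(kern)
  n <- length(trace)
  # reflect edges (clamped for very short traces)
  li <- pmax(1L, pmin(n, rev(seq_len(half))))
  ri <- pmax(1L, pmin(n, seq.int(n, by = -1L, length.out = half)))
  padded <- c(trace[li], trace, trace[ri])
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
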