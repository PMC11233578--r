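#' Parameters of the circular-shift responsiveness bootstrap
#'
#' @param n_shifts number of random circular rotations (>= 100).
#' @param percentile_bound upper percentile of the null used for the
#'   two-sided call (97.5 gives a nominal 5% two-sided test).
#' @param statistic_window window over which the evoked statistic (mean
#'   baseline-subtracted dF/F0) is taken, s relative to onset.
#' @param baseline_window width of the pre-onset baseline window, s.
#' @param rotate `"dff"` (default) rotates the session-long normalised
#'   activity; `"raw"` rotates the raw fluorescence and recomputes the slow
#'   baseline on every rotation (much slower).
#' @param seed RNG seed for the shift draws.
#' @return list of class `bootstrap_params`.
#' @export
bootstrap_params <- function(n_shifts = 1000, percentile_bound = 97.5,
                             statistic_window = c(0, 1),
                             baseline_window = 0.5,
                             rotate = c("dff", "raw"), seed = 1L) {
  stopifnot(n_shifts >= 100, percentile_bound > 50, percentile_bound < 100,
            baseline_window > 0, diff(statistic_window) > 0)
  structure(list(n_shifts = as.integer(n_shifts),
                 percentile_bound = percentile_bound,
                 statistic_window = statistic_window,
                 baseline_window = baseline_window,
                 rotate = match.arg(rotate),
                 seed = as.integer(seed)), class = "bootstrap_params")
}

## Circular moving means: post-window mean (frames [t + k0, t + k0 + k)) and
## pre-window mean (frames [t - b, t)) of x for every position t.
circ_window_means <- function(x, k0, k, b) {
  n <- length(x)
  S <- cumsum(c(0, x, x[seq_len(k + k0)]))
  post <- (S[seq_len(n) + k0 + k] - S[seq_len(n) + k0]) / k
  Sb <- cumsum(c(0, x[(n - b + 1):n], x))  # prefix padded for wrap-around
  base <- (Sb[seq_len(n) + b] - Sb[seq_len(n)]) / b
  list(post = post, base = base)
}

## Event statistic evaluated at every circular position: the mean dF/F0 over
## the statistic window with the dF/F0 definition applied locally,
##   stat(t) = mean_win[(f - f_b(t)) / f0] = mean_win(f/f0) - f_b(t) mean_win(1/f0),
## where f_b(t) is the pre-onset mean of the raw fluorescence. The raw trace
## and its slow baseline rotate jointly, so evaluating the profile at a
## shifted position is exactly the statistic of the rotated activity.
event_stat_profile <- function(f, f0, frame_rate, params) {
  n <- length(f)
  k0 <- round(params$statistic_window[1] * frame_rate)
  k1 <- round(params$statistic_window[2] * frame_rate)
  k <- k1 - k0                            # frames in [w1, w2)
  b <- round(params$baseline_window * frame_rate)
  if (k < 1 || b < 1) stop("windows too short for this frame rate")
  if (n <= k + b) stop("trace shorter than the analysis window")
  if (is.null(f0)) f0 <- rep(1, n)
  U <- circ_window_means(f / f0, k0, k, b)
  W <- circ_window_means(1 / f0, k0, k, b)
  Bf <- circ_window_means(f, k0, k, b)
  U$post - Bf$base * W$post
}

#' Null distribution of the evoked statistic by circular rotation
#'
#' Rotates the session-long activity trace by `n_shifts` uniform random
#' offsets in `[1, T - 1]` (drawn with replacement, shift 0 excluded) relative
#' to the fixed stimulus onsets, recomputing the event-aligned statistic with
#' the identical windowing and baseline logic for every rotation. The
#' rotation preserves the trace's autocorrelation, making the null
#' exchangeable with the observed statistic.
#'
#' @param activity session-long raw fluorescence trace (rotated jointly with
#'   its slow baseline `f0`); when `f0` is `NULL` the trace is taken as
#'   already-normalised dF/F0-level activity.
#' @param onsets event onset frames.
#' @param params a [bootstrap_params()].
#' @param frame_rate frames per second.
#' @param f0 slow baseline trace matching `activity` (see
#'   [running_percentile_baseline()]), or `NULL`.
#' @return list with `observed` (statistic on the unrotated trace) and
#'   `null` (vector of `n_shifts` rotated statistics).
#' @export
circular_shift_null <- function(activity, onsets, params, frame_rate,
                                f0 = NULL) {
  n <- length(activity)
  if (!length(onsets)) stop("need at least one onset")
  prof <- event_stat_profile(activity, f0, frame_rate, params)
  observed <- mean(prof[onsets])
  if (!is.null(params$seed)) set.seed(params$seed)
  shifts <- sample.int(n - 1L, params$n_shifts, replace = TRUE)
  idx <- outer(onsets, shifts, function(o, s) ((o - s - 1L) %% n) + 1L)
  null <- colMeans(matrix(prof[idx], nrow = length(onsets)))
  list(observed = observed, null = null)
}

#' Classify a neuron's responsiveness from its bootstrap null
#'
#' Two-sided rule: responsive iff the observed statistic lies strictly above
#' the `percentile_bound`-th or strictly below the
#' `(100 - percentile_bound)`-th percentile of the null sample. Equality (the
#' degenerate constant-trace case) is not responsive.
#'
#' @param observed observed statistic.
#' @param null_sample vector of null statistics (length `n_shifts`).
#' @param params a [bootstrap_params()].
#' @return list of class `responsiveness_result`: `observed`, `null_low`,
#'   `null_high`, `responsive`, `direction` (`activated`, `suppressed`,
#'   `none`), `invalid`.
#' @export
classify_responsive <- function(observed, null_sample, params) {
  if (length(null_sample) != params$n_shifts)
    stop("null sample size must equal n_shifts")
  lo <- unname(quantile(null_sample, (100 - params$percentile_bound) / 100,
                        type = 7))
  hi <- unname(quantile(null_sample, params$percentile_bound / 100, type = 7))
  if (!is.finite(observed)) {
    return(structure(list(observed = observed, null_low = lo, null_high = hi,
                          responsive = FALSE, direction = "none",
                          invalid = TRUE), class = "responsiveness_result"))
  }
  responsive <- observed > hi || observed < lo
  direction <- if (observed > hi) "activated"
               else if (observed < lo) "suppressed" else "none"
  structure(list(observed = observed, null_low = lo, null_high = hi,
                 responsive = responsive, direction = direction,
                 invalid = FALSE), class = "responsiveness_result")
}

#' Full responsiveness test for one neuron-session
#'
#' Computes the slow baseline f0 on ROI + background
#' ([running_percentile_baseline()]) and the observed event statistic — the
#' mean dF/F0 \eqn{(f - f_b)/f_0} over the statistic window, averaged across
#' events — then compares it with the circular-rotation null in which the
#' fluorescence and its slow baseline are rotated jointly relative to the
#' fixed event times. With `rotate = "raw"` the raw fluorescence is rotated
#' alone and the slow baseline is recomputed on every rotation.
#'
#' @inheritParams compute_dff
#' @param params a [bootstrap_params()].
#' @param dffp a [dff_params()] (slow-baseline settings).
#' @return a `responsiveness_result` (see [classify_responsive()]).
#' @export
responsiveness_test <- function(f, background, onsets, frame_rate,
                                params = bootstrap_params(),
                                dffp = dff_params()) {
  if (params$rotate == "dff") {
    f0 <- running_percentile_baseline(f + background, dffp$percentile_window,
                                      dffp$percentile, frame_rate,
                                      dffp$percentile_centering)
    res <- circular_shift_null(f, onsets, params, frame_rate, f0 = f0)
  } else {
    res <- raw_rotation_null(f, background, onsets, frame_rate, params, dffp)
  }
  classify_responsive(res$observed, res$null, params)
}

## Raw-fluorescence rotation variant: the slow baseline is recomputed on the
## rotated trace so null and observed pipelines stay identical.
raw_rotation_null <- function(f, background, onsets, frame_rate, params,
                              dffp) {
  n <- length(f)
  stat_of <- function(fr_trace, bg_trace) {
    f0 <- running_percentile_baseline(fr_trace + bg_trace,
                                      dffp$percentile_window,
                                      dffp$percentile, frame_rate,
                                      dffp$percentile_centering)
    prof <- event_stat_profile(fr_trace, f0, frame_rate, params)
    mean(prof[onsets])
  }
  observed <- stat_of(f, background)
  set.seed(params$seed)
  shifts <- sample.int(n - 1L, params$n_shifts, replace = TRUE)
  null <- vapply(shifts, function(s) {
    rot <- c(f[(s + 1):n], f[1:s])
    rot_bg <- c(background[(s + 1):n], background[1:s])
    stat_of(rot, rot_bg)
  }, numeric(1))
  list(observed = observed, null = null)
}

#' Session-union inclusion filter
#'
#' A neuron enters the downstream analyses if it was significantly responsive
#' in one or more sessions.
#'
#' @param responsive_by_session logical matrix, neurons x sessions.
#' @return logical inclusion vector (one per neuron).
#' @export
session_union_filter <- function(responsive_by_session) {
  m <- as.matrix(responsive_by_session)
  if (any(is.na(m))) stop("missing session verdicts")
  apply(m, 1, any)
}
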