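#' Trial-mean evoked response
#'
#' Framewise arithmetic mean of the stimulus-aligned dF/F0 trials.
#'
#' @param aligned an [align_to_events()] result.
#' @return numeric mean trace (one value per frame of the alignment window).
#' @export
mean_evoked_response <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_response"))
  if (nrow(aligned$dff) == 0) stop("no trials")
  colMeans(aligned$dff)
}

#' Area under the evoked-response curve
#'
#' Trapezoidal integral of the signed mean trace over a time window
#' (default windows of interest: 0-5 s, 0-1 s during the stimulus, 1-5 s
#' after it). Integration uses the closed interval `[from, to]` so that areas
#' over adjoining windows sharing an endpoint add exactly.
#'
#' @param mean_trace numeric trace.
#' @param time_axis time of each frame, s (onset at 0).
#' @param window `c(from, to)`, s.
#' @return area, dF/F0 x s.
#' @export
compute_auc <- function(mean_trace, time_axis, window) {
  idx <- which(time_axis >= window[1] - 1e-9 & time_axis <= window[2] + 1e-9)
  if (length(idx) < 2) stop("window must contain at least two frames")
  pracma::trapz(time_axis[idx], mean_trace[idx])
}

#' Mean dF/F0 over a window
#'
#' Mean of the trial-mean trace over the half-open window `[from, to)`
#' (the "during" 0-1 s and "post" 1-5 s summaries).
#'
#' @inheritParams compute_auc
#' @return mean dF/F0.
#' @export
mean_dff_window <- function(mean_trace, time_axis, window) {
  idx <- which(time_axis >= window[1] - 1e-9 & time_axis < window[2] - 1e-9)
  if (!length(idx)) stop("empty window")
  mean(mean_trace[idx])
}

#' Fold change of an evoked-response summary relative to a reference session
#'
#' \deqn{(x_{target} - x_{ref}) / |x_{ref}|}
#' Undefined (flagged, not an error) when the reference is exactly zero;
#' undefined values are excluded from group statistics and counted in QC.
#'
#' @param auc_ref,auc_target summaries computed on the same window.
#' @return list with `value`, `defined`.
#' @export
fold_change <- function(auc_ref, auc_target) {
  if (auc_ref == 0) return(list(value = NA_real_, defined = FALSE))
  list(value = (auc_target - auc_ref) / abs(auc_ref), defined = TRUE)
}

#' Assign neurons to cortical layers from their lens-referenced coordinate
#'
#' Interval lookup with half-open bins `[b_k, b_{k+1})`: a coordinate exactly
#' on a boundary belongs to the deeper layer. Coordinates outside the
#' configured range are `unassigned`. Boundary defaults reflect the lens
#' geometry used for deep-layer imaging and are configuration, not
#' measurement.
#'
#' @param ml_coordinate_um numeric coordinates, micrometres.
#' @param boundaries strictly increasing cut points `c(start, L1/L2-3,
#'   L2-3/L5, end)`, micrometres.
#' @return data.frame with `ml_coordinate_um` and `layer` (factor with levels
#'   `L1`, `L2/3`, `L5`, `unassigned`).
#' @export
assign_layer <- function(ml_coordinate_um,
                         boundaries = c(0, 100, 350, 900)) {
  if (length(boundaries) != 4 || any(diff(boundaries) <= 0))
    stop("boundaries must be 4 strictly increasing values")
  lv <- c("L1", "L2/3", "L5", "unassigned")
  bin <- findInterval(ml_coordinate_um, boundaries,
                      rightmost.closed = FALSE, left.open = FALSE)
  layer <- lv[ifelse(bin %in% 1:3, bin, 4L)]
  data.frame(ml_coordinate_um = ml_coordinate_um,
             layer = factor(layer, levels = lv))
}

#' Per-neuron, per-session response metrics table
#'
#' Convenience wrapper computing the standard summaries (AUC 0-5, 0-1 and
#' 1-5 s; window means 0-1 and 1-5 s) from an aligned response.
#'
#' @param aligned an [align_to_events()] result.
#' @return one-row data.frame of metrics.
#' @export
response_metrics <- function(aligned) {
  m <- mean_evoked_response(aligned)
  ta <- aligned$time_axis
  data.frame(neuron_id = aligned$neuron_id, session_id = aligned$session_id,
             auc_0_5 = compute_auc(m, ta, c(0, 5)),
             auc_0_1 = compute_auc(m, ta, c(0, 1)),
             auc_1_5 = compute_auc(m, ta, c(1, 5)),
             mean_dff_0_1 = mean_dff_window(m, ta, c(0, 1)),
             mean_dff_1_5 = mean_dff_window(m, ta, c(1, 5)))
}
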