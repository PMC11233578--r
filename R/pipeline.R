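#' Analyse a session set: dF/F0, responsiveness, evoked metrics
#'
#' Runs the per-neuron, per-session trace analysis: slow baseline, aligned
#' dF/F0 segments, trial-mean evoked traces, AUC/window-mean metrics, and the
#' circular-shift responsiveness verdict. The bootstrap seed is derived
#' per neuron and session from `bootp$seed` so verdicts are independent
#' across neurons yet reproducible.
#'
#' @param ss a `session_set`.
#' @param dffp a [dff_params()].
#' @param bootp a [bootstrap_params()].
#' @return list: `metrics` (data.frame, one row per neuron x session),
#'   `responsive` / `direction` (neuron x session matrices), `included`
#'   (session-union filter), `mean_traces` (per session, neuron x frame),
#'   `time_axis`.
#' @export
analyze_session_set <- function(ss, dffp = dff_params(),
                                bootp = bootstrap_params()) {
  n_sessions <- length(ss$sessions)
  n <- nrow(ss$sessions[[1]]$f)
  fr <- ss$frame_rate
  pre_f <- round(dffp$pre * fr); post_f <- round(dffp$post * fr)
  time_axis <- (seq_len(pre_f + post_f) - pre_f - 1) / fr

  responsive <- matrix(NA, n, n_sessions)
  direction <- matrix("none", n, n_sessions)
  mean_traces <- lapply(seq_len(n_sessions), function(s)
    matrix(NA_real_, n, pre_f + post_f))
  metrics <- vector("list", n_sessions * n)

  for (s in seq_len(n_sessions)) {
    onsets <- ss$events$onset_frame[ss$events$session == s]
    fmat <- ss$sessions[[s]]$f
    bmat <- ss$sessions[[s]]$background
    for (i in seq_len(n)) {
      f <- fmat[i, ]; bg <- bmat[i, ]
      f0 <- running_percentile_baseline(f + bg, dffp$percentile_window,
                                        dffp$percentile, fr,
                                        dffp$percentile_centering)
      ## responsiveness: fluorescence and slow baseline rotate jointly
      bp_i <- bootp
      bp_i$seed <- bootp$seed + 7919L * s + i
      res <- circular_shift_null(f, onsets, bp_i, fr, f0 = f0)
      verdict <- classify_responsive(res$observed, res$null, bp_i)
      responsive[i, s] <- verdict$responsive
      direction[i, s] <- verdict$direction
      ## aligned segments reuse the same slow baseline
      dff <- compute_dff_prebaselined(f, f0, onsets, dffp, fr)
      aligned <- align_to_events(dff, neuron_id = i, session_id = s)
      mean_traces[[s]][i, ] <- mean_evoked_response(aligned)
      metrics[[(s - 1) * n + i]] <- response_metrics(aligned)
    }
  }
  metrics <- do.call(rbind, metrics)
  list(metrics = metrics, responsive = responsive, direction = direction,
       included = session_union_filter(responsive),
       mean_traces = mean_traces, time_axis = time_axis)
}

## compute_dff with a precomputed slow baseline (avoids recomputing the
## running percentile when responsiveness and alignment share it)
compute_dff_prebaselined <- function(f, f0, onsets, params, frame_rate) {
  n <- length(f)
  pre_f <- round(params$pre * frame_rate)
  post_f <- round(params$post * frame_rate)
  base_f <- round(params$baseline_pre_window * frame_rate)
  full <- onsets - max(pre_f, base_f) >= 1 & onsets + post_f - 1 <= n
  onsets <- onsets[full]
  segs <- matrix(NA_real_, length(onsets), pre_f + post_f)
  valid <- logical(length(onsets))
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    f_b <- mean(f[(o - base_f):(o - 1)])
    idx <- (o - pre_f):(o + post_f - 1)
    seg_f0 <- f0[idx]
    valid[k] <- all(seg_f0 > 0)
    if (valid[k]) segs[k, ] <- (f[idx] - f_b) / seg_f0
  }
  list(segments = segs[valid, , drop = FALSE],
       time_axis = (seq_len(pre_f + post_f) - pre_f - 1) / frame_rate,
       valid = valid, dropped = integer(0), f0 = f0,
       onsets_used = onsets[valid])
}

#' Run the full imaging pipeline on a configuration
#'
#' Simulation (or a supplied `session_set`), per-neuron dF/F0 and
#' responsiveness, session-union inclusion, evoked-response metrics and fold
#' changes, ensemble discovery on the included neurons, and the
#' session-comparison statistics (Friedman across sessions on the 0-5 s AUC,
#' session-1-referenced Wilcoxon signed-rank tests with Bonferroni family 2,
#' and the responsive-proportion trend). Identical configs and seeds give
#' identical results.
#'
#' @param config a [sim_config()] (ignored when `ss` is supplied).
#' @param ss optional pre-built `session_set`.
#' @param dffp,bootp,ensp stage parameter bundles.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `pipeline_result` with `session_set`, `analysis`,
#'   `fold_changes`, `ensembles`, `stats`, `report`.
#' @export
run_pipeline <- function(config = sim_config(), ss = NULL,
                         dffp = dff_params(), bootp = bootstrap_params(),
                         ensp = ensemble_params(), out_dir = NULL) {
  if (is.null(ss)) ss <- simulate_session_set(config)
  an <- analyze_session_set(ss, dffp, bootp)
  n_sessions <- length(ss$sessions)

  ## fold changes of the 0-5 s AUC relative to session 1
  auc_by_session <- matrix(an$metrics$auc_0_5,
                           ncol = n_sessions)   # neurons x sessions
  fc <- NULL
  if (n_sessions >= 2) {
    fc <- do.call(rbind, lapply(2:n_sessions, function(s) {
      per <- lapply(seq_len(nrow(auc_by_session)), function(i)
        fold_change(auc_by_session[i, 1], auc_by_session[i, s]))
      data.frame(neuron = seq_len(nrow(auc_by_session)), session = s,
                 fold_change = vapply(per, `[[`, numeric(1), "value"),
                 defined = vapply(per, `[[`, logical(1), "defined"))
    }))
  }

  ## ensembles on the included (ever-responsive) neurons
  ens <- NULL
  if (sum(an$included) > ensp$n_components + max(ensp$k_candidates)) {
    mt_inc <- lapply(an$mean_traces, function(m)
      m[an$included, , drop = FALSE])
    ens <- discover_ensembles(mt_inc, an$time_axis, ensp)
  }

  ## session statistics on the included neurons
  stats_res <- list()
  if (n_sessions >= 3 && sum(an$included) >= 5) {
    inc_auc <- auc_by_session[an$included, , drop = FALSE]
    stats_res$auc_friedman <- run_comparison(inc_auc, "friedman_dunn")
    stats_res$auc_s1_vs_s2 <- run_comparison(
      list(inc_auc[, 1], inc_auc[, 2]), "wilcoxon_bonferroni",
      correction_family_size = 2)
    stats_res$auc_s1_vs_s3 <- run_comparison(
      list(inc_auc[, 1], inc_auc[, 3]), "wilcoxon_bonferroni",
      correction_family_size = 2)
    trend <- responsive_proportion_trend(an$responsive)
    stats_res$responsive_trend_chi2 <- trend$chi2
  }
  report <- build_report(stats_res)

  out <- structure(list(session_set = ss, analysis = an,
                        fold_changes = fc, ensembles = ens,
                        stats = stats_res, report = report),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    atomic_fwrite(an$metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(fc)) atomic_fwrite(fc, file.path(out_dir,
                                                  "fold_changes.csv"))
    atomic_write(function(p) writeLines(as.character(report$json), p),
                 file.path(out_dir, "stats_report.json"))
    if (!is.null(ens))
      atomic_fwrite(data.frame(neuron = which(an$included),
                               cluster = ens$labels,
                               ensemble = if (!is.null(ens$ensemble_map))
                                 ens$ensemble_map[as.character(ens$labels)]
                               else NA),
                    file.path(out_dir, "ensembles.csv"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  n <- length(x$analysis$included)
  cat("<pipeline_result> ", n, " neurons, ",
      sum(x$analysis$included), " included (",
      sprintf("%.1f%%", 100 * mean(x$analysis$included)), ")\n", sep = "")
  if (!is.null(x$ensembles))
    cat("  ensembles: chosen k = ", x$ensembles$chosen_k, "\n", sep = "")
  invisible(x)
}
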