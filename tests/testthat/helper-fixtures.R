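# Shared fixtures: everything is generated in code at test time.

# Small imaging simulation for fast end-to-end checks; the stimulus count
# scales with the (reduced) session length so schedules stay feasible.
small_sim <- function(n_neurons = 30, session_length = 200, seed = 3, ...) {
  extra <- list(...)
  if (is.null(extra$n_stimuli_per_session))
    extra$n_stimuli_per_session <- min(24, floor(session_length / 12))
  do.call(sim_config, c(list(n_neurons = n_neurons,
                             session_length = session_length, seed = seed),
                        extra))
}

# Brute-force running percentile: per-frame sort-and-index with linear
# interpolation (quantile type 7), centered truncated windows.
brute_running_percentile <- function(x, w_frames, q) {
  n <- length(x)
  halfwin <- w_frames %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - halfwin); hi <- min(n, i + halfwin)
    unname(quantile(x[lo:hi], q / 100, type = 7))
  }, numeric(1))
}

# Brute-force mean silhouette width from the pairwise-distance definition.
brute_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(d[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# A hand-built sweep_set from an explicit voltage matrix (for arithmetic
# fixtures that bypass the simulator).
manual_sweep_set <- function(sweeps, current_steps, sampling_rate = 20000,
                             step_onset_s = 0.2, step_dur_s = 1) {
  structure(list(time = (seq_len(nrow(sweeps)) - 1) / sampling_rate,
                 sweeps = sweeps, current_steps = current_steps,
                 sampling_rate = sampling_rate, step_onset_s = step_onset_s,
                 step_dur_s = step_dur_s, archetype = "manual",
                 planted = list()), class = "sweep_set")
}
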