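#' Write and read session sets as plain-text CSV + YAML
#'
#' Traces are stored one CSV matrix per session (`sessionK_f.csv`,
#' `sessionK_background.csv`, neurons in rows, full precision via
#' [data.table::fwrite()]), events in `events.csv` (columns `session`,
#' `onset_frame`, `duration_frames`, `withdrawal`, `opto`), per-neuron
#' metadata in `neurons.csv` and scalar metadata in `meta.yaml`. All writes
#' are atomic (temp file + rename). The numeric payload round-trips
#' losslessly.
#'
#' @param ss a `session_set`.
#' @param dir output directory (created if needed).
#' @return `write_session_set()`: `dir`, invisibly. `read_session_set()`:
#'   a `session_set`.
#' @export
write_session_set <- function(ss, dir) {
  stopifnot(inherits(ss, "session_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_along(ss$sessions)) {
    atomic_fwrite(as.data.frame(ss$sessions[[s]]$f),
                  file.path(dir, sprintf("session%d_f.csv", s)))
    atomic_fwrite(as.data.frame(ss$sessions[[s]]$background),
                  file.path(dir, sprintf("session%d_background.csv", s)))
  }
  atomic_fwrite(ss$events, file.path(dir, "events.csv"))
  atomic_fwrite(data.frame(neuron = seq_along(ss$ml_coordinate_um),
                           ml_coordinate_um = ss$ml_coordinate_um,
                           class = ss$ground_truth$class,
                           amplitude = ss$ground_truth$amplitude),
                file.path(dir, "neurons.csv"))
  meta <- list(frame_rate = ss$frame_rate, n_sessions = length(ss$sessions),
               n_neurons = nrow(ss$sessions[[1]]$f),
               n_frames = ncol(ss$sessions[[1]]$f))
  atomic_write(function(p) yaml::write_yaml(meta, p),
               file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_session_set
#' @export
read_session_set <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) stop("missing dataset file: meta.yaml")
  meta <- yaml::read_yaml(meta_path)
  for (fld in c("frame_rate", "n_sessions", "n_frames"))
    if (is.null(meta[[fld]])) stop("meta.yaml missing field: ", fld)
  sessions <- lapply(seq_len(meta$n_sessions), function(s) {
    fp <- file.path(dir, sprintf("session%d_f.csv", s))
    bp <- file.path(dir, sprintf("session%d_background.csv", s))
    if (!file.exists(fp) || !file.exists(bp))
      stop("missing dataset file for session ", s)
    list(f = as.matrix(data.table::fread(fp)),
         background = as.matrix(data.table::fread(bp)))
  })
  events <- read_events_csv(file.path(dir, "events.csv"), meta$n_frames,
                            meta$n_sessions)
  neurons <- as.data.frame(data.table::fread(file.path(dir, "neurons.csv")))
  structure(list(sessions = sessions, events = events,
                 frame_rate = meta$frame_rate,
                 ml_coordinate_um = neurons$ml_coordinate_um,
                 ground_truth = data.frame(neuron = neurons$neuron,
                                           class = neurons$class,
                                           amplitude = neurons$amplitude),
                 config = NULL), class = "session_set")
}

#' Read and validate a stimulus-event table
#'
#' @param path CSV with columns `session`, `onset_frame`, `duration_frames`,
#'   `withdrawal`, `opto`.
#' @param n_frames,n_sessions bounds used for validation.
#' @return validated data.frame.
#' @export
read_events_csv <- function(path, n_frames = Inf, n_sessions = Inf) {
  if (!file.exists(path)) stop("missing events file: ", path)
  ev <- as.data.frame(data.table::fread(path))
  need <- c("session", "onset_frame", "duration_frames", "withdrawal", "opto")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events.csv missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(ev$onset_frame < 1 | ev$onset_frame > n_frames |
                 ev$session < 1 | ev$session > n_sessions)
  if (length(bad))
    stop("events.csv row(s) out of range: ", paste(bad, collapse = ", "))
  ev$withdrawal <- as.logical(ev$withdrawal)
  ev$opto <- as.logical(ev$opto)
  ev
}

#' Round-trip a simulation config through YAML
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config()`: a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  atomic_write(function(p) yaml::write_yaml(unclass(config), p), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$fraction_nonresponsive <- NULL        # derived field
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' Write a sweep set to CSV + YAML
#'
#' @param sw a `sweep_set`.
#' @param dir output directory.
#' @return `dir` invisibly; `read_sweep_set()` returns a `sweep_set`.
#' @export
write_sweep_set <- function(sw, dir) {
  stopifnot(inherits(sw, "sweep_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(sw$sweeps)
  names(df) <- paste0("I_", sw$current_steps, "pA")
  atomic_fwrite(df, file.path(dir, "sweeps.csv"))
  meta <- list(sampling_rate = sw$sampling_rate,
               step_onset_s = sw$step_onset_s, step_dur_s = sw$step_dur_s,
               current_steps = sw$current_steps, archetype = sw$archetype,
               planted = sw$planted)
  atomic_write(function(p) yaml::write_yaml(meta, p),
               file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) stop("missing dataset file: meta.yaml")
  meta <- yaml::read_yaml(meta_path)
  sweeps <- as.matrix(data.table::fread(file.path(dir, "sweeps.csv")))
  tt <- (seq_len(nrow(sweeps)) - 1) / meta$sampling_rate
  structure(list(time = tt, sweeps = unname(sweeps),
                 current_steps = unlist(meta$current_steps),
                 sampling_rate = meta$sampling_rate,
                 step_onset_s = meta$step_onset_s,
                 step_dur_s = meta$step_dur_s,
                 archetype = meta$archetype, planted = meta$planted),
            class = "sweep_set")
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
}

atomic_fwrite <- function(df, path) {
  atomic_write(function(p) data.table::fwrite(df, p), path)
}
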