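#' Parameters for ensemble discovery
#'
#' @param bin_width bin width, s.
#' @param window feature window relative to stimulus onset, s.
#' @param n_components number of principal components kept.
#' @param min_variance_explained warn if the kept components explain less
#'   cumulative variance than this.
#' @param k_candidates candidate cluster counts for silhouette selection.
#' @param kmeans_n_init random k-means restarts; the best-inertia solution is
#'   kept.
#' @param seed RNG seed for k-means initialisation.
#' @return list of class `ensemble_params`.
#' @export
ensemble_params <- function(bin_width = 0.1, window = c(-1, 2),
                            n_components = 4, min_variance_explained = 0.60,
                            k_candidates = 2:6, kmeans_n_init = 50,
                            seed = 1L) {
  n_bins <- diff(window) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("window must divide into whole bins")
  stopifnot(min_variance_explained > 0, min_variance_explained < 1,
            n_components >= 1, length(k_candidates) >= 1)
  structure(list(bin_width = bin_width, window = window,
                 n_components = as.integer(n_components),
                 min_variance_explained = min_variance_explained,
                 k_candidates = as.integer(k_candidates),
                 kmeans_n_init = as.integer(kmeans_n_init),
                 seed = as.integer(seed)), class = "ensemble_params")
}

#' Binned, concatenated feature matrix for ensemble clustering
#'
#' Bins each session's trial-mean evoked trace (per-bin mean of the dF/F0
#' values whose time falls in `[bin_start, bin_end)`) over the feature window
#' and concatenates the sessions in order, one row per neuron. At the
#' defaults (0.1-s bins over -1..+2 s, three sessions) each neuron
#' contributes a 90-dimensional feature vector.
#'
#' @param mean_traces list (one element per session) of neuron x frame
#'   matrices of trial-mean dF/F0.
#' @param time_axis frame times, s relative to onset.
#' @param params an [ensemble_params()].
#' @return neuron x (bins x sessions) feature matrix.
#' @export
build_feature_matrix <- function(mean_traces, time_axis, params) {
  stopifnot(length(mean_traces) >= 1)
  n_neuron <- nrow(mean_traces[[1]])
  edges <- seq(params$window[1], params$window[2], by = params$bin_width)
  n_bins <- length(edges) - 1
  bin_of <- findInterval(time_axis + 1e-9, edges, left.open = FALSE)
  per_session <- lapply(mean_traces, function(m) {
    stopifnot(nrow(m) == n_neuron, ncol(m) == length(time_axis))
    out <- matrix(NA_real_, n_neuron, n_bins)
    for (b in seq_len(n_bins)) {
      cols <- which(bin_of == b)
      if (!length(cols)) stop("empty bin: frame rate too low for bin width")
      out[, b] <- rowMeans(m[, cols, drop = FALSE])
    }
    out
  })
  do.call(cbind, per_session)
}

#' PCA projection of the feature matrix
#'
#' Columns are mean-centred (no variance scaling, preserving the amplitude
#' information the ensembles differ in) and the neurons are projected on the
#' first `n_components` principal components. Warns when those components
#' explain less cumulative variance than `min_variance_explained`.
#'
#' @param feature_matrix neuron x feature matrix.
#' @param params an [ensemble_params()].
#' @return list: `projection` (neuron x component scores),
#'   `variance_explained` (per component, all components), `cumulative`
#'   (for the kept components).
#' @export
pca_project <- function(feature_matrix, params) {
  if (nrow(feature_matrix) < params$n_components + 1)
    stop("need more neurons than components")
  pc <- prcomp(feature_matrix, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(min(params$n_components, ncol(pc$x)))
  cum <- sum(ve[keep])
  if (cum < params$min_variance_explained)
    warning(sprintf("first %d components explain %.1f%% variance (< %.0f%%)",
                    length(keep), 100 * cum,
                    100 * params$min_variance_explained))
  list(projection = pc$x[, keep, drop = FALSE], variance_explained = ve,
       cumulative = cum)
}

#' k-means clustering of the PC projection
#'
#' Euclidean k-means with `kmeans_n_init` seeded random restarts; the
#' best-inertia solution is returned, so results are deterministic for a
#' fixed seed.
#'
#' @param projection neuron x component score matrix.
#' @param k number of clusters (>= 2).
#' @param params an [ensemble_params()].
#' @return integer cluster labels (1-based).
#' @export
kmeans_cluster <- function(projection, k, params) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(projection)) stop("k exceeds the number of neurons")
  set.seed(params$seed)
  km <- kmeans(projection, centers = k, nstart = params$kmeans_n_init,
               iter.max = 100)
  km$cluster
}

#' Silhouette-based selection of the number of clusters
#'
#' Runs [kmeans_cluster()] for every candidate k and returns the k with the
#' largest mean silhouette width (ties broken toward the smallest k).
#'
#' @inheritParams kmeans_cluster
#' @return list: `chosen_k`, `silhouette_by_k` (named vector).
#' @export
optimal_k_silhouette <- function(projection, params) {
  if (length(params$k_candidates) < 2)
    stop("need at least two candidate k values")
  d <- dist(projection)
  if (max(d) == 0) stop("all points identical: silhouette undefined")
  sil <- vapply(params$k_candidates, function(k) {
    labs <- kmeans_cluster(projection, k, params)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- params$k_candidates
  list(chosen_k = params$k_candidates[which.max(sil)],
       silhouette_by_k = sil)
}

#' Label the two clusters as stimulus-activated / stimulus-inactivated
#'
#' The cluster whose session-1 feature bins show the larger post-onset
#' (0 to +2 s) minus pre-onset (-1 to 0 s) mean signal is labelled
#' `activated`, the other `inactivated`. Refuses to map more than two
#' clusters. An exact tie is broken deterministically (cluster 1 activated)
#' with a warning.
#'
#' @param labels cluster labels from [kmeans_cluster()] with k = 2.
#' @param feature_matrix the matrix the clustering was computed from.
#' @param params an [ensemble_params()].
#' @return named character vector mapping cluster id to ensemble label.
#' @export
label_ensembles <- function(labels, feature_matrix, params) {
  ks <- sort(unique(labels))
  if (length(ks) != 2)
    stop("ensemble labelling requires exactly 2 clusters; got ", length(ks))
  n_bins <- diff(params$window) / params$bin_width
  centers <- seq(params$window[1] + params$bin_width / 2, params$window[2],
                 by = params$bin_width)
  s1 <- feature_matrix[, seq_len(n_bins), drop = FALSE]  # session 1 bins
  post <- centers > 0
  contrast <- vapply(ks, function(k) {
    m <- colMeans(s1[labels == k, , drop = FALSE])
    mean(m[post]) - mean(m[!post])
  }, numeric(1))
  if (contrast[1] == contrast[2]) {
    warning("tied cluster contrasts; breaking tie toward cluster ", ks[1])
    act <- ks[1]
  } else act <- ks[which.max(contrast)]
  out <- ifelse(ks == act, "activated", "inactivated")
  names(out) <- ks
  out
}

#' Compare ensemble proportions between groups
#'
#' Builds the ensemble-by-group contingency table and tests it with Fisher's
#' exact test (2 x 2) or the chi-squared test.
#'
#' @param labels ensemble label per neuron (e.g. `"activated"` /
#'   `"inactivated"`).
#' @param group group membership per neuron (e.g. control vs opsin).
#' @param test `"fisher"` or `"chisq"`.
#' @return list: `table`, `proportions` (per group), `p_value`, `test`.
#' @export
ensemble_proportions <- function(labels, group, test = c("fisher", "chisq")) {
  test <- match.arg(test)
  tab <- table(labels, group)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(colSums(tab) == 0))
    stop("empty group or single-level factor")
  res <- if (test == "fisher") fisher.test(tab) else chisq.test(tab)
  list(table = tab, proportions = prop.table(tab, margin = 2),
       p_value = res$p.value, test = test)
}

#' End-to-end ensemble discovery
#'
#' Feature construction, PCA, silhouette-based k selection, k-means and (for
#' k = 2) activated/inactivated labelling in one call.
#'
#' @inheritParams build_feature_matrix
#' @return object of class `ensemble_model`.
#' @export
discover_ensembles <- function(mean_traces, time_axis,
                               params = ensemble_params()) {
  fm <- build_feature_matrix(mean_traces, time_axis, params)
  pcres <- pca_project(fm, params)
  sel <- optimal_k_silhouette(pcres$projection, params)
  labels <- kmeans_cluster(pcres$projection, sel$chosen_k, params)
  emap <- if (sel$chosen_k == 2) label_ensembles(labels, fm, params) else NULL
  structure(list(feature_matrix = fm, pc_projection = pcres$projection,
                 variance_explained = pcres$variance_explained,
                 cumulative_variance = pcres$cumulative,
                 labels = labels, silhouette_by_k = sel$silhouette_by_k,
                 chosen_k = sel$chosen_k, ensemble_map = emap,
                 params = params), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", nrow(x$feature_matrix), " neurons, ",
      ncol(x$feature_matrix), " features, chosen k = ", x$chosen_k,
      sprintf(" (mean silhouette %.3f)",
              max(x$silhouette_by_k)), "\n", sep = "")
  if (!is.null(x$ensemble_map)) {
    tab <- table(x$ensemble_map[as.character(x$labels)])
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}
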