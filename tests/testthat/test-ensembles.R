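test_that("feature matrix has bins x sessions structure and exact bin means", {
  ta <- (1:120 - 21) / 20                 # 1 s pre, 5 s post at 20 Hz
  ep <- ensemble_params()
  const <- lapply(1:3, function(s) matrix(0.4, 5, 120))
  fm <- build_feature_matrix(const, ta, ep)
  expect_equal(dim(fm), c(5, 90))
  expect_true(all(fm == 0.4))
  # brute-force per-bin averages on a random trace
  set.seed(1)
  m <- matrix(rnorm(120), 1)
  fm1 <- build_feature_matrix(list(m), ta, ep)
  edges <- seq(-1, 2, by = 0.1)
  brute <- vapply(seq_len(30), function(b) {
    mean(m[1, ta >= edges[b] - 1e-9 & ta < edges[b + 1] - 1e-9])
  }, numeric(1))
  expect_equal(as.numeric(fm1), brute, tolerance = 1e-12)
})

test_that("PCA projection reports the covariance eigen-spectrum", {
  set.seed(2)
  ep <- ensemble_params()
  # exact rank-2 data: 4 PCs explain all variance
  basis <- matrix(rnorm(2 * 30), 2, 30)
  x <- matrix(rnorm(40 * 2), 40, 2) %*% basis
  p <- pca_project(x, ep)
  expect_equal(p$cumulative, 1, tolerance = 1e-9)
  # eigen-decomposition oracle on a generic matrix (isotropic data also
  # exercises the low-cumulative-variance warning)
  y <- matrix(rnorm(50 * 10), 50, 10)
  expect_warning(py <- pca_project(y, ep), "variance")
  ev <- eigen(stats::cov(y), symmetric = TRUE)$values
  expect_equal(py$variance_explained, ev / sum(ev), tolerance = 1e-9)
  # rotational invariance of the variance spectrum
  qr_r <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  expect_equal(suppressWarnings(
    pca_project(y %*% qr_r, ep))$variance_explained,
    py$variance_explained, tolerance = 1e-9)
})

test_that("k-means separates blobs and keeps duplicates together", {
  ep <- ensemble_params(seed = 5)
  set.seed(3)
  blob <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
                matrix(rnorm(60, 5, 0.2), 30, 2))
  labs <- kmeans_cluster(blob, 2, ep)
  expect_equal(length(unique(labs[1:30])), 1)
  expect_equal(length(unique(labs[31:60])), 1)
  expect_true(labs[1] != labs[31])
  dup <- blob[c(1:10, 1:10), ]
  labs2 <- kmeans_cluster(dup, 2, ep)
  expect_equal(labs2[1:10], labs2[11:20])
  expect_error(kmeans_cluster(blob, 1, ep), "k must be")
})

test_that("silhouette selection matches a brute-force oracle and finds k", {
  ep <- ensemble_params(k_candidates = 2:5, seed = 6)
  set.seed(4)
  three <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                 matrix(rnorm(40, 6, 0.3), 20, 2),
                 cbind(rnorm(20, 3, 0.3), rnorm(20, 6, 0.3)))
  sel3 <- optimal_k_silhouette(three, ep)
  expect_equal(sel3$chosen_k, 3)
  two <- three[1:40, ]
  sel2 <- optimal_k_silhouette(two, ep)
  expect_equal(sel2$chosen_k, 2)
  # oracle on 30 points
  pts <- three[seq(1, 60, by = 2), ]
  labs <- kmeans_cluster(pts, 3, ep)
  expect_equal(mean(cluster::silhouette(labs, dist(pts))[, "sil_width"]),
               brute_silhouette(pts, labs), tolerance = 1e-12)
  expect_error(optimal_k_silhouette(matrix(1, 10, 2), ep), "identical")
})

test_that("ensemble labelling keys on the post-minus-pre contrast", {
  ep <- ensemble_params()
  ta <- seq(-0.95, 5, by = 0.05)
  n_fr <- length(ta)
  up <- matrix(rep(ifelse(ta >= 0 & ta < 2, 1, 0), each = 10), 10)
  down <- -up
  traces <- list(rbind(up, down), rbind(up, down), rbind(up, down))
  fm <- build_feature_matrix(traces, ta, ep)
  labels <- rep(c(1, 2), each = 10)
  map <- label_ensembles(labels, fm, ep)
  expect_equal(unname(map["1"]), "activated")
  expect_equal(unname(map["2"]), "inactivated")
  # sign flip flips the mapping
  map_fl <- label_ensembles(labels, -fm, ep)
  expect_equal(unname(map_fl["1"]), "inactivated")
  # exact tie: deterministic with warning
  expect_warning(map_tie <- label_ensembles(labels, fm * 0, ep), "tie")
  expect_equal(unname(map_tie["1"]), "activated")
  expect_error(label_ensembles(rep(1:3, 5), fm[1:15, ], ep), "2 clusters")
})

test_that("planted two-ensemble data are recovered end to end", {
  cfg <- small_sim(n_neurons = 40, seed = 13, fraction_activated = 0.6,
                   fraction_inactivated = 0.4)
  ss <- simulate_session_set(cfg)
  res <- analyze_session_set(ss, bootp = bootstrap_params(n_shifts = 200,
                                                          seed = 14))
  ens <- discover_ensembles(lapply(res$mean_traces, function(m)
    m[res$included, , drop = FALSE]), res$time_axis,
    ensemble_params(seed = 15))
  expect_equal(ens$chosen_k, 2)
  lab <- ens$ensemble_map[as.character(ens$labels)]
  gt <- ss$ground_truth$class[res$included]
  expect_gte(mclust::adjustedRandIndex(gt, lab), 0.9)
  # mapping agrees with the planted identity
  expect_gte(mean(lab[gt == "activated"] == "activated"), 0.9)
})

test_that("ensemble proportion tables reproduce ratios and test calibration", {
  res <- ensemble_proportions(rep(c("a", "i"), c(10, 10)),
                              rep(c("g1", "g2"), 10))
  expect_equal(unname(res$proportions[1, ]), c(0.5, 0.5))
  expect_equal(res$p_value, 1)
  # proportions reproduce input ratios exactly
  lab <- rep(c("a", "i", "a", "i"), c(189, 118, 254, 143))
  grp <- rep(c("control", "opsin"), c(307, 397))
  pr <- ensemble_proportions(lab, grp)$proportions
  expect_equal(unname(pr["a", "control"]), 189 / 307)
  expect_equal(unname(pr["a", "opsin"]), 254 / 397)
  # under equal true proportions the test rarely rejects
  set.seed(7)
  pvals <- replicate(200, {
    l <- sample(c("a", "i"), 80, replace = TRUE)
    g <- rep(c("g1", "g2"), 40)
    ensemble_proportions(l, g)$p_value
  })
  expect_lte(mean(pvals < 0.05), 0.08)
  expect_error(ensemble_proportions(c("a", "i"), c("g1", "g1")), "empty")
})
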