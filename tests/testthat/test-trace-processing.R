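test_that("running percentile matches a brute-force oracle and its identities", {
  # constant input and positive-scale equivariance
  expect_equal(running_percentile_baseline(rep(3.7, 50), 1, 8, 20),
               rep(3.7, 50))
  set.seed(1)
  x <- runif(200, 1, 2)
  b1 <- running_percentile_baseline(x, 1, 8, 20)
  b2 <- running_percentile_baseline(2.5 * x, 1, 8, 20)
  expect_equal(b2, 2.5 * b1, tolerance = 1e-12)

  # 40-frame sawtooth at 20 Hz: exact agreement with sort-and-index
  saw <- rep(c(1, 2, 3, 4, 5, 4, 3, 2), 5)
  expect_equal(running_percentile_baseline(saw, 1, 8, 20),
               brute_running_percentile(saw, 20, 8), tolerance = 1e-12)

  # random traces, several window widths and percentiles
  for (k in 1:5) {
    set.seed(k)
    x <- rnorm(150)
    w <- sample(c(0.5, 1, 2), 1)
    q <- sample(c(8, 25, 50), 1)
    expect_equal(running_percentile_baseline(x, w, q, 20),
                 brute_running_percentile(x, round(20 * w), q),
                 tolerance = 1e-12)
  }
  expect_error(running_percentile_baseline(numeric(0), 1, 8, 20), "empty")
})

test_that("trailing-window centering is supported", {
  set.seed(2)
  x <- rnorm(60)
  b <- running_percentile_baseline(x, 0.5, 8, 20, centering = "trailing")
  # frame 30 should be the percentile of frames 21..30
  expect_equal(b[30], unname(quantile(x[21:30], 0.08, type = 7)))
})

test_that("dF/F0 is zero for constant input and invariant to joint rescaling", {
  fr <- 20
  f <- rep(2, 600); bg <- rep(0, 600)
  d <- compute_dff(f, bg, c(100, 300), dff_params(), fr)
  expect_true(all(abs(d$segments) < 1e-12))
  expect_equal(nrow(d$segments), 2)

  set.seed(3)
  f <- 2 + 0.1 * rnorm(600); bg <- rep(0.5, 600)
  d1 <- compute_dff(f, bg, c(100, 300), dff_params(), fr)
  d2 <- compute_dff(3 * f, 3 * bg, c(100, 300), dff_params(), fr)
  expect_equal(d1$segments, d2$segments, tolerance = 1e-12)
})

test_that("dF/F0 of a step response matches the framewise hand formula", {
  fr <- 20
  f <- rep(1, 400)
  f[201:260] <- 1.2                       # +20% step at frame 201
  bg <- rep(0, 400)
  d <- compute_dff(f, bg, 201, dff_params(), fr)
  f0 <- running_percentile_baseline(f + bg, 1, 8, fr)
  f_b <- mean(f[191:200])
  idx <- 181:300                          # pre 1 s .. post 5 s
  expect_equal(as.numeric(d$segments[1, ]), (f[idx] - f_b) / f0[idx],
               tolerance = 1e-12)
  # mid-plateau: the centered 1-s f0 window sits inside the step, so
  # f0 = 1.2 and dF/F0 = (1.2 - 1) / 1.2
  expect_equal(unname(d$segments[1, 31]), 0.2 / 1.2, tolerance = 1e-9)
})

test_that("segments with non-positive f0 are excluded with a report", {
  fr <- 20
  f <- rep(1, 400); bg <- rep(0, 400)
  f[230:290] <- -2                        # drives the percentile negative
  expect_warning(d <- compute_dff(f, bg, c(100, 240), dff_params(), fr),
                 "non-positive f0")
  expect_equal(sum(d$valid), 1)
  expect_equal(nrow(d$segments), 1)
})

test_that("events without a full window are dropped with a warning", {
  fr <- 20
  set.seed(4)
  f <- 1 + 0.05 * rnorm(300); bg <- rep(0, 300)
  expect_warning(d <- compute_dff(f, bg, c(3, 150), dff_params(), fr),
                 "dropped")
  expect_equal(d$dropped, 3)
  expect_equal(nrow(d$segments), 1)
})

test_that("aligned pre-onset mean is zero by construction when f0 is flat", {
  fr <- 20
  f <- rep(1, 800)
  f[401:440] <- 1.5                       # transient far from other windows
  set.seed(5)
  f[101:110] <- 1 + runif(10, 0, 0.2)     # structure inside the pre window
  bg <- rep(0.3, 800)
  d <- compute_dff(f, bg, 111, dff_params(), fr)
  pre_mean <- mean(d$segments[1, d$time_axis >= -0.5 & d$time_axis < 0])
  expect_equal(pre_mean, 0, tolerance = 1e-12)
})

test_that("event alignment conserves trials and the mean ignores order", {
  fr <- 20
  set.seed(6)
  f <- 1 + 0.05 * rnorm(4000); bg <- rep(0, 4000)
  onsets <- seq(200, 3800, length.out = 24)
  d <- compute_dff(f, bg, onsets, dff_params(), fr)
  al <- align_to_events(d, 1, 1)
  expect_equal(nrow(al$dff), 24)
  d2 <- compute_dff(f, bg, sample(onsets), dff_params(), fr)
  expect_equal(mean_evoked_response(align_to_events(d2, 1, 1)),
               mean_evoked_response(al), tolerance = 1e-12)
})

test_that("gaussian smoothing is DC-preserving, normalised and optional", {
  expect_identical(gaussian_smooth(1:10, 0, 20), 1:10)
  expect_equal(gaussian_smooth(rep(2.2, 100), 0.1, 20), rep(2.2, 100),
               tolerance = 1e-9)
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp, 0.1, 20)
  expect_equal(sum(sm), 1, tolerance = 1e-9)   # kernel normalisation
  # samples of a normalised gaussian at the kernel scale
  sig_f <- 0.1 * 20
  expect_equal(max(sm), 1 / sqrt(2 * pi * sig_f^2), tolerance = 1e-3)
  # integral preservation on a random trace
  set.seed(7)
  x <- rnorm(300)
  expect_equal(sum(gaussian_smooth(x, 0.15, 20)), sum(x), tolerance = 1e-6)
})
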