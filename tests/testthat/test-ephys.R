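test_that("input resistance obeys Ohm's law on ideal cells", {
  sw <- simulate_voltage_sweeps("NGF", planted = list(rin_mohm = 100,
                                                      sag_depth_mv = 0,
                                                      rheobase_pa = 1000))
  expect_equal(input_resistance(sw), 100, tolerance = 1e-6)
  # steady-state deflection at -30 pA is -3 mV
  j <- which(sw$current_steps == -30)
  ts <- sw$time - sw$step_onset_s
  defl <- sw$sweeps[, j] - median(sw$sweeps[ts < 0, j])
  expect_equal(median(defl[ts >= 0.7 & ts < 1]), -3, tolerance = 1e-6)
  # zero deflection: slope 0
  flat <- manual_sweep_set(matrix(-65, 30000, 4), c(-30, -10, 10, 30))
  expect_equal(input_resistance(flat), 0)
  # noisy sweeps recover a planted 150 MOhm within 5%
  swn <- simulate_voltage_sweeps("NGF", planted = list(rin_mohm = 150,
                                                       rheobase_pa = 1000),
                                 noise_sd_mv = 0.5, seed = 4)
  expect_equal(input_resistance(swn), 150, tolerance = 0.05)
})

test_that("membrane time constant is recovered from the exponential fit", {
  for (tau in c(20, 5)) {
    sw <- simulate_voltage_sweeps("NGF", planted = list(tau_ms = tau,
                                                        sag_depth_mv = 0,
                                                        rheobase_pa = 1000))
    expect_equal(membrane_time_constant(sw), tau, tolerance = 0.02)
  }
  flat <- manual_sweep_set(matrix(-65, 30000, 1), -50)
  expect_error(membrane_time_constant(flat), "degenerate")
})

test_that("sag ratio follows its defining arithmetic", {
  # constructed sweep: steady deflection -5 mV, minimum -10 mV
  fs <- 20000
  n <- 30000
  ts <- (seq_len(n) - 1) / fs - 0.2
  v <- rep(-60, n)
  v[ts >= 0 & ts < 1] <- -65              # steady -5
  v[ts >= 0.1 & ts < 0.2] <- -70          # early minimum -10
  sw <- manual_sweep_set(matrix(v, ncol = 1), -50)
  expect_equal(sag_ratio(sw), 0.5)
  # no-sag limit and monotone planted ladder
  ratios <- vapply(c(0, 1, 2, 3), function(d) {
    sag_ratio(simulate_voltage_sweeps("NGF", planted = list(sag_depth_mv = d)))
  }, numeric(1))
  expect_equal(ratios[1], 1, tolerance = 1e-3)
  expect_true(all(diff(ratios) < 0))
})

test_that("AP detection: dV/dt criterion, ordering, latency to one sample", {
  sw <- simulate_voltage_sweeps("SBC")
  j <- near_threshold_sweep(sw)
  expect_equal(sw$current_steps[j], sw$planted$rheobase_pa)
  sp <- detect_aps(sw$sweeps[, j], sw$sampling_rate)
  expect_equal(nrow(sp), 1)
  lat <- first_spike_latency(sw, j)
  expect_equal(lat, sw$planted$spike_latency_s,
               tolerance = 1.01 / sw$sampling_rate / sw$planted$spike_latency_s)
  # subthreshold sweep: no crossings
  j_sub <- which(sw$current_steps == 10)
  expect_equal(nrow(detect_aps(sw$sweeps[, j_sub], sw$sampling_rate)), 0)
  # two inserted APs detected in order
  j50 <- which(sw$current_steps == 50)
  sp2 <- detect_aps(sw$sweeps[, j50], sw$sampling_rate)
  expect_equal(nrow(sp2), 2)
  expect_true(all(diff(sp2$i_peak) > 0))
  expect_true(all(sp2$amplitude > 0))
})

test_that("AHP latency measures threshold-to-minimum at the planted value", {
  sw <- simulate_voltage_sweeps("SBC", planted = list(ahp_latency_s = 0.008))
  j <- near_threshold_sweep(sw)
  expect_equal(first_ahp_latency(sw, j), 0.008, tolerance = 0.02)
  # search bounded by the second spike on a two-spike sweep
  j50 <- which(sw$current_steps == 50)
  expect_lt(first_ahp_latency(sw, j50), 0.1)
  flat <- manual_sweep_set(matrix(-65, 30000, 1), 50)
  expect_error(first_ahp_latency(flat, 1), "no spikes")
})

test_that("hump amplitude implements both class rules", {
  # smooth flat depolarisation (no spike): delayed-spiking rule gives 0
  fs <- 20000
  n <- 30000
  ts <- (seq_len(n) - 1) / fs - 0.2
  v <- -65 + 10 * (1 - exp(-pmax(ts, 0) / 0.02)) * (ts >= 0 & ts < 1)
  sw_flat <- manual_sweep_set(matrix(v, ncol = 1), 40)
  expect_equal(suppressWarnings(hump_amplitude(sw_flat, 1))$ngf_rule, 0,
               tolerance = 1e-4)
  # planted 6 mV above the 0.3-s potential, delayed-spiking rule
  ngf <- simulate_voltage_sweeps("NGF", planted = list(hump_mv = 6))
  h_ngf <- hump_amplitude(ngf, near_threshold_sweep(ngf), "pNGF")
  expect_equal(h_ngf$value, 6, tolerance = 0.02)
  # early-spiking rule: threshold 6 mV above the 0.3-s potential
  sbc <- simulate_voltage_sweeps("SBC", planted = list(hump_mv = 6))
  h_sbc <- hump_amplitude(sbc, near_threshold_sweep(sbc), "pSBC")
  expect_equal(h_sbc$value, 6, tolerance = 0.02)
  # no spike: early-spiking rule flagged
  expect_warning(h0 <- hump_amplitude(sw_flat, 1), "no spike")
  expect_true(is.na(h0$sbc_rule))
})

test_that("features are DC-invariant except the AP threshold", {
  sw <- simulate_voltage_sweeps("SBC")
  f1 <- ephys_features(sw)
  sw2 <- sw; sw2$sweeps <- sw$sweeps + 10
  f2 <- ephys_features(sw2)
  for (nm in c("input_resistance", "membrane_tau", "sag_ratio",
               "first_spike_latency", "ap_amplitude", "first_ahp_latency"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  expect_equal(f2$ap_threshold, f1$ap_threshold + 10, tolerance = 1e-6)
})

test_that("interneuron classification is deterministic in its two features", {
  ngf <- ephys_features(simulate_voltage_sweeps("NGF"))
  sbc <- ephys_features(simulate_voltage_sweeps("SBC"))
  expect_equal(classify_l1_interneuron(ngf)$cell_class, "pNGF")
  expect_equal(classify_l1_interneuron(sbc)$cell_class, "pSBC")
  # boundary tie-breaks toward pNGF with a warning
  expect_warning(
    tie <- classify_l1_interneuron(list(first_spike_latency = 0.1,
                                        first_ahp_latency = 0.005)),
    "boundary")
  expect_equal(tie$cell_class, "pNGF")
  miss <- classify_l1_interneuron(list(first_spike_latency = NA,
                                       first_ahp_latency = 0.005))
  expect_equal(miss$cell_class, "other")
})

test_that("population Gaussian-mixture fallback separates the archetypes", {
  set.seed(5)
  feats <- c(
    lapply(1:8, function(i) list(first_spike_latency = 0.4 * runif(1, .8, 1.2),
                                 first_ahp_latency = 0.015 * runif(1, .8, 1.2))),
    lapply(1:8, function(i) list(first_spike_latency = 0.04 * runif(1, .8, 1.2),
                                 first_ahp_latency = 0.006 * runif(1, .8, 1.2))))
  calls <- classify_l1_population(feats)
  expect_equal(calls, rep(c("pNGF", "pSBC"), each = 8))
})
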