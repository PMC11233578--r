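test_that("pure-scaling case leaves a numerically zero residual", {
  ts <- simulate_psc_recording(psc_sim(ipsc_release_probability = 0))
  ff <- isolate_ff_ipsc(ts)
  expect_lt(max(abs(ff$isolated_trace)), 1e-9)
  expect_equal(ff$scale_factor, 0.6, tolerance = 1e-6)
})

test_that("planted IPSC amplitude and latency are recovered", {
  ts <- simulate_psc_recording(psc_sim(ipsc_release_probability = 1))
  ff <- isolate_ff_ipsc(ts)
  expect_equal(ff$latency_ms, 3, tolerance = 0.2 / 3)
  expect_equal(ff$amplitude_pa, 50, tolerance = 0.05)
  # Bernoulli release: the averaged IPSC is p x amplitude (kernel arithmetic)
  tp <- simulate_psc_recording(psc_sim(ipsc_release_probability = 0.7,
                                       seed = 2))
  fp <- isolate_ff_ipsc(tp)
  p_real <- mean(tp$planted$released)
  expect_equal(fp$amplitude_pa, p_real * 50, tolerance = 0.05)
})

test_that("noise-only trials fail onset detection gracefully", {
  ts <- simulate_psc_recording(psc_sim(epsc_amplitude_pa = 0,
                                       ipsc_amplitude_pa = 0,
                                       noise_sd_pa = 2, seed = 3))
  expect_error(isolate_ff_ipsc(ts), "undetectable")
})

test_that("exclusion rules trigger on 100% incidence and sub-ms latency", {
  t100 <- simulate_psc_recording(psc_sim(ipsc_release_probability = 1))
  f100 <- apply_exclusion_rules(t100, isolate_ff_ipsc(t100))
  expect_true(f100$excluded)
  expect_equal(f100$exclusion_reason, "outward_incidence_100")
  expect_equal(f100$outward_incidence, 1)

  tshort <- simulate_psc_recording(psc_sim(ipsc_latency_ms = 0.6,
                                           ipsc_release_probability = 0.7,
                                           seed = 2))
  fshort <- apply_exclusion_rules(tshort, isolate_ff_ipsc(tshort))
  expect_true(fshort$excluded)
  expect_equal(fshort$exclusion_reason, "latency_below_1ms")
  expect_lt(fshort$latency_ms, 1)

  tok <- simulate_psc_recording(psc_sim(ipsc_release_probability = 0.7,
                                        seed = 2))
  fok <- apply_exclusion_rules(tok, isolate_ff_ipsc(tok))
  expect_false(fok$excluded)
  expect_equal(fok$exclusion_reason, "none")
  expect_lt(fok$outward_incidence, 1)
})

test_that("inward charge integrates only the inward component", {
  fs <- 20000
  tt <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  tr <- numeric(length(tt))
  tr[tt >= 0.01 & tt <= 0.012] <- -100     # 100 pA for 2 ms -> 0.2 pC
  expect_equal(inward_charge(tr, tt, c(0, 0.05))$inward_charge_pc, 0.2,
               tolerance = 0.05)
  expect_equal(inward_charge(abs(tr), tt, c(0, 0.05))$inward_charge_pc, 0)
  # biexponential kernel against the closed-form integral
  tau_d <- 0.004; tau_r <- 3e-4; A <- 80
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  k <- -A * k / max(k)
  analytic <- A * (tau_d - tau_r) / max(exp(-tt / tau_d) - exp(-tt / tau_r))
  expect_equal(inward_charge(k, tt, c(0, 0.1))$inward_charge_pc * 1e3,
               analytic * 1e3, tolerance = 0.01)
  # additivity over disjoint windows, invariance to outward components
  set.seed(4)
  r <- rnorm(length(tt), 0, 30)
  q1 <- inward_charge(r, tt, c(0, 0.05))$inward_charge_pc
  q2 <- inward_charge(r, tt, c(0.05, 0.1))$inward_charge_pc
  expect_equal(q1 + q2,
               inward_charge(r, tt, c(0, 0.1))$inward_charge_pc,
               tolerance = 1e-6)
  expect_error(inward_charge(r, tt, c(1, 2)), "window")
})

test_that("spiking probability is the per-condition percentage", {
  out <- spike_probability(c(rep(TRUE, 3), rep(FALSE, 7)), rep("before", 10))
  expect_equal(out$probability, 30)
  expect_equal(spike_probability(rep(FALSE, 10),
                                 rep("during_opto", 10))$probability, 0)
  expect_error(spike_probability(logical(0), character(0)), "zero trials")
  # Bernoulli simulation: recovered within the binomial CI
  set.seed(5)
  cond <- rep(c("before", "during_opto", "after"), each = 200)
  p_true <- c(before = 0.7, during_opto = 0.45, after = 0.6)
  spikes <- runif(600) < p_true[cond]
  est <- spike_probability(spikes, cond)
  for (cn in names(p_true)) {
    ci <- 100 * 1.96 * sqrt(p_true[cn] * (1 - p_true[cn]) / 200)
    expect_lt(abs(est$probability[est$condition == cn] - 100 * p_true[cn]),
              ci)
  }
})

test_that("connectivity percentages use the two-decimal convention", {
  counts <- data.frame(cell_type = c("pNGF", "pSBC", "pNGF_rev", "pSBC_rev",
                                     "pSOM"),
                       connected = c(21, 19, 4, 9, 0),
                       tested = c(58, 36, 48, 25, 10))
  out <- connectivity_summary(counts)
  expect_equal(out$percent, c(36.21, 52.78, 8.33, 36.00, 0.00))
  # round trip within rounding
  expect_true(all(abs(out$percent * out$tested / 100 - out$connected) < 0.05))
  expect_error(connectivity_summary(data.frame(cell_type = "x", connected = 1,
                                               tested = 0)), "zero")
  expect_error(connectivity_summary(data.frame(cell_type = "x", connected = 5,
                                               tested = 3)), "counts")
})
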