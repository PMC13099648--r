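np_std <- neuron_params(r_in = 200, c_m = 100, v_rest = -70, v_thresh = -50)
ss_std <- simulate_current_clamp(np_std,
  step_protocol(start_pa = 50, increment_pa = 50, n_steps = 8,
                hyper_pa = -50))

test_that("spike detection recovers stamped APs and is threshold-monotone", {
  sub <- ss_std$sweeps[[1]] # hyperpolarizing sweep: no spikes
  expect_equal(nrow(detect_spikes(sub$v, ss_std$dt)), 0)
  sup <- ss_std$sweeps[[5]]
  sp <- detect_spikes(sup$v, ss_std$dt)
  expect_equal(nrow(sp), length(sup$spike_idx_true))
  expect_true(all(abs(sp$t_s - (sup$spike_idx_true - 1) * ss_std$dt) <=
                    2 * ss_std$dt))
  expect_true(all(sp$amplitude_mv > 0 & sp$half_width_ms > 0))
  n_hi <- nrow(detect_spikes(sup$v, ss_std$dt, dvdt_threshold = 40))
  expect_lte(n_hi, nrow(sp))
})

test_that("I-F curve counts match the closed-form LIF rate within 1 spike", {
  ifc <- build_if_curve(ss_std)
  expect_equal(ifc$i_pa, seq(50, 400, by = 50))
  for (i in seq_len(nrow(ifc))) {
    f <- lif_rate(ifc$i_pa[i], 200, 100, -70, -65, -50, 0.002)
    expect_lte(abs(ifc$n_spikes[i] - floor(f)), 1)
  }
  # all-subthreshold family
  weak <- simulate_current_clamp(np_std,
    step_protocol(start_pa = 10, increment_pa = 10, n_steps = 5,
                  hyper_pa = NULL))
  expect_true(all(build_if_curve(weak)$n_spikes == 0))
  # duplicate currents flagged
  dup <- ss_std
  dup$sweeps <- c(dup$sweeps, dup$sweeps[2])
  expect_error(build_if_curve(dup), "duplicate")
})

test_that("gain is the OLS slope of the rising I-F limb", {
  ifc <- data.frame(i_pa = c(0, 50, 100, 150), n_spikes = c(0, 2, 4, 6))
  expect_equal(compute_gain(ifc), 0.04)
  flat <- data.frame(i_pa = c(0, 50, 100, 150), n_spikes = c(0, 3, 3, 3))
  expect_equal(compute_gain(flat), 0)
  expect_true(is.na(compute_gain(
    data.frame(i_pa = c(0, 50, 100), n_spikes = c(0, 0, 4)))))
  # descending limb from depolarization block is excluded
  blk <- data.frame(i_pa = seq(0, 250, 50), n_spikes = c(0, 2, 4, 6, 3, 0))
  expect_equal(compute_gain(blk), 0.04)
})

test_that("rheobase is the smallest suprathreshold step", {
  expect_equal(compute_rheobase(
    data.frame(i_pa = c(50, 100, 150, 200), n_spikes = c(0, 0, 2, 5))), 150)
  expect_true(is.na(compute_rheobase(
    data.frame(i_pa = c(50, 100), n_spikes = c(0, 0)))))
})

test_that("ramp latency matches fine-grid integration within 2 samples", {
  ramp <- simulate_current_clamp(np_std, ramp_protocol())
  lat <- compute_spike_latency(ramp)
  oracle <- lif_ramp_first_crossing(800, 1, 200, 100, -70, -50) * 1000
  expect_equal(lat, oracle, tolerance = 2 * ramp$dt * 1000 / oracle)
  # halving R_in delays the first crossing
  np_lo <- neuron_params(r_in = 100, c_m = 100, v_rest = -70,
                         v_thresh = -50)
  lat_lo <- compute_spike_latency(simulate_current_clamp(np_lo,
                                                         ramp_protocol()))
  expect_gt(lat_lo, lat)
  # no spikes: missing
  tiny <- simulate_current_clamp(np_std, ramp_protocol(peak_pa = 50))
  expect_true(is.na(compute_spike_latency(tiny)))
})

test_that("passive properties are recovered from the hyperpolarizing step", {
  np <- neuron_params(r_in = 150, c_m = 120, v_rest = -70, v_thresh = -50)
  ss <- simulate_current_clamp(np, step_protocol(start_pa = 50,
    increment_pa = 50, n_steps = 2, hyper_pa = -50))
  pas <- compute_passive(ss)
  expect_equal(pas$r_in_mohm, 150, tolerance = 0.05)
  expect_equal(pas$c_m_pf, 120, tolerance = 0.05)
  expect_equal(pas$rmp_mv, -70, tolerance = 1e-6)
  # doubling C at fixed R doubles tau
  np2 <- neuron_params(r_in = 150, c_m = 240, v_rest = -70, v_thresh = -50)
  ss2 <- simulate_current_clamp(np2, step_protocol(start_pa = 50,
    increment_pa = 50, n_steps = 1, hyper_pa = -50))
  expect_equal(compute_passive(ss2)$tau_ms / pas$tau_ms, 2,
               tolerance = 0.05)
  # spiking step is rejected
  spiky <- simulate_current_clamp(np, step_protocol(start_pa = 300,
    increment_pa = 50, n_steps = 1, hyper_pa = NULL))
  expect_error(compute_passive(spiky), "spikes")
})

test_that("secondary parameters: max rate and accommodation", {
  ifc <- data.frame(i_pa = c(50, 100, 150, 200), n_spikes = c(0, 3, 7, 5))
  sec <- compute_secondary(ss_std, if_curve = ifc)
  expect_equal(sec$max_rate_hz, 7)
  # LIF trains are regular: accommodation ~ 1
  sec2 <- compute_secondary(ss_std)
  expect_equal(sec2$accommodation, 1, tolerance = 0.05)
  # hand-made ISI sequence 10, 20, 40, 80 ms: ratio 8
  isi <- c(10, 20, 40, 80) / 1000
  expect_equal(isi[length(isi)] / isi[1], 8)
})

test_that("inactivation threshold follows the block rule, LIF never blocks", {
  expect_true(is.na(compute_inactivation_threshold(ss_std)))
  # constructed sweep set: counts (2, 8, 10, 3, 0) with late sweeps
  # ceasing early; rule-by-rule the threshold is the 4th step current
  mk_sweep <- function(amp, spike_times, dt = 1e-4) {
    n <- round(1.2 / dt)
    v <- rep(-70, n); i <- rep(0, n)
    stim <- (round(0.1 / dt) + 1):round(1.1 / dt)
    i[stim] <- amp
    tmpl <- hippex:::ap_template(dt, -50, -65)
    for (ts in spike_times) {
      k <- round((0.1 + ts) / dt)
      v[k:(k + length(tmpl) - 1)] <- tmpl
    }
    list(t = (seq_len(n) - 1) * dt, v = v, i_pa = i)
  }
  counts <- list(seq(0.1, 0.9, length.out = 2),
                 seq(0.05, 0.95, length.out = 8),
                 seq(0.05, 0.95, length.out = 10),
                 seq(0.05, 0.3, length.out = 3), # ceases at 30%
                 numeric(0))
  ss <- structure(list(
    sweeps = lapply(1:5, function(k) mk_sweep(100 * k, counts[[k]])),
    protocol = step_protocol(start_pa = 100, increment_pa = 100,
                             n_steps = 5, hyper_pa = NULL),
    dt = 1e-4, truth = NULL), class = "sweep_set")
  expect_equal(compute_inactivation_threshold(ss), 400)
  # monotonically increasing counts: none
  ss_mono <- structure(list(
    sweeps = lapply(1:4, function(k)
      mk_sweep(100 * k, seq(0.05, 0.95, length.out = 2 * k))),
    protocol = step_protocol(start_pa = 100, increment_pa = 100,
                             n_steps = 4, hyper_pa = NULL),
    dt = 1e-4, truth = NULL), class = "sweep_set")
  expect_true(is.na(compute_inactivation_threshold(ss_mono)))
})

test_that("DGC typing separates a bimodal threshold mixture", {
  set.seed(8)
  truth <- rep(c("I", "II"), c(60, 60))
  thr <- c(rnorm(60, 150, 30), rnorm(60, 400, 40))
  cls <- classify_dgc_type(thr)
  expect_gt(mean(cls$type == truth), 0.95)
  expect_true(cls$cutoff_pa > 200 && cls$cutoff_pa < 350)
  # no finite thresholds: all Type II (with a warning about the cutoff)
  expect_warning(all_na <- classify_dgc_type(rep(NA_real_, 5)), "cutoff")
  expect_true(all(all_na$type == "II"))
  # manual cutoff respected exactly
  man <- classify_dgc_type(c(100, 250, NA), cutoff = 200)
  expect_equal(as.character(man$type), c("I", "II", "II"))
})

test_that("soma volume prediction follows the specific-capacitance law", {
  # C_m = 90 pF at 0.9 uF/cm^2: area 1e4 um^2, sphere volume 9.40e4 um^3
  expect_equal(predict_soma_volume(90), 9.403e4, tolerance = 1e-3)
  expect_equal(predict_soma_volume(180) / predict_soma_volume(90),
               2^1.5, tolerance = 1e-9)
  expect_error(predict_soma_volume(0), "positive")
})

test_that("percent-of-control normalisation", {
  expect_equal(percent_of_control(20, c(10, 20, 30)), 100)
  expect_equal(percent_of_control(40, c(10, 20, 30)), 200)
  expect_equal(percent_of_control(40, c(30, 10, 20)), 200)
  expect_error(percent_of_control(1, c(-1, 1)), "nonzero")
})

test_that("feature extraction is deterministic and never codes missing as 0", {
  f1 <- extract_features(ss_std)
  f2 <- extract_features(ss_std)
  expect_identical(f1, f2)
  expect_true(is.na(f1$spike_latency_ms)) # no ramp supplied
  expect_true(is.na(f1$inactivation_threshold_pa))
  expect_gt(f1$soma_volume_um3, 0)
})
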