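test_that("preprocessing removes DC, subtracts reference and validates", {
  x <- matrix(50, 30000, 1)
  rec <- lfp_recording(x, 1000)
  pp <- preprocess_lfp(rec, hp_cutoff = 0.5, smooth_ms = NULL)
  # steady-state portion after edge transients
  expect_lt(max(abs(pp$samples[10000:20000, 1])), 0.5)
  # identical data and reference channel cancel exactly
  two <- lfp_recording(cbind(sin(1:1000), sin(1:1000)), 1000,
                       channel_meta = data.frame(channel = 1:2,
                                                 region = c("CA3", "reference"),
                                                 layer = "cell"))
  pp2 <- preprocess_lfp(two, hp_cutoff = NULL, smooth_ms = NULL,
                        reference_channel = 2)
  expect_equal(ncol(pp2$samples), 1)
  expect_true(all(pp2$samples == 0))
  expect_error(preprocess_lfp(rec, target_fs = 2000), "target_fs")
  expect_error(preprocess_lfp(rec, hp_cutoff = 600), "Nyquist")
})

test_that("a 1 kHz sine survives 30 kHz -> 5 kHz decimation within 1%", {
  tt <- (0:(30000 * 10 - 1)) / 30000
  rec <- lfp_recording(matrix(sin(2 * pi * 1000 * tt), ncol = 1), 30000)
  pp <- preprocess_lfp(rec, target_fs = 5000, hp_cutoff = 0.1,
                       smooth_ms = NULL)
  expect_equal(pp$fs_hz, 5000)
  seg <- pp$samples[10000:40000, 1]
  expect_equal(sqrt(mean(seg^2)) * sqrt(2), 1, tolerance = 0.01)
})

test_that("baseline sd estimate is accurate and robust to spikes", {
  set.seed(4)
  rec <- lfp_recording(matrix(rnorm(60 * 1000, sd = 10), ncol = 1), 1000)
  expect_equal(estimate_baseline_sd(rec), 10, tolerance = 0.05)
  # constant trace: zero spread
  expect_equal(estimate_baseline_sd(
    lfp_recording(matrix(5, 2000, 1), 1000)), 0)
  # contamination with sparse large spikes barely moves the estimate,
  # unlike the plain sd
  x <- rnorm(60000, sd = 10)
  spikes <- sample(60000, 600)
  x[spikes] <- x[spikes] + 200
  recc <- lfp_recording(matrix(x, ncol = 1), 1000)
  expect_equal(estimate_baseline_sd(recc), 10, tolerance = 0.10)
  expect_gt(sd(x), 15)
  expect_error(estimate_baseline_sd(rec, mask = rep(FALSE, 60000)), "mask")
})

test_that("IIS detection applies amplitude and duration gates", {
  rec0 <- lfp_recording(matrix(0, 10000, 1), 1000)
  expect_equal(nrow(detect_iis(rec0, baseline_sd = 1)), 0)
  mk <- function(width_ms, amp) {
    ev <- data.frame(onset_s = 2, amplitude_sd = amp, width_ms = width_ms,
                     polarity = "+")
    simulate_lfp(lfp_sim_config(5, 5000, noise_sd = 0, events = ev))
  }
  d20 <- detect_iis(mk(20, 8), baseline_sd = 1)
  expect_equal(nrow(d20), 1)
  expect_true(d20$duration_ms >= 10 && d20$duration_ms <= 100)
  expect_equal(d20$onset_s, 2, tolerance = 0.005)
  # 5 ms pulse and 150 ms plateau at 8 sd are rejected by the gates
  expect_equal(nrow(detect_iis(mk(5, 8), baseline_sd = 1)), 0)
  plateau <- matrix(0, 25000, 1); plateau[10000:10750] <- 8
  expect_equal(nrow(detect_iis(lfp_recording(plateau, 5000),
                               baseline_sd = 1)), 0)
  expect_error(detect_iis(rec0, baseline_sd = 0), "baseline_sd")
})

test_that("detector matches the sample-wise threshold-scan oracle", {
  for (seed in 1:5) {
    ev <- data.frame(onset_s = c(3, 10, 17, 24),
                     amplitude_sd = c(8, 6, 12, 8),
                     width_ms = c(20, 40, 70, 140),
                     polarity = c("+", "-", "+", "-"))
    rec <- simulate_lfp(lfp_sim_config(30, 2000, noise_sd = 0, events = ev,
                                       seed = seed))
    det <- detect_iis(rec, baseline_sd = 1)
    oracle <- scan_events(rec$samples[, 1], 2000, thr = 5, boundary = 1,
                          min_ms = 10, max_ms = 100)
    expect_equal(nrow(det), length(oracle))
    if (length(oracle))
      expect_equal(det$onset_s,
                   vapply(oracle, `[[`, numeric(1), "onset"))
  }
})

test_that("detection is scale-equivariant and events never overlap", {
  ev <- data.frame(onset_s = seq(1, 55, by = 3), amplitude_sd = 8,
                   width_ms = 30, polarity = "+")
  rec <- simulate_lfp(lfp_sim_config(60, 2000, noise_sd = 10, events = ev,
                                     seed = 12))
  bsd <- estimate_baseline_sd(rec)
  sm <- preprocess_lfp(rec, hp_cutoff = NULL, smooth_ms = 2)
  d1 <- detect_iis(sm, bsd)
  sm10 <- sm; sm10$samples <- sm$samples * 10
  d2 <- detect_iis(sm10, bsd * 10)
  expect_equal(d1, d2)
  expect_true(all(diff(as.vector(rbind(d1$onset_s, d1$offset_s))) >= 0))
  expect_lte(nrow(d1), floor(60 * 1000 / 10))
})

test_that("IIS rate counts events inside the activity mask per minute", {
  ev <- data.frame(onset_s = c(10, 20, 30, 40, 50, 60),
                   offset_s = c(10, 20, 30, 40, 50, 60) + 0.03)
  ev$duration_ms <- 30; ev$peak_amplitude_sd <- 8; ev$polarity <- "+"
  mask <- rep(TRUE, 180 * 100) # 3 min at 100 Hz
  r <- iis_rate(ev, mask, 100)
  expect_equal(r$rate_per_min, 2.0)
  expect_equal(iis_rate(ev[0, ], mask, 100)$rate_per_min, 0)
  expect_error(iis_rate(ev, rep(FALSE, 100), 100), "zero active")
  # events counted iff onset falls inside the mask (brute-force check)
  mask2 <- rep(FALSE, 180 * 100)
  mask2[1:(35 * 100)] <- TRUE # active up to 35 s
  r2 <- iis_rate(ev, mask2, 100)
  manual <- sum(vapply(ev$onset_s, function(o)
    mask2[floor(o * 100) + 1], logical(1)))
  expect_equal(r2$n_events, manual)
  expect_equal(r2$n_events, 3)
})
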