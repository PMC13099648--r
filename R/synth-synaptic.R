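#' Configuration for a synthetic voltage-clamp trace
#'
#' Spontaneous synaptic currents are simulated as a Poisson train of onsets
#' convolved with a double-exponential kernel (time-to-peak set by `rise_ms`,
#' relaxation by `decay_ms`) plus Gaussian current noise. The holding
#' potential determines event polarity: inward (negative) deflections at
#' -70 mV (sEPSC), outward (positive) at 0 mV (sIPSC).
#'
#' @param rate_hz Mean event rate, Hz.
#' @param amp_mean_pa,amp_sd_pa Event amplitude distribution (magnitudes, pA);
#'   draws are truncated at one tenth of the mean.
#' @param rise_ms,decay_ms Kernel time constants, ms (`decay > rise > 0`).
#' @param noise_sd_pa Baseline current noise s.d., pA.
#' @param duration_s Trace duration, s.
#' @param holding_mv Holding potential, mV (-70 or 0 by convention).
#' @param dt Sample interval, s.
#' @param seed Integer seed.
#' @return An object of class `synaptic_sim_config`.
#' @export
synaptic_sim_config <- function(rate_hz = 2, amp_mean_pa = 20, amp_sd_pa = 5,
                                rise_ms = 1, decay_ms = 6, noise_sd_pa = 2,
                                duration_s = 60, holding_mv = -70,
                                dt = 5e-4, seed = 1L) {
  assert_number(rate_hz, "rate_hz", nonneg = TRUE)
  assert_number(amp_mean_pa, "amp_mean_pa", positive = TRUE)
  assert_number(rise_ms, "rise_ms", positive = TRUE)
  assert_number(decay_ms, "decay_ms", positive = TRUE)
  if (decay_ms <= rise_ms) stop("decay_ms must exceed rise_ms")
  assert_number(duration_s, "duration_s", positive = TRUE)
  if (dt <= 0) stop("dt must be > 0")
  structure(list(rate_hz = rate_hz, amp_mean_pa = amp_mean_pa,
                 amp_sd_pa = amp_sd_pa, rise_ms = rise_ms,
                 decay_ms = decay_ms, noise_sd_pa = noise_sd_pa,
                 duration_s = duration_s, holding_mv = holding_mv,
                 dt = dt, seed = seed),
            class = "synaptic_sim_config")
}

# Unit-peak double-exponential kernel sampled at dt.
synaptic_kernel <- function(rise_ms, decay_ms, dt,
                            support_ms = rise_ms + 6 * decay_ms) {
  tt <- seq(0, support_ms / 1000, by = dt)
  k <- exp(-tt / (decay_ms / 1000)) - exp(-tt / (rise_ms / 1000))
  if (max(k) <= 0) stop("degenerate kernel")
  k / max(k)
}

#' Simulate a voltage-clamp trace with spontaneous synaptic events
#'
#' @param config A [synaptic_sim_config()].
#' @param onsets_s Optional fixed onset times (seconds) overriding the
#'   Poisson draw, for fully controlled traces.
#' @return A `vc_trace`: list with `t`, `i_pa`, `dt`, `holding_mv`,
#'   `duration_s` and ground-truth `truth` (`onset_s`, `amplitude_pa`).
#' @export
simulate_synaptic_trace <- function(config, onsets_s = NULL) {
  stopifnot(inherits(config, "synaptic_sim_config"))
  n <- round(config$duration_s / config$dt)
  out <- with_seed(config$seed, {
    if (is.null(onsets_s)) {
      n_ev <- rpois(1, config$rate_hz * config$duration_s)
      onsets_s <- sort(runif(n_ev, 0, config$duration_s))
    }
    amps <- pmax(config$amp_mean_pa / 10,
                 rnorm(length(onsets_s), config$amp_mean_pa, config$amp_sd_pa))
    noise <- if (config$noise_sd_pa > 0) rnorm(n, sd = config$noise_sd_pa)
             else numeric(n)
    list(onsets_s = onsets_s, amps = amps, noise = noise)
  })
  sgn <- if (config$holding_mv < -30) -1 else 1
  kern <- synaptic_kernel(config$rise_ms, config$decay_ms, config$dt)
  x <- out$noise
  keep <- out$onsets_s < config$duration_s - config$dt
  onsets <- out$onsets_s[keep]
  amps <- out$amps[keep]
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] / config$dt) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] + sgn * amps[i] * kern[seq_along(idx)]
  }
  structure(list(t = (seq_len(n) - 1) * config$dt, i_pa = x, dt = config$dt,
                 holding_mv = config$holding_mv,
                 duration_s = config$duration_s,
                 truth = data.frame(onset_s = (floor(onsets / config$dt)) * config$dt,
                                    amplitude_pa = amps)),
            class = "vc_trace")
}

#' @exportS3Method base::print
print.vc_trace <- function(x, ...) {
  cat(sprintf("<vc_trace> %.1f s at %g Hz, holding %g mV, %d true event(s)\n",
              x$duration_s, 1 / x$dt, x$holding_mv,
              if (is.null(x$truth)) NA_integer_ else nrow(x$truth)))
  invisible(x)
}
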