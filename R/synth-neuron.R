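#' Ground-truth parameters of a model neuron
#'
#' Parameter set for the leaky integrate-and-fire (LIF) model used to
#' generate current-clamp sweeps with analytically known passive properties
#' and rheobase: for a long step, the minimum spiking current is
#' `(V_thresh - V_rest) / R_in`.
#'
#' @param r_in Input resistance, MOhm.
#' @param c_m Membrane capacitance, pF (`tau = r_in * c_m`).
#' @param v_rest Resting membrane potential, mV.
#' @param v_thresh Spike threshold, mV (must exceed `v_rest`).
#' @param v_reset Post-spike reset potential, mV.
#' @param refractory_ms Absolute refractory period, ms.
#' @param noise_sd Per-sample Gaussian voltage noise, mV (0 = deterministic).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(r_in = 200, c_m = 100, v_rest = -70,
                          v_thresh = -50, v_reset = -65,
                          refractory_ms = 2, noise_sd = 0, seed = 1L) {
  assert_number(r_in, "r_in", positive = TRUE)
  assert_number(c_m, "c_m", positive = TRUE)
  assert_number(v_rest, "v_rest")
  assert_number(v_thresh, "v_thresh")
  if (v_thresh <= v_rest) stop("v_thresh must exceed v_rest")
  assert_number(refractory_ms, "refractory_ms", nonneg = TRUE)
  assert_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(r_in = r_in, c_m = c_m, v_rest = v_rest,
                 v_thresh = v_thresh, v_reset = v_reset,
                 refractory_ms = refractory_ms, noise_sd = noise_sd,
                 seed = seed),
            class = "neuron_params")
}

#' Current-clamp stimulation protocols
#'
#' `step_protocol()` describes a family of 1-s square current steps of
#' incremental amplitude (50-pA increments for pyramidal cells, 20 pA for
#' dentate granule cells), optionally preceded by a hyperpolarizing step for
#' passive-property estimation. `ramp_protocol()` describes a linear ramp
#' (default 800 pA over 1 s) used to measure spike latency.
#'
#' @param start_pa First step amplitude, pA.
#' @param increment_pa Step increment, pA.
#' @param n_steps Number of depolarizing steps.
#' @param duration_s Stimulus duration, s.
#' @param pre_s,post_s Baseline before and after the stimulus, s.
#' @param hyper_pa Amplitude of the passive-property step, pA (negative);
#'   `NULL` to omit.
#' @param n_hyper Number of repeated passive-property sweeps (averaged at
#'   analysis time, as in a standard membrane test).
#' @param dt Sample interval, s.
#' @return A `step_protocol` / `ramp_protocol` object.
#' @export
step_protocol <- function(start_pa = 50, increment_pa = 50, n_steps = 10,
                          duration_s = 1, pre_s = 0.1, post_s = 0.1,
                          hyper_pa = -50, n_hyper = 1, dt = 1e-4) {
  if (dt <= 0) stop("dt must be > 0")
  assert_number(duration_s, "duration_s", positive = TRUE)
  structure(list(kind = "step", start_pa = start_pa,
                 increment_pa = increment_pa, n_steps = n_steps,
                 duration_s = duration_s, pre_s = pre_s, post_s = post_s,
                 hyper_pa = hyper_pa, n_hyper = n_hyper, dt = dt),
            class = "ephys_protocol")
}

#' @rdname step_protocol
#' @param peak_pa Current at the end of the ramp, pA.
#' @export
ramp_protocol <- function(peak_pa = 800, duration_s = 1, pre_s = 0.1,
                          post_s = 0.1, dt = 1e-4) {
  if (dt <= 0) stop("dt must be > 0")
  structure(list(kind = "ramp", peak_pa = peak_pa, duration_s = duration_s,
                 pre_s = pre_s, post_s = post_s, dt = dt),
            class = "ephys_protocol")
}

# Stationary Ornstein-Uhlenbeck noise with sd `sigma` and correlation
# time `tau_s`.
ou_noise <- function(n, dt, sigma, tau_s) {
  a <- exp(-dt / tau_s)
  innov <- rnorm(n, sd = sigma * sqrt(1 - a^2))
  innov[1] <- rnorm(1, sd = sigma)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Stereotyped 2-ms action-potential waveform stamped at LIF spike times so
# waveform metrics (amplitude, half-width, rise time, fAHP) are computable.
ap_template <- function(dt, v_thresh, v_reset, peak_mv = 40, fahp_mv = 8,
                        width_ms = 2) {
  n <- max(4L, round(width_ms / 1000 / dt))
  n_up <- max(2L, round(n / 4))
  up <- seq(v_thresh, peak_mv, length.out = n_up)
  n_dn <- n - n_up
  dn <- peak_mv - (peak_mv - (v_reset - fahp_mv)) *
    (1 - exp(-seq_len(n_dn) / (n_dn / 3)))
  c(up, dn)
}

#' Simulate current-clamp sweeps from a LIF neuron
#'
#' Integrates `dV/dt = (-(V - V_rest) + I * R_in) / tau` with spike emission
#' at threshold, reset and absolute refractory period, then stamps a
#' stereotyped 2-ms action-potential waveform at each spike time. The
#' analytic model keeps rheobase, passive properties and latency known in
#' closed form while producing realistic-looking sweeps.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [step_protocol()] or [ramp_protocol()].
#' @return A `sweep_set`: list with `sweeps` (each `t`, `v` mV, `i_pa`),
#'   `protocol`, `dt` and `truth = params`.
#' @export
simulate_current_clamp <- function(params, protocol) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "ephys_protocol"))
  dt <- protocol$dt
  if (dt <= 0) stop("dt must be > 0")
  n_pre <- round(protocol$pre_s / dt)
  n_stim <- round(protocol$duration_s / dt)
  n_post <- round(protocol$post_s / dt)
  currents <- if (protocol$kind == "step") {
    amps <- protocol$start_pa + protocol$increment_pa * (seq_len(protocol$n_steps) - 1)
    if (!is.null(protocol$hyper_pa))
      amps <- c(rep(protocol$hyper_pa, protocol$n_hyper %||% 1), amps)
    lapply(amps, function(a) c(rep(0, n_pre), rep(a, n_stim), rep(0, n_post)))
  } else {
    list(c(rep(0, n_pre),
           protocol$peak_pa * seq_len(n_stim) / n_stim,
           rep(0, n_post)))
  }
  tmpl <- ap_template(dt, params$v_thresh, params$v_reset)
  sweeps <- vector("list", length(currents))
  for (s in seq_along(currents)) {
    ivec <- currents[[s]]
    res <- .lif_integrate_cpp(ivec, dt, params$r_in, params$c_m,
                              params$v_rest, params$v_thresh, params$v_reset,
                              params$refractory_ms / 1000, numeric(0))
    v <- res$v
    for (k in res$spike_idx) {
      idx <- k:min(length(v), k + length(tmpl) - 1L)
      v[idx] <- tmpl[seq_along(idx)]
    }
    if (params$noise_sd > 0) {
      # band-limited (OU, 1-ms correlation time) voltage noise on the
      # recorded trace; per-sample white noise at sub-ms sampling would
      # imply unphysical slew rates
      v <- v + with_seed(derive_seed(params$seed, s),
                         ou_noise(length(v), dt, params$noise_sd, 1e-3))
    }
    sweeps[[s]] <- list(t = (seq_along(ivec) - 1) * dt, v = v, i_pa = ivec,
                        spike_idx_true = res$spike_idx)
  }
  structure(list(sweeps = sweeps, protocol = protocol, dt = dt,
                 truth = params),
            class = "sweep_set")
}

#' @exportS3Method base::print
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps (%s protocol), dt = %g s\n",
              length(x$sweeps), x$protocol$kind, x$dt))
  invisible(x)
}
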