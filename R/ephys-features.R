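#' Detect action potentials in a current-clamp sweep
#'
#' Spike onset is the first sample where dV/dt crosses `dvdt_threshold`
#' (mV/ms) upward; the derivative is a central difference over
#' `deriv_window_ms` so band-limited recording noise does not mimic an
#' action-potential upstroke. Successive onsets closer than 1 ms are
#' merged. Per-spike
#' waveform metrics follow standard conventions: amplitude = peak minus
#' threshold voltage, half-width at half-amplitude (linear interpolation of
#' the crossing times), 10-90% rise time on the upstroke, fast
#' afterhyperpolarization (fAHP) = threshold voltage minus the minimum
#' within 5 ms after the peak.
#'
#' @param v Membrane voltage, mV.
#' @param dt Sample interval, s.
#' @param dvdt_threshold Onset criterion, mV/ms.
#' @param deriv_window_ms Central-difference half-window for the
#'   derivative, ms.
#' @return `data.frame` with one row per spike: `t_s`, `threshold_mv`,
#'   `peak_mv`, `amplitude_mv`, `half_width_ms`, `rise_time_ms`, `fahp_mv`.
#' @export
detect_spikes <- function(v, dt, dvdt_threshold = 20, deriv_window_ms = 0.2) {
  empty <- data.frame(t_s = numeric(0), threshold_mv = numeric(0),
                      peak_mv = numeric(0), amplitude_mv = numeric(0),
                      half_width_ms = numeric(0), rise_time_ms = numeric(0),
                      fahp_mv = numeric(0))
  n <- length(v)
  if (n < 5) return(empty)
  k <- max(1L, round(deriv_window_ms / 1000 / dt))
  dvdt <- c(rep(0, k), (v[(2 * k + 1):n] - v[1:(n - 2 * k)]) /
                        (2 * k * dt * 1000), rep(0, k))
  cross <- which(dvdt[-1] >= dvdt_threshold & dvdt[-length(dvdt)] < dvdt_threshold) + 1L
  if (!length(cross)) return(empty)
  min_sep <- max(1L, round(0.001 / dt))
  onsets <- cross[c(TRUE, diff(cross) > min_sep)]
  win <- max(2L, round(0.003 / dt)) # peak search window: 3 ms
  rows <- lapply(onsets, function(i0) {
    seg <- i0:min(n, i0 + win)
    pk_rel <- which.max(v[seg])
    pk <- seg[pk_rel]
    thr <- v[i0]
    amp <- v[pk] - thr
    if (amp <= 0) return(NULL)
    half_lvl <- thr + amp / 2
    # half-width: crossings of half_lvl on up- and downstroke
    up <- i0:pk
    iu <- which(v[up] >= half_lvl)[1]
    t_up <- if (is.na(iu) || iu == 1) up[1] else {
      a <- up[iu - 1]; b <- up[iu]
      a + (half_lvl - v[a]) / (v[b] - v[a])
    }
    dn_end <- min(n, pk + win)
    dn <- pk:dn_end
    id <- which(v[dn] <= half_lvl)[1]
    t_dn <- if (is.na(id) || id == 1) dn[length(dn)] else {
      a <- dn[id - 1]; b <- dn[id]
      a + (v[a] - half_lvl) / (v[a] - v[b])
    }
    hw_ms <- (t_dn - t_up) * dt * 1000
    # 10-90% rise time
    l10 <- thr + 0.1 * amp; l90 <- thr + 0.9 * amp
    i10 <- which(v[up] >= l10)[1]; i90 <- which(v[up] >= l90)[1]
    rt_ms <- if (is.na(i10) || is.na(i90)) NA_real_
             else (i90 - i10) * dt * 1000
    post <- pk:min(n, pk + round(0.005 / dt))
    fahp <- thr - min(v[post])
    data.frame(t_s = (i0 - 1) * dt, threshold_mv = thr, peak_mv = v[pk],
               amplitude_mv = amp, half_width_ms = hw_ms,
               rise_time_ms = rt_ms, fahp_mv = fahp)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Step sweeps of a sweep_set with their amplitudes; excludes the
# hyperpolarizing passive-property sweep.
step_sweeps <- function(ss, depolarizing_only = TRUE) {
  stopifnot(inherits(ss, "sweep_set"))
  if (ss$protocol$kind != "step") stop("step-family protocol required")
  amps <- vapply(ss$sweeps, function(sw) {
    i <- sw$i_pa
    on <- which(i != 0)
    if (!length(on)) 0 else i[on[1]]
  }, numeric(1))
  keep <- if (depolarizing_only) amps > 0 else rep(TRUE, length(amps))
  list(sweeps = ss$sweeps[keep], amps = amps[keep])
}

#' Build the input current vs firing rate (I-F) curve
#'
#' Counts spikes elicited during each 1-s depolarizing step, one point per
#' step, ordered by current.
#'
#' @param ss A step-protocol `sweep_set`.
#' @param dvdt_threshold Spike onset criterion passed to [detect_spikes()].
#' @return `data.frame` with `i_pa` and `n_spikes` (spikes per step, i.e.
#'   Hz for 1-s steps).
#' @export
build_if_curve <- function(ss, dvdt_threshold = 20) {
  st <- step_sweeps(ss)
  if (!length(st$sweeps)) stop("no depolarizing steps in sweep set")
  if (anyDuplicated(st$amps)) stop("duplicate step currents in sweep set")
  counts <- vapply(seq_along(st$sweeps), function(k) {
    sw <- st$sweeps[[k]]
    stim <- which(sw$i_pa != 0)
    sp <- detect_spikes(sw$v, ss$dt, dvdt_threshold)
    sum(sp$t_s >= (stim[1] - 1) * ss$dt & sp$t_s < stim[length(stim)] * ss$dt)
  }, numeric(1))
  o <- order(st$amps)
  data.frame(i_pa = st$amps[o], n_spikes = counts[o])
}

#' Output gain: linear slope of the rising I-F curve
#'
#' Ordinary least-squares slope fitted from the first suprathreshold point
#' through the maximum-rate point (inclusive), excluding any descending
#' limb caused by depolarization block. Requires at least 3 points in the
#' fit range, otherwise `NA`.
#'
#' @param if_curve `data.frame` from [build_if_curve()].
#' @return Gain in spikes s^-1 pA^-1 (multiply by 1000 for Hz/nA).
#' @export
compute_gain <- function(if_curve) {
  supra <- which(if_curve$n_spikes > 0)
  if (!length(supra)) return(NA_real_)
  i0 <- supra[1]
  # last point attaining the maximum, so a flat plateau is fitted whole
  i1 <- max(which(if_curve$n_spikes == max(if_curve$n_spikes)))
  if (i1 - i0 + 1 < 3) return(NA_real_)
  seg <- if_curve[i0:i1, ]
  unname(coef(lm(n_spikes ~ i_pa, data = seg))[2])
}

#' Rheobase: minimum step current eliciting at least one spike
#'
#' @param if_curve `data.frame` from [build_if_curve()].
#' @return Rheobase in pA, or `NA` if no step is suprathreshold.
#' @export
compute_rheobase <- function(if_curve) {
  supra <- which(if_curve$n_spikes >= 1)
  if (!length(supra)) return(NA_real_)
  if_curve$i_pa[supra[1]]
}

#' Spike latency under a ramped current injection
#'
#' Delay from ramp onset to the first action potential, in ms; `NA` when no
#' spike occurs.
#'
#' @param ss A ramp-protocol `sweep_set`.
#' @param dvdt_threshold Spike onset criterion.
#' @return Latency in ms.
#' @export
compute_spike_latency <- function(ss, dvdt_threshold = 20) {
  stopifnot(inherits(ss, "sweep_set"))
  if (ss$protocol$kind != "ramp") stop("ramp protocol required")
  sw <- ss$sweeps[[1]]
  onset <- which(sw$i_pa != 0)[1]
  sp <- detect_spikes(sw$v, ss$dt, dvdt_threshold)
  sp <- sp[sp$t_s >= (onset - 1) * ss$dt, , drop = FALSE]
  if (!nrow(sp)) return(NA_real_)
  (sp$t_s[1] - (onset - 1) * ss$dt) * 1000
}

#' Passive membrane properties from a subthreshold step
#'
#' Resting membrane potential is the mean pre-step voltage; input
#' resistance is the steady-state voltage deflection divided by the
#' injected current; the membrane time constant comes from a
#' single-exponential fit of the onset transient (initialised from the 63%
#' crossing time and refined by nonlinear least squares), giving
#' `C_m = tau / R_in`. When the protocol repeats the test pulse
#' (`n_hyper > 1`) the sweeps are averaged before fitting, as in a
#' standard membrane test.
#'
#' @param ss A `sweep_set` containing one or more identical subthreshold
#'   (typically hyperpolarizing) step sweeps.
#' @param sweep Indices of the passive-property sweeps; by default all
#'   sweeps whose step current is negative, or the first sweep if none.
#' @return List with `r_in_mohm`, `c_m_pf`, `rmp_mv`, `tau_ms`.
#' @export
compute_passive <- function(ss, sweep = NULL) {
  stopifnot(inherits(ss, "sweep_set"))
  dt <- ss$dt
  if (is.null(sweep)) {
    amps <- vapply(ss$sweeps, function(s) {
      on <- which(s$i_pa != 0)
      if (!length(on)) 0 else s$i_pa[on[1]]
    }, numeric(1))
    sweep <- which(amps < 0)
    if (!length(sweep)) sweep <- 1L
  }
  sw <- ss$sweeps[[sweep[1]]]
  if (length(sweep) > 1) {
    vs <- vapply(sweep, function(k) ss$sweeps[[k]]$v,
                 numeric(length(sw$v)))
    sw$v <- rowMeans(vs)
  }
  stim <- which(sw$i_pa != 0)
  if (!length(stim)) stop("sweep carries no current step")
  i_amp <- sw$i_pa[stim[1]]
  sp <- detect_spikes(sw$v, dt)
  if (nrow(sp)) stop("passive-property step evokes spikes; use a smaller step")
  pre <- 1:(stim[1] - 1)
  rmp <- mean(sw$v[pre])
  tail_idx <- stim[max(1, floor(0.8 * length(stim))):length(stim)]
  v_ss <- mean(sw$v[tail_idx])
  dv <- v_ss - rmp
  if (abs(dv) < 1e-9) stop("no measurable voltage deflection")
  r_in <- dv / i_amp * 1000 # mV/pA -> GOhm -> MOhm
  # tau: time to 63.2% of the deflection, refined by nls
  seg <- stim[1]:stim[length(stim)]
  tt <- (seg - stim[1]) * dt
  vv <- sw$v[seg]
  cross <- which(abs(vv - rmp) >= 0.632 * abs(dv))[1]
  tau0 <- max(tt[cross], dt)
  tau <- tryCatch({
    fit <- nls(vv ~ vss + (rmp - vss) * exp(-tt / tau),
               start = list(vss = v_ss, tau = tau0),
               control = list(warnOnly = TRUE))
    abs(coef(fit)[["tau"]])
  }, error = function(e) tau0)
  c_m <- tau / (r_in * 1e6) * 1e12 # s / Ohm -> F -> pF
  list(r_in_mohm = r_in, c_m_pf = c_m, rmp_mv = rmp, tau_ms = tau * 1000)
}

#' Secondary excitability parameters
#'
#' Maximal firing rate is the largest spike count over the 1-s steps.
#' Spike accommodation is the ratio of the last to the first inter-spike
#' interval at the first step eliciting at least five spikes (`NA` when no
#' such step exists).
#'
#' @param ss A step-protocol `sweep_set`.
#' @param if_curve Optional precomputed I-F curve.
#' @param dvdt_threshold Spike onset criterion.
#' @return List with `max_rate_hz` and `accommodation`.
#' @export
compute_secondary <- function(ss, if_curve = NULL, dvdt_threshold = 20) {
  if (is.null(if_curve)) if_curve <- build_if_curve(ss, dvdt_threshold)
  max_rate <- max(if_curve$n_spikes)
  st <- step_sweeps(ss)
  o <- order(st$amps)
  accommodation <- NA_real_
  for (k in o) {
    sw <- st$sweeps[[k]]
    sp <- detect_spikes(sw$v, ss$dt, dvdt_threshold)
    if (nrow(sp) >= 5) {
      isi <- diff(sp$t_s)
      accommodation <- isi[length(isi)] / isi[1]
      break
    }
  }
  list(max_rate_hz = max_rate, accommodation = accommodation)
}

#' Depolarization-block (inactivation) threshold
#'
#' The smallest step current, beyond the maximum-rate step, at which the
#' spike count falls below half the neuron's maximum and spiking ceases
#' before `early_frac` of the step duration — the signature of entry into
#' depolarization block. Returns `NA` when the neuron sustains firing at
#' all tested intensities.
#'
#' @param ss A step-protocol `sweep_set`.
#' @param if_curve Optional precomputed I-F curve.
#' @param count_frac Fraction of the maximal count defining "reduced
#'   firing" (default 0.5).
#' @param early_frac Fraction of step duration before which firing must
#'   cease (default 0.8).
#' @param dvdt_threshold Spike onset criterion.
#' @return Threshold current in pA, or `NA`.
#' @export
compute_inactivation_threshold <- function(ss, if_curve = NULL,
                                           count_frac = 0.5,
                                           early_frac = 0.8,
                                           dvdt_threshold = 20) {
  if (is.null(if_curve)) if_curve <- build_if_curve(ss, dvdt_threshold)
  st <- step_sweeps(ss)
  o <- order(st$amps)
  counts <- if_curve$n_spikes
  imax <- which.max(counts)
  if (imax >= length(counts)) return(NA_real_)
  for (j in (imax + 1):length(counts)) {
    if (counts[j] >= count_frac * counts[imax]) next
    sw <- st$sweeps[[o[j]]]
    stim <- which(sw$i_pa != 0)
    t_on <- (stim[1] - 1) * ss$dt
    t_dur <- length(stim) * ss$dt
    sp <- detect_spikes(sw$v, ss$dt, dvdt_threshold)
    sp <- sp[sp$t_s >= t_on, , drop = FALSE]
    last_t <- if (nrow(sp)) max(sp$t_s) else t_on
    if (last_t < t_on + early_frac * t_dur)
      return(if_curve$i_pa[j])
  }
  NA_real_
}

#' Classify dentate granule cells into Type I and Type II
#'
#' Type I cells cannot sustain firing at high stimulation intensity and
#' show a finite, low depolarization-block threshold; Type II cells show a
#' high or absent threshold. With `cutoff = "auto"` the boundary is placed
#' at the minimum-density valley between the two modes of the threshold
#' histogram; a numeric cutoff is used as given. Cells without a finite
#' threshold are Type II.
#'
#' @param thresholds Numeric vector of inactivation thresholds (pA), `NA`
#'   for cells that never block.
#' @param cutoff `"auto"` or a numeric current in pA.
#' @return List with `type` (factor `"I"`/`"II"`) and `cutoff_pa`.
#' @export
classify_dgc_type <- function(thresholds, cutoff = "auto") {
  fin <- thresholds[is.finite(thresholds)]
  if (identical(cutoff, "auto")) {
    if (length(fin) < 4) {
      warning("too few finite thresholds for automatic cutoff; all finite labelled Type I")
      cutoff_pa <- Inf
    } else {
      d <- density(fin)
      ispeak <- which(diff(sign(diff(d$y))) == -2) + 1L
      if (length(ispeak) < 2) {
        warning("unimodal threshold distribution; all finite thresholds labelled Type I")
        cutoff_pa <- Inf
      } else {
        top2 <- sort(ispeak[order(d$y[ispeak], decreasing = TRUE)][1:2])
        valley <- seq(top2[1], top2[2])
        cutoff_pa <- d$x[valley[which.min(d$y[valley])]]
      }
    }
  } else {
    assert_number(cutoff, "cutoff")
    cutoff_pa <- cutoff
  }
  type <- ifelse(is.finite(thresholds) & thresholds <= cutoff_pa, "I", "II")
  list(type = factor(type, levels = c("I", "II")), cutoff_pa = cutoff_pa)
}

#' Predict soma volume from membrane capacitance
#'
#' Specific membrane capacitance is essentially constant across neuron
#' types (0.9 uF/cm^2), so membrane area follows from `C_m` and the
#' equivalent-sphere volume provides a size proxy:
#' `A = C_m / c_spec`, `V = (4/3) pi r^3` with `r = sqrt(A / 4 pi)`.
#'
#' @param c_m_pf Membrane capacitance, pF.
#' @param specific_cm_uf_cm2 Specific capacitance, uF/cm^2.
#' @return Predicted soma volume in um^3.
#' @export
predict_soma_volume <- function(c_m_pf, specific_cm_uf_cm2 = 0.9) {
  if (any(!is.finite(c_m_pf)) || any(c_m_pf <= 0))
    stop("c_m_pf must be positive")
  c_spec_pf_um2 <- specific_cm_uf_cm2 * 1e-2 # uF/cm^2 -> pF/um^2
  area_um2 <- c_m_pf / c_spec_pf_um2
  r <- sqrt(area_um2 / (4 * pi))
  (4 / 3) * pi * r^3
}

#' Express values as percent of a within-mouse control mean
#'
#' @param values Numeric vector of measurements.
#' @param control_values Control measurements from the same mouse.
#' @return `100 * values / mean(control_values)`.
#' @export
percent_of_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) stop("control mean must be nonzero")
  100 * values / m
}

#' Extract the full morpho-electric feature vector for one neuron
#'
#' Convenience wrapper running the whole feature chain on a step-family
#' sweep set (with leading hyperpolarizing sweep) and a ramp sweep set.
#'
#' @param ss_step Step-protocol `sweep_set` including the passive sweep.
#' @param ss_ramp Ramp-protocol `sweep_set`, or `NULL`.
#' @param dvdt_threshold Spike onset criterion.
#' @return One-row `data.frame` of features (missing values are `NA`,
#'   never 0).
#' @export
extract_features <- function(ss_step, ss_ramp = NULL, dvdt_threshold = 20) {
  ifc <- build_if_curve(ss_step, dvdt_threshold)
  pas <- compute_passive(ss_step)
  sec <- compute_secondary(ss_step, ifc, dvdt_threshold)
  inact <- compute_inactivation_threshold(ss_step, ifc,
                                          dvdt_threshold = dvdt_threshold)
  data.frame(
    rheobase_pa = compute_rheobase(ifc),
    gain = compute_gain(ifc),
    spike_latency_ms = if (is.null(ss_ramp)) NA_real_
                       else compute_spike_latency(ss_ramp, dvdt_threshold),
    r_in_mohm = pas$r_in_mohm,
    c_m_pf = pas$c_m_pf,
    rmp_mv = pas$rmp_mv,
    max_rate_hz = sec$max_rate_hz,
    accommodation = sec$accommodation,
    inactivation_threshold_pa = inact,
    soma_volume_um3 = if (pas$c_m_pf > 0) predict_soma_volume(pas$c_m_pf)
                      else NA_real_)
}
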