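# Independent oracles used across tests. These re-derive expected values
# by brute force or closed form, independently of the implementation path
# they check.

# Exhaustive minimum-inertia 2-partition of a small point set.
brute_force_kmeans2 <- function(x) {
  n <- nrow(x)
  best <- NULL; best_inertia <- Inf
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; skip empty
    grp <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    inertia <- 0
    for (g in 1:2) {
      pts <- x[grp == g, , drop = FALSE]
      if (nrow(pts) == 0) { inertia <- Inf; break }
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    if (inertia < best_inertia) { best_inertia <- inertia; best <- grp }
  }
  list(cluster = best, inertia = best_inertia)
}

# Sample-wise threshold-scan event finder: runs above `boundary` that
# contain a sample above `thr`, with duration gates. Mirrors the detector
# contract via an independent explicit loop.
scan_events <- function(x, fs, thr, boundary, min_ms, max_ms) {
  above_b <- abs(x) > boundary
  events <- list()
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (above_b[i]) {
      j <- i
      while (j < n && above_b[j + 1L]) j <- j + 1L
      dur <- (j - i + 1L) / fs * 1000
      if (any(abs(x[i:j]) > thr) && dur >= min_ms && dur <= max_ms)
        events[[length(events) + 1L]] <- c(onset = (i - 1L) / fs, dur = dur)
      i <- j + 1L
    } else i <- i + 1L
  }
  events
}

# Closed-form LIF steady firing rate for a constant current step:
# inter-spike interval = refractory + time from reset to threshold.
lif_rate <- function(i_pa, r_mohm, c_pf, v_rest, v_reset, v_thresh,
                     refr_s) {
  drive <- i_pa * r_mohm * 1e-3 # mV above rest
  dv_th <- v_thresh - v_rest
  dv_re <- v_reset - v_rest
  if (drive <= dv_th) return(0)
  tau <- r_mohm * c_pf * 1e-6
  1 / (refr_s + tau * log((drive - dv_re) / (drive - dv_th)))
}

# Fine-grid Euler integration of the LIF under a current ramp; returns
# the first threshold-crossing time (s) from ramp onset.
lif_ramp_first_crossing <- function(peak_pa, dur_s, r_mohm, c_pf,
                                    v_rest, v_thresh, dt = 1e-5) {
  tau <- r_mohm * c_pf * 1e-6
  v <- v_rest
  nn <- round(dur_s / dt)
  for (i in seq_len(nn)) {
    ii <- peak_pa * i / nn
    v <- v + dt * (-(v - v_rest) + ii * r_mohm * 1e-3) / tau
    if (v >= v_thresh) return(i * dt)
  }
  NA_real_
}

canonical_features <- c("gain", "r_in_mohm", "rheobase_pa",
                        "spike_latency_ms", "c_m_pf")

# Two archetype blobs on the canonical features (helper for clustering
# tests); returns matrix plus archetype membership.
make_blobs <- function(n_hyper, n_normal, sep, seed) {
  set.seed(seed)
  signs <- c(1, 1, -1, -1, -1)
  gen <- function(n, ctr) matrix(rnorm(n * 5), n, 5) +
    matrix(rep(ctr, each = n), n, 5)
  x <- rbind(gen(n_hyper, signs * sep / 2), gen(n_normal, -signs * sep / 2))
  colnames(x) <- canonical_features
  list(x = x, hyper = rep(c(TRUE, FALSE), c(n_hyper, n_normal)))
}
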