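# Study-condition benchmarks: seeded end-to-end exercises of each stage on
# synthetic data with known ground truth. These drive both the test suite
# and the reproduction script, so the numbers they return are always
# recomputed from scratch.

#' Interictal-spike detector benchmark
#'
#' Simulates seeded LFP traces carrying one event of each configured width
#' at a fixed amplitude, runs the detection chain (baseline estimate on
#' the raw trace, 2-ms Gaussian smoothing, 5-s.d. detection with the
#' 10-100 ms duration gate) and scores recall and precision against the
#' in-gate widths and the count of detections attributable to out-of-gate
#' widths.
#'
#' @param n_traces Number of traces.
#' @param duration_s,fs_hz Trace geometry.
#' @param widths_ms Injected event widths; widths outside (min_ms, max_ms)
#'   are the out-of-gate probes.
#' @param amplitude_sd Event amplitude in baseline s.d. units.
#' @param noise_sd Noise s.d., uV.
#' @param threshold_sd,min_ms,max_ms Detector settings.
#' @param seed Integer seed.
#' @return List with `recall`, `precision`, `out_of_gate_detections`,
#'   `n_traces`, `per_width` table.
#' @export
iis_detection_benchmark <- function(n_traces = 200, duration_s = 60,
                                    fs_hz = 5000,
                                    widths_ms = c(5, 20, 50, 150),
                                    amplitude_sd = 8, noise_sd = 10,
                                    threshold_sd = 5, min_ms = 10,
                                    max_ms = 100, seed = 1L) {
  in_gate <- widths_ms > min_ms & widths_ms < max_ms
  tp <- 0L; fn <- 0L; fp <- 0L; out_hits <- 0L
  width_hits <- setNames(integer(length(widths_ms)), widths_ms)
  for (tr in seq_len(n_traces)) {
    gap <- duration_s / (length(widths_ms) + 1)
    onsets <- gap * seq_along(widths_ms)
    ev <- data.frame(onset_s = onsets, amplitude_sd = amplitude_sd,
                     width_ms = widths_ms,
                     polarity = rep_len(c("+", "-"), length(widths_ms)))
    rec <- simulate_lfp(lfp_sim_config(duration_s, fs_hz, noise_sd,
                                       events = ev,
                                       seed = derive_seed(seed, tr)))
    bsd <- estimate_baseline_sd(rec)
    sm <- preprocess_lfp(rec, target_fs = fs_hz, hp_cutoff = NULL,
                         smooth_ms = 2)
    det <- detect_iis(sm, bsd, threshold_sd, min_ms, max_ms)
    matched <- rep(FALSE, nrow(det))
    for (j in seq_along(onsets)) {
      hit <- which(!matched &
                   det$onset_s > onsets[j] - 0.02 &
                   det$onset_s < onsets[j] + widths_ms[j] / 1000)
      if (length(hit)) {
        matched[hit[1]] <- TRUE
        width_hits[j] <- width_hits[j] + 1L
        if (in_gate[j]) tp <- tp + 1L else out_hits <- out_hits + 1L
      } else if (in_gate[j]) fn <- fn + 1L
    }
    fp <- fp + sum(!matched)
  }
  n_in <- n_traces * sum(in_gate)
  list(recall = tp / n_in,
       precision = if (tp + fp + out_hits == 0) NA_real_
                   else tp / (tp + fp + out_hits),
       out_of_gate_detections = out_hits + fp,
       n_traces = n_traces,
       per_width = data.frame(width_ms = widths_ms, in_gate = in_gate,
                              detected = as.integer(width_hits)))
}

#' Morpho-electric parameter recovery benchmark
#'
#' Simulates a family of LIF neurons with known passive properties, runs
#' the feature-extraction chain and reports worst-case relative errors of
#' `R_in` and `C_m`, the rheobase offset in protocol steps, and the
#' monotonicity of the fitted gain across a fixed-time-constant family
#' (where capacitance trades off against resistance, mirroring the
#' inverse C_m-R_in relation seen in recordings).
#'
#' @param n_neurons Neurons in the recovery family.
#' @param noise_sd Recording noise, mV (0 = noise-free).
#' @param seed Integer seed.
#' @return List with `r_in_err_max`, `c_m_err_max` (relative),
#'   `rheobase_step_offset_max`, `gain_by_r_in`, `gain_monotone`,
#'   `cm_rin_cor` (fixed-tau family).
#' @export
lif_recovery_benchmark <- function(n_neurons = 50, noise_sd = 0, seed = 1L) {
  proto <- step_protocol(start_pa = 20, increment_pa = 20, n_steps = 12,
                         hyper_pa = -60, n_hyper = 4)
  draws <- with_seed(derive_seed(seed, 0), {
    data.frame(r = runif(n_neurons, 120, 300),
               cm = runif(n_neurons, 80, 200))
  })
  errs <- t(vapply(seq_len(n_neurons), function(i) {
    np <- neuron_params(r_in = draws$r[i], c_m = draws$cm[i],
                        v_rest = -70, v_thresh = -50, noise_sd = noise_sd,
                        seed = derive_seed(seed, i))
    ss <- simulate_current_clamp(np, proto)
    pas <- compute_passive(ss)
    ifc <- build_if_curve(ss)
    rb <- compute_rheobase(ifc)
    c(abs(pas$r_in_mohm - draws$r[i]) / draws$r[i],
      abs(pas$c_m_pf - draws$cm[i]) / draws$cm[i],
      abs(rb - 20000 / draws$r[i]) / proto$increment_pa)
  }, numeric(3)))
  # fixed-tau family: C_m = tau / R_in, so gain grows with R_in
  rs <- seq(120, 280, length.out = 6)
  tau_us <- 24000
  fam <- vapply(rs, function(r) {
    np <- neuron_params(r_in = r, c_m = tau_us / r, v_rest = -70,
                        v_thresh = -50)
    feats <- simulate_current_clamp(np, proto)
    pas <- compute_passive(feats)
    c(gain = compute_gain(build_if_curve(feats)),
      r_in = pas$r_in_mohm, c_m = pas$c_m_pf)
  }, numeric(3))
  list(r_in_err_max = max(errs[, 1]),
       c_m_err_max = max(errs[, 2]),
       rheobase_step_offset_max = max(errs[, 3]),
       gain_by_r_in = data.frame(r_in = rs, gain = fam["gain", ]),
       gain_monotone = all(diff(fam["gain", ]) > 0),
       cm_rin_cor = cor(fam["r_in", ], fam["c_m", ]))
}

# Feature matrix of two Gaussian archetypes on the five canonical
# features; `sep_sd` is the centroid separation per feature in noise-sd
# units. labels: TRUE = hyperexcitable archetype.
archetype_features <- function(n_hyper, n_normal, sep_sd = 10) {
  signs <- c(gain = 1, r_in_mohm = 1, rheobase_pa = -1,
             spike_latency_ms = -1, c_m_pf = -1)
  gen <- function(n, centre) {
    m <- matrix(rnorm(n * 5), n, 5)
    m + matrix(rep(centre, each = n), n, 5)
  }
  x <- rbind(gen(n_hyper, signs * sep_sd / 2),
             gen(n_normal, -signs * sep_sd / 2))
  colnames(x) <- names(signs)
  list(x = x, hyper = c(rep(TRUE, n_hyper), rep(FALSE, n_normal)))
}

#' Clustering stability benchmark
#'
#' Runs the bootstrap-validated k-means on (a) two well-separated
#' archetype blobs and (b) a single isotropic blob forced to k = 2,
#' returning the retention diagnostics for both.
#'
#' @param n_per_blob Cells per archetype.
#' @param sep_sd Archetype separation per feature, in s.d. units.
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return List with `two_blob` and `one_blob` results from
#'   [bootstrap_stability()].
#' @export
clustering_stability_benchmark <- function(n_per_blob = 50, sep_sd = 10,
                                           n_iter = 1000, seed = 1L) {
  two <- with_seed(derive_seed(seed, 0),
                   archetype_features(n_per_blob, n_per_blob, sep_sd))
  z2 <- zscore_features(two$x)
  b2 <- bootstrap_stability(z2, 2, n_iter = n_iter,
                            seed = derive_seed(seed, 1))
  one_x <- with_seed(derive_seed(seed, 2), {
    m <- matrix(rnorm(2 * n_per_blob * 5), 2 * n_per_blob, 5)
    colnames(m) <- colnames(two$x)
    m
  })
  b1 <- bootstrap_stability(zscore_features(one_x), 2, n_iter = n_iter,
                            seed = derive_seed(seed, 3))
  list(two_blob = b2, one_blob = b1)
}

#' Membership-residual enrichment power benchmark
#'
#' Simulates cohorts in which one genotype draws 70% of its neurons from
#' the hyperexcitable archetype and the other 30% (at both ages), fits the
#' clustering, computes membership residuals and tests the genotype effect
#' with the two-way ANOVA. Returns the fraction of replicates with a
#' significant genotype effect (power).
#'
#' @param n_reps Replicates.
#' @param n_per_group Cells per genotype x age group.
#' @param sep_sd Archetype separation per feature (s.d. units); 2 gives
#'   visibly overlapping clusters.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return List with `power`, `n_reps`, `n_per_group`.
#' @export
enrichment_power_benchmark <- function(n_reps = 100, n_per_group = 25,
                                       sep_sd = 2, alpha = 0.05,
                                       seed = 1L) {
  hits <- 0L
  for (r in seq_len(n_reps)) {
    sim <- with_seed(derive_seed(seed, r), {
      grp <- expand.grid(genotype = c("E3", "E4"), age = c("young", "aged"))
      xs <- list(); hyper <- list()
      for (g in seq_len(nrow(grp))) {
        p_hyper <- if (grp$genotype[g] == "E4") 0.7 else 0.3
        nh <- rbinom(1, n_per_group, p_hyper)
        af <- archetype_features(nh, n_per_group - nh, sep_sd)
        xs[[g]] <- af$x
      }
      list(x = do.call(rbind, xs),
           genotype = rep(grp$genotype, each = n_per_group),
           age = rep(grp$age, each = n_per_group))
    })
    z <- zscore_features(sim$x)
    model <- label_clusters(fit_kmeans(z, 2, seed = derive_seed(seed, r)))
    mem <- membership_residuals(model, z)
    res <- compare_residuals(mem$residual, sim$genotype, sim$age)
    p_gen <- res$anova$p[res$anova$term == "genotype"]
    if (is.finite(p_gen) && p_gen < alpha) hits <- hits + 1L
  }
  list(power = hits / n_reps, n_reps = n_reps, n_per_group = n_per_group)
}

#' Statistical-framework calibration benchmark
#'
#' Monte-Carlo calibration of the inferential core: type-I error of the
#' age-genotype likelihood-ratio test on a null 2x2 design, and
#' Kolmogorov-Smirnov uniformity of the two-sided Pearson null p-value.
#'
#' @param n_reps_lrt LRT null replicates.
#' @param n_per_cell Observations per design cell.
#' @param n_reps_corr Pearson null replicates.
#' @param n_corr Sample size per correlation replicate.
#' @param seed Integer seed.
#' @return List with `lrt_type1`, `pearson_ks_p`.
#' @export
stats_calibration_benchmark <- function(n_reps_lrt = 1000, n_per_cell = 15,
                                        n_reps_corr = 2000, n_corr = 10,
                                        seed = 1L) {
  lrt_rej <- with_seed(derive_seed(seed, 0), {
    genotype <- rep(c("E3", "E4"), each = 2 * n_per_cell)
    age <- rep(rep(c("young", "aged"), each = n_per_cell), 2)
    mean(vapply(seq_len(n_reps_lrt), function(i) {
      lrt_age_genotype(rnorm(length(genotype)), genotype, age)$p < 0.05
    }, logical(1)))
  })
  pear_p <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_reps_corr), function(i)
      pearson_corr(rnorm(n_corr), rnorm(n_corr))$p, numeric(1))
  })
  ks <- stats::ks.test(pear_p, "punif")
  list(lrt_type1 = lrt_rej, pearson_ks_p = ks$p.value)
}

#' Planted-pattern configuration for the candidate-gene filter study
#'
#' Eight genes realise the pass/fail patterns of the six selection
#' criteria: two full candidates (one up-, one down-regulated), and one
#' failure at each individual criterion (no 10-month effect; aberrant
#' fE4/Syn1-Cre effect; persistent 20-month effect; no APOE-high effect;
#' no ageing effect; inconsistent direction). Planted fold changes are
#' 0.8 in natural log.
#'
#' @param n_genes Background genes.
#' @param cells_per_group Cells per genotype x age group.
#' @param seed Integer seed.
#' @return A [synth_count_config()] whose `true_candidates` attribute
#'   holds the genes that must survive the filter.
#' @export
candidate_study_config <- function(n_genes = 300, cells_per_group = 1200,
                                   seed = 1L) {
  pl <- function(g, cs, l) data.frame(gene = g, contrast = cs, lfc = l,
                                      stringsAsFactors = FALSE)
  cand <- c("e4_vs_e3_5mo", "e4_vs_e3_10mo", "apoehigh_e4_vs_e3_10mo",
            "e3_20mo_vs_e3_5mo")
  planted <- rbind(
    pl("g0001", cand, 0.8),
    pl("g0002", cand, -0.8),
    pl("g0003", "e4_vs_e3_5mo", 0.8),
    pl("g0004", c(cand, "fe4_vs_e3_5mo"), 0.8),
    pl("g0005", c(cand, "e4_vs_e3_20mo"), 0.8),
    pl("g0006", setdiff(cand, "apoehigh_e4_vs_e3_10mo"), 0.8),
    pl("g0007", setdiff(cand, "e3_20mo_vs_e3_5mo"), 0.8),
    rbind(pl("g0008", "e4_vs_e3_5mo", 0.8),
          pl("g0008", setdiff(cand, "e4_vs_e3_5mo"), -0.8)))
  cfg <- synth_count_config(
    n_genes = n_genes, cells_per_group = cells_per_group, base_mean = 15,
    dispersion = 0.05, libsize_sdlog = 0.2, apoe_high_frac = 0.05,
    apoe_high_mult = 100, planted = planted, seed = seed)
  attr(cfg, "true_candidates") <- c("g0001", "g0002")
  cfg
}

#' Candidate-gene filter recovery benchmark
#'
#' Simulates the [candidate_study_config()] design, runs QC-free
#' normalisation, the seven study DE contrasts and the six-criterion
#' filter, and compares the candidate set with the planted truth.
#'
#' @param seed Integer seed.
#' @param config Optional pre-built configuration.
#' @return List with `candidates`, `true_candidates`, `exact_match`,
#'   `successive_counts`, `counts_nonincreasing`, `report`.
#' @export
candidate_recovery_benchmark <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- candidate_study_config(seed = seed)
  sim <- simulate_counts(config)
  norm <- lognormalize(sim$counts)
  tabs <- study_de_tables(norm, sim$meta, apoe_gene = config$apoe_gene)
  report <- multilevel_filter(tabs)
  truth <- attr(config, "true_candidates")
  list(candidates = report$candidates,
       true_candidates = truth,
       exact_match = setequal(report$candidates, truth),
       successive_counts = report$successive_counts,
       counts_nonincreasing = all(diff(report$successive_counts) <= 0),
       report = report)
}

#' Synaptic event detection benchmark
#'
#' Poisson event trains at signal-to-noise ratio `snr` with inter-event
#' structure left to chance; reports recall of true onsets (within 5 ms)
#' by the sliding-template detector.
#'
#' @param n_traces Traces.
#' @param duration_s Trace length.
#' @param rate_hz Event rate.
#' @param snr Amplitude / noise-sd ratio.
#' @param seed Integer seed.
#' @return List with `recall`, `n_events`.
#' @export
synaptic_detection_benchmark <- function(n_traces = 5, duration_s = 120,
                                         rate_hz = 1, snr = 5, seed = 1L) {
  tp <- 0L; n_true <- 0L
  for (tr in seq_len(n_traces)) {
    cfg <- synaptic_sim_config(rate_hz = rate_hz, amp_mean_pa = 20,
                               amp_sd_pa = 2, noise_sd_pa = 20 / snr,
                               duration_s = duration_s,
                               seed = derive_seed(seed, tr))
    trc <- simulate_synaptic_trace(cfg)
    det <- detect_events(trc)
    n_true <- n_true + nrow(trc$truth)
    tp <- tp + sum(vapply(trc$truth$onset_s, function(o)
      any(abs(det$onset_s - o) < 0.005), logical(1)))
  }
  list(recall = tp / n_true, n_events = n_true)
}
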