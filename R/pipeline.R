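pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "hippex_run",
    stages = c("lfp"),
    lfp = list(n_per_genotype = 4, duration_s = 60, fs_hz = 1000,
               noise_sd = 10, rate_per_min = c(E3 = 1, E4 = 4),
               amplitude_sd = 8, width_ms = 30, threshold_sd = 5,
               min_ms = 10, max_ms = 100),
    ephys = list(n_per_group = 12,
                 r_in_mohm = c(E3 = 160, E4 = 220), r_in_sd = 20,
                 c_m_pf = c(E3 = 140, E4 = 100), c_m_sd = 15,
                 delta_v = 20, step_start_pa = 50, step_increment_pa = 50,
                 n_steps = 8, noise_sd = 0),
    clustering = list(k = 2, n_iter = 200),
    counts = list(n_genes = 120, cells_per_group = 400,
                  planted_gene = "g0001", planted_lfc = 1,
                  target_cluster = "C1"))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

#' Run the end-to-end synthetic study pipeline
#'
#' Chains the package stages on synthetic data with known ground truth:
#' an LFP cohort (genotype-specific interictal-spike rates, detection,
#' per-mouse rate table), a morpho-electric cohort (LIF neurons per
#' genotype, feature extraction), excitability clustering with membership
#' residuals, and a count matrix pushed through the six-criterion
#' candidate-gene filter. All outputs are tidy TSV/JSON files under
#' `out_dir`, together with a resolved-configuration snapshot and a run
#' log; all randomness flows from the single `seed`.
#'
#' @param config Named list overriding any subset of the defaults
#'   (unknown keys are rejected), or the path to a YAML file with the same
#'   structure.
#' @return Invisibly, a list with per-stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  bad <- setdiff(cfg$stages, c("lfp", "ephys", "clustering", "counts"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("clustering" %in% cfg$stages && !"ephys" %in% cfg$stages)
    stop("stage 'clustering' requires upstream stage 'ephys'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log <- c(sprintf("hippex %s", as.character(utils::packageVersion("hippex"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  results <- list()

  if ("lfp" %in% cfg$stages) {
    p <- cfg$lfp
    rows <- list()
    stream <- 0L
    for (gt in names(p$rate_per_min)) {
      for (m in seq_len(p$n_per_genotype)) {
        stream <- stream + 1L
        n_ev <- round(p$rate_per_min[[gt]] * p$duration_s / 60)
        onsets <- if (n_ev > 0)
          seq(1, p$duration_s - 1, length.out = n_ev) else numeric(0)
        ev <- data.frame(onset_s = onsets,
                         amplitude_sd = rep(p$amplitude_sd, n_ev),
                         width_ms = rep(p$width_ms, n_ev),
                         polarity = rep("+", n_ev))
        rec <- simulate_lfp(lfp_sim_config(
          p$duration_s, p$fs_hz, p$noise_sd, events = ev,
          seed = derive_seed(cfg$seed, stream)))
        bsd <- estimate_baseline_sd(rec)
        sm <- preprocess_lfp(rec, hp_cutoff = NULL, smooth_ms = 2)
        det <- detect_iis(sm, bsd, p$threshold_sd, p$min_ms, p$max_ms)
        rate <- iis_rate(det, rec$activity_mask %||% rep(TRUE, nrow(rec$samples)),
                         rec$fs_hz)
        rows[[stream]] <- data.frame(genotype = gt, mouse = m,
                                     n_events = rate$n_events,
                                     rate_per_min = rate$rate_per_min)
      }
    }
    rates <- do.call(rbind, rows)
    write_tabular(rates, file.path(cfg$out_dir, "iis_rates.tsv"))
    results$lfp <- rates
    log <- c(log, sprintf("lfp: %d recordings, rates written", nrow(rates)))
  }

  if ("ephys" %in% cfg$stages) {
    p <- cfg$ephys
    rows <- list(); stream <- 1000L
    for (gt in names(p$r_in_mohm)) {
      for (i in seq_len(p$n_per_group)) {
        stream <- stream + 1L
        draws <- with_seed(derive_seed(cfg$seed, stream), {
          c(r = rnorm(1, p$r_in_mohm[[gt]], p$r_in_sd),
            c = rnorm(1, p$c_m_pf[[gt]], p$c_m_sd))
        })
        np <- neuron_params(r_in = max(draws[["r"]], 50),
                            c_m = max(draws[["c"]], 40),
                            v_rest = -70, v_thresh = -70 + p$delta_v,
                            noise_sd = p$noise_sd,
                            seed = derive_seed(cfg$seed, stream + 1L))
        ss <- simulate_current_clamp(np, step_protocol(
          p$step_start_pa, p$step_increment_pa, p$n_steps))
        ramp <- simulate_current_clamp(np, ramp_protocol())
        feats <- extract_features(ss, ramp)
        feats$genotype <- gt; feats$cell <- sprintf("%s_%02d", gt, i)
        rows[[length(rows) + 1L]] <- feats
      }
    }
    features <- do.call(rbind, rows)
    write_tabular(features, file.path(cfg$out_dir, "features.tsv"))
    results$ephys <- features
    log <- c(log, sprintf("ephys: %d neurons featurised", nrow(features)))
  }

  if ("clustering" %in% cfg$stages) {
    feats <- results$ephys
    fm <- feats[, c("gain", "rheobase_pa", "spike_latency_ms",
                    "c_m_pf", "r_in_mohm")]
    ok <- complete.cases(fm)
    z <- zscore_features(fm[ok, ])
    model <- label_clusters(fit_kmeans(z, cfg$clustering$k,
                                       seed = derive_seed(cfg$seed, 2000)))
    boot <- bootstrap_stability(z, cfg$clustering$k,
                                n_iter = cfg$clustering$n_iter,
                                seed = derive_seed(cfg$seed, 2001))
    mem <- membership_residuals(model, z)
    mem$cell <- feats$cell[ok]
    mem$retention_p <- boot$retention_p
    write_tabular(mem, file.path(cfg$out_dir, "membership.tsv"))
    jsonlite::write_json(
      list(centroids = as.data.frame(model$centers),
           labels = unname(model$labels), stable = boot$stable,
           mean_retention = boot$mean_retention),
      file.path(cfg$out_dir, "cluster_model.json"),
      auto_unbox = TRUE, digits = NA)
    results$clustering <- list(model = model, boot = boot, membership = mem)
    log <- c(log, sprintf("clustering: mean retention %.3f (%s)",
                          boot$mean_retention,
                          if (boot$stable) "stable" else "unstable"))
  }

  if ("counts" %in% cfg$stages) {
    p <- cfg$counts
    planted <- data.frame(
      gene = p$planted_gene,
      contrast = c("e4_vs_e3_5mo", "e4_vs_e3_10mo", "apoehigh_e4_vs_e3_10mo",
                   "e3_20mo_vs_e3_5mo"),
      lfc = p$planted_lfc)
    sim <- simulate_counts(synth_count_config(
      n_genes = p$n_genes, cells_per_group = p$cells_per_group,
      base_mean = 15, dispersion = 0.1, apoe_high_frac = 0.1,
      apoe_high_mult = 100, planted = planted,
      cluster_id = p$target_cluster,
      seed = derive_seed(cfg$seed, 3000)))
    qc <- qc_filter(sim$counts, sim$meta, gene_lo = 0, gene_hi = Inf,
                    umi_lo = 0, umi_hi = Inf, mito_max = 0.01)
    norm <- lognormalize(qc$counts)
    tabs <- study_de_tables(norm, qc$meta, cluster = p$target_cluster)
    report <- multilevel_filter(tabs)
    jsonlite::write_json(
      list(candidates = report$candidates,
           successive_counts = as.list(report$successive_counts)),
      file.path(cfg$out_dir, "candidates.json"),
      auto_unbox = TRUE, digits = NA)
    write_tabular(report$flags, file.path(cfg$out_dir, "candidate_flags.tsv"))
    results$counts <- report
    log <- c(log, sprintf("counts: %d candidate(s): %s",
                          length(report$candidates),
                          paste(report$candidates, collapse = ", ")))
  }

  writeLines(log, file.path(cfg$out_dir, "run.log"))
  invisible(results)
}
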