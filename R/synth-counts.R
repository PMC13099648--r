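#' Canonical differential-expression contrasts of the study design
#'
#' The six-criterion candidate-gene filter consumes DE tables for these
#' named contrasts: APOE4 vs APOE3 knock-in at 5, 10 and 20 months, the
#' APOE-high-cell contrast at 10 months, the neuronal-APOE4-deletion
#' (fE4/Syn1-Cre+) contrasts at 5 and 10 months, and APOE3 ageing
#' (20 vs 5 months).
#'
#' @return Character vector of contrast identifiers.
#' @export
study_contrasts <- function() {
  c("e4_vs_e3_5mo", "e4_vs_e3_10mo", "apoehigh_e4_vs_e3_10mo",
    "fe4_vs_e3_5mo", "fe4_vs_e3_10mo", "e4_vs_e3_20mo", "e3_20mo_vs_e3_5mo")
}

#' Configuration for a synthetic single-nucleus count matrix
#'
#' Simulates negative-binomial UMI counts (mean/dispersion parameterisation,
#' log-normal library-size variation) for a hippocampal snRNA-seq study
#' design: genotypes E3, E4 and fE4 (neuronal APOE4 deletion; 5 and 10
#' months only) at the configured ages. A designated fraction of cells per
#' group forms an APOE-expression-high subpopulation in which the APOE-like
#' gene is drawn at `apoe_high_mult` times its baseline mean.
#'
#' Planted differential expression is specified per contrast
#' (see [study_contrasts()]) and translated into multiplicative group-mean
#' effects: the 5-/10-/20-month E4-vs-E3 fold changes multiply the E4 group
#' mean at that age; the fE4 fold changes multiply the fE4 groups; the
#' ageing fold change multiplies both 20-month genotypes (so the 20-month
#' E4-vs-E3 contrast stays clean); and the APOE-high fold change replaces
#' the 10-month E4 effect within the high subpopulation.
#'
#' @param n_genes Number of background genes (gene ids `g0001`, ...); the
#'   APOE-like gene is appended.
#' @param cells_per_group Cells per (genotype, age) group; scalar or a
#'   function of no arguments returning one draw.
#' @param ages Ages (months) for E3/E4; fE4 is restricted to 5 and 10.
#' @param base_mean Median baseline mean count per gene (gene means are
#'   log-normal around this with `sdlog = 1`).
#' @param dispersion NB dispersion: `var = mu + dispersion * mu^2`.
#' @param libsize_sdlog Log-normal s.d. of per-cell library-size factors.
#' @param planted `data.frame(gene, contrast, lfc)` of planted natural-log
#'   fold changes; contrasts must come from [study_contrasts()].
#' @param apoe_gene Name of the APOE-like gene.
#' @param apoe_base_mean Baseline mean count of the APOE-like gene.
#' @param apoe_high_frac Fraction of cells in the high subpopulation.
#' @param apoe_high_mult Fold elevation of the APOE-like gene in that
#'   subpopulation.
#' @param mito_mean Mean mitochondrial read fraction (Beta-distributed).
#' @param cluster_id Cluster label written to the metadata.
#' @param seed Integer seed.
#' @return An object of class `synth_count_config`.
#' @export
synth_count_config <- function(n_genes = 200, cells_per_group = 150,
                               ages = c(5, 10, 20), base_mean = 2,
                               dispersion = 0.5, libsize_sdlog = 0.25,
                               planted = NULL, apoe_gene = "Apoe",
                               apoe_base_mean = 3, apoe_high_frac = 0.08,
                               apoe_high_mult = 50, mito_mean = 0.001,
                               cluster_id = "C1", seed = 1L) {
  assert_number(n_genes, "n_genes", positive = TRUE)
  assert_number(base_mean, "base_mean", positive = TRUE)
  assert_number(dispersion, "dispersion", nonneg = TRUE)
  assert_number(apoe_high_frac, "apoe_high_frac", nonneg = TRUE)
  if (apoe_high_frac >= 1) stop("apoe_high_frac must be < 1")
  genes <- c(sprintf("g%04d", seq_len(n_genes)), apoe_gene)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (!all(c("gene", "contrast", "lfc") %in% names(planted)))
      stop("`planted` needs columns gene, contrast, lfc")
    bad <- setdiff(planted$contrast, study_contrasts())
    if (length(bad))
      stop("unknown contrast(s) in `planted`: ", paste(bad, collapse = ", "))
    miss <- setdiff(planted$gene, genes)
    if (length(miss))
      stop("planted gene(s) not in gene list: ", paste(miss, collapse = ", "))
  }
  structure(list(n_genes = n_genes, genes = genes,
                 cells_per_group = cells_per_group, ages = ages,
                 base_mean = base_mean, dispersion = dispersion,
                 libsize_sdlog = libsize_sdlog, planted = planted,
                 apoe_gene = apoe_gene, apoe_base_mean = apoe_base_mean,
                 apoe_high_frac = apoe_high_frac,
                 apoe_high_mult = apoe_high_mult, mito_mean = mito_mean,
                 cluster_id = cluster_id, seed = seed),
            class = "synth_count_config")
}

#' Simulate single-nucleus UMI counts with planted effects
#'
#' @param config A [synth_count_config()].
#' @return List with `counts` (sparse genes x cells `dgCMatrix`), `genes`,
#'   `barcodes` and `meta` (`data.frame` with `barcode`, `genotype`,
#'   `age_months`, `cluster_id`, `apoe_high_true`, `mito_fraction`,
#'   `n_umi`, `n_genes_detected`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "synth_count_config"))
  genos <- list(E3 = config$ages, E4 = config$ages,
                fE4 = intersect(config$ages, c(5, 10)))
  groups <- do.call(rbind, lapply(names(genos), function(g)
    if (length(genos[[g]]))
      data.frame(genotype = g, age_months = genos[[g]],
                 stringsAsFactors = FALSE)))
  n_genes_tot <- length(config$genes)
  with_seed(config$seed, {
    base <- rlnorm(config$n_genes, log(config$base_mean), 1)
    base <- c(base, config$apoe_base_mean)
    names(base) <- config$genes
    # planted genes sit at the configured baseline mean so their
    # ground-truth detectability is controlled, not a lottery
    if (!is.null(config$planted))
      base[unique(config$planted$gene)] <- config$base_mean

    meta_list <- list(); blocks <- list()
    for (gi in seq_len(nrow(groups))) {
      gt <- groups$genotype[gi]; age <- groups$age_months[gi]
      nc <- if (is.function(config$cells_per_group)) config$cells_per_group()
            else config$cells_per_group
      high <- runif(nc) < config$apoe_high_frac

      mult <- rep(1, n_genes_tot); names(mult) <- config$genes
      mult_high <- NULL
      pl <- config$planted
      if (!is.null(pl) && nrow(pl)) {
        eff <- function(contrast) pl[pl$contrast == contrast, , drop = FALSE]
        apply_lfc <- function(m, tab) {
          if (nrow(tab)) m[tab$gene] <- m[tab$gene] * exp(tab$lfc)
          m
        }
        if (gt == "E4" && age == 5) mult <- apply_lfc(mult, eff("e4_vs_e3_5mo"))
        if (gt == "E4" && age == 10) {
          mult <- apply_lfc(mult, eff("e4_vs_e3_10mo"))
          # the high subpopulation realises the APOE-high contrast instead
          # of the bulk 10-month effect (unspecified contrast = null effect)
          mult_high <- rep(1, n_genes_tot); names(mult_high) <- config$genes
          mult_high <- apply_lfc(mult_high, eff("apoehigh_e4_vs_e3_10mo"))
        }
        if (gt == "E4" && age == 20) {
          mult <- apply_lfc(mult, eff("e4_vs_e3_20mo"))
          mult <- apply_lfc(mult, eff("e3_20mo_vs_e3_5mo"))
        }
        if (gt == "E3" && age == 20) mult <- apply_lfc(mult, eff("e3_20mo_vs_e3_5mo"))
        if (gt == "fE4") mult <- apply_lfc(mult, eff(paste0("fe4_vs_e3_", age, "mo")))
      }

      libf <- rlnorm(nc, 0, config$libsize_sdlog)
      mu <- outer(base * mult, libf)
      if (!is.null(mult_high) && any(high)) {
        mu_h <- outer(base * mult_high, libf[high])
        mu[, high] <- mu_h
      }
      mu[config$apoe_gene, high] <- mu[config$apoe_gene, high] * config$apoe_high_mult
      size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = size),
                    nrow = n_genes_tot)
      blocks[[gi]] <- cnt
      mito_m <- config$mito_mean
      meta_list[[gi]] <- data.frame(
        genotype = gt, age_months = age, cluster_id = config$cluster_id,
        apoe_high_true = high,
        mito_fraction = rbeta(nc, 2, 2 * (1 - mito_m) / mito_m),
        stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, blocks)
    meta <- do.call(rbind, meta_list)
    meta$barcode <- sprintf("cell%05d", seq_len(nrow(meta)))
    rownames(meta) <- meta$barcode
    meta$n_umi <- colSums(counts)
    meta$n_genes_detected <- colSums(counts > 0)
    meta <- meta[, c("barcode", "genotype", "age_months", "cluster_id",
                     "apoe_high_true", "mito_fraction", "n_umi",
                     "n_genes_detected")]
    dimnames(counts) <- list(config$genes, meta$barcode)
    list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "CsparseMatrix"), "generalMatrix"),
         genes = config$genes, barcodes = meta$barcode, meta = meta)
  })
}
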