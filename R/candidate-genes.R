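#' Quality-control filtering of cells
#'
#' Retains cells with `gene_lo`-`gene_hi` detected genes (inclusive),
#' `umi_lo`-`umi_hi` total UMIs (inclusive) and a mitochondrial read
#' fraction strictly below `mito_max`.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param meta Cell metadata `data.frame` with `mito_fraction`; detected
#'   genes and UMI totals are computed from `counts` unless present as
#'   `n_genes_detected` / `n_umi`.
#' @param gene_lo,gene_hi Detected-gene bounds.
#' @param umi_lo,umi_hi UMI-count bounds.
#' @param mito_max Strict upper bound on mitochondrial fraction (0.0025 =
#'   0.25%).
#' @return List with filtered `counts` and `meta`.
#' @export
qc_filter <- function(counts, meta, gene_lo = 200, gene_hi = 2400,
                      umi_lo = 500, umi_hi = 4500, mito_max = 0.0025) {
  if (ncol(counts) != nrow(meta))
    stop("metadata rows must match count-matrix columns")
  n_genes <- meta$n_genes_detected %||% Matrix::colSums(counts > 0)
  n_umi <- meta$n_umi %||% Matrix::colSums(counts)
  keep <- n_genes >= gene_lo & n_genes <= gene_hi &
    n_umi >= umi_lo & n_umi <= umi_hi &
    meta$mito_fraction < mito_max
  if (!any(keep)) stop("all cells removed by QC filter")
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Log-normalise UMI counts
#'
#' Per-cell depth normalisation to `scale` counts followed by `log1p`:
#' `x -> ln(1 + scale * x / cell_total)`.
#'
#' @param counts Genes x cells count matrix.
#' @param scale Scale factor (default 10,000).
#' @return Normalised matrix (sparse if the input was sparse).
#' @export
lognormalize <- function(counts, scale = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cell(s) with zero total counts")
  if (inherits(counts, "sparseMatrix")) {
    norm <- counts %*% Matrix::Diagonal(x = scale / tot)
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(counts)
    norm
  } else {
    log1p(sweep(as.matrix(counts), 2, tot, "/") * scale)
  }
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' A gene enters testing only if it is detected in at least `min_pct` of
#' cells in either group and shows `|log_fc| >= logfc_min`, where the fold
#' change is computed on back-transformed group means with a pseudocount:
#' `log(mean(expm1(A)) + 1) - log(mean(expm1(B)) + 1)` (natural log by
#' default; set `logfc_base = 2` for log2). Raw p-values come from the
#' rank-sum test on normalised expression; BH-adjusted values are reported
#' alongside.
#'
#' @param norm Normalised genes x cells matrix (see [lognormalize()]).
#' @param cells_a,cells_b Column indices or names of the two groups.
#' @param min_pct Detection-fraction gate.
#' @param logfc_min Fold-change gate.
#' @param logfc_base Base of the reported log fold change.
#' @return `data.frame` per gene: `gene`, `log_fc`, `pct_1`, `pct_2`,
#'   `tested`, `p_raw`, `p_adj` (p is `NA` for untested genes).
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.1,
                        logfc_min = 0.05, logfc_base = exp(1)) {
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stop("empty cell group")
  pct1 <- Matrix::rowSums(a > 0) / ncol(a)
  pct2 <- Matrix::rowSums(b > 0) / ncol(b)
  mean_a <- Matrix::rowSums(expm1(as.matrix(a))) / ncol(a)
  mean_b <- Matrix::rowSums(expm1(as.matrix(b))) / ncol(b)
  log_fc <- (log(mean_a + 1) - log(mean_b + 1)) / log(logfc_base)
  tested <- (pct1 >= min_pct | pct2 >= min_pct) & abs(log_fc) >= logfc_min
  p_raw <- rep(NA_real_, nrow(norm))
  am <- as.matrix(a); bm <- as.matrix(b)
  for (g in which(tested)) {
    p_raw[g] <- suppressWarnings(
      wilcox.test(am[g, ], bm[g, ], exact = FALSE)$p.value)
  }
  p_adj <- rep(NA_real_, nrow(norm))
  p_adj[tested] <- p.adjust(p_raw[tested], method = "BH")
  data.frame(gene = rownames(norm) %||% as.character(seq_len(nrow(norm))),
             log_fc = log_fc, pct_1 = pct1, pct_2 = pct2,
             tested = tested, p_raw = p_raw, p_adj = p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positive marker genes per cluster (one-vs-rest)
#'
#' For every cluster, genes detected in at least `min_pct` of its cells
#' and expressed at least `logfc_min` log2-fold higher than in all other
#' cells, with a significant (BH-adjusted p < `alpha`) rank-sum test.
#' Singleton clusters are skipped with a warning.
#'
#' @param norm Normalised genes x cells matrix.
#' @param cluster_labels Cluster label per cell.
#' @param min_pct Detection gate inside the cluster.
#' @param logfc_min Positive log2 fold-change gate (default 0.25).
#' @param alpha Adjusted-p significance level.
#' @return Named list of marker gene character vectors, one per cluster.
#' @export
find_markers <- function(norm, cluster_labels, min_pct = 0.10,
                         logfc_min = 0.25, alpha = 0.05) {
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != ncol(norm))
    stop("one cluster label per cell required")
  cls <- sort(unique(cluster_labels))
  if (length(cls) < 2) stop("need at least 2 clusters")
  out <- list()
  for (cl in cls) {
    inc <- which(cluster_labels == cl)
    if (length(inc) < 2) {
      warning("singleton cluster ", cl, " skipped")
      out[[cl]] <- character(0)
      next
    }
    de <- wilcoxon_de(norm, inc, setdiff(seq_len(ncol(norm)), inc),
                      min_pct = min_pct, logfc_min = logfc_min,
                      logfc_base = 2)
    sig <- de$tested & de$log_fc > 0 & de$pct_1 >= min_pct &
      !is.na(de$p_adj) & de$p_adj < alpha
    out[[cl]] <- de$gene[sig]
  }
  out
}

#' Classify APOE-expression-high cells
#'
#' Within each cell type (cluster), a cell is APOE-high if its normalised
#' APOE expression exceeds the cell-type median by more than two sample
#' standard deviations (strict inequality). Cell types with fewer than 3
#' cells cannot support the estimate and are labelled not-high with a
#' warning.
#'
#' @param norm Normalised genes x cells matrix containing `apoe_gene`.
#' @param meta Cell metadata with `cluster_id`.
#' @param apoe_gene Row name of the APOE gene.
#' @return Logical vector per cell.
#' @export
classify_apoe_high <- function(norm, meta, apoe_gene = "Apoe") {
  if (!apoe_gene %in% rownames(norm))
    stop("gene ", apoe_gene, " not present")
  lev <- as.numeric(norm[apoe_gene, ])
  high <- logical(length(lev))
  for (cl in unique(meta$cluster_id)) {
    idx <- which(meta$cluster_id == cl)
    if (length(idx) < 3) {
      warning("cell type ", cl, " has < 3 cells; none labelled APOE-high")
      next
    }
    thr <- median(lev[idx]) + 2 * sd(lev[idx])
    high[idx] <- lev[idx] > thr
  }
  high
}

# A gene counts as differentially expressed in a contrast table when it
# passed the pct/log-fc gates and its raw p is below alpha.
.de_flag <- function(tab, alpha) {
  tab$tested & !is.na(tab$p_raw) & tab$p_raw < alpha
}

#' Six-criterion multilevel candidate-gene filter
#'
#' A gene is a candidate for a target cluster iff, with a consistent
#' direction of change across all positive criteria:
#' \enumerate{
#'   \item DE between E4 and E3 at 5 months;
#'   \item DE between E4 and E3 at 10 months, same direction;
#'   \item DE between APOE-high E4 and E3 cells at 10 months, same
#'     direction;
#'   \item NOT DE between fE4/Syn1-Cre+ and E3 at either 5 or 10 months;
#'   \item NOT DE between E4 and E3 at 20 months;
#'   \item DE between 20-month and 5-month E3, same direction.
#' }
#' "DE" means passing the detection-fraction and fold-change gates of
#' [wilcoxon_de()] with raw p < `alpha` (unadjusted by design, to stay
#' permissive for downstream functional validation); "not DE" is the
#' negation of that joint gate. Successive pass counts are reported in
#' filter order.
#'
#' @param de_tables Named list of [wilcoxon_de()] tables covering all of
#'   [study_contrasts()].
#' @param alpha Significance gate on raw p.
#' @return A `candidate_report`: list with `candidates` (character),
#'   `flags` (per-gene logical criteria matrix plus direction),
#'   `successive_counts` (named integer vector in filter order).
#' @export
multilevel_filter <- function(de_tables, alpha = 0.05) {
  need <- study_contrasts()
  miss <- setdiff(need, names(de_tables))
  if (length(miss))
    stop("missing contrast table(s): ", paste(miss, collapse = ", "))
  genes <- sort(unique(unlist(lapply(de_tables[need], `[[`, "gene"))))
  get <- function(contrast) {
    tab <- de_tables[[contrast]]
    i <- match(genes, tab$gene)
    list(de = ifelse(is.na(i), FALSE, .de_flag(tab, alpha)[i]),
         sign = ifelse(is.na(i), 0, sign(tab$log_fc[i])))
  }
  c1 <- get("e4_vs_e3_5mo"); c2 <- get("e4_vs_e3_10mo")
  c3 <- get("apoehigh_e4_vs_e3_10mo")
  c4a <- get("fe4_vs_e3_5mo"); c4b <- get("fe4_vs_e3_10mo")
  c5 <- get("e4_vs_e3_20mo"); c6 <- get("e3_20mo_vs_e3_5mo")
  dir <- c1$sign
  f1 <- c1$de
  f2 <- c2$de & c2$sign == dir
  f3 <- c3$de & c3$sign == dir
  f4 <- !c4a$de & !c4b$de
  f5 <- !c5$de
  f6 <- c6$de & c6$sign == dir
  flags <- data.frame(gene = genes, direction = dir,
                      c1 = f1, c2 = f2, c3 = f3, c4 = f4, c5 = f5, c6 = f6,
                      stringsAsFactors = FALSE)
  cum <- list(f1, f1 & f2, f1 & f2 & f3, f1 & f2 & f3 & f4,
              f1 & f2 & f3 & f4 & f5,
              f1 & f2 & f3 & f4 & f5 & f6)
  successive <- vapply(cum, sum, numeric(1))
  names(successive) <- c("c1", "c2", "c3", "c4", "c5", "c6")
  structure(list(candidates = genes[cum[[6]]], flags = flags,
                 successive_counts = successive, alpha = alpha),
            class = "candidate_report")
}

#' @exportS3Method base::print
print.candidate_report <- function(x, ...) {
  cat("<candidate_report>\n  successive counts:",
      paste(sprintf("%s=%d", names(x$successive_counts),
                    as.integer(x$successive_counts)), collapse = " "),
      "\n  candidates:", if (length(x$candidates))
        paste(x$candidates, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Jaccard similarity index between two gene sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b Character vectors (sets).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Greedy one-to-one cluster matching on a Jaccard-similarity matrix
#'
#' Repeatedly assigns the globally highest remaining similarity, removing
#' the matched row and column. Ties are broken by the smaller relative
#' cluster-size difference, then lexically. Zero-similarity pairs are
#' never matched.
#'
#' @param jsi Numeric matrix, new clusters (rows) x reference clusters
#'   (columns), with dimnames.
#' @param sizes_new,sizes_ref Named cluster sizes used for tie-breaking
#'   (optional).
#' @return List with `mapping` (`data.frame`: `new`, `ref`, `jsi`) and
#'   `unmatched_new`, `unmatched_ref`.
#' @export
greedy_cluster_match <- function(jsi, sizes_new = NULL, sizes_ref = NULL) {
  jsi <- as.matrix(jsi)
  if (is.null(rownames(jsi))) rownames(jsi) <- as.character(seq_len(nrow(jsi)))
  if (is.null(colnames(jsi))) colnames(jsi) <- as.character(seq_len(ncol(jsi)))
  m <- jsi
  mapping <- data.frame(new = character(0), ref = character(0),
                        jsi = numeric(0), stringsAsFactors = FALSE)
  while (nrow(m) > 0 && ncol(m) > 0 && max(m) > 0) {
    best <- max(m)
    cand <- which(m == best, arr.ind = TRUE)
    if (nrow(cand) > 1 && !is.null(sizes_new) && !is.null(sizes_ref)) {
      rel <- apply(cand, 1, function(rc) {
        sn <- sizes_new[[rownames(m)[rc[1]]]] %||% NA_real_
        sr <- sizes_ref[[colnames(m)[rc[2]]]] %||% NA_real_
        if (is.na(sn) || is.na(sr)) Inf else abs(sn - sr) / max(sn, sr)
      })
      cand <- cand[rel == min(rel), , drop = FALSE]
    }
    if (nrow(cand) > 1) {
      keys <- paste(rownames(m)[cand[, 1]], colnames(m)[cand[, 2]])
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    ri <- cand[1, 1]; ci <- cand[1, 2]
    mapping <- rbind(mapping, data.frame(new = rownames(m)[ri],
                                         ref = colnames(m)[ci],
                                         jsi = best,
                                         stringsAsFactors = FALSE))
    m <- m[-ri, -ci, drop = FALSE]
  }
  list(mapping = mapping,
       unmatched_new = setdiff(rownames(jsi), mapping$new),
       unmatched_ref = setdiff(colnames(jsi), mapping$ref))
}

#' Build all study DE tables from counts and metadata
#'
#' Convenience driver producing the seven contrast tables consumed by
#' [multilevel_filter()] from a QC-filtered, normalised matrix and its
#' metadata (columns `genotype` in E3/E4/fE4, `age_months`, `cluster_id`).
#' The APOE-high contrast uses [classify_apoe_high()] at 10 months.
#'
#' @param norm Normalised genes x cells matrix.
#' @param meta Cell metadata aligned to columns.
#' @param cluster Target cluster id (cells outside it are ignored).
#' @param apoe_gene APOE gene name for the high-cell classification.
#' @param min_pct,logfc_min Gates passed to [wilcoxon_de()].
#' @return Named list of DE tables keyed by [study_contrasts()].
#' @export
study_de_tables <- function(norm, meta, cluster = NULL, apoe_gene = "Apoe",
                            min_pct = 0.1, logfc_min = 0.05) {
  if (!is.null(cluster)) {
    keep <- meta$cluster_id == cluster
    norm <- norm[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  high <- classify_apoe_high(norm, meta, apoe_gene)
  grp <- function(genotype, age, high_only = FALSE) {
    sel <- meta$genotype == genotype & meta$age_months == age
    if (high_only) sel <- sel & high
    which(sel)
  }
  de <- function(a, b) wilcoxon_de(norm, a, b, min_pct, logfc_min)
  list(
    e4_vs_e3_5mo = de(grp("E4", 5), grp("E3", 5)),
    e4_vs_e3_10mo = de(grp("E4", 10), grp("E3", 10)),
    apoehigh_e4_vs_e3_10mo = de(grp("E4", 10, TRUE), grp("E3", 10, TRUE)),
    fe4_vs_e3_5mo = de(grp("fE4", 5), grp("E3", 5)),
    fe4_vs_e3_10mo = de(grp("fE4", 10), grp("E3", 10)),
    e4_vs_e3_20mo = de(grp("E4", 20), grp("E3", 20)),
    e3_20mo_vs_e3_5mo = de(grp("E3", 20), grp("E3", 5)))
}
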