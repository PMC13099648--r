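#' Z-score a neuron feature matrix
#'
#' Column-wise standardisation (sample standard deviation, denominator
#' `n - 1`) applied before k-means so features contribute on a common
#' scale.
#'
#' @param x Numeric matrix or data frame, neurons x features.
#' @return Matrix with column mean 0 and sd 1; errors naming any constant
#'   column.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (anyNA(x)) stop("feature matrix contains missing values; filter rows first")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x)[, , drop = FALSE]
}

#' Fit k-means to (z-scored) neuron features
#'
#' Standard k-means (Hartigan-Wong) with multiple random restarts, made
#' deterministic by the seed. Restart count trades runtime against the
#' chance of a local optimum; 10 restarts recover the global minimum-inertia
#' partition on problems of this size.
#'
#' @param x Numeric matrix, typically from [zscore_features()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of random restarts.
#' @return A `cluster_model`: list with `k`, `centers`, `cluster`
#'   assignments, `inertia` and `features`.
#' @export
fit_kmeans <- function(x, k = 2, seed = 1L, nstart = 10) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("need at least k rows")
  km <- with_seed(seed, kmeans(x, centers = k, nstart = nstart,
                               iter.max = 100))
  structure(list(k = k, centers = km$centers, cluster = km$cluster,
                 inertia = km$tot.withinss,
                 features = colnames(x), labels = NULL),
            class = "cluster_model")
}

# Canonical feature names and the centroid sign expected for the
# hyperexcitable phenotype: higher gain and R_in, lower rheobase, spike
# latency and C_m.
hyper_signs <- c(gain = 1, r_in_mohm = 1, rheobase_pa = -1,
                 spike_latency_ms = -1, c_m_pf = -1)

#' Label the two clusters as hyperexcitable vs normal
#'
#' For each canonical feature present in the model, the centroid lying on
#' the hyperexcitable side (higher gain and input resistance; lower
#' rheobase, spike latency and capacitance) earns one vote; the majority
#' winner is labelled `"hyperexcitable"`. A tie is an error requiring a
#' manual label.
#'
#' @param model A k = 2 `cluster_model` whose features include the
#'   canonical five.
#' @return The model with `$labels` set (named character vector of length
#'   2, values `"hyperexcitable"`/`"normal"`).
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 2) stop("labelling is defined for k = 2 models")
  feats <- intersect(names(hyper_signs), model$features)
  if (!length(feats))
    stop("no canonical features (gain, r_in_mohm, rheobase_pa, ",
         "spike_latency_ms, c_m_pf) in model")
  votes <- c(0, 0)
  for (f in feats) {
    hi <- which.max(model$centers[, f] * hyper_signs[f])
    votes[hi] <- votes[hi] + 1
  }
  if (votes[1] == votes[2])
    stop("tie vote between centroids; supply labels manually")
  hyper <- which.max(votes)
  labels <- rep("normal", 2)
  labels[hyper] <- "hyperexcitable"
  model$labels <- setNames(labels, rownames(model$centers) %||% c("1", "2"))
  model
}

#' Per-cell membership residuals relative to the unity line
#'
#' Euclidean distances from every cell to the hyperexcitable and normal
#' centroids are z-scored across cells; the residual is the signed
#' perpendicular offset from the unity line in that (z_H, z_N) plane,
#' `(z(d_normal) - z(d_hyper)) / sqrt(2)`. Positive residuals indicate
#' stronger affinity for the hyperexcitable cluster.
#'
#' @param model A labelled `cluster_model` (see [label_clusters()]).
#' @param x Feature matrix on the same scale the model was fitted on.
#' @return `data.frame` with distances, z-scored distances, `residual`,
#'   `assigned` cluster label and row names preserved.
#' @export
membership_residuals <- function(model, x) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$labels)) model <- label_clusters(model)
  x <- as.matrix(x)
  hyper_i <- which(model$labels == "hyperexcitable")
  norm_i <- which(model$labels == "normal")
  d_h <- sqrt(colSums((t(x) - model$centers[hyper_i, ])^2))
  d_n <- sqrt(colSums((t(x) - model$centers[norm_i, ])^2))
  z_h <- as.numeric(scale(d_h))
  z_n <- as.numeric(scale(d_n))
  res <- (z_n - z_h) / sqrt(2)
  data.frame(d_hyper = d_h, d_normal = d_n, z_hyper = z_h, z_normal = z_n,
             residual = res,
             assigned = ifelse(d_h <= d_n, "hyperexcitable", "normal"),
             row.names = rownames(x))
}

# Optimal one-to-one pairing of iteration centroids to reference centroids
# by total distance (all permutations; k is small).
match_centroids <- function(centers, ref_centers) {
  k <- nrow(ref_centers)
  perms <- permutations_of(k)
  best <- NULL; best_cost <- Inf
  d <- as.matrix(dist(rbind(centers, ref_centers)))[seq_len(k),
                                                    k + seq_len(k), drop = FALSE]
  for (p in perms) {
    cost <- sum(d[cbind(seq_len(k), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best # best[i] = reference cluster matched to iteration cluster i
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- permutations_of(k - 1)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[r])
  }
  out
}

#' Bootstrap stability of the k-means clustering
#'
#' Repeats the clustering on random 80% subsamples: in each iteration the
#' model is fitted on the subsample, all cells are assigned to the nearest
#' iteration centroid, iteration clusters are matched to the full-data
#' clusters by optimal centroid pairing, and each cell is scored as
#' retained if it keeps its full-data cluster. The per-cell retention
#' probability and the per-iteration agreement are the k-selection
#' diagnostics. The clustering is flagged stable only when even the least
#' reliable cells are retained: the 5th percentile of per-cell retention
#' must reach `stability_threshold`. With genuine clusters the decision
#' boundary crosses empty space and every cell is retained in essentially
#' all iterations; forcing k clusters onto unstructured data places cells
#' on the boundary, whose retention collapses even when the average stays
#' high.
#'
#' @param x Feature matrix (z-scored).
#' @param k Number of clusters.
#' @param n_iter Number of resampling iterations (default 1000).
#' @param train_frac Fraction of cells used for fitting (default 0.8).
#' @param seed Integer seed.
#' @param nstart Restarts per iteration fit.
#' @param stability_threshold Minimum 5th-percentile per-cell retention
#'   for a stable call.
#' @param strict_5fold If `TRUE`, iterations cycle deterministic 5-fold
#'   train/test splits (in groups of 5) instead of independent resamples.
#' @return List with `retention_p` (per cell), `mean_retention`,
#'   `retention_q05`, `iter_agreement`, `match_to_full_p`, `stable`,
#'   `full_model`.
#' @export
bootstrap_stability <- function(x, k = 2, n_iter = 1000, train_frac = 0.8,
                                seed = 1L, nstart = 5,
                                stability_threshold = 0.9,
                                strict_5fold = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (floor(n * train_frac) < k) stop("training subsample smaller than k")
  full <- fit_kmeans(x, k, seed = derive_seed(seed, 0))
  retained <- numeric(n)
  agreement <- numeric(n_iter)
  folds <- NULL
  with_seed(derive_seed(seed, 1), {
    for (it in seq_len(n_iter)) {
      if (strict_5fold) {
        r <- (it - 1) %% 5 + 1
        if (r == 1) folds <- sample(rep(1:5, length.out = n))
        train <- which(folds != r)
      } else {
        train <- sample.int(n, floor(n * train_frac))
      }
      km <- kmeans(x[train, , drop = FALSE], centers = k, nstart = nstart,
                   iter.max = 100)
      # assign every cell to the nearest iteration centroid
      dmat <- vapply(seq_len(k), function(j)
        colSums((t(x) - km$centers[j, ])^2), numeric(n))
      assign_it <- max.col(-dmat)
      map <- match_centroids(km$centers, full$centers)
      ok <- map[assign_it] == full$cluster
      retained <- retained + ok
      agreement[it] <- mean(ok)
    }
  })
  retention_p <- retained / n_iter
  list(retention_p = retention_p,
       mean_retention = mean(retention_p),
       retention_q05 = unname(quantile(retention_p, 0.05)),
       iter_agreement = agreement,
       match_to_full_p = mean(agreement >= 0.95),
       stable = unname(quantile(retention_p, 0.05)) >= stability_threshold,
       full_model = full)
}

#' Compare membership residuals across genotype and age
#'
#' Two-way ANOVA (type II sums of squares, interaction included) on the
#' residuals with post hoc Tukey HSD contrasts, the inferential step that
#' turns per-cell cluster affinity into group-level claims.
#'
#' @param residual Numeric vector of membership residuals.
#' @param genotype,age Factors (coerced) with at least 2 levels each.
#' @return List with `anova` (data frame: term, sum_sq, df, F, p) and
#'   `tukey` (the [TukeyHSD()] tables).
#' @export
compare_residuals <- function(residual, genotype, age) {
  genotype <- factor(genotype); age <- factor(age)
  if (nlevels(genotype) < 2 || nlevels(age) < 2)
    stop("need at least 2 levels per factor")
  if (any(table(genotype, age) == 0))
    stop("empty cell in the genotype x age design")
  d <- data.frame(residual = residual, genotype = genotype, age = age)
  fit <- lm(residual ~ genotype * age, data = d)
  a2 <- car::Anova(fit, type = 2)
  tab <- data.frame(term = rownames(a2), sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]], F = a2[["F value"]],
                    p = a2[["Pr(>F)"]], row.names = NULL)
  tuk <- TukeyHSD(aov(residual ~ genotype * age, data = d))
  list(anova = tab, tukey = tuk)
}
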