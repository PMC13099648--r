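# small deterministic matrix helpers
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(mat)))
  colnames(m) <- cells %||% sprintf("c%02d", seq_len(ncol(mat)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC filter applies inclusive count bounds and strict mito bound", {
  meta <- data.frame(
    n_genes_detected = c(2400, 2401, 200, 199, 1000, 1000, 1000, 1000, 1000, 1000),
    n_umi = c(4500, 3000, 3000, 3000, 4501, 500, 499, 3000, 3000, 3000),
    mito_fraction = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001,
                      0.0025, 0.00249, 0.01))
  counts <- toy_counts(matrix(1, 3, 10))
  r <- qc_filter(counts, meta)
  # brute-force rule evaluation
  keep <- with(meta, n_genes_detected >= 200 & n_genes_detected <= 2400 &
                 n_umi >= 500 & n_umi <= 4500 & mito_fraction < 0.0025)
  expect_equal(rownames(r$meta), rownames(meta)[keep])
  expect_true(all(c("1", "6", "9") %in% rownames(r$meta)))
  expect_false(any(c("2", "4", "7", "8", "10") %in% rownames(r$meta)))
  strict <- meta; strict$mito_fraction <- 1
  expect_error(qc_filter(counts, strict), "all cells removed")
})

test_that("log-normalisation formula and scale invariance", {
  m <- toy_counts(rbind(c(100, 0), c(9900, 50)))
  n <- lognormalize(m, scale = 1e4)
  expect_equal(n[1, 1], log(101))
  expect_equal(n[1, 2], 0)
  # multiplying a cell's counts by a constant leaves it unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 7
  expect_equal(as.matrix(lognormalize(m2)), as.matrix(n))
  zero <- toy_counts(matrix(0, 2, 1))
  expect_error(lognormalize(zero), "zero total")
})

test_that("Wilcoxon DE applies detection and fold-change gates", {
  set.seed(31)
  nA <- 200; nB <- 200
  base <- matrix(rpois(5 * (nA + nB), 5), 5)
  # gene 1: planted e^1 ratio in group A; gene 4: detected in 5% only
  base[1, 1:nA] <- rpois(nA, 5 * exp(1))
  base[4, ] <- 0
  on4 <- c(sample(nA, round(0.05 * nA)), nA + sample(nB, round(0.05 * nB)))
  base[4, on4] <- 3
  m <- toy_counts(base, genes = paste0("gene", 1:5))
  norm <- lognormalize(m)
  de <- wilcoxon_de(norm, 1:nA, nA + 1:nB)
  expect_true(de$tested[1])
  expect_lt(de$p_raw[1], 1e-3)
  expect_gt(de$log_fc[1], 0.5)
  expect_false(de$tested[4]) # pct gate
  # identical groups: near-null p for tested genes
  de_same <- wilcoxon_de(norm, 1:100, 101:200)
  expect_true(all(de_same$p_raw[de_same$tested] > 0.001, na.rm = TRUE))
  expect_error(wilcoxon_de(norm, integer(0), 1:5), "empty")
})

test_that("marker finding returns planted cluster-specific genes", {
  set.seed(32)
  n <- 90
  labels <- rep(c("A", "B", "C"), each = n / 3)
  mat <- matrix(rpois(6 * n, 2), 6)
  mat[1, labels == "A"] <- rpois(n / 3, 20)
  mat[2, labels == "B"] <- rpois(n / 3, 20)
  mat[3, labels == "C"] <- rpois(n / 3, 20)
  # gene 4 uniform high, genes 5-6 uniform low
  mat[4, ] <- rpois(n, 20)
  m <- toy_counts(mat, genes = paste0("gene", 1:6))
  mk <- find_markers(lognormalize(m), labels)
  expect_equal(mk$A, "gene1")
  expect_equal(mk$B, "gene2")
  expect_equal(mk$C, "gene3")
})

test_that("APOE-high rule: strict 2-sd-above-median within cell type", {
  # tight mass near 2 plus one moderate (3) and one extreme (5) cell:
  # the rule must flag only the extreme one
  set.seed(90)
  lev <- c(2 + rnorm(18, 0, 0.1), 3, 5)
  norm <- toy_counts(matrix(lev, 1), genes = "Apoe")
  meta <- data.frame(cluster_id = rep("C1", length(lev)))
  high <- classify_apoe_high(norm, meta, "Apoe")
  thr <- median(lev) + 2 * sd(lev) # independent restatement of the rule
  expect_equal(high, lev > thr)
  expect_true(high[20])   # the 5.0 cell
  expect_false(high[19])  # the 3.0 cell
  expect_equal(sum(high), 1)
  # all equal: none high; shuffling cells leaves labels aligned
  flat <- toy_counts(matrix(3, 1, 6), genes = "Apoe")
  expect_false(any(classify_apoe_high(flat, data.frame(cluster_id = rep("C1", 6)))))
  perm <- c(20, 1:19)
  highp <- classify_apoe_high(norm[, perm, drop = FALSE],
                              meta[perm, , drop = FALSE])
  expect_equal(highp, high[perm])
  tiny <- toy_counts(matrix(c(1, 9), 1), genes = "Apoe")
  expect_warning(ht <- classify_apoe_high(tiny,
    data.frame(cluster_id = c("C1", "C1"))), "< 3 cells")
  expect_false(any(ht))
})

# hand-built DE tables for the filter: p/log_fc/tested are set directly
de_row <- function(gene, lfc, p, tested = TRUE) {
  data.frame(gene = gene, log_fc = lfc, pct_1 = 1, pct_2 = 1,
             tested = tested, p_raw = p, p_adj = p, stringsAsFactors = FALSE)
}
null_row <- function(gene) de_row(gene, 0.0, 0.9, tested = FALSE)

mk_tables <- function(per_contrast) {
  tabs <- lapply(study_contrasts(), function(cn) {
    do.call(rbind, lapply(names(per_contrast), function(g) {
      pat <- per_contrast[[g]]
      if (cn %in% names(pat)) de_row(g, pat[[cn]], 1e-4) else null_row(g)
    }))
  })
  names(tabs) <- study_contrasts()
  tabs
}

test_that("multilevel filter enforces the six criteria and direction", {
  cand <- c("e4_vs_e3_5mo", "e4_vs_e3_10mo", "apoehigh_e4_vs_e3_10mo",
            "e3_20mo_vs_e3_5mo")
  patterns <- list(
    good_up = setNames(as.list(rep(1, 4)), cand),
    good_dn = setNames(as.list(rep(-1, 4)), cand),
    fail_c5 = c(setNames(as.list(rep(1, 4)), cand),
                list(e4_vs_e3_20mo = 1)),
    fail_c4 = c(setNames(as.list(rep(1, 4)), cand),
                list(fe4_vs_e3_10mo = 1)),
    fail_dir = c(list(e4_vs_e3_5mo = 1),
                 setNames(as.list(rep(-1, 3)), cand[2:4])),
    fail_c6 = setNames(as.list(rep(1, 3)), cand[1:3]))
  tabs <- mk_tables(patterns)
  rep <- multilevel_filter(tabs)
  expect_setequal(rep$candidates, c("good_up", "good_dn"))
  fl <- rep$flags
  expect_false(fl$c5[fl$gene == "fail_c5"])
  expect_false(fl$c4[fl$gene == "fail_c4"])
  expect_false(fl$c2[fl$gene == "fail_dir"])
  expect_false(fl$c6[fl$gene == "fail_c6"])
  expect_true(all(diff(rep$successive_counts) <= 0))
  # single-flag flip: making fail_c5 clean in c5 promotes it
  patterns2 <- patterns
  patterns2$fail_c5$e4_vs_e3_20mo <- NULL
  rep2 <- multilevel_filter(mk_tables(patterns2))
  expect_true("fail_c5" %in% rep2$candidates)
  # missing contrast is an error naming it
  expect_error(multilevel_filter(tabs[-3]), "apoehigh_e4_vs_e3_10mo")
  # empty tables: empty candidate list
  empty <- lapply(study_contrasts(), function(x) de_row("dummy", 0, 1)[0, ])
  names(empty) <- study_contrasts()
  expect_equal(length(multilevel_filter(empty)$candidates), 0)
})

test_that("filter output is invariant to gene and row order", {
  cand <- c("e4_vs_e3_5mo", "e4_vs_e3_10mo", "apoehigh_e4_vs_e3_10mo",
            "e3_20mo_vs_e3_5mo")
  patterns <- list(zz = setNames(as.list(rep(1, 4)), cand),
               aa = setNames(as.list(rep(-1, 4)), cand),
               mm = list(e4_vs_e3_5mo = 1))
  tabs <- mk_tables(patterns)
  shuffled <- lapply(tabs, function(t) t[rev(seq_len(nrow(t))), ])
  expect_equal(multilevel_filter(tabs)$candidates,
               multilevel_filter(shuffled)$candidates)
})

test_that("Jaccard similarity and greedy cluster matching", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity("a", "b"), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
  # identity matrix maps one-to-one
  j <- diag(3); dimnames(j) <- list(paste0("n", 1:3), paste0("r", 1:3))
  m <- greedy_cluster_match(j)
  expect_equal(m$mapping$ref, paste0("r", 1:3))
  # hand-traced ambiguous 3x3: highest remaining JSI wins each round
  j2 <- matrix(c(0.9, 0.8, 0.1,
                 0.85, 0.7, 0.2,
                 0.1, 0.1, 0.6), 3, byrow = TRUE,
               dimnames = list(paste0("n", 1:3), paste0("r", 1:3)))
  m2 <- greedy_cluster_match(j2)
  # trace: (n1, r1, 0.9) -> remove -> (n2, r2 = 0.7) -> (n3, r3 = 0.6)
  expect_equal(m2$mapping$new, paste0("n", 1:3))
  expect_equal(m2$mapping$ref, paste0("r", 1:3))
  expect_equal(m2$mapping$jsi, c(0.9, 0.7, 0.6))
  # tie broken by closer relative size
  j3 <- matrix(c(0.5, 0.5), 1, dimnames = list("n1", c("r1", "r2")))
  m3 <- greedy_cluster_match(j3, sizes_new = c(n1 = 100),
                             sizes_ref = c(r1 = 30, r2 = 90))
  expect_equal(m3$mapping$ref, "r2")
  z <- matrix(0, 2, 2, dimnames = list(c("n1", "n2"), c("r1", "r2")))
  mz <- greedy_cluster_match(z)
  expect_equal(nrow(mz$mapping), 0)
  expect_setequal(mz$unmatched_new, c("n1", "n2"))
})
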