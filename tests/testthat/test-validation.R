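make_de <- function(genes, log2_fc, p_raw) {
  data.frame(gene = genes, fold_change = 2^log2_fc, log2_fc = log2_fc,
             p_raw = p_raw, p_adj = p_raw, stringsAsFactors = FALSE)
}

test_that("cross-cohort comparison has the expected symmetries", {
  set.seed(81)
  a <- make_de(sprintf("G%02d", 1:20), rnorm(20), runif(20))
  cmp <- compare_de_tables(a, a)
  expect_equal(cmp$pearson_r_logp, 1)
  expect_equal(cmp$pearson_r_logfc, 1)
  expect_equal(cmp$direction_agreement, 1)
  expect_equal(cmp$n_common, 20)

  b <- a; b$log2_fc <- -a$log2_fc
  cmp2 <- compare_de_tables(a, b)
  expect_equal(cmp2$pearson_r_logfc, -1)
  expect_equal(cmp2$direction_agreement, 0)

  # symmetric in its arguments
  set.seed(82)
  c <- make_de(sprintf("G%02d", 5:24), rnorm(20), runif(20))
  ab <- compare_de_tables(a, c); ba <- compare_de_tables(c, a)
  expect_equal(ab$pearson_r_logp, ba$pearson_r_logp)
  expect_equal(ab$pearson_r_logfc, ba$pearson_r_logfc)
  expect_equal(ab$direction_agreement, ba$direction_agreement)

  expect_error(compare_de_tables(a[1:2, ], a[1:2, ]), "3 common")
})

test_that("two cohorts simulated from one truth table replicate directions", {
  cfg <- sim_config(n_genes = 200, n_de = 30, n_pairs = 40, seed = 83,
                    log2fc_range = c(1, 2))
  # same planted truth, independent measurement noise
  sim1 <- generate_paired(cfg, noise_seed = 831)
  sim2 <- generate_paired(cfg, noise_seed = 832)
  expect_identical(sim1$truth, sim2$truth)
  de1 <- de_screen(sim1$cohort, "paired", alpha = 1)
  de2 <- de_screen(sim2$cohort, "paired", alpha = 1)
  planted <- sim1$truth$gene[sim1$truth$planted_log2fc != 0]
  cmp <- compare_de_tables(de1[de1$gene %in% planted, ],
                           de2[de2$gene %in% planted, ])
  expect_gte(cmp$direction_agreement, 0.9)
  expect_gt(cmp$pearson_r_logfc, 0.9)
})

test_that("PCA separates planted subtypes and obeys spectral conventions", {
  cfg <- sim_config(n_genes = 100, n_de = 30, log2fc_range = c(1, 2),
                    sigma_gene = 0.7, seed = 84)
  sim <- generate_two_subtypes(cfg, n_a = 50, n_b = 28)
  planted <- sim$truth$gene[sim$truth$planted_log2fc != 0]
  pca <- pca_project(sim$cohort, planted)
  # best linear split on PC1
  acc <- max(vapply(pca$PC1, function(th)
    max(mean((pca$PC1 > th) == (sim$labels == "AC")),
        mean((pca$PC1 <= th) == (sim$labels == "AC"))), numeric(1)))
  expect_gte(acc, 0.95)
  ve <- attr(pca, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))

  # duplicating every sample duplicates the coordinates
  dup <- expression_cohort(cbind(sim$cohort$matrix,
                                 `colnames<-`(sim$cohort$matrix,
                                              paste0(colnames(sim$cohort$matrix),
                                                     "_d"))))
  pd <- pca_project(dup, planted)
  n <- ncol(sim$cohort$matrix)
  expect_equal(pd$PC1[1:n], pd$PC1[(n + 1):(2 * n)], tolerance = 1e-9)

  # sample order does not change coordinates (up to the fixed sign rule)
  perm <- sample(ncol(sim$cohort$matrix))
  shuf <- expression_cohort(sim$cohort$matrix[, perm])
  ps <- pca_project(shuf, planted)
  expect_equal(ps$PC1[match(pca$sample, ps$sample)], pca$PC1,
               tolerance = 1e-9)
})

test_that("PCA drops zero-variance genes and validates input", {
  mat <- rbind(G1 = rnorm(5), G2 = rep(3, 5), G3 = rnorm(5))
  colnames(mat) <- paste0("S", 1:5)
  cohort <- expression_cohort(mat)
  expect_warning(out <- pca_project(cohort, c("G1", "G2", "G3")), "G2")
  expect_equal(nrow(attr(out, "loadings")), 2)
  expect_error(pca_project(cohort, "G1"), "2 genes")
})

test_that("Ward/Manhattan merge heights follow the Lance-Williams recursion", {
  mat <- rbind(A = 0, B = 1, C = 10)
  colnames(mat) <- "S1"
  # pad with a second constant-offset sample so distances double
  mat <- cbind(mat, mat[, 1])
  colnames(mat) <- c("S1", "S2")
  cohort <- expression_cohort(mat)
  hc <- hier_cluster(cohort)$gene_hclust
  # pairwise Manhattan distances: d(A,B) = 2, d(A,C) = 20, d(B,C) = 18
  # first merge {A,B} at 2; then d({A,B},C) = (2*20 + 2*18 - 1*2)/3 = 74/3
  expect_equal(hc$height, c(2, 74 / 3), tolerance = 1e-9)
})

test_that("well-separated planted clusters are recovered at k = 2", {
  set.seed(85)
  mat <- rbind(matrix(rnorm(5 * 6, 0, 0.2), 5, 6),
               matrix(rnorm(3 * 6, 10, 0.2), 3, 6))
  dimnames(mat) <- list(sprintf("G%d", 1:8), sprintf("S%d", 1:6))
  cohort <- expression_cohort(mat)
  res <- hier_cluster(cohort)
  cut <- cutree(res$gene_hclust, 2)
  expect_equal(length(unique(cut[1:5])), 1)
  expect_equal(length(unique(cut[6:8])), 1)
  expect_false(cut[1] == cut[6])

  # permuting input order leaves the k = 2 partition unchanged
  perm <- sample(8)
  res_p <- hier_cluster(expression_cohort(mat[perm, ]))
  cut_p <- cutree(res_p$gene_hclust, 2)[rownames(mat)]
  expect_true(all((cut_p == cut_p[1]) == (cut == cut[1])))

  # degenerate single-item axis gets the identity order
  one <- hier_cluster(expression_cohort(mat[1, , drop = FALSE]))
  expect_identical(one$gene_order, "G1")
  expect_null(one$gene_hclust)
})

test_that("the k = 2 partition minimizes the exhaustive Ward cost", {
  set.seed(86)
  mat <- rbind(matrix(rnorm(4 * 5, 0, 0.3), 4, 5),
               matrix(rnorm(4 * 5, 6, 0.3), 4, 5))
  dimnames(mat) <- list(sprintf("G%d", 1:8), sprintf("S%d", 1:5))
  d <- dist(mat, method = "manhattan")
  cut <- cutree(hier_cluster(expression_cohort(mat))$gene_hclust, 2)
  best <- Inf; best_lab <- NULL
  for (mask in 1:(2^7 - 1)) {   # all bipartitions, item 8 fixed to group 0
    lab <- c(as.integer(intToBits(mask))[1:7], 0L)
    if (length(unique(lab)) < 2) next
    cost <- ward_partition_cost(d, lab)
    if (cost < best) { best <- cost; best_lab <- lab }
  }
  expect_true(all((best_lab == best_lab[1]) == (cut == cut[1])))
})

test_that("categorical chi-square matches hand computation", {
  same <- categorical_chisq(c(s1 = 10, s2 = 20, s3 = 30),
                            c(s1 = 20, s2 = 40, s3 = 60))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  hard <- categorical_chisq(c(a = 10, b = 0), c(a = 0, b = 10))
  expect_equal(hard$chisq, 20, tolerance = 1e-12)

  ab <- categorical_chisq(c(a = 5, b = 9), c(a = 7, b = 3))
  ba <- categorical_chisq(c(a = 7, b = 3), c(a = 5, b = 9))
  expect_equal(ab$chisq, ba$chisq)

  expect_error(categorical_chisq(c(a = 1), c(b = 1)), "categories")
  expect_error(categorical_chisq(c(a = 0, b = 5), c(a = 0, b = 3)), "zero")
})
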