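#' Cross-cohort agreement between two differential-expression tables
#'
#' Over the genes common to both tables: Pearson correlation of the
#' log10-transformed raw p-values, Pearson correlation of the log2 fold
#' changes, and the fraction of genes whose fold-change direction agrees.
#'
#' @param a,b `DiffExprTable` data.frames (see [de_screen()]); raw
#'   p-values are correlated (the adjusted column can be selected with
#'   `p_column`).
#' @param p_column which p column to correlate, default `"p_raw"`.
#' @return a `CohortComparison` list: `pearson_r_logp`,
#'   `pearson_r_logfc`, `direction_agreement`, `n_common`.
#' @export
compare_de_tables <- function(a, b, p_column = "p_raw") {
  common <- intersect(a$gene, b$gene)
  if (length(common) < 3) stop("fewer than 3 common genes")
  ia <- match(common, a$gene); ib <- match(common, b$gene)
  structure(list(
    pearson_r_logp = stats::cor(log10(a[[p_column]][ia]), log10(b[[p_column]][ib])),
    pearson_r_logfc = stats::cor(a$log2_fc[ia], b$log2_fc[ib]),
    direction_agreement = mean(sign(a$log2_fc[ia]) == sign(b$log2_fc[ib])),
    n_common = length(common)), class = "CohortComparison")
}

#' Project samples onto the first two principal components
#'
#' PCA of the samples restricted to a gene subset, with each gene
#' centered and scaled to unit variance before decomposition. Zero-
#' variance genes are dropped with a warning. Component signs follow a
#' fixed convention (the largest-magnitude loading of each component is
#' positive) so coordinates are reproducible.
#'
#' @param cohort an `ExpressionCohort`.
#' @param genes gene subset (>= 2 genes present).
#' @return data.frame (`sample`, `PC1`, `PC2`) with attributes
#'   `var_explained` (all components) and `loadings`.
#' @export
pca_project <- function(cohort, genes) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  genes <- intersect(genes, rownames(cohort$matrix))
  if (length(genes) < 2) stop("need at least 2 genes present in the cohort")
  if (ncol(cohort$matrix) < 3) stop("need at least 3 samples")
  x <- t(cohort$matrix[genes, , drop = FALSE])
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 genes with variance")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  out <- data.frame(sample = rownames(x), PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "loadings") <- pc$rotation
  out
}

#' Hierarchical clustering with Ward linkage on Manhattan distances
#'
#' Agglomerative clustering of both genes and samples, the combination
#' classically used for expression heatmap layout. Leaf orders for both
#' axes are returned; a degenerate axis (single item) gets the identity
#' order.
#'
#' @param cohort an `ExpressionCohort`.
#' @param genes gene subset.
#' @return list with `gene_order`, `sample_order` (leaf-order ids) and
#'   the underlying `gene_hclust`, `sample_hclust` objects (NULL when
#'   degenerate).
#' @export
hier_cluster <- function(cohort, genes = rownames(cohort$matrix)) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  genes <- intersect(genes, rownames(cohort$matrix))
  x <- cohort$matrix[genes, , drop = FALSE]
  cluster_axis <- function(m) {
    if (nrow(m) < 2) return(list(order = rownames(m), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "manhattan"), method = "ward.D")
    list(order = rownames(m)[hc$order], hclust = hc)
  }
  g <- cluster_axis(x)
  s <- cluster_axis(t(x))
  list(gene_order = g$order, sample_order = s$order,
       gene_hclust = g$hclust, sample_hclust = s$hclust)
}

#' Chi-square comparison of two categorical count distributions
#'
#' Classical contingency chi-square (no continuity correction) on the
#' 2 x k table of counts, e.g. comparing the tumor-stage distribution of
#' two cohorts.
#'
#' @param table_a,table_b named count vectors over the same categories.
#' @return list with `chisq`, `df`, `p`.
#' @export
categorical_chisq <- function(table_a, table_b) {
  if (is.null(names(table_a)) || is.null(names(table_b)) ||
      !setequal(names(table_a), names(table_b)))
    stop("count tables must share the same named categories")
  tab <- rbind(a = table_a, b = table_b[names(table_a)])
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero")
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
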