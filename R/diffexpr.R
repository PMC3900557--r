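#' Paired t-test for one gene
#'
#' Tests the per-pair tumor minus normal differences against zero; the
#' two-sided p comes from the t distribution with (pairs - 1) degrees of
#' freedom.
#'
#' @param tumor,normal numeric vectors, one value per patient, same order.
#' @return list with `t`, `p`, `df`.
#' @export
paired_t <- function(tumor, normal) {
  if (length(tumor) != length(normal)) stop("tumor and normal must be paired")
  if (length(tumor) < 2) stop("need at least 2 pairs")
  d <- tumor - normal
  if (stats::sd(d) == 0) stop("degenerate pairs: zero variance of differences")
  fit <- stats::t.test(tumor, normal, paired = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value, df = unname(fit$parameter))
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance form (the safer default when the test is
#' described only as a "t-test").
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("both groups are constant")
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), p = fit$p.value, df = unname(fit$parameter))
}

#' Fold change from log2 expression
#'
#' Returns `2^(mean(group_num) - mean(group_den))`: the ratio of
#' geometric means on the linear scale, which is the natural fold change
#' for log2-normalized data.
#'
#' @param group_num,group_den numeric log2 expression vectors
#'   (numerator = tumor or adenocarcinoma, denominator = normal or SCC).
#' @return positive scalar fold change.
#' @export
fold_change <- function(group_num, group_den) {
  if (!length(group_num) || !length(group_den)) stop("empty group")
  2^(mean(group_num) - mean(group_den))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the supplied family of p-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# vectorized per-gene tests over a genes x samples matrix split in two
de_test_all <- function(mat_a, mat_b, design) {
  if (design == "paired") {
    d <- mat_a - mat_b
    k <- ncol(d)
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (k - 1))
    tstat <- m / (s / sqrt(k))
    df <- k - 1
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    na <- ncol(mat_a); nb <- ncol(mat_b)
    ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
    va <- rowSums((mat_a - ma)^2) / (na - 1)
    vb <- rowSums((mat_b - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  data.frame(log2_fc = rowMeans(mat_a) - rowMeans(mat_b), t = tstat, p_raw = p)
}

#' Screen a cohort for differentially expressed genes
#'
#' Runs the per-gene test (paired t for normal/tumor pairs, Welch t for
#' two groups), computes fold changes, applies Benjamini-Hochberg over
#' all tested genes, and returns the genes with adjusted P strictly below
#' `alpha`, sorted by gene symbol. When a `genes` panel is supplied (for
#' example an ion-channel list) both the testing and the BH family are
#' restricted to the panel.
#'
#' @param cohort an `ExpressionCohort`. Paired design requires
#'   `cohort$pairing`.
#' @param design `"paired"` or `"two_group"`.
#' @param labels for `design = "two_group"`: a 2-level factor over the
#'   cohort's samples; the first level is the fold-change numerator.
#' @param alpha adjusted-P threshold in (0, 1]; rows with
#'   `p_adj < alpha` are returned (`alpha = 1` returns every tested gene).
#' @param genes optional gene panel restricting the screen.
#' @return `DiffExprTable` data.frame with columns `gene`, `fold_change`,
#'   `log2_fc`, `t`, `p_raw`, `p_adj`, `test`.
#' @export
de_screen <- function(cohort, design = c("paired", "two_group"),
                      labels = NULL, alpha = 0.05, genes = NULL) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  design <- match.arg(design)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  mat <- cohort$matrix
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing) == length(genes)) stop("no panel gene present in the cohort")
    mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  }
  if (design == "paired") {
    if (is.null(cohort$pairing)) stop("paired design requires cohort pairing")
    mat_a <- mat[, cohort$pairing$tumor, drop = FALSE]
    mat_b <- mat[, cohort$pairing$normal, drop = FALSE]
    test <- "paired_t"
  } else {
    if (is.null(labels)) stop("two_group design requires labels")
    labels <- factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
    mat_a <- mat[, labels == levels(labels)[1], drop = FALSE]
    mat_b <- mat[, labels == levels(labels)[2], drop = FALSE]
    test <- "two_sample_t"
  }
  res <- de_test_all(mat_a, mat_b, design)
  testable <- is.finite(res$t) & is.finite(res$p_raw)
  if (!any(testable)) {
    warning("no gene passed the test preconditions; empty table")
    out <- data.frame(gene = character(), fold_change = numeric(),
                      log2_fc = numeric(), t = numeric(), p_raw = numeric(),
                      p_adj = numeric(), test = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  res <- res[testable, , drop = FALSE]
  out <- data.frame(gene = rownames(mat)[testable],
                    fold_change = 2^res$log2_fc, log2_fc = res$log2_fc,
                    t = res$t, p_raw = res$p_raw,
                    p_adj = bh_adjust(res$p_raw), test = test,
                    stringsAsFactors = FALSE)
  out <- out[out$p_adj < alpha, , drop = FALSE]
  if (!nrow(out)) warning("no gene significant at adjusted P < ", alpha)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
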