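#' Build a sign-weighted signature from a differential-expression table
#'
#' Each gene's weight is the sign of its discovery log2 fold change:
#' +1 for genes up-regulated in the discovery contrast (fc > 1), -1 for
#' down-regulated genes (fc < 1). A fold change of exactly 1 gives weight
#' 0; such genes are flagged with a warning and excluded from scoring.
#' The weights are frozen at build time — scoring cohorts never changes
#' them.
#'
#' @param de data.frame with at least columns `gene` and `fold_change`
#'   (a `DiffExprTable` from [de_screen()] or a transcribed discovery
#'   table).
#' @param source_cohort label recording where the signature came from.
#' @return a `Signature`: data.frame (`gene`, `weight`, `discovery_fc`)
#'   with attribute `source_cohort`.
#' @export
build_signature <- function(de, source_cohort = "discovery") {
  if (!is.data.frame(de) || !nrow(de)) stop("empty differential-expression table")
  if (!all(c("gene", "fold_change") %in% names(de)))
    stop("table must have 'gene' and 'fold_change' columns")
  if (any(de$fold_change <= 0)) stop("fold changes must be positive")
  w <- sign(log2(de$fold_change))
  if (any(w == 0))
    warning("gene(s) with fold change 1 get weight 0 and are not scored: ",
            paste(de$gene[w == 0], collapse = ", "))
  sig <- data.frame(gene = de$gene, weight = as.integer(w),
                    discovery_fc = de$fold_change, stringsAsFactors = FALSE)
  attr(sig, "source_cohort") <- source_cohort
  class(sig) <- c("Signature", "data.frame")
  sig
}

#' The packaged 37-gene ion-channel lung-adenocarcinoma signature
#'
#' Transcribed from the published normal-vs-tumor discovery screen
#' (paired design, adjusted P < 0.001): 37 ion-channel genes, 10
#' up-regulated and 27 down-regulated in tumor tissue.
#'
#' @return a `Signature` (see [build_signature()]).
#' @export
ilas_signature <- function() {
  path <- system.file("extdata", "ilas_table1_discovery.tsv", package = "ionsig")
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_signature(de, source_cohort = "TWN_discovery")
}

#' The packaged 30-gene adenocarcinoma-vs-squamous subtype signature
#'
#' Transcribed from the published subtype discovery screen (Welch/two-
#' sample design, adjusted P < 0.05): 30 ion-channel genes, 21 higher in
#' adenocarcinoma and 9 lower.
#'
#' @return a `Signature`.
#' @export
subtype_signature <- function() {
  path <- system.file("extdata", "subtype_table4_discovery.tsv", package = "ionsig")
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  build_signature(de, source_cohort = "SWE_discovery")
}

#' Per-patient sign-weighted standardized risk score
#'
#' For each signature gene i present in the cohort, the gene's expression
#' is standardized across all scored samples (mean mu_i, sample SD tau_i,
#' both recomputed within the scored cohort) and the patient's score is
#' `s = sum_i w_i * (e_i - mu_i) / tau_i`. Because every standardized
#' gene sums to zero across samples, the cohort mean score is zero up to
#' float error. Signature genes absent from the cohort (platform
#' differences) are dropped with a message and the score is not rescaled;
#' the dropped count is recorded so cross-platform scores are flagged as
#' n-dependent.
#'
#' @param cohort an `ExpressionCohort`.
#' @param sig a `Signature`.
#' @return a `RiskScoreResult`: data.frame (`sample`, `score`, `status`)
#'   with attributes `gene_stats` (mu_i, tau_i, weight per scored gene)
#'   and `n_dropped`. `status` is NA until [dichotomize()] is applied.
#' @export
score_cohort <- function(cohort, sig) {
  stopifnot(inherits(cohort, "ExpressionCohort"), inherits(sig, "Signature"))
  sig <- sig[sig$weight != 0, , drop = FALSE]
  present <- sig$gene %in% rownames(cohort$matrix)
  if (!any(present)) stop("no signature gene present in the cohort")
  n_dropped <- sum(!present)
  if (n_dropped)
    message(n_dropped, " signature gene(s) absent from cohort '",
            cohort$cohort_name, "' dropped: ",
            paste(sig$gene[!present], collapse = ", "))
  sig <- sig[present, , drop = FALSE]
  e <- cohort$matrix[sig$gene, , drop = FALSE]
  mu <- rowMeans(e)
  tau <- sqrt(rowSums((e - mu)^2) / (ncol(e) - 1))
  if (any(tau == 0))
    stop("zero-variance signature gene(s): ",
         paste(sig$gene[tau == 0], collapse = ", "))
  z <- (e - mu) / tau
  s <- as.numeric(crossprod(z, sig$weight))
  res <- data.frame(sample = colnames(e), score = s,
                    status = factor(rep(NA, ncol(e)),
                                    levels = c("negative", "positive")),
                    stringsAsFactors = FALSE)
  attr(res, "gene_stats") <- data.frame(gene = sig$gene, weight = sig$weight,
                                        mu = mu, tau = tau,
                                        stringsAsFactors = FALSE)
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("RiskScoreResult", "data.frame")
  res
}

#' Dichotomize risk scores at the cohort median
#'
#' A patient is signature-positive when their score is strictly greater
#' than the cohort median; scores at or below the median (including exact
#' ties) are negative. The rule is deterministic.
#'
#' @param result a `RiskScoreResult` from [score_cohort()].
#' @return the result with `status` filled in.
#' @export
dichotomize <- function(result) {
  stopifnot(inherits(result, "RiskScoreResult"))
  if (nrow(result) < 2) stop("need at least 2 patients to dichotomize")
  med <- stats::median(result$score)
  result$status <- factor(ifelse(result$score > med, "positive", "negative"),
                          levels = c("negative", "positive"))
  result
}
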