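#' Summed Cox coefficient for a signature across cohorts
#'
#' For each cohort: score with the signature, dichotomize at the cohort
#' median, fit a univariate Cox model on the positive-vs-negative status,
#' and take the log hazard ratio (Cox coefficient). The statistic Z is
#' the sum of these coefficients across cohorts; larger Z means a
#' stronger adverse survival association under the sign-weight
#' convention.
#'
#' @param cohorts list of entries, each a list with `cohort`
#'   (`ExpressionCohort`), `clinical` (data.frame with
#'   `<outcome>_time` / `<outcome>_event` aligned to the cohort samples)
#'   and `outcome` (`"overall"` or `"recurrence"`).
#' @param sig a `Signature`.
#' @return scalar Z.
#' @export
signature_z <- function(cohorts, sig) {
  z <- vapply(seq_along(cohorts), function(i) {
    entry <- cohorts[[i]]
    nm <- entry$cohort$cohort_name %||% as.character(i)
    tryCatch({
      sc <- dichotomize(suppressMessages(score_cohort(entry$cohort, sig)))
      cl <- entry$clinical
      idx <- match(sc$sample, cl$sample)
      if (anyNA(idx)) stop("clinical table does not cover all scored samples")
      time <- cl[[paste0(entry$outcome, "_time")]][idx]
      event <- cl[[paste0(entry$outcome, "_event")]][idx]
      fit <- cox_univariate(time, event, sc$status, term = "status",
                            outcome = entry$outcome)
      fit$coefficient
    }, error = function(e) stop("cohort '", nm, "': ", conditionMessage(e),
                                call. = FALSE))
  }, numeric(1))
  sum(z)
}

#' Null distribution of Z from random gene signatures
#'
#' Draws `B` random signatures of `size` genes, sampled uniformly without
#' replacement from the discovery universe, builds each with the same
#' sign-of-fold-change weight rule as the real signature, and computes Z
#' for each. Deterministic under `seed`.
#'
#' @param cohorts as in [signature_z()].
#' @param universe data.frame with `gene` and `fold_change` columns for
#'   every candidate gene (typically the full discovery screen at
#'   `alpha = 1`); the fold change supplies each sampled gene's weight.
#' @param size signature size (genes per random signature).
#' @param B number of random signatures.
#' @param seed integer seed.
#' @return a `ResamplingResult` list: `z_null`, `B`, `seed`,
#'   `universe_size`, `size`; `z_observed` and `p_empirical` are NA until
#'   filled by [resampling_test()].
#' @export
null_distribution <- function(cohorts, universe, size, B = 1000L, seed = 1L) {
  stopifnot(is.data.frame(universe), all(c("gene", "fold_change") %in% names(universe)))
  if (size > nrow(universe)) stop("size exceeds the gene universe")
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  z_null <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(universe), size)
    rsig <- suppressWarnings(build_signature(universe[idx, , drop = FALSE],
                                             source_cohort = "random"))
    signature_z(cohorts, rsig)
  }, numeric(1))
  structure(list(z_observed = NA_real_, z_null = z_null, p_empirical = NA_real_,
                 B = as.integer(B), seed = as.integer(seed),
                 universe_size = nrow(universe), size = as.integer(size),
                 weight_rule = "sign(log2 discovery fold change)"),
            class = "ResamplingResult")
}

#' Empirical one-sided p-value against a resampling null
#'
#' `p = (1 + #\{z_null >= z_observed\}) / (B + 1)`: the add-one
#' permutation form, one-sided in the poor-survival direction, never
#' exactly zero and bounded below by 1/(B+1).
#'
#' @param z_observed observed Z.
#' @param z_null numeric vector of null Z draws.
#' @return empirical p in [1/(B+1), 1].
#' @export
empirical_p <- function(z_observed, z_null) {
  if (!length(z_null)) stop("empty null distribution")
  (1 + sum(z_null >= z_observed)) / (length(z_null) + 1)
}

#' Full signature non-randomness test
#'
#' Computes the observed Z for the signature, the random-signature null
#' of the same size, and the empirical p.
#'
#' @inheritParams null_distribution
#' @param sig the signature under test; `size` defaults to its number of
#'   nonzero-weight genes.
#' @return a completed `ResamplingResult`.
#' @export
resampling_test <- function(cohorts, sig, universe, B = 1000L, seed = 1L,
                            size = sum(sig$weight != 0)) {
  res <- null_distribution(cohorts, universe, size, B = B, seed = seed)
  res$z_observed <- signature_z(cohorts, sig)
  res$p_empirical <- empirical_p(res$z_observed, res$z_null)
  res
}

#' @export
print.ResamplingResult <- function(x, ...) {
  cat(sprintf("ResamplingResult: B = %d random signatures of %d genes (universe %d)\n",
              x$B, x$size, x$universe_size))
  if (is.finite(x$z_observed))
    cat(sprintf("  observed Z = %.4f, empirical P = %.4g\n",
                x$z_observed, x$p_empirical))
  invisible(x)
}
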