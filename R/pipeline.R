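#' Compare risk scores between two groups of patients
#'
#' Per-group mean, median and SD of the score plus a two-sided Welch
#' t-test for a group difference (e.g. ever- vs never-smokers).
#'
#' @param result a `RiskScoreResult`.
#' @param labels 2-level grouping aligned with `result$sample`.
#' @return list with `summary` (per-group n, mean, median, sd) and `p`.
#' @export
compare_scores_by_group <- function(result, labels) {
  stopifnot(inherits(result, "RiskScoreResult"))
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly 2 nonempty levels")
  sp <- split(result$score, labels)
  if (any(lengths(sp) == 0)) stop("both groups must be nonempty")
  smry <- data.frame(group = names(sp), n = lengths(sp),
                     mean = vapply(sp, mean, numeric(1)),
                     median = vapply(sp, stats::median, numeric(1)),
                     sd = vapply(sp, stats::sd, numeric(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
  p <- stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE)$p.value
  list(summary = smry, p = p)
}

write_stage_tsv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full signature analysis pipeline
#'
#' Executes, in order: the panel-restricted discovery screen on the
#' paired cohort; signature construction; scoring and median
#' dichotomization of each survival cohort; Kaplan-Meier/log-rank,
#' univariate Cox on status, Cox on the continuous score, and (where
#' clinical covariates are available) multivariate Cox; a smoking-
#' stratified score comparison; the random-signature resampling test;
#' and the subtype screen with PCA and Ward/Manhattan clustering. Any
#' stage failure aborts with the stage name; results computed before the
#' failure are retained in `out_dir` when given. The run is a pure
#' function of its inputs and `seed`.
#'
#' @param discovery `ExpressionCohort` with pairing (normal/tumor).
#' @param survival_cohorts named list; each entry a list with `cohort`,
#'   `clinical` and `outcome` (`"overall"` or `"recurrence"`).
#' @param subtype optional list with `cohort` and `labels` (2-level,
#'   first level = fold-change numerator).
#' @param panel optional gene panel restricting the discovery and
#'   subtype screens (the ion-channel list in the published analysis).
#' @param alpha_discovery adjusted-P cutoff for the discovery screen.
#' @param alpha_subtype adjusted-P cutoff for the subtype screen.
#' @param B random signatures for the resampling test.
#' @param seed top-level seed; stage seeds are derived from it.
#' @param multivariate_covariates clinical columns used in the
#'   multivariate model when present in a cohort's clinical table.
#' @param out_dir optional directory; stage outputs are persisted as TSV
#'   plus a JSON summary.
#' @return a report list with elements `de_table`, `signature`, `scores`,
#'   `survival_fits`, `km`, `smoking`, `resampling`, `subtype`.
#' @export
run_pipeline <- function(discovery, survival_cohorts = list(), subtype = NULL,
                         panel = NULL, alpha_discovery = 0.001,
                         alpha_subtype = 0.05, B = 1000L, seed = 1L,
                         multivariate_covariates = c("age", "gender", "stage",
                                                     "smoking", "myc", "mutation"),
                         out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list()

  report$de_table <- stage("discovery_screen", {
    de <- de_screen(discovery, design = "paired", alpha = alpha_discovery,
                    genes = panel)
    if (!nrow(de)) stop("empty signature: no gene significant at adjusted P < ",
                        alpha_discovery)
    de
  })
  write_stage_tsv(report$de_table, out_dir, "discovery_de")

  report$signature <- stage("build_signature",
    build_signature(report$de_table, source_cohort = discovery$cohort_name))
  write_stage_tsv(report$signature, out_dir, "signature")

  report$scores <- list()
  report$km <- list()
  fits <- list()
  for (nm in names(survival_cohorts)) {
    entry <- survival_cohorts[[nm]]
    sc <- stage(paste0("score_", nm),
                dichotomize(score_cohort(entry$cohort, report$signature)))
    report$scores[[nm]] <- sc
    write_stage_tsv(sc, out_dir, paste0("scores_", nm))
    cl <- entry$clinical
    idx <- match(sc$sample, cl$sample)
    time <- cl[[paste0(entry$outcome, "_time")]][idx]
    event <- cl[[paste0(entry$outcome, "_event")]][idx]
    report$km[[nm]] <- stage(paste0("km_", nm),
                             km_logrank(time, event, sc$status))
    uni <- stage(paste0("cox_univariate_", nm),
                 cox_univariate(time, event, sc$status, term = "status",
                                outcome = entry$outcome))
    uni$cohort <- nm
    cont <- stage(paste0("cox_continuous_", nm),
                  cox_continuous_score(time, event, sc$score,
                                       outcome = entry$outcome))
    cont$cohort <- nm
    fits[[paste0(nm, "_uni")]] <- uni
    fits[[paste0(nm, "_cont")]] <- cont
    covars <- intersect(multivariate_covariates, names(cl))
    if (length(covars) >= 1) {
      cv <- cl[idx, covars, drop = FALSE]
      cv <- cbind(status = sc$status, cv)
      multi <- stage(paste0("cox_multivariate_", nm),
                     cox_multivariate(time, event, cv, outcome = entry$outcome))
      multi$cohort <- nm
      fits[[paste0(nm, "_multi")]] <- multi
    }
  }
  report$survival_fits <- do.call(rbind, lapply(fits, function(f) {
    f$per_point_increase <- if ("per_point_increase" %in% names(f))
      f$per_point_increase else NA_real_
    f
  }))
  if (!is.null(report$survival_fits)) {
    rownames(report$survival_fits) <- NULL
    write_stage_tsv(report$survival_fits, out_dir, "survival_fits")
  }

  report$smoking <- list()
  for (nm in names(survival_cohorts)) {
    cl <- survival_cohorts[[nm]]$clinical
    if (!"smoking" %in% names(cl)) next
    sc <- report$scores[[nm]]
    smoking <- cl$smoking[match(sc$sample, cl$sample)]
    report$smoking[[nm]] <- stage(paste0("smoking_comparison_", nm),
                                  compare_scores_by_group(sc, smoking))
  }

  if (length(survival_cohorts)) {
    report$resampling <- stage("resampling", {
      universe <- de_screen(discovery, design = "paired", alpha = 1,
                            genes = panel)
      entries <- lapply(survival_cohorts, function(e)
        list(cohort = e$cohort, clinical = e$clinical, outcome = e$outcome))
      resampling_test(unname(entries), report$signature, universe, B = B,
                      seed = seed + 1L)
    })
    if (!is.null(out_dir))
      write_stage_tsv(data.frame(z_null = report$resampling$z_null),
                      out_dir, "resampling_null")
  }

  if (!is.null(subtype)) {
    report$subtype <- stage("subtype_analysis", {
      de <- de_screen(subtype$cohort, design = "two_group",
                      labels = subtype$labels, alpha = alpha_subtype,
                      genes = panel)
      pca <- if (nrow(de) >= 2)
        pca_project(subtype$cohort, de$gene) else NULL
      clust <- if (nrow(de) >= 2)
        hier_cluster(subtype$cohort, de$gene) else NULL
      list(de_table = de, pca = pca, clustering = clust)
    })
    write_stage_tsv(report$subtype$de_table, out_dir, "subtype_de")
    if (!is.null(report$subtype$pca))
      write_stage_tsv(report$subtype$pca, out_dir, "subtype_pca")
  }

  if (!is.null(out_dir)) {
    summary <- list(
      n_signature_genes = nrow(report$signature),
      n_up = sum(report$signature$weight > 0),
      n_down = sum(report$signature$weight < 0),
      cohorts = names(survival_cohorts),
      resampling_p = if (!is.null(report$resampling))
        report$resampling$p_empirical else NULL,
      subtype_n_genes = if (!is.null(report$subtype))
        nrow(report$subtype$de_table) else NULL,
      seed = seed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
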