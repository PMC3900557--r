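#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival curves per group plus the two-sided log-rank
#' test of equality (chi-square with 1 df).
#'
#' @param time nonnegative durations (days).
#' @param event 0/1 event indicators.
#' @param group 2-level grouping (e.g. signature status).
#' @return a `KMEstimate`: list with `curves` (per group: `time`, `surv`,
#'   `n_risk`), `chisq`, `logrank_p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need two groups for the log-rank test")
  if (nlevels(group) > 2) stop("only two groups supported")
  if (sum(event) == 0) stop("no events: all observations censored")
  if (any(table(group) == 0)) stop("both groups must be nonempty")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- lapply(split(seq_along(fit$time), strata), function(i)
    data.frame(time = fit$time[i], surv = fit$surv[i], n_risk = fit$n.risk[i]))
  names(curves) <- sub("^group=", "", names(curves))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd$chisq), logrank_p = p),
            class = "KMEstimate")
}

fit_to_survivalfit <- function(fit, model, outcome) {
  s <- summary(fit)
  ci <- s$conf.int
  out <- data.frame(term = rownames(s$coefficients),
                    coefficient = s$coefficients[, "coef"],
                    hazard_ratio = s$coefficients[, "exp(coef)"],
                    ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    model = model, outcome = outcome,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("SurvivalFit", "data.frame")
  out
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron handling of tied event times; Wald
#' 95% confidence interval and p-value, matching the usual
#' (HR, 95% CI, P) reporting triplet.
#'
#' @param time,event survival data (days, 0/1).
#' @param covariate binary (factor/logical) or numeric covariate.
#' @param term name used for the covariate in the output.
#' @param outcome label (`"overall"` or `"recurrence"`).
#' @return a `SurvivalFit` data.frame with one row.
#' @export
cox_univariate <- function(time, event, covariate, term = "covariate",
                           outcome = "overall") {
  if (sum(event) == 0) stop("no events: Cox model undefined")
  x <- if (is.factor(covariate) || is.logical(covariate) || is.character(covariate))
    as.numeric(factor(covariate)) - 1 else as.numeric(covariate)
  if (length(unique(x)) < 2) stop("covariate is constant")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  if (!is.finite(fit$coefficients) || abs(fit$coefficients) > 20)
    warning("possible complete separation: Cox coefficient did not stabilize")
  out <- fit_to_survivalfit(fit, "univariate", outcome)
  out$term <- term
  out
}

#' Multivariate Cox proportional-hazards regression
#'
#' Joint fit of signature status plus clinical covariates. Stage is
#' treated as a single ordinal numeric term (one hazard ratio per unit
#' stage increase). The design matrix must be full rank; collinear
#' columns are reported by name.
#'
#' @param time,event survival data.
#' @param covariates data.frame of covariates (factors or numerics), one
#'   row per patient; each categorical covariate needs >= 2 observed
#'   levels.
#' @param outcome label.
#' @return a `SurvivalFit` with one row per model term.
#' @export
cox_multivariate <- function(time, event, covariates, outcome = "overall") {
  stopifnot(is.data.frame(covariates))
  if (sum(event) == 0) stop("no events: Cox model undefined")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("covariate '", nm, "' has fewer than 2 observed levels")
  }
  mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(time = time, event = event, mm, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(mm)),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  fit_to_survivalfit(fit, "multivariate", outcome)
}

#' Cox regression on the continuous risk score
#'
#' Same as [cox_univariate()] with a real-valued covariate; additionally
#' reports the per-point hazard increase `exp(coefficient) - 1`, the
#' quantity behind statements like "a one-point increment in the risk
#' score raised the hazard by 2%".
#'
#' @param time,event survival data.
#' @param score numeric risk score per patient.
#' @param outcome label.
#' @return a `SurvivalFit` with an extra `per_point_increase` column.
#' @export
cox_continuous_score <- function(time, event, score, outcome = "overall") {
  out <- cox_univariate(time, event, as.numeric(score), term = "score",
                        outcome = outcome)
  out$per_point_increase <- exp(out$coefficient) - 1
  out
}
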