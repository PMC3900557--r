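#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list. Defaults describe a discovery-sized lung-cancer cohort: 500
#' genes of which 30 carry a planted tumor/normal difference with
#' |log2 fold change| between 1 and 2, 60 normal/tumor pairs, per-gene
#' noise SD 0.5 on the log2 scale, and an exponential survival model with
#' a median-scale baseline hazard and uniform censoring over ~8 years.
#'
#' @param n_genes total number of genes simulated.
#' @param n_de number of genes with a planted differential effect.
#' @param n_pairs patients in the paired design, or samples per group in
#'   the two-group design.
#' @param log2fc_range interval for the planted |log2 fold change|.
#' @param sigma_gene per-gene noise SD (log2 scale), > 0.
#' @param baseline_range interval for per-gene baseline log2 means.
#' @param beta_score Cox log-hazard per unit of true risk score.
#' @param baseline_hazard baseline event rate, events/day.
#' @param censor_window censoring drawn uniformly on (0, censor_window) days.
#' @param covariate_effects named log-hazard ratios for the clinical
#'   covariates (age, gender, stage, smoking, myc, mutation).
#' @param covariate_marginals distributions the covariates are drawn from.
#' @param seed integer; fully determines every generator's output.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 500L, n_de = 30L, n_pairs = 60L,
                       log2fc_range = c(1, 2), sigma_gene = 0.5,
                       baseline_range = c(4, 10),
                       beta_score = log(2), baseline_hazard = 1 / 1500,
                       censor_window = 3000,
                       covariate_effects = c(age = 0, gender = 0, stage = 0,
                                             smoking = 0, myc = 0, mutation = 0),
                       covariate_marginals = list(age_mean = 65, age_sd = 8,
                                                  gender_p = 0.5,
                                                  stage_levels = 1:3,
                                                  smoking_p = 0.5, myc_p = 0.3,
                                                  mutation_p = 0.4),
                       seed = 1L) {
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  if (sigma_gene <= 0) stop("sigma_gene must be > 0")
  if (censor_window <= 0) stop("censor_window must be > 0")
  structure(list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
                 n_pairs = as.integer(n_pairs), log2fc_range = log2fc_range,
                 sigma_gene = sigma_gene, baseline_range = baseline_range,
                 beta_score = beta_score, baseline_hazard = baseline_hazard,
                 censor_window = censor_window,
                 covariate_effects = covariate_effects,
                 covariate_marginals = covariate_marginals,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

planted_effects <- function(cfg) {
  # planted genes get alternating +/- signs so both weight directions are
  # exercised; magnitudes uniform over log2fc_range
  delta <- numeric(cfg$n_genes)
  if (cfg$n_de > 0) {
    idx <- sample.int(cfg$n_genes, cfg$n_de)
    mag <- stats::runif(cfg$n_de, cfg$log2fc_range[1], cfg$log2fc_range[2])
    delta[idx] <- rep(c(1, -1), length.out = cfg$n_de) * mag
  }
  delta
}

#' Generate a paired normal/tumor cohort with planted fold changes
#'
#' Normal samples are drawn gene-wise from Normal(baseline, sigma) and
#' the paired tumor samples from Normal(baseline + delta, sigma), where
#' delta is the planted log2 fold change (0 for null genes). The exact
#' planted effects are returned as a truth table so recovery can be
#' checked downstream.
#'
#' @param cfg a [sim_config()].
#' @param noise_seed seed for the sampling noise only; baselines and
#'   planted effects always follow `cfg$seed`, so two calls with the same
#'   config but different `noise_seed` are independent replication
#'   cohorts of the same underlying truth.
#' @return list with `cohort` (an `ExpressionCohort` with pairing) and
#'   `truth` (data.frame `gene`, `planted_log2fc`).
#' @export
generate_paired <- function(cfg, noise_seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  g <- cfg$n_genes; n <- cfg$n_pairs
  genes <- sprintf("G%04d", seq_len(g))
  baseline <- stats::runif(g, cfg$baseline_range[1], cfg$baseline_range[2])
  delta <- planted_effects(cfg)
  set.seed(noise_seed)
  normal <- baseline + matrix(stats::rnorm(g * n, 0, cfg$sigma_gene), g, n)
  tumor <- baseline + delta + matrix(stats::rnorm(g * n, 0, cfg$sigma_gene), g, n)
  mat <- cbind(normal, tumor)
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("P%03d_N", seq_len(n)), sprintf("P%03d_T", seq_len(n)))
  pairing <- data.frame(normal = sprintf("P%03d_N", seq_len(n)),
                        tumor = sprintf("P%03d_T", seq_len(n)),
                        stringsAsFactors = FALSE)
  list(cohort = expression_cohort(mat, pairing = pairing,
                                  cohort_name = "synthetic_paired"),
       truth = data.frame(gene = genes, planted_log2fc = delta,
                          stringsAsFactors = FALSE))
}

#' Generate a two-subtype cohort with planted between-group differences
#'
#' Two independent groups (adenocarcinoma-like "AC" and squamous-like
#' "SCC") share per-gene baselines; planted genes differ between groups
#' by the planted log2 fold change (AC minus SCC).
#'
#' @param cfg a [sim_config()].
#' @param n_a,n_b samples per group; default `cfg$n_pairs` each.
#' @param noise_seed seed for the sampling noise only (see
#'   [generate_paired()]).
#' @return list with `cohort`, `labels` (factor AC/SCC per sample) and
#'   `truth`.
#' @export
generate_two_subtypes <- function(cfg, n_a = cfg$n_pairs, n_b = cfg$n_pairs,
                                  noise_seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  g <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(g))
  baseline <- stats::runif(g, cfg$baseline_range[1], cfg$baseline_range[2])
  delta <- planted_effects(cfg)
  set.seed(noise_seed)
  a <- baseline + delta + matrix(stats::rnorm(g * n_a, 0, cfg$sigma_gene), g, n_a)
  b <- baseline + matrix(stats::rnorm(g * n_b, 0, cfg$sigma_gene), g, n_b)
  mat <- cbind(a, b)
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("AC%03d", seq_len(n_a)), sprintf("SCC%03d", seq_len(n_b)))
  labels <- factor(rep(c("AC", "SCC"), c(n_a, n_b)), levels = c("AC", "SCC"))
  list(cohort = expression_cohort(mat, cohort_name = "synthetic_subtypes"),
       labels = labels,
       truth = data.frame(gene = genes, planted_log2fc = delta,
                          stringsAsFactors = FALSE))
}

#' Generate clinical outcomes from a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta_score * score + covariate effects)`;
#' censoring is uniform on (0, censor_window); the observed time is the
#' minimum with the corresponding event flag. Overall and recurrence
#' outcomes are two independent draws from the same linear predictor.
#' Clinical covariates are drawn from the marginals declared in the
#' config.
#'
#' @param cfg a [sim_config()].
#' @param scores numeric vector, one true risk score per patient.
#' @param sample_ids optional sample identifiers.
#' @param seed seed for this draw; defaults to `cfg$seed`.
#' @return clinical data.frame (times in days, events 0/1, covariates).
#' @export
generate_survival <- function(cfg, scores, sample_ids = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (!all(is.finite(scores))) stop("scores must be finite")
  set.seed(seed)
  n <- length(scores)
  m <- cfg$covariate_marginals
  age <- stats::rnorm(n, m$age_mean, m$age_sd)
  gender <- ifelse(stats::rbinom(n, 1, m$gender_p) == 1, "M", "F")
  stage <- sample(m$stage_levels, n, replace = TRUE)
  smoking <- ifelse(stats::rbinom(n, 1, m$smoking_p) == 1, "ever", "never")
  myc <- ifelse(stats::rbinom(n, 1, m$myc_p) == 1, "high", "low")
  mutation <- ifelse(stats::rbinom(n, 1, m$mutation_p) == 1, "+", "-")
  ce <- cfg$covariate_effects
  lp <- cfg$beta_score * scores +
    ce[["age"]] * (age - m$age_mean) + ce[["gender"]] * (gender == "M") +
    ce[["stage"]] * (stage - mean(m$stage_levels)) +
    ce[["smoking"]] * (smoking == "ever") + ce[["myc"]] * (myc == "high") +
    ce[["mutation"]] * (mutation == "+")
  rate <- cfg$baseline_hazard * exp(lp)
  draw <- function() {
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 0, cfg$censor_window)
    list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  }
  ov <- draw(); rec <- draw()
  data.frame(sample = sample_ids %||% sprintf("S%04d", seq_len(n)),
             overall_time = ov$time, overall_event = ov$event,
             recurrence_time = rec$time, recurrence_event = rec$event,
             age = age, gender = gender, stage = as.integer(stage),
             smoking = smoking, myc = myc, mutation = mutation,
             stringsAsFactors = FALSE)
}
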