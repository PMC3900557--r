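# ionsig

Sign-weighted gene-signature risk scoring and survival analysis for lung
adenocarcinoma, built around a 37-gene ion-channel signature.

## What this package is for

Ion channels regulate proliferation, apoptosis and migration in tumors,
and their transcriptional dysregulation carries prognostic information in
non-small cell lung cancer. `ionsig` implements the complete analysis
that turns that observation into a validated risk score:

1. **Differential-expression screening** — paired t-tests between matched
   normal/tumor tissue (or Welch t-tests between adenocarcinoma and
   squamous-cell carcinoma), Benjamini–Hochberg corrected, optionally
   restricted to a gene panel such as an ion-channel list.
2. **Signature construction and risk scoring** — each signature gene *i*
   gets the frozen weight sgn(log₂ *fc*ᵢ) from its discovery fold change,
   and a patient's score is

   *s* = Σᵢ sgn(log₂ *fc*ᵢ) · (*e*ᵢ − *μ*ᵢ) / *τ*ᵢ

   where *e*ᵢ is the patient's log2 expression of gene *i* and *μ*ᵢ, *τ*ᵢ
   are that gene's mean and SD across all samples of the scored cohort.
   Patients above the cohort-median score are signature-positive.
3. **Survival stratification** — Kaplan–Meier curves with log-rank tests,
   and univariate, continuous-score and multivariate Cox
   proportional-hazards models (Efron ties, Wald CIs) against age,
   gender, stage, smoking, Myc level and EGFR/KRAS/ALK mutation status.
4. **A resampling null** — the signature's summed Cox coefficient *Z*
   across cohorts is referenced against *B* random gene signatures of the
   same size, giving an empirical (add-one) p-value for whether its
   prognostic power exceeds chance.
5. **Cross-cohort validation** — correlation of log10 p-values and fold
   changes between cohorts, scaled PCA, Ward/Manhattan hierarchical
   clustering, and chi-square comparison of categorical (e.g. stage)
   distributions.
6. **A synthetic-cohort generator** — paired, two-subtype and
   proportional-hazards outcome simulators with exact truth tables, so
   every stage is testable end to end without external data.

The two published discovery tables ship as plain-text fixtures: the
37-gene normal-vs-tumor signature (`ilas_signature()`, 10 up / 27 down)
and the 30-gene adenocarcinoma-vs-squamous signature
(`subtype_signature()`, 21 up / 9 down).

## Worked example

Screen a synthetic discovery cohort, build a signature, and test it on an
independent survival cohort in which half the patients carry the planted
tumor profile at a true hazard ratio of 2:

```r
library(ionsig)

sig <- ilas_signature()
sig[sig$gene %in% c("ANO1", "KCNK5", "CLIC5"), ]
#>     gene weight discovery_fc
#> 1   ANO1     -1         0.48
#> 11 CLIC5     -1         0.06
#> 19 KCNK5      1         4.77

cfg  <- sim_config(n_genes = 500, n_de = 30, n_pairs = 60, seed = 42)
disc <- generate_paired(cfg)
de   <- de_screen(disc$cohort, design = "paired", alpha = 0.001)
nrow(de)
#> [1] 30                      # all 30 planted genes, no false positives
own  <- build_signature(de, source_cohort = "synthetic_discovery")

# validation cohort: 200 patients, half with the planted high-risk profile
set.seed(43)
carrier <- rep(0:1, length.out = 200)
expr <- rowMeans(disc$cohort$matrix) +
  outer(disc$truth$planted_log2fc, carrier) +
  matrix(rnorm(500 * 200, 0, 0.5), 500, 200)
dimnames(expr) <- list(disc$truth$gene, sprintf("V%03d", 1:200))
val    <- expression_cohort(expr, cohort_name = "validation")
clin   <- generate_survival(cfg, carrier, sample_ids = colnames(expr), seed = 44)

scores <- dichotomize(score_cohort(val, own))
km  <- km_logrank(clin$overall_time, clin$overall_event, scores$status)
fit <- cox_univariate(clin$overall_time, clin$overall_event, scores$status,
                      term = "status")
km$logrank_p
#> [1] 1.841084e-05
fit[, c("term", "hazard_ratio", "ci_low", "ci_high", "p")]
#>     term hazard_ratio   ci_low  ci_high            p
#> 1 status     2.133601 1.496754 3.041416 2.793843e-05
```

Signature-positive patients die at roughly twice the rate of
signature-negative patients — the planted hazard ratio of 2 is recovered
with a log-rank P of about 2×10⁻⁵. `run_pipeline()` chains all of these
stages (screen → signature → scoring → KM/Cox → smoking comparison →
resampling → subtype PCA/clustering) from one call with persisted TSV
intermediates.

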