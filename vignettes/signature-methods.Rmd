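---
title: "Methods: sign-weighted signature scoring and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sign-weighted signature scoring and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsig)
```

## The model

`ionsig` evaluates whether an expression signature — an ordered gene list
with frozen ±1 weights — stratifies survival in lung adenocarcinoma. The
score of a patient is a sign-weighted sum of standardized log2
expression values:

$$s \;=\; \sum_{i=1}^{n} \operatorname{sgn}(\log_2 fc_i)\,
  \frac{e_i - \mu_i}{\tau_i}$$

where $fc_i$ is gene $i$'s discovery-cohort fold change (tumor/normal on
the linear scale), $e_i$ the patient's log2 expression, and $\mu_i,
\tau_i$ the mean and sample SD of gene $i$ across **all samples of the
cohort being scored**. The weight convention encodes the working
hypothesis that genes up-regulated in tumors are adverse: a patient who
over-expresses the up-regulated genes and under-expresses the
down-regulated ones accumulates a high score, and higher scores are
assumed to imply worse outcome monotonically. Patients are dichotomized
at the cohort-median score (strictly greater = positive), which splits
each cohort into equal halves up to median ties.

Two consequences of the standardization are load-bearing and are tested
as exact identities: the cohort mean score is zero up to float error
(each standardized gene sums to zero), and the score is invariant to any
per-gene affine rescaling $e \mapsto a e + b$, $a > 0$, which is what
makes scoring well-defined across array platforms with different
per-gene offsets and scales.

### Design choices in the scoring rule

Several points are genuinely open in a verbal description of this score;
the package fixes them as follows.

* $\mu_i, \tau_i$ are recomputed inside every scored cohort, never
  carried over from the discovery cohort. This matches the formula's
  "across all samples" and makes cross-platform scoring well-defined;
  the cost is that a score is only comparable within a cohort.
* $\tau_i$ is the $n-1$ sample SD.
* Signature genes missing from a platform are dropped without rescaling
  the remaining sum; the dropped count is recorded on the result
  (`n_dropped`) because a 33-gene score and a 37-gene score are not on
  the same scale. Rescaling by $n_{\text{avail}}/n_{\text{total}}$ was
  considered and rejected: it would silently change the variance of the
  score without making cohorts comparable anyway.
* A fold change of exactly 1 gives weight 0; the gene is flagged and
  excluded from scoring rather than arbitrarily assigned a direction.
* Median ties are negative ("strictly greater than the median" defines
  positive), making dichotomization deterministic.

## Differential-expression screening

The discovery screen uses a paired t-test on per-patient tumor−normal
differences; the subtype screen uses Welch's unequal-variance two-sample
t-test (the safer default when equal variances cannot be assumed).
P-values are Benjamini–Hochberg adjusted **within the tested family**:
when the screen is restricted to a gene panel, BH runs over the panel
only, so the adjusted P matches a per-analysis false-discovery-rate
interpretation. Significance thresholds are strict inequalities
(adjusted P < 0.001 for the normal/tumor screen, < 0.05 for the subtype
screen, both configurable). Fold change is computed as
$2^{\bar a - \bar b}$ from log2 means — the ratio of geometric means on
the linear scale — because the input is log2-normalized expression;
whether to use arithmetic or geometric means is otherwise undecidable
from a printed fold-change table, and the geometric form is the natural
one for log-scale data.

Gene retention before any screen follows two microarray conventions:
keep genes "present" in at least a fraction (default 2/3, inclusive) of
samples, judged per cohort from a detection-call matrix; and exclude
chromosome X/Y genes to avoid gender confounding. Genes without
chromosome annotation are kept with a warning — dropping them silently
would conflate annotation gaps with biology.

## Survival models

Kaplan–Meier curves and the log-rank test come from the `survival`
package (`survfit`/`survdiff`); Cox models use `coxph` with the Efron
approximation for ties (more accurate than Breslow; the choice only
matters with heavy ties) and Wald confidence intervals and p-values,
matching the (HR, 95% CI, P) triplets such analyses report. Stage enters
the multivariate model as a single ordinal numeric term — one hazard
ratio per unit stage increase — rather than as dummy-coded levels, since
a single stage HR is what a compact multivariate table reports and the
ordinal trend is the quantity of clinical interest. The continuous-score
model additionally reports $\exp(\beta) - 1$, the per-point hazard
increase.

## The resampling null

Random signatures are known to stratify survival more often than chance
would naively suggest, so a significant log-rank P is weak evidence that
a *particular* signature is special. The package's non-randomness test
draws $B$ random signatures of the same size from a configurable gene
universe (default: all genes retained in the discovery cohort), weights
each by the **same** sign-of-fold-change rule as the real signature (the
fold changes come with the universe table), computes for each the sum
$Z$ of dichotomized-status Cox coefficients across the validation
cohorts, and reports the one-sided add-one empirical p
$(1 + \#\{Z_{\text{null}} \ge Z_{\text{obs}}\})/(B+1)$, bounded below by
$1/(B+1)$ and exactly $1/(B+1)$ when the observed $Z$ exceeds every null
draw. Weighting nulls by the same rule as the real signature is the
choice that makes the comparison fair — unweighted or randomly-weighted
nulls would be structurally handicapped; the rule is recorded in the
result's metadata.

## Cross-cohort and subtype validation

Reproducibility between two screens is summarized by the Pearson
correlation of log10 **raw** p-values (raw rather than adjusted, because
BH re-ranks nothing but rescales non-linearly with family size, which
would distort the correlation between cohorts of different sizes; the
column is selectable), the correlation of log2 fold changes, and the
fraction of genes with agreeing fold-change direction. Subtype structure
is visualized by PCA on the differential genes with per-gene unit
scaling (so high-variance genes do not dominate) and a deterministic
sign convention (the largest-magnitude loading of each component is
positive), and by agglomerative clustering with Ward linkage on
Manhattan distances — the classic expression-heatmap combination
(`hclust` method `"ward.D"`, the update rule historically paired with
non-squared distances). Stage distributions between cohorts are compared
with an uncorrected contingency chi-square.

## The synthetic-data generator

The generators emulate the statistical structure the analysis assumes,
at the study's scale:

* **Paired design** (`generate_paired`): gene baselines uniform on
  [4, 10] log2 units; normal samples
  $\mathcal N(\text{baseline}, \sigma)$, tumors
  $\mathcal N(\text{baseline} + \delta, \sigma)$ with $\sigma = 0.5$ by
  default and planted $|\delta| \in [1, 2]$ on `n_de` genes, signs
  alternating so both weight directions are exercised. Defaults are 60
  pairs and 30 planted genes among 500 — a discovery cohort of the size
  used in practice.
* **Two-subtype design** (`generate_two_subtypes`): the same planted
  structure between two independent groups; the default validation uses
  50 + 28 samples, matching a realistic adenocarcinoma/squamous split.
* **Outcomes** (`generate_survival`): exponential event times with rate
  $h_0 \exp(\beta s + \mathbf x^\top \boldsymbol\gamma)$ — the simplest
  model satisfying proportional hazards exactly, which is the property
  the Cox recovery tests need — with uniform censoring on
  $(0, \text{censor\_window})$ and covariates drawn from declared
  marginals (age $\mathcal N(65, 8)$, stage uniform on {1, 2, 3},
  smoking/gender Bernoulli(0.5), Myc Bernoulli(0.3), mutation
  Bernoulli(0.4)).

Every generator is a pure function of its config's seed; expression
generators additionally accept a `noise_seed` so replication cohorts can
share one planted truth with independent noise. Truth tables record the
planted effects exactly and are what recovery tests compare against.

What the generator deliberately does **not** model: probe-level effects,
background correction artifacts, batch effects, correlated gene modules,
non-proportional hazards, and informative censoring. Passing recovery
tests therefore demonstrates that the pipeline's statistics are
implemented correctly and have the advertised operating characteristics
under the assumed model — not that real microarray cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Expression TSVs are written with 17 significant digits so a
  write/read round trip is bit-exact.
* Zero-variance differences (paired test), constant covariates,
  all-censored outcomes, rank-deficient design matrices and
  zero-variance signature genes are all hard errors naming the offender;
  zero-variance genes in a PCA subset are dropped with a warning instead,
  because there the subset is auxiliary.
* Possible complete separation in a Cox fit (|coefficient| > 20) is
  flagged as a warning rather than an error, since `coxph` still returns
  a usable direction.
* Clinical time units are declared in the file header (`# time_unit:
  months`) and normalized to days at 30.4375 days/month.
* The presence-call threshold is inclusive ($\ge$), and is applied per
  cohort (not per tissue group) — with a per-cohort detection matrix
  this is the only unambiguous reading.

## Problem sizes used by the test suite

The suite exercises recovery at sizes chosen to make the expected
behavior near-certain rather than marginal: hazard-ratio recovery at
n = 2000 (sampling error of the log HR ≈ 0.05), the paired screen at 60
pairs with $|\delta| \ge 1$ and $\sigma = 0.5$ (per-gene power ≈ 1 at
adjusted P < 0.001), resampling-null calibration with 200 replicates of
B = 50 signatures, and exhaustive oracles (permutation log-rank,
brute-force partial likelihood, all bipartitions for Ward clustering) on
fixtures of 4–20 items where enumeration is exact.

## Known limitations

Scores are cohort-relative: the median split and the z-standardization
both depend on the cohort's composition, so a patient's status can
change if the surrounding cohort changes. The resampling null preserves
signature size but not the correlation structure among signature genes.
The multivariate model assumes proportional hazards for all covariates
and provides no diagnostics. None of the statistics here address
probe-to-gene mapping, normalization from raw arrays, or time-varying
covariates.
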