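# shared builders for small in-code fixtures

random_cohort <- function(n_genes = 10, n_samples = 6, seed = 1,
                          cohort_name = "toy") {
  set.seed(seed)
  mat <- matrix(rnorm(n_genes * n_samples, mean = 6),
                n_genes, n_samples,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
  expression_cohort(mat, cohort_name = cohort_name)
}

# exponential survival data with a binary covariate at a known hazard ratio
two_group_survival <- function(n, hr, seed, base_rate = 1 / 1000,
                               censor = 3000) {
  set.seed(seed)
  x <- rep(0:1, length.out = n)
  t_event <- rexp(n, base_rate * hr^x)
  t_cens <- runif(n, 0, censor)
  list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens),
       x = x)
}

# independent step-up implementation of Benjamini-Hochberg
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# hand-rolled log-rank chi-square (O-E form), independent of survdiff
logrank_stat <- function(time, event, group) {
  group <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d1 <- sum(event == 1 & time == t & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_tot
    if (n_tot > 1)
      v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  (o1 - e1)^2 / v
}

# negative log partial likelihood (Breslow form, valid when no ties)
neg_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# generalized Ward objective of a partition: per cluster, mean pairwise
# distance contribution sum_{i<j in C} d_ij / |C|
ward_partition_cost <- function(d, labels) {
  d <- as.matrix(d)
  sum(vapply(unique(labels), function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2) return(0)
    sum(d[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
  }, numeric(1)))
}
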