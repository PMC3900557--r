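test_that("the weight rule maps fold changes to signs", {
  de <- data.frame(gene = c("ANO1", "KCNK5", "FLAT"),
                   fold_change = c(0.48, 4.77, 1.0))
  expect_warning(sig <- build_signature(de), "FLAT")
  expect_identical(sig$weight[sig$gene == "ANO1"], -1L)
  expect_identical(sig$weight[sig$gene == "KCNK5"], 1L)
  expect_identical(sig$weight[sig$gene == "FLAT"], 0L)

  expect_error(build_signature(de[0, ]), "empty")
  expect_error(build_signature(data.frame(gene = "A", fold_change = -1)),
               "positive")
})

test_that("packaged discovery signatures reproduce the printed composition", {
  ilas <- ilas_signature()
  expect_equal(nrow(ilas), 37)
  expect_equal(sum(ilas$weight == 1L), 10)
  expect_equal(sum(ilas$weight == -1L), 27)

  sub <- subtype_signature()
  expect_equal(nrow(sub), 30)
  expect_equal(sum(sub$weight == 1L), 21)
  expect_equal(sum(sub$weight == -1L), 9)
})

test_that("scores follow the standardized sign-weighted formula", {
  # one +1-weighted gene with expression (-1, 0, 1): mean 0, sample SD 1,
  # so the patient exactly 1 SD above the mean scores +1
  m1 <- matrix(c(-1, 0, 1), 1, 3, dimnames = list("A", c("S1", "S2", "S3")))
  sig1 <- build_signature(data.frame(gene = "A", fold_change = 2))
  r1 <- score_cohort(expression_cohort(m1), sig1)
  expect_equal(r1$score, c(-1, 0, 1), tolerance = 1e-12)

  # the same gene with weight -1 flips every score
  sig_dn <- build_signature(data.frame(gene = "A", fold_change = 0.5))
  expect_equal(score_cohort(expression_cohort(m1), sig_dn)$score, c(1, 0, -1),
               tolerance = 1e-12)
})

test_that("a 3-gene x 4-patient worked example matches hand arithmetic", {
  mat <- matrix(c(1, 2, 3, 6,
                  4, 0, 2, 2,
                  5, 5, 7, 3), 3, 4, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), paste0("P", 1:4)))
  sig <- build_signature(data.frame(gene = c("A", "B", "C"),
                                    fold_change = c(2, 0.5, 2)))
  # independent arithmetic: z-scores per gene with sample SD, weights +1,-1,+1
  expected <- numeric(4)
  w <- c(1, -1, 1)
  for (j in 1:4) {
    s <- 0
    for (i in 1:3) {
      mu <- mean(mat[i, ]); tau <- sd(mat[i, ])
      s <- s + w[i] * (mat[i, j] - mu) / tau
    }
    expected[j] <- s
  }
  res <- score_cohort(expression_cohort(mat), sig)
  expect_equal(res$score, expected, tolerance = 1e-9)
  expect_equal(sum(res$score), 0, tolerance = 1e-9)
})

test_that("scoring errors and dropped genes are reported", {
  mat <- matrix(c(1, 2, 3, 3, 3, 3), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), paste0("S", 1:3)))
  sigAB <- build_signature(data.frame(gene = c("A", "B"),
                                      fold_change = c(2, 2)))
  expect_error(score_cohort(expression_cohort(mat), sigAB), "B")

  sigAZ <- build_signature(data.frame(gene = c("A", "Z"),
                                      fold_change = c(2, 2)))
  expect_message(res <- score_cohort(expression_cohort(mat[1, , drop = FALSE]),
                                     sigAZ), "Z")
  expect_equal(attr(res, "n_dropped"), 1)

  sigZ <- build_signature(data.frame(gene = "Z", fold_change = 2))
  expect_error(score_cohort(expression_cohort(mat), sigZ), "no signature gene")
})

test_that("median dichotomization uses the strict-greater tie rule", {
  mk <- function(s) {
    r <- data.frame(sample = paste0("S", seq_along(s)), score = s,
                    status = factor(rep(NA, length(s)),
                                    levels = c("negative", "positive")))
    class(r) <- c("RiskScoreResult", "data.frame")
    r
  }
  out <- dichotomize(mk(c(-2, -1, 1, 2)))
  expect_identical(as.character(out$status),
                   c("negative", "negative", "positive", "positive"))

  out <- dichotomize(mk(c(-1, 0, 2)))
  expect_identical(as.character(out$status[out$score == 0]), "negative")

  # counting property: positives can never exceed half the cohort, and the
  # split is exact when no score ties the median
  set.seed(23)
  for (i in 1:25) {
    s <- round(rnorm(sample(3:40, 1)), sample(0:2, 1))
    out <- dichotomize(mk(s))
    n_pos <- sum(out$status == "positive")
    expect_lte(n_pos, floor(length(s) / 2))
    if (!any(s == median(s)))
      expect_equal(n_pos, length(s) / 2)
    expect_true(all((out$score > median(s)) == (out$status == "positive")))
  }
  expect_error(dichotomize(mk(1)), "at least 2")
})

test_that("score symmetry and invariance properties hold", {
  cohort <- random_cohort(n_genes = 8, n_samples = 10, seed = 51)
  fc <- c(2, 0.5, 3, 0.25, 1.5, 0.8, 4, 0.1)
  de <- data.frame(gene = rownames(cohort$matrix), fold_change = fc)
  sig <- build_signature(de)
  res <- score_cohort(cohort, sig)
  expect_equal(mean(res$score), 0, tolerance = 1e-12)

  # inverting every fold change negates every score
  flipped <- build_signature(transform(de, fold_change = 1 / fold_change))
  res_f <- score_cohort(cohort, flipped)
  expect_equal(res_f$score, -res$score, tolerance = 1e-12)

  # per-gene affine rescaling (a*e + b, a > 0) leaves scores unchanged
  a <- runif(8, 0.5, 3); b <- rnorm(8)
  rescaled <- expression_cohort(cohort$matrix * a + b)
  res_r <- score_cohort(rescaled, sig)
  expect_equal(res_r$score, res$score, tolerance = 1e-9)

  # raising a +1-weighted gene (frozen cohort stats) raises that score
  gs <- attr(res, "gene_stats")
  g <- gs$gene[gs$weight == 1][1]
  bumped <- cohort$matrix
  bumped[g, 3] <- bumped[g, 3] + 1
  manual <- sum(gs$weight * (bumped[gs$gene, 3] - gs$mu) / gs$tau)
  expect_gt(manual, res$score[3])
})
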