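test_that("per-sequence summaries match their defining scales", {
  s <- sequenceSummaries("V")
  expect_equal(s$gravy, 4.2)            # Kyte-Doolittle value of valine
  expect_equal(s$bulkiness, 21.57)      # Zimmerman
  expect_equal(s$polarity, 5.9)         # Grantham
  expect_equal(sequenceSummaries("FWY")$aromaticity, 1)
  expect_equal(sequenceSummaries("AAA")$aromaticity, 0)
  expect_equal(sequenceSummaries("CASSF")$cdr3_length, 5L)
  expect_equal(sequenceSummaries("DE")$acidity, 1)
  expect_equal(sequenceSummaries("KRH")$basicity, 1)
  # aliphatic index, Ikai formula on residue fractions
  expect_equal(sequenceSummaries("AVIL")$aliphatic_index,
               (1 + 2.9 + 3.9 * 2) / 4)
  # net side-chain charge at pH 7: R positive, D negative, G neutral
  expect_gt(sequenceSummaries("R")$charge, 0.9)
  expect_lt(sequenceSummaries("D")$charge, -0.9)
  expect_equal(sequenceSummaries("G")$charge, 0)
  expect_error(sequenceSummaries(""), "empty")
})

test_that("l1 divergence satisfies its identities", {
  p <- c(a = 0.5, b = 0.5, c = 0)
  expect_equal(l1Divergence(p, p), 0)
  expect_equal(l1Divergence(c(a = 1, b = 0), c(a = 0, b = 1)), 2)
  expect_equal(l1Divergence(c(a = 0.5, b = 0.5), c(a = 1, b = 0)), 1)
  expect_error(l1Divergence(c(a = 1), c(b = 1)), "mismatched support")
})

test_that("Jensen-Shannon divergence is symmetric, bounded and zero iff equal", {
  expect_equal(jsDivergence(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 0)
  expect_equal(jsDivergence(c(a = 1, b = 0), c(a = 0, b = 1)), log(2))
  set.seed(4)
  for (i in 1:5) {
    p <- prop.table(runif(6)); q <- prop.table(runif(6))
    names(p) <- names(q) <- letters[1:6]
    expect_equal(jsDivergence(p, q), jsDivergence(q, p))
    expect_gt(jsDivergence(p, q), 0)
    expect_lt(jsDivergence(p, q), log(2))
  }
})

test_that("a repertoire compared with itself has zero divergence on all 15 stats", {
  df <- sampleTriples(defaultRecombSpec(), 400L, seed = 5L)
  rep <- divergenceReport(df, df, seed = 2L)
  expect_equal(nrow(rep), 15L)
  expect_setequal(rep$statistic, c(
    "acidity", "aliphatic_index", "aromaticity", "basicity", "bulkiness",
    "cdr3_length", "charge", "gravy", "polarity",
    "nearest_neighbor_levenshtein", "pairwise_levenshtein",
    "cdr3_2mer_freq", "cdr3_aa_freq", "j_gene_freq", "v_gene_freq"))
  expect_equal(sum(rep$kind == "js"), 11L)
  expect_equal(sum(rep$kind == "l1"), 4L)
  expect_true(all(rep$divergence == 0))
})

test_that("divergences are symmetric because bins come from the pooled pair", {
  a <- sampleTriples(defaultRecombSpec(), 300L, seed = 6L)
  b <- sampleTriples(defaultRecombSpec(), 300L, seed = 7L)
  r1 <- divergenceReport(a, b, seed = 3L)
  r2 <- divergenceReport(b, a, seed = 3L)
  expect_equal(r1$divergence, r2$divergence)
})

test_that("the log-log frequency fit recovers exact linear relations", {
  fit <- cohortFrequencyFit(c(0, 2, 4), c(0, 1, 2))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  shifted <- cohortFrequencyFit(log(c(1, 2, 4, 8)) + 3, log(c(1, 2, 4, 8)))
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$r_squared, 1)
  # constant predictor: R^2 = 0 by convention
  expect_equal(cohortFrequencyFit(c(1, 2, 3), c(5, 5, 5))$r_squared, 0)
  # non-finite pairs are dropped and counted
  fit2 <- cohortFrequencyFit(c(0, 2, 4, 1), c(0, 1, 2, -Inf))
  expect_equal(fit2$n_dropped, 1L)
  expect_equal(fit2$n_used, 3L)
  expect_error(cohortFrequencyFit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("latent PCA centers, is orthonormal and finds 1-D structure", {
  set.seed(9)
  t1 <- rnorm(50)
  X <- outer(t1, runif(20)) + matrix(rnorm(50 * 20, sd = 1e-4), 50)
  pca <- latentPca(X, labels = rep(c("a", "b"), 25))
  expect_equal(colMeans(pca$projection), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  expect_equal(crossprod(pca$rotation), diag(2), ignore_attr = TRUE)
  expect_gt(pca$explained_variance_ratio[1], 0.999)
  expect_length(pca$labels, 50L)
  expect_error(latentPca(X[1, , drop = FALSE]), "at least 2")
})
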