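test_that("key marginal estimation prefers exact marginals and matches MC", {
  sp <- toySpec()
  exact <- estimateKeyMarginals(sp)
  expect_identical(exact, keyMarginals(sp))
  # Monte Carlo route (forced by hiding the exact method behind a plain df)
  s <- sampleTriples(sp, 1e5, seed = 2L)
  emp <- tcrvae:::empiricalKeyFreq(s)
  m <- merge(exact, emp, by = c("v_gene", "j_gene", "cdr3_length"),
             suffixes = c("_exact", "_mc"), all.x = TRUE)
  m$probability_mc[is.na(m$probability_mc)] <- 0
  expect_lt(sum(abs(m$probability_exact - m$probability_mc)), 0.02)
  expect_error(estimateKeyMarginals(sp, n_samples = 0), "n_samples")
})

test_that("Q estimation is the truncated frequency ratio", {
  sp <- toySpec()
  km <- keyMarginals(sp)
  # build training data with known empirical key frequencies:
  # 200 draws of key1, 800 of an impossible composition for the model?  use
  # direct ratio checks instead on constructed data
  k1 <- km[1, ]; k2 <- km[2, ]
  mk <- function(key, n) data.frame(
    amino_acid = strrep("A", key$cdr3_length), v_gene = key$v_gene,
    j_gene = key$j_gene)[rep(1, n), ]
  train <- rbind(mk(k1, 20L), mk(k2, 80L))
  qt <- fitQ(train, sp, marginals = km)
  expect_equal(tcrvae:::qLookup(qt, k1$v_gene, k1$j_gene, k1$cdr3_length),
               0.2 / k1$probability)
  expect_equal(tcrvae:::qLookup(qt, k2$v_gene, k2$j_gene, k2$cdr3_length),
               0.8 / k2$probability)
  # ratios beyond the truncation bound are stored as qMax
  rare <- km[which.min(km$probability), ]
  qt2 <- fitQ(mk(rare, 100L), sp, marginals = km)
  expect_equal(qt2@table$q, min(1 / rare$probability, 100))
  expect_equal(qt2@table$q, 100)
  # unseen keys follow the unseen policy
  expect_equal(tcrvae:::qLookup(qt, k1$v_gene, k1$j_gene, 29L), 0)
  qt3 <- fitQ(train, sp, marginals = km, unseenQ = 0.5)
  expect_equal(tcrvae:::qLookup(qt3, k1$v_gene, k1$j_gene, 29L), 0.5)
  expect_error(fitQ(train[0, ], sp), "empty")
})

test_that("keys unexplainable by the model get qMax with a warning", {
  sp <- toySpec()
  km <- keyMarginals(sp)
  odd <- data.frame(amino_acid = strrep("A", 25), v_gene = "V1", j_gene = "J1")
  expect_warning(qt <- fitQ(odd, sp, marginals = km), "zero model")
  expect_equal(tcrvae:::qLookup(qt, "V1", "J1", 25L), 100)
})

test_that("scores are pgen times Q, with a normalizing helper", {
  sp <- toySpec()
  km <- keyMarginals(sp)
  ones <- qTable(data.frame(km[c("v_gene", "j_gene", "cdr3_length")], q = 1))
  df <- sampleTriples(sp, 50L, seed = 3L)
  expect_equal(scoreTriples(df, sp, ones), pgen(sp, df))
  zero <- qTable(data.frame(km[c("v_gene", "j_gene", "cdr3_length")], q = 0))
  expect_true(all(scoreTriples(df, sp, zero) == 0))
  ns <- normalizeScores(scoreTriples(df, sp, ones))
  expect_equal(sum(ns), 1)
  expect_error(normalizeScores(c(0, 0)), "sum to zero")
})

test_that("stored Q never exceeds qMax regardless of input", {
  expect_error(qTable(data.frame(v_gene = "V1", j_gene = "J1",
                                 cdr3_length = 5L, q = 120), qMax = 100),
               "exceed qMax")
  sp <- toySpec()
  s <- sampleTriples(sp, 2000L, seed = 8L)
  qt <- fitQ(s, sp, qMax = 1.5)
  expect_true(all(qt@table$q <= 1.5))
})

test_that("rejection sampling accepts at rate Q/qMax and is deterministic", {
  sp <- toySpec()
  km <- keyMarginals(sp)
  half <- qTable(data.frame(km[c("v_gene", "j_gene", "cdr3_length")],
                            q = km$probability * 0 + 1), qMax = 2)
  # Q constant at qMax/2: every key accepted with probability 1/2, so the
  # output distribution equals the provider's; check acceptance indirectly
  # through the proposal stream consumed for a fixed output size
  s <- rejectionSample(sp, half, 1e5, seed = 6L)
  expect_equal(nrow(s), 1e5)
  emp <- tcrvae:::empiricalKeyFreq(s)
  m <- merge(km, emp, by = c("v_gene", "j_gene", "cdr3_length"),
             suffixes = c("_exact", "_emp"), all.x = TRUE)
  m$probability_emp[is.na(m$probability_emp)] <- 0
  expect_lt(sum(abs(m$probability_exact - m$probability_emp)), 0.02)
  expect_identical(rejectionSample(sp, half, 300L, seed = 7L),
                   rejectionSample(sp, half, 300L, seed = 7L))
  # acceptance floor triggers a helpful error
  never <- qTable(data.frame(km[c("v_gene", "j_gene", "cdr3_length")],
                             q = rep(1e-5, nrow(km))), qMax = 100)
  expect_error(rejectionSample(sp, never, 50L, seed = 1L), "smaller qMax")
})

test_that("QTable serialization round-trips through CSV and JSON", {
  qt <- qTable(data.frame(v_gene = c("V1", "V2"), j_gene = "J1",
                          cdr3_length = c(5L, 6L), q = c(1.5, 0.25)),
               qMax = 10, unseenQ = 0.1)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeQTable(qt, csv)
  b1 <- readQTable(csv, qMax = 10, unseenQ = 0.1)
  expect_equal(b1@table, qt@table)
  js <- withr::local_tempfile(fileext = ".json")
  writeQTable(qt, js)
  b2 <- readQTable(js)
  expect_equal(b2@table, qt@table, ignore_attr = TRUE)
  expect_equal(b2@qMax, 10)
  expect_equal(b2@unseenQ, 0.1)
})
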