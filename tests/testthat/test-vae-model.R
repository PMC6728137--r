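test_that("KL divergence matches the closed form and a sampling oracle", {
  L <- 4L
  expect_equal(klDivergence(list(mean = rep(0, L), log_variance = rep(0, L))), 0)
  expect_equal(klDivergence(list(mean = 1, log_variance = 0)), 0.5)
  # Monte Carlo oracle: E_q[log q - log p] on random parameters
  set.seed(8)
  mu <- rnorm(3); lv <- rnorm(3, sd = 0.5)
  n <- 1e5
  z <- matrix(rnorm(n * 3), n) * rep(exp(lv / 2), each = n) + rep(mu, each = n)
  lq <- rowSums(dnorm(z, mean = rep(mu, each = n), sd = rep(exp(lv / 2), each = n),
                      log = TRUE))
  lp <- rowSums(dnorm(z, log = TRUE))
  mc <- mean(lq - lp)
  se <- sd(lq - lp) / sqrt(n)
  expect_lt(abs(klDivergence(list(mean = mu, log_variance = lv)) - mc), 3 * se)
  expect_error(klDivergence(list(mean = NaN, log_variance = 0)), "non-finite")
})

test_that("germline match counts are maximal contiguous end matches", {
  germ <- data.frame(gene = c("V1", "J1"), segment = c("V", "J"),
                     cdr3_seq = c("CASS", "NVLTF"))
  mc <- function(aa) germlineMatchCounts(
    data.frame(amino_acid = aa, v_gene = "V1", j_gene = "J1"), germ)
  expect_equal(mc("CASSFNVLTF"), data.frame(v_match = 4L, j_match = 5L))
  expect_equal(mc("CGSSF")$v_match, 1L)       # stops at first mismatch
  expect_equal(mc("CASSF")$j_match, 1L)
  expect_equal(mc("QQ"), data.frame(v_match = 0L, j_match = 0L))
})

test_that("reconstruction loss identities hold", {
  model <- tinyModel("basic")
  reg <- model@registry
  x <- data.frame(amino_acid = "CASSF", v_gene = "V1", j_gene = "J1")
  X <- encodeTriples(x, reg)
  # decoder that puts probability 1 on every true symbol
  perfect <- list(
    v_probs = as.numeric(X[1, 631:632]), j_probs = as.numeric(X[1, 633:634]),
    cdr3_probs = matrix(X[1, 1:630], 30, 21, byrow = TRUE))
  expect_equal(reconstructionLoss(X, perfect, model@config, model), 0)
  uniform <- list(v_probs = rep(1 / 2, 2), j_probs = rep(1 / 2, 2),
                  cdr3_probs = matrix(1 / 21, 30, 21))
  expect_equal(reconstructionLoss(X, uniform, model@config, model),
               log(2) + log(2) + log(21))  # CDR3 term is exactly log 21
  # unnormalized probabilities are rejected
  broken <- uniform; broken$v_probs <- c(0.7, 0.7)
  expect_error(reconstructionLoss(X, broken, model@config, model),
               "not normalized")
})

test_that("count_match adds exactly-zero squared terms for perfect predictions", {
  model <- tinyModel("count_match")
  x <- data.frame(amino_acid = "CASSF", v_gene = "V1", j_gene = "J1")
  X <- encodeTriples(x, model@registry)
  mc <- germlineMatchCounts(x, model@germline)
  perfect <- list(
    v_probs = as.numeric(X[1, 631:632]), j_probs = as.numeric(X[1, 633:634]),
    cdr3_probs = matrix(X[1, 1:630], 30, 21, byrow = TRUE),
    predicted_match = c(mc$v_match, mc$j_match), predicted_length = 5)
  expect_equal(reconstructionLoss(X, perfect, model@config, model, triples = x), 0)
  off <- perfect; off$predicted_length <- 7
  expect_equal(reconstructionLoss(X, off, model@config, model, triples = x), 4)
})

test_that("total loss is reconstruction plus beta KL, monotone in beta", {
  model <- tinyModel("basic")
  x <- data.frame(amino_acid = "CATTF", v_gene = "V2", j_gene = "J2")
  X <- encodeTriples(x, model@registry)
  enc <- vaeEncode(model, X)
  out <- vaeDecode(model, enc$mean)
  r <- reconstructionLoss(X, out, model@config, model)
  expect_equal(totalLoss(X, enc, out, model@config, model, beta = 0), r)
  betas <- c(0, 0.25, 0.75, 2)
  tl <- vapply(betas, function(b)
    totalLoss(X, enc, out, model@config, model, beta = b), numeric(1))
  expect_true(all(diff(tl) > 0))  # KL > 0 here
  # perfect reconstruction with prior-matched encoder gives 0
  perfect <- list(v_probs = as.numeric(X[1, 631:632]),
                  j_probs = as.numeric(X[1, 633:634]),
                  cdr3_probs = matrix(X[1, 1:630], 30, 21, byrow = TRUE))
  prior <- list(mean = rep(0, 3), log_variance = rep(0, 3))
  expect_equal(totalLoss(X, prior, perfect, model@config, model, beta = 0.75), 0)
})

test_that("conditional log-probability is a normalized product of categoricals", {
  model <- tinyModel("basic")
  reg <- model@registry
  x <- data.frame(amino_acid = "CASSF", v_gene = "V1", j_gene = "J1")
  X <- encodeTriples(x, reg)
  perfect <- list(v_probs = c(1, 0), j_probs = c(1, 0),
                  cdr3_probs = matrix(X[1, 1:630], 30, 21, byrow = TRUE))
  expect_equal(conditionalLogProb(X, perfect, model), 0)
  uniform <- list(v_probs = rep(1 / 2, 2), j_probs = rep(1 / 2, 2),
                  cdr3_probs = matrix(1 / 21, 30, 21))
  expect_equal(conditionalLogProb(X, uniform, model),
               log(1 / 2) + log(1 / 2) + 30 * log(1 / 21))
  # zero probability on an observed symbol returns -Inf, no exception
  zeroed <- perfect; zeroed$v_probs <- c(0, 1)
  expect_identical(conditionalLogProb(X, zeroed, model), -Inf)

  # brute-force normalization: free distributions on two sites (all other
  # sites concentrated on gap), summed over every (site1, site30, V, J)
  set.seed(3)
  p1 <- prop.table(runif(21)); p30 <- prop.table(runif(21))
  cp <- matrix(0, 30, 21); cp[, 21] <- 1
  cp[1, ] <- p1; cp[30, ] <- p30
  pv <- prop.table(runif(2)); pj <- prop.table(runif(2))
  out <- list(v_probs = pv, j_probs = pj, cdr3_probs = cp)
  total <- 0
  for (c1 in 1:21) for (c30 in 1:21) for (v in 1:2) for (j in 1:2) {
    xf <- numeric(634)
    xf[(1:30 - 1) * 21 + 21] <- 1            # gaps everywhere...
    xf[(1 - 1) * 21 + 21] <- 0; xf[(1 - 1) * 21 + c1] <- 1    # ...except site 1
    xf[(30 - 1) * 21 + 21] <- 0; xf[(30 - 1) * 21 + c30] <- 1 # ...and site 30
    xf[630 + v] <- 1; xf[632 + j] <- 1
    total <- total + exp(conditionalLogProb(matrix(xf, 1), out, model))
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("generation is deterministic under argmax and respects the registry", {
  model <- tinyModel("basic")
  z <- matrix(rnorm(10 * 3, 0, 2), 10)
  g1 <- generateTcrs(model, 10L, seed = 2L, mode = "argmax", z = z)
  g2 <- generateTcrs(model, 10L, seed = 9L, mode = "argmax", z = z)
  expect_identical(g1, g2)
  s <- generateTcrs(model, 200L, seed = 3L)
  expect_true(all(s$v_gene %in% vGenes(model@registry)))
  expect_true(all(s$j_gene %in% jGenes(model@registry)))
  expect_true(all(nchar(s$amino_acid) >= 1L))
})

test_that("sampling frequencies follow a concentrated decoder", {
  model <- tinyModel("basic")
  # make the decoder ignore z and emit one fixed triple
  X <- encodeTriples(data.frame(amino_acid = "CASTF", v_gene = "V2",
                                j_gene = "J1"), model@registry)
  model@params$U1[] <- 0
  model@params$U2[] <- 0
  big <- 50
  model@params$cv <- big * as.numeric(X[1, 631:632])
  model@params$cj <- big * as.numeric(X[1, 633:634])
  model@params$cc <- big * as.numeric(X[1, 1:630])
  for (mode in c("sample", "argmax")) {
    g <- generateTcrs(model, 5L, seed = 4L, mode = mode)
    expect_true(all(g$amino_acid == "CASTF" & g$v_gene == "V2" & g$j_gene == "J1"))
  }
})

test_that("model serialization round-trips and fails loudly on mismatch", {
  model <- tinyModel("count_match")
  prefix <- withr::local_tempfile()
  saveVae(model, prefix)
  back <- loadVae(prefix)
  expect_equal(back@params, model@params)
  expect_equal(back@config, model@config)
  df <- sampleTriples(toySpec(), 5L, seed = 1L)
  expect_equal(logPvae(df, back, 20L, seed = 2L),
               logPvae(df, model, 20L, seed = 2L))
  # corrupt the weights file: length mismatch must be detected
  writeLines(c("0.1", "0.2"), paste0(prefix, ".weights"))
  expect_error(loadVae(prefix), "metadata implies")
})

test_that("reparameterized encoder draws have the posterior's moments", {
  model <- tinyModel("basic")
  df <- data.frame(amino_acid = "CASSF", v_gene = "V1", j_gene = "J1")
  enc <- vaeEncode(model, df)
  set.seed(11)
  n <- 2e4
  eps <- matrix(rnorm(n * 3), n)
  z <- sweep(sweep(eps, 2, exp(enc$log_variance[1, ] / 2), "*"), 2,
             enc$mean[1, ], "+")
  sdz <- exp(enc$log_variance[1, ] / 2)
  expect_true(all(abs(colMeans(z) - enc$mean[1, ]) < 4 * sdz / sqrt(n)))
  expect_true(all(abs(apply(z, 2, var) / sdz^2 - 1) < 0.05))
})
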