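test_that("the beta schedule starts at 0, rises linearly and clamps", {
  cfg <- trainConfig(beta_final = 0.75, warmup_epochs = 20L)
  expect_equal(betaSchedule(0L, cfg), 0)
  expect_equal(betaSchedule(10L, cfg), 0.375)  # half-way
  expect_equal(betaSchedule(20L, cfg), 0.75)
  expect_equal(betaSchedule(500L, cfg), 0.75)
  expect_equal(betaSchedule(0L, trainConfig(warmup_epochs = 0L)), 0.75)
})

test_that("analytic gradients match finite differences for both model kinds", {
  sp <- toySpec()
  df <- sampleTriples(sp, 4L, seed = 2L)
  for (kind in c("basic", "count_match")) {
    model <- tinyModel(kind)
    tens <- tcrvae:::trainTensors(df, model)
    eps <- withr::with_seed(6, matrix(rnorm(4 * 3), 4))
    gr <- tcrvae:::vaeGradients(model, tens, 1:4, beta = 0.7, eps)
    set.seed(13)
    for (nm in c("Wa", "Wv", "W1", "Wmu", "Wlv", "U1", "Uc", "cv", "b2")) {
      p0 <- model@params[[nm]]
      for (k in sample(length(p0), min(3L, length(p0)))) {
        h <- 1e-5
        up <- model; up@params[[nm]][k] <- p0[k] + h
        dn <- model; dn@params[[nm]][k] <- p0[k] - h
        num <- (tcrvae:::vaeGradients(up, tens, 1:4, 0.7, eps, wantGrads = FALSE)$loss -
                tcrvae:::vaeGradients(dn, tens, 1:4, 0.7, eps, wantGrads = FALSE)$loss) /
               (2 * h)
        expect_equal(gr$grads[[nm]][k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("a tiny model memorizes a repeated sequence at beta 0", {
  df <- data.frame(amino_acid = "CASSF", v_gene = "V1", j_gene = "J1")[rep(1, 200), ]
  fit <- trainVae(df,
    modelConfig = vaeConfig("basic", latent_dim = 2L, hidden_dims = c(20L, 20L),
                            v_embedding_dim = 4L),
    config = trainConfig(beta_final = 0, warmup_epochs = 0L,
                         n_pretrain_phases = 1L, pretrain_epochs = 3L,
                         max_epochs = 40L, patience = 10L, seed = 5L),
    registry = toyReg())
  expect_lt(fit$report@bestValLoss, 0.1)
  g <- generateTcrs(fit$model, 3L, seed = 1L, mode = "argmax",
                    z = vaeEncode(fit$model, df[1:3, ])$mean)
  expect_true(all(g$amino_acid == "CASSF"))
})

test_that("training is deterministic and restores the best checkpoint", {
  df <- sampleTriples(toySpec(), 60L, seed = 3L)
  run <- function() trainVae(df,
    modelConfig = vaeConfig("basic", latent_dim = 2L, hidden_dims = c(10L, 10L),
                            v_embedding_dim = 4L),
    config = trainConfig(n_pretrain_phases = 2L, pretrain_epochs = 2L,
                         warmup_epochs = 4L, max_epochs = 12L, patience = 3L,
                         batch_size = 20L, seed = 7L),
    registry = toyReg())
  f1 <- run(); f2 <- run()
  expect_identical(f1$report@history, f2$report@history)
  expect_identical(f1$model@params, f2$model@params)
  # restored checkpoint attains the minimum validation loss observed in the
  # full run and the carried-over end of the chosen pre-training phase
  hist <- f1$report@history
  full <- hist[hist$phase == 0L, ]
  carried <- hist[hist$phase == f1$report@chosenPhase, ]
  carried <- carried$val_loss[which.max(carried$epoch)]
  expect_equal(f1$report@bestValLoss, min(c(full$val_loss, carried)))
  expect_true(f1$report@chosenPhase %in% c(1L, 2L))
  expect_true(f1$model@trained)
})

test_that("early stopping waits exactly `patience` epochs past the best epoch", {
  df <- sampleTriples(toySpec(), 60L, seed = 4L)
  fit <- trainVae(df,
    modelConfig = vaeConfig("basic", latent_dim = 2L, hidden_dims = c(8L, 8L),
                            v_embedding_dim = 4L),
    config = trainConfig(n_pretrain_phases = 1L, pretrain_epochs = 1L,
                         warmup_epochs = 0L, max_epochs = 400L, patience = 3L,
                         batch_size = 20L, seed = 8L),
    registry = toyReg())
  hist <- fit$report@history
  full <- hist[hist$phase == 0L, ]
  carried <- hist$val_loss[hist$phase == fit$report@chosenPhase]
  carried <- carried[length(carried)]
  if (fit$report@stoppingEpoch < 400L && min(full$val_loss) < carried) {
    bestEpoch <- full$epoch[which.min(full$val_loss)]
    expect_equal(fit$report@stoppingEpoch, bestEpoch + 3L)
  }
})

test_that("loss-weight regression recovers exact linear combinations", {
  set.seed(2)
  C <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  w <- c(a = 1.5, b = 0.25, c = 3)
  fitted <- fitLossWeights(C, as.numeric(C %*% w))
  expect_equal(fitted, w, tolerance = 1e-6)
  # single component proportional to the target gives the scalar ratio
  expect_equal(unname(fitLossWeights(C[, 1, drop = FALSE], 2.5 * C[, 1])), 2.5,
               tolerance = 1e-8)
  expect_error(fitLossWeights(cbind(C, a2 = C[, 1]), rowSums(C)), "collinear")
  expect_warning(w2 <- fitLossWeights(C, as.numeric(C %*% c(1, -2, 1))),
                 "clipped")
  expect_true(all(w2 >= 0))
})

test_that("the beta sweep trains one independent model per grid value", {
  expect_equal(seq(0.625, 1, length.out = 7)[4], 0.8125)  # grid midpoint sanity
  df <- sampleTriples(toySpec(), 50L, seed = 5L)
  sw <- betaSweep(df, betas = c(0.625, 1),
    modelConfig = vaeConfig("basic", latent_dim = 2L, hidden_dims = c(8L, 8L),
                            v_embedding_dim = 4L),
    config = trainConfig(n_pretrain_phases = 1L, pretrain_epochs = 1L,
                         warmup_epochs = 2L, max_epochs = 4L, patience = 2L,
                         batch_size = 25L, seed = 6L),
    registry = toyReg())
  expect_equal(sw$summary$beta, c(0.625, 1))
  expect_length(sw$fits, 2L)
  expect_false(identical(sw$fits[[1]]$model@params, sw$fits[[2]]$model@params))
})

test_that("per-sequence loss components feed the weight regression", {
  model <- tinyModel("count_match")
  df <- sampleTriples(toySpec(), 30L, seed = 9L)
  comp <- lossComponents(model, df, seed = 1L)
  expect_named(comp, c("ce_v", "ce_j", "ce_cdr3", "kl", "sq_match", "sq_length"))
  expect_true(all(comp >= 0))
  target <- as.numeric(as.matrix(comp) %*% rep(1, 6))
  w <- fitLossWeights(comp, target)
  expect_equal(unname(w), rep(1, 6), tolerance = 1e-6)
})
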