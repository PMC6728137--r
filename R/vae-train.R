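# Training protocol: validation split, linear beta warm-up, pre-training
# phases with restart selection, early stopping with best-checkpoint
# restore, Adam. Gradients are computed analytically (backpropagation
# written out on the matrix forward pass of vae-model.R).

#' Training configuration
#'
#' @param beta_final final KL weight after warm-up (default 0.75).
#' @param warmup_epochs epochs over which beta rises linearly from 0.
#' @param n_pretrain_phases short runs from fresh random weights; the one
#'   with the best validation loss seeds the full run.
#' @param pretrain_epochs epochs per pre-training phase.
#' @param max_epochs cap on the full run.
#' @param patience epochs without validation improvement before stopping.
#' @param validation_fraction fraction of the data held out for the
#'   validation loss.
#' @param learning_rate,adam_beta1,adam_beta2,adam_eps Adam settings.
#' @param batch_size minibatch size.
#' @param seed master seed; the data split, per-phase weight draws and
#'   epoch shuffles use hierarchically derived sub-seeds so each is
#'   independently reproducible.
#' @return a configuration list.
#' @export
trainConfig <- function(beta_final = 0.75, warmup_epochs = 20L,
                        n_pretrain_phases = 3L, pretrain_epochs = 10L,
                        max_epochs = 500L, patience = 20L,
                        validation_fraction = 0.1,
                        learning_rate = 1e-3, adam_beta1 = 0.9,
                        adam_beta2 = 0.999, adam_eps = 1e-8,
                        batch_size = 100L, seed = 1L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1, patience >= 1L,
            beta_final >= 0)
  list(beta_final = beta_final, warmup_epochs = as.integer(warmup_epochs),
       n_pretrain_phases = as.integer(n_pretrain_phases),
       pretrain_epochs = as.integer(pretrain_epochs),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       validation_fraction = validation_fraction,
       learning_rate = learning_rate, adam_beta1 = adam_beta1,
       adam_beta2 = adam_beta2, adam_eps = adam_eps,
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

#' KL-annealing schedule
#'
#' beta is 0 at epoch 0, rises linearly each epoch, and is clamped at
#' `beta_final` from `warmup_epochs` onwards.
#'
#' @param epoch epoch index (0-based).
#' @param config a [trainConfig()].
#' @return the beta value in force at `epoch`.
#' @export
betaSchedule <- function(epoch, config) {
  stopifnot(all(epoch >= 0))
  if (config$warmup_epochs <= 0L) return(rep(config$beta_final, length(epoch)))
  pmin(epoch / config$warmup_epochs, 1) * config$beta_final
}

# Pre-encoded training tensors for a triple data.frame.
trainTensors <- function(df, model) {
  X <- encodeTriples(df, model@registry)
  out <- list(X = X, n = nrow(X))
  if (model@config$model_kind == "count_match") {
    out$G <- germBlock(df, model@germline, model@config$germline_width)
    mc <- germlineMatchCounts(df, model@germline)
    out$mTrue <- as.matrix(mc)
    out$lTrue <- nchar(df$amino_acid)
  }
  out
}

# Loss (and optionally gradients) of one minibatch. `eps` is the matrix of
# standard-normal reparameterization draws.
vaeGradients <- function(model, tens, idx, beta, eps, wantGrads = TRUE) {
  p <- model@params
  cfg <- model@config
  d <- vaeDims(cfg, model@registry)
  Xb <- tens$X[idx, , drop = FALSE]
  n <- nrow(Xb)
  w <- cfg$loss_weights
  enc <- encoderForward(model, Xb)
  sdz <- exp(0.5 * enc$lv)
  z <- enc$mu + sdz * eps
  Zin <- if (cfg$model_kind == "count_match") {
    cbind(z, tens$G[idx, , drop = FALSE])
  } else z
  dec <- decoderForward(model, Zin)
  Tv <- Xb[, d$dCdr3 + seq_len(d$nv), drop = FALSE]
  Tj <- Xb[, d$dCdr3 + d$nv + seq_len(d$nj), drop = FALSE]
  TcS <- toSites(Xb[, seq_len(d$dCdr3), drop = FALSE], n)
  tiny <- 1e-12
  ceV <- -log(pmax(rowSums(dec$pv * Tv), tiny))
  ceJ <- -log(pmax(rowSums(dec$pj * Tj), tiny))
  ceC <- rowSums(matrix(-log(pmax(rowSums(dec$pcSites * TcS), tiny)), nrow = n)) / cdr3Width
  recon <- w[["v"]] * ceV + w[["j"]] * ceJ + w[["cdr3"]] * ceC
  if (cfg$model_kind == "count_match") {
    mT <- tens$mTrue[idx, , drop = FALSE]
    lT <- tens$lTrue[idx]
    recon <- recon + w[["match"]] * rowSums((dec$mhat - mT)^2) +
      w[["length"]] * (dec$lhat[, 1L] - lT)^2
  }
  kl <- 0.5 * rowSums(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
  loss <- mean(recon) + beta * mean(kl)
  if (!wantGrads) return(list(loss = loss))

  g <- list()
  dLv <- w[["v"]] * (dec$pv - Tv) / n
  dLj <- w[["j"]] * (dec$pj - Tj) / n
  dLc <- fromSites(w[["cdr3"]] / cdr3Width * (dec$pcSites - TcS) / n, n)
  g$Uv <- crossprod(dec$G2, dLv); g$cv <- colSums(dLv)
  g$Uj <- crossprod(dec$G2, dLj); g$cj <- colSums(dLj)
  g$Uc <- crossprod(dec$G2, dLc); g$cc <- colSums(dLc)
  dG2 <- tcrossprod(dLv, p$Uv) + tcrossprod(dLj, p$Uj) + tcrossprod(dLc, p$Uc)
  if (cfg$model_kind == "count_match") {
    dmh <- 2 * w[["match"]] * (dec$mhat - mT) / n
    dlh <- 2 * w[["length"]] * (dec$lhat - cbind(lT)) / n
    g$Um <- crossprod(dec$G2, dmh); g$cm <- colSums(dmh)
    g$Ul <- crossprod(dec$G2, dlh); g$cl <- colSums(dlh)
    dG2 <- dG2 + tcrossprod(dmh, p$Um) + tcrossprod(dlh, p$Ul)
  }
  dG2p <- dG2 * eluGrad(dec$G2p, dec$G2)
  g$U2 <- crossprod(dec$G1, dG2p); g$c2 <- colSums(dG2p)
  dG1p <- tcrossprod(dG2p, p$U2) * eluGrad(dec$G1p, dec$G1)
  g$U1 <- crossprod(Zin, dG1p); g$c1 <- colSums(dG1p)
  dz <- tcrossprod(dG1p, p$U1)[, seq_len(cfg$latent_dim), drop = FALSE]
  dmu <- dz + beta * enc$mu / n
  dlv <- (dz * 0.5 * sdz * eps + beta * 0.5 * (exp(enc$lv) - 1) / n) * enc$lvMask
  g$Wmu <- crossprod(enc$A2, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(enc$A2, dlv); g$blv <- colSums(dlv)
  dA2 <- tcrossprod(dmu, p$Wmu) + tcrossprod(dlv, p$Wlv)
  dZ2 <- dA2 * eluGrad(enc$Z2, enc$A2)
  g$W2 <- crossprod(enc$A1, dZ2); g$b2 <- colSums(dZ2)
  dZ1 <- tcrossprod(dZ2, p$W2) * eluGrad(enc$Z1, enc$A1)
  g$W1 <- crossprod(enc$E, dZ1); g$b1 <- colSums(dZ1)
  dE <- tcrossprod(dZ1, p$W1)
  dEc <- dE[, seq_len(d$dCdr3), drop = FALSE]
  dEv <- dE[, d$dCdr3 + seq_len(model@config$v_embedding_dim), drop = FALSE]
  dEj <- dE[, (d$dCdr3 + model@config$v_embedding_dim + 1L):ncol(dE), drop = FALSE]
  g$Wv <- crossprod(enc$B$Xv, dEv)
  g$Wj <- crossprod(enc$B$Xj, dEj)
  g$Wa <- crossprod(enc$Mx, toSites(dEc, n))
  list(loss = loss, grads = g)
}

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0), v = lapply(params, function(x) x * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  c1 <- 1 - cfg$adam_beta1^state$t
  c2 <- 1 - cfg$adam_beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- cfg$adam_beta1 * state$m[[nm]] + (1 - cfg$adam_beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$adam_beta2 * state$v[[nm]] + (1 - cfg$adam_beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

#' Train a beta-VAE on TCR triples
#'
#' Implements the full protocol: the data are split into true-training
#' and validation sets; `n_pretrain_phases` short runs start from fresh
#' random weights under the beta warm-up schedule; the phase with the
#' best validation loss seeds a full run, which stops after `patience`
#' epochs without validation improvement (or at `max_epochs`) and
#' restores the best-validation checkpoint. Fully deterministic given
#' `config$seed`.
#'
#' @param data data.frame of triples (`amino_acid`, `v_gene`, `j_gene`).
#' @param modelConfig a [vaeConfig()].
#' @param config a [trainConfig()]; `beta_final` overrides
#'   `modelConfig$beta` for the schedule.
#' @param registry a \linkS4class{GeneRegistry}.
#' @param germline germline table, required for `count_match`.
#' @return list with elements `model` (trained \linkS4class{TcrVae}) and
#'   `report` (\linkS4class{TrainReport}).
#' @export
trainVae <- function(data, modelConfig = vaeConfig(), config = trainConfig(),
                     registry = defaultGeneRegistry(), germline = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 2L) stop("need at least 2 sequences to train", call. = FALSE)
  modelConfig$beta <- config$beta_final
  proto <- tcrVae(modelConfig, registry, germline, seed = config$seed)
  tens <- trainTensors(data, proto)
  nVal <- max(1L, round(config$validation_fraction * tens$n))
  valIdx <- withSeed(deriveSeed(config$seed, 1L),
                     sample.int(tens$n, nVal))
  trnIdx <- setdiff(seq_len(tens$n), valIdx)
  if (!length(trnIdx)) stop("validation split left no training data", call. = FALSE)
  valEps <- withSeed(deriveSeed(config$seed, 2L),
                     matrix(stats::rnorm(nVal * modelConfig$latent_dim), nrow = nVal))
  valLoss <- function(model, beta) {
    vaeGradients(model, tens, valIdx, beta, valEps, wantGrads = FALSE)$loss
  }

  runEpochs <- function(model, adam, epochs, epochOffset, phase, history,
                        track = NULL) {
    for (e in seq_len(epochs)) {
      epoch <- epochOffset + e
      beta <- betaSchedule(epoch - 1L, config)
      ord <- withSeed(deriveSeed(config$seed, 1000L * phase + epoch),
                      sample(trnIdx))
      epsAll <- withSeed(deriveSeed(config$seed, 1000L * phase + epoch + 500000L),
                         matrix(stats::rnorm(length(ord) * modelConfig$latent_dim),
                                nrow = length(ord)))
      batches <- split(seq_along(ord), ceiling(seq_along(ord) / config$batch_size))
      epochLoss <- 0
      for (b in batches) {
        gr <- vaeGradients(model, tens, ord[b], beta, epsAll[b, , drop = FALSE])
        if (!is.finite(gr$loss)) {
          stop(sprintf("non-finite training loss at phase %d epoch %d", phase, epoch),
               call. = FALSE)
        }
        upd <- adamStep(model@params, gr$grads, adam, config)
        model@params <- upd$params
        adam <- upd$state
        epochLoss <- epochLoss + gr$loss * length(b)
      }
      # monitor the final objective: validation loss always at beta_final,
      # so checkpoint selection is not distorted by the warm-up schedule
      vl <- valLoss(model, config$beta_final)
      history[[length(history) + 1L]] <- data.frame(
        phase = phase, epoch = epoch, beta = beta,
        train_loss = epochLoss / length(ord), val_loss = vl)
      if (!is.null(track)) track(model, vl, epoch)
    }
    list(model = model, adam = adam, history = history,
         lastVal = history[[length(history)]]$val_loss)
  }

  # pre-training phases from fresh random weights
  history <- list()
  best <- NULL
  for (ph in seq_len(config$n_pretrain_phases)) {
    model <- tcrVae(modelConfig, registry, germline,
                    seed = deriveSeed(config$seed, 100L + ph))
    res <- runEpochs(model, adamInit(model@params), config$pretrain_epochs, 0L,
                     ph, history)
    history <- res$history
    if (is.null(best) || res$lastVal < best$val) {
      best <- list(model = res$model, adam = res$adam, val = res$lastVal, phase = ph)
    }
  }
  chosen <- best$phase

  # full run seeded by the best phase, with early stopping
  model <- best$model
  adam <- best$adam
  bestParams <- model@params
  bestVal <- best$val  # checkpoint carried over from the chosen phase
  sinceImprove <- 0L
  epoch <- config$pretrain_epochs
  while (epoch < config$max_epochs && sinceImprove < config$patience) {
    res <- runEpochs(model, adam, 1L, epoch, 0L, history)
    history <- res$history
    model <- res$model
    adam <- res$adam
    epoch <- epoch + 1L
    if (res$lastVal < bestVal - 1e-9) {
      bestVal <- res$lastVal
      bestParams <- model@params
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
    }
  }
  model@params <- bestParams  # restore best checkpoint, never the last epoch
  model@trained <- TRUE
  hist <- do.call(rbind, history)
  report <- methods::new("TrainReport", history = hist,
                         chosenPhase = as.integer(chosen),
                         stoppingEpoch = as.integer(epoch),
                         bestValLoss = bestVal,
                         finalBeta = betaSchedule(epoch - 1L, config))
  list(model = model, report = report)
}

#' Per-sequence loss components
#'
#' Evaluates each reconstruction component and the KL term per sequence
#' (one reparameterized latent draw per sequence), e.g. as the design
#' matrix for [fitLossWeights()].
#'
#' @param model a trained \linkS4class{TcrVae}.
#' @param data data.frame of triples.
#' @param seed seed for the latent draws.
#' @return data.frame with columns `ce_v`, `ce_j`, `ce_cdr3`, `kl` and,
#'   for count_match, `sq_match`, `sq_length`.
#' @export
lossComponents <- function(model, data, seed = 1L) {
  tens <- trainTensors(as.data.frame(data), model)
  d <- vaeDims(model@config, model@registry)
  n <- tens$n
  enc <- encoderForward(model, tens$X)
  eps <- withSeed(seed, matrix(stats::rnorm(n * model@config$latent_dim), nrow = n))
  z <- enc$mu + exp(0.5 * enc$lv) * eps
  Zin <- if (model@config$model_kind == "count_match") cbind(z, tens$G) else z
  dec <- decoderForward(model, Zin)
  Tv <- tens$X[, d$dCdr3 + seq_len(d$nv), drop = FALSE]
  Tj <- tens$X[, d$dCdr3 + d$nv + seq_len(d$nj), drop = FALSE]
  TcS <- toSites(tens$X[, seq_len(d$dCdr3), drop = FALSE], n)
  tiny <- 1e-12
  out <- data.frame(
    ce_v = -log(pmax(rowSums(dec$pv * Tv), tiny)),
    ce_j = -log(pmax(rowSums(dec$pj * Tj), tiny)),
    ce_cdr3 = rowSums(matrix(-log(pmax(rowSums(dec$pcSites * TcS), tiny)),
                             nrow = n)) / cdr3Width,
    kl = 0.5 * rowSums(enc$mu^2 + exp(enc$lv) - 1 - enc$lv))
  if (model@config$model_kind == "count_match") {
    out$sq_match <- rowSums((dec$mhat - tens$mTrue)^2)
    out$sq_length <- (dec$lhat[, 1L] - tens$lTrue)^2
  }
  out
}

#' Fit reconstruction-loss component weights by least squares
#'
#' Finds the weights of the linear combination of loss components that
#' best matches a per-sequence log-likelihood target (squared error, no
#' intercept). Negative solutions are clipped to 0 with a warning.
#'
#' @param components numeric matrix or data.frame, one column per loss
#'   component, one row per sequence.
#' @param targets numeric vector (e.g. negated importance-sampling
#'   log-likelihood estimates).
#' @return named non-negative weight vector.
#' @export
fitLossWeights <- function(components, targets) {
  X <- as.matrix(components)
  stopifnot(nrow(X) == length(targets), nrow(X) >= ncol(X))
  if (any(!is.finite(X)) || any(!is.finite(targets))) {
    stop("components and targets must be finite", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient component matrix; remove collinear components",
         call. = FALSE)
  }
  w <- qr.coef(qrX, targets)
  if (any(w < 0)) {
    warning("negative fitted weights clipped to 0")
    w <- pmax(w, 0)
  }
  stats::setNames(as.numeric(w), colnames(X))
}

#' Sweep the final beta value
#'
#' Trains one model per beta (independently, with the same other
#' settings) over an evenly spaced grid — seven values from 0.625 to 1 by
#' default — and reports each run's best validation loss.
#'
#' @param data training triples.
#' @param betas beta grid.
#' @param ... passed to [trainVae()] (`modelConfig`, `config`, ...).
#' @return list with `summary` (data.frame of beta and best validation
#'   loss) and `fits` (per-beta [trainVae()] results).
#' @export
betaSweep <- function(data, betas = seq(0.625, 1, length.out = 7), ...) {
  args <- list(...)
  fits <- lapply(betas, function(b) {
    a <- args
    a$config <- if (is.null(a$config)) trainConfig(beta_final = b) else {
      a$config$beta_final <- b; a$config
    }
    do.call(trainVae, c(list(data = data), a))
  })
  list(summary = data.frame(beta = betas,
                            best_val_loss = vapply(fits, function(f)
                              f$report@bestValLoss, numeric(1))),
       fits = fits)
}
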