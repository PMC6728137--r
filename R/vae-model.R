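# beta-VAE architectures over one-hot TCR triples: 'basic' (independent
# V / J / CDR3 heads) and 'count_match' (germline-aware decoder input plus
# auxiliary germline-match-count and CDR3-length regression heads).
#
# Networks are small dense stacks (default two 100-unit ELU layers each
# way) implemented directly on base matrix operations; training and
# gradients live in vae-train.R.

#' VAE model configuration
#'
#' @param model_kind `"basic"` or `"count_match"`.
#' @param latent_dim latent-space dimension (default 20).
#' @param hidden_dims widths of the two dense layers used by both encoder
#'   and decoder.
#' @param v_embedding_dim dimension the one-hot V block is linearly
#'   projected to at the encoder input (default 30); the J and amino-acid
#'   input embeddings keep their dimension.
#' @param beta weight on the KL term of the training objective
#'   (default 0.75).
#' @param loss_weights named non-negative weights for the reconstruction
#'   components `v`, `j`, `cdr3`, and (count_match only) `match`, `length`.
#' @param germline_width residues of germline CDR3 prefix/suffix encoded
#'   into the count_match decoder input, per side.
#' @return a validated configuration list.
#' @export
vaeConfig <- function(model_kind = c("basic", "count_match"),
                      latent_dim = 20L,
                      hidden_dims = c(100L, 100L),
                      v_embedding_dim = 30L,
                      beta = 0.75,
                      loss_weights = c(v = 1, j = 1, cdr3 = 1, match = 1, length = 1),
                      germline_width = 8L) {
  model_kind <- match.arg(model_kind)
  stopifnot(latent_dim >= 1L, length(hidden_dims) == 2L, beta >= 0,
            all(loss_weights >= 0))
  w <- c(v = 1, j = 1, cdr3 = 1, match = 1, length = 1)
  w[names(loss_weights)] <- loss_weights
  list(model_kind = model_kind, latent_dim = as.integer(latent_dim),
       hidden_dims = as.integer(hidden_dims),
       v_embedding_dim = as.integer(v_embedding_dim),
       beta = beta, loss_weights = w, germline_width = as.integer(germline_width))
}

# site-major n x 630 block <-> (n*30) x 21 per-site rows
toSites <- function(Xc, n) {
  matrix(aperm(array(Xc, c(n, 21L, cdr3Width)), c(1L, 3L, 2L)), nrow = n * cdr3Width)
}
fromSites <- function(M, n) {
  matrix(aperm(array(M, c(n, cdr3Width, 21L)), c(1L, 3L, 2L)), nrow = n)
}

eluFun <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
eluGrad <- function(pre, act) ifelse(pre > 0, 1, act + 1)

vaeDims <- function(config, registry) {
  nv <- length(registry@vGenes); nj <- length(registry@jGenes)
  dEnc <- cdr3Width * 21L + config$v_embedding_dim + nj
  dDec <- config$latent_dim +
    if (config$model_kind == "count_match") 2L * config$germline_width * 21L else 0L
  list(nv = nv, nj = nj, dEnc = dEnc, dDec = dDec, dCdr3 = cdr3Width * 21L)
}

#' Construct an (untrained) TcrVae model
#'
#' Weights are Glorot-uniform initialized, deterministically given `seed`.
#'
#' @param config a [vaeConfig()] list.
#' @param registry the \linkS4class{GeneRegistry} fixing encoding
#'   dimensions.
#' @param germline germline CDR3 table (see [germlineTable()]); required
#'   for `count_match`.
#' @param seed integer seed for weight initialization.
#' @return a \linkS4class{TcrVae}.
#' @export
tcrVae <- function(config = vaeConfig(), registry = defaultGeneRegistry(),
                   germline = NULL, seed = 1L) {
  if (config$model_kind == "count_match" && is.null(germline)) {
    stop("count_match requires a germline CDR3 table", call. = FALSE)
  }
  if (is.null(germline)) {
    germline <- data.frame(gene = character(), segment = character(),
                           cdr3_seq = character(), stringsAsFactors = FALSE)
  }
  d <- vaeDims(config, registry)
  h1 <- config$hidden_dims[1L]; h2 <- config$hidden_dims[2L]
  L <- config$latent_dim
  shapes <- list(
    Wa = c(21L, 21L), Wv = c(d$nv, config$v_embedding_dim), Wj = c(d$nj, d$nj),
    W1 = c(d$dEnc, h1), b1 = h1, W2 = c(h1, h2), b2 = h2,
    Wmu = c(h2, L), bmu = L, Wlv = c(h2, L), blv = L,
    U1 = c(d$dDec, h1), c1 = h1, U2 = c(h1, h2), c2 = h2,
    Uv = c(h2, d$nv), cv = d$nv, Uj = c(h2, d$nj), cj = d$nj,
    Uc = c(h2, d$dCdr3), cc = d$dCdr3)
  if (config$model_kind == "count_match") {
    shapes <- c(shapes, list(Um = c(h2, 2L), cm = 2L, Ul = c(h2, 1L), cl = 1L))
  }
  params <- withSeed(seed, lapply(shapes, function(s) {
    if (length(s) == 1L) {
      numeric(s)
    } else {
      lim <- sqrt(6 / (s[1L] + s[2L]))
      matrix(stats::runif(prod(s), -lim, lim), nrow = s[1L], ncol = s[2L])
    }
  }))
  methods::new("TcrVae", config = config, params = params, registry = registry,
               germline = germline, trained = FALSE)
}

# Germline decoder-input block for count_match: prefix of the V germline
# (gap-padded right) and suffix of the J germline (gap-padded left), each
# one-hot encoded over gw sites x 21 channels.
germBlock <- function(df, germline, gw) {
  n <- nrow(df)
  symbols <- aaAlphabet(TRUE)
  vSeq <- germline$cdr3_seq[germline$segment == "V"][
    match(df$v_gene, germline$gene[germline$segment == "V"])]
  jSeq <- germline$cdr3_seq[germline$segment == "J"][
    match(df$j_gene, germline$gene[germline$segment == "J"])]
  vSeq[is.na(vSeq)] <- ""; jSeq[is.na(jSeq)] <- ""
  padR <- function(s) paste0(substring(s, 1L, gw), strrep("-", pmax(gw - nchar(s), 0L)))
  padL <- function(s) {
    k <- nchar(s)
    paste0(strrep("-", pmax(gw - k, 0L)), substring(s, pmax(k - gw + 1L, 1L), k))
  }
  enc <- function(strs) {
    chars <- matrix(unlist(strsplit(strs, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, ncol = gw, byrow = TRUE)
    idx <- match(chars, symbols)
    out <- matrix(0, n, gw * 21L)
    out[cbind(rep(seq_len(n), gw),
              (rep(seq_len(gw), each = n) - 1L) * 21L + as.vector(idx))] <- 1
    out
  }
  cbind(enc(padR(vSeq)), enc(padL(jSeq)))
}

# Split a flat one-hot batch into its component blocks.
splitBlocks <- function(X, dims) {
  list(Xc = X[, seq_len(dims$dCdr3), drop = FALSE],
       Xv = X[, dims$dCdr3 + seq_len(dims$nv), drop = FALSE],
       Xj = X[, dims$dCdr3 + dims$nv + seq_len(dims$nj), drop = FALSE])
}

# Encoder forward pass with caches for backprop.
encoderForward <- function(model, X) {
  p <- model@params
  d <- vaeDims(model@config, model@registry)
  n <- nrow(X)
  B <- splitBlocks(X, d)
  Mx <- toSites(B$Xc, n)
  Ec <- fromSites(Mx %*% p$Wa, n)
  E <- cbind(Ec, B$Xv %*% p$Wv, B$Xj %*% p$Wj)
  Z1 <- sweep(E %*% p$W1, 2L, p$b1, "+"); A1 <- eluFun(Z1)
  Z2 <- sweep(A1 %*% p$W2, 2L, p$b2, "+"); A2 <- eluFun(Z2)
  mu <- sweep(A2 %*% p$Wmu, 2L, p$bmu, "+")
  lvRaw <- sweep(A2 %*% p$Wlv, 2L, p$blv, "+")
  lv <- pmin(pmax(lvRaw, -10), 10)  # guard against variance blow-up
  list(X = X, B = B, Mx = Mx, E = E, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
       mu = mu, lv = lv, lvMask = (lvRaw > -10 & lvRaw < 10) * 1)
}

# Decoder forward pass; Zin already includes any germline block columns.
decoderForward <- function(model, Zin) {
  p <- model@params
  n <- nrow(Zin)
  G1p <- sweep(Zin %*% p$U1, 2L, p$c1, "+"); G1 <- eluFun(G1p)
  G2p <- sweep(G1 %*% p$U2, 2L, p$c2, "+"); G2 <- eluFun(G2p)
  out <- list(Zin = Zin, G1p = G1p, G1 = G1, G2p = G2p, G2 = G2,
              pv = softmaxRows(sweep(G2 %*% p$Uv, 2L, p$cv, "+")),
              pj = softmaxRows(sweep(G2 %*% p$Uj, 2L, p$cj, "+")),
              pcSites = softmaxRows(toSites(sweep(G2 %*% p$Uc, 2L, p$cc, "+"), n)))
  if (model@config$model_kind == "count_match") {
    out$mhat <- sweep(G2 %*% p$Um, 2L, p$cm, "+")
    out$lhat <- sweep(G2 %*% p$Ul, 2L, p$cl, "+")
  }
  out
}

#' Encode triples to their latent posterior parameters
#'
#' @param model a \linkS4class{TcrVae}.
#' @param data data.frame of triples or a pre-encoded one-hot matrix.
#' @return list with matrices `mean` and `log_variance` (rows =
#'   sequences, columns = latent dimensions).
#' @export
vaeEncode <- function(model, data) {
  X <- if (is.matrix(data)) data else encodeTriples(data, model@registry)
  enc <- encoderForward(model, X)
  list(mean = enc$mu, log_variance = enc$lv)
}

#' Decoder output for given latent points
#'
#' @param model a \linkS4class{TcrVae}.
#' @param z numeric matrix of latent points (rows) or a single vector.
#' @param triples for `count_match` models, the triples whose germline
#'   V/J CDR3 sequences are wired into the decoder input (one row per row
#'   of `z`); ignored for `basic`.
#' @return list with `v_probs`, `j_probs` (matrices, rows summing to 1)
#'   and `cdr3_probs` (list of 30 x 21 per-site probability matrices, one
#'   per latent point), plus `predicted_match` and `predicted_length` for
#'   `count_match`.
#' @export
vaeDecode <- function(model, z, triples = NULL) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  n <- nrow(z)
  Zin <- z
  if (model@config$model_kind == "count_match") {
    if (is.null(triples)) {
      gb <- matrix(0, n, 2L * model@config$germline_width * 21L)
    } else {
      gb <- germBlock(as.data.frame(triples), model@germline,
                      model@config$germline_width)
    }
    Zin <- cbind(z, gb)
  }
  dec <- decoderForward(model, Zin)
  out <- list(
    v_probs = dec$pv, j_probs = dec$pj,
    cdr3_probs = lapply(seq_len(n), function(i) {
      m <- dec$pcSites[i + (seq_len(cdr3Width) - 1L) * n, , drop = FALSE]
      colnames(m) <- aaAlphabet(TRUE)
      m
    }))
  if (!is.null(dec$mhat)) {
    out$predicted_match <- dec$mhat
    out$predicted_length <- dec$lhat[, 1L]
  }
  out
}

#' Kullback-Leibler divergence of the encoder posterior from the prior
#'
#' Closed form for a diagonal normal against the standard normal:
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)` per sequence.
#'
#' @param enc list with `mean` and `log_variance` (vectors for one
#'   sequence, or matrices with one row per sequence).
#' @return non-negative numeric vector, one value per sequence.
#' @export
klDivergence <- function(enc) {
  mu <- enc$mean; lv <- enc$log_variance
  if (!is.matrix(mu)) { mu <- matrix(mu, nrow = 1L); lv <- matrix(lv, nrow = 1L) }
  if (any(!is.finite(mu)) || any(!is.finite(lv))) {
    stop("non-finite encoder output", call. = FALSE)
  }
  0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
}

# Normalize x/out pairs into batch matrices used by the loss functions.
lossInputs <- function(model, x, out) {
  d <- vaeDims(model@config, model@registry)
  X <- if (is.matrix(x)) x else if (is.list(x) && !is.null(x$cdr3_block)) {
    matrix(c(t(x$cdr3_block), x$v_block, x$j_block), nrow = 1L)
  } else matrix(x, nrow = 1L)
  n <- nrow(X)
  if (!is.null(out$pcSites)) {  # internal decoderForward structure
    pv <- out$pv; pj <- out$pj; pcS <- out$pcSites
    mhat <- out$mhat; lhat <- out$lhat
  } else {
    pv <- if (is.matrix(out$v_probs)) out$v_probs else matrix(out$v_probs, nrow = 1L)
    pj <- if (is.matrix(out$j_probs)) out$j_probs else matrix(out$j_probs, nrow = 1L)
    cp <- out$cdr3_probs
    if (is.matrix(cp)) cp <- list(cp)
    pcS <- matrix(0, n * cdr3Width, 21L)
    for (i in seq_len(n)) pcS[i + (seq_len(cdr3Width) - 1L) * n, ] <- cp[[i]]
    mhat <- if (!is.null(out$predicted_match)) {
      if (is.matrix(out$predicted_match)) out$predicted_match
      else matrix(out$predicted_match, nrow = 1L)
    }
    lhat <- if (!is.null(out$predicted_length)) cbind(out$predicted_length)
  }
  tol <- 1e-4
  if (any(abs(rowSums(pv) - 1) > tol) || any(abs(rowSums(pj) - 1) > tol) ||
      any(abs(rowSums(pcS) - 1) > tol)) {
    stop("decoder probability block not normalized", call. = FALSE)
  }
  list(X = X, n = n, d = d, pv = pv, pj = pj, pcS = pcS, mhat = mhat, lhat = lhat)
}

#' Reconstruction loss of decoded outputs against true sequences
#'
#' Categorical cross-entropy for the V and J heads, the average
#' cross-entropy over the 30 CDR3 sites for the CDR3 head, combined with
#' the configured component weights. For `count_match`, adds
#' two-dimensional squared loss on the germline-match-count head and
#' squared loss on the CDR3-length head.
#'
#' @param x an encoded sequence ([oneHotEncode()] list, flat vector, or
#'   one-hot matrix for a batch).
#' @param out decoder output ([vaeDecode()] structure).
#' @param config the model's [vaeConfig()].
#' @param model the \linkS4class{TcrVae} (supplies registry dimensions and
#'   the germline table for the auxiliary targets).
#' @param triples original triples (data.frame), required for
#'   `count_match` targets; recovered by argmax decoding when omitted.
#' @return non-negative numeric vector of per-sequence losses.
#' @export
reconstructionLoss <- function(x, out, config, model, triples = NULL) {
  li <- lossInputs(model, x, out)
  w <- config$loss_weights
  eps <- 1e-12
  ceV <- -log(pmax(rowSums(li$pv * li$X[, li$d$dCdr3 + seq_len(li$d$nv), drop = FALSE]), eps))
  ceJ <- -log(pmax(rowSums(li$pj * li$X[, li$d$dCdr3 + li$d$nv + seq_len(li$d$nj), drop = FALSE]), eps))
  TcS <- toSites(li$X[, seq_len(li$d$dCdr3), drop = FALSE], li$n)
  ceSite <- -log(pmax(rowSums(li$pcS * TcS), eps))
  ceC <- rowSums(matrix(ceSite, nrow = li$n)) / cdr3Width
  loss <- w[["v"]] * ceV + w[["j"]] * ceJ + w[["cdr3"]] * ceC
  if (config$model_kind == "count_match") {
    if (is.null(triples)) triples <- decodeOneHot(li$X, model@registry)
    mc <- germlineMatchCounts(triples, model@germline)
    loss <- loss +
      w[["match"]] * ((li$mhat[, 1L] - mc$v_match)^2 + (li$mhat[, 2L] - mc$j_match)^2) +
      w[["length"]] * (li$lhat[, 1L] - nchar(triples$amino_acid))^2
  }
  unname(loss)
}

#' Total beta-VAE training loss
#'
#' `reconstruction + beta * KL`, per sequence.
#'
#' @inheritParams reconstructionLoss
#' @param enc encoder output as from [vaeEncode()].
#' @param beta override for the annealed KL weight (defaults to
#'   `config$beta`).
#' @return numeric vector of per-sequence losses.
#' @export
totalLoss <- function(x, enc, out, config, model, triples = NULL, beta = NULL) {
  if (is.null(beta)) beta <- config$beta
  reconstructionLoss(x, out, config, model, triples) + beta * klDivergence(enc)
}

#' Conditional log-probability of sequences given decoder outputs
#'
#' `log p(x | z)`: the log V probability plus the log J probability plus
#' the summed log per-site CDR3 probabilities over all 30 padded sites
#' (gaps included). Zero probability on an observed symbol yields `-Inf`,
#' not an error.
#'
#' @inheritParams reconstructionLoss
#' @return numeric vector, each element <= 0.
#' @export
conditionalLogProb <- function(x, out, model) {
  li <- lossInputs(model, x, out)
  lpV <- log(rowSums(li$pv * li$X[, li$d$dCdr3 + seq_len(li$d$nv), drop = FALSE]))
  lpJ <- log(rowSums(li$pj * li$X[, li$d$dCdr3 + li$d$nv + seq_len(li$d$nj), drop = FALSE]))
  TcS <- toSites(li$X[, seq_len(li$d$dCdr3), drop = FALSE], li$n)
  lpSite <- log(rowSums(li$pcS * TcS))
  lpC <- rowSums(matrix(lpSite, nrow = li$n))
  unname(lpV + lpJ + lpC)
}

#' Generate TCR triples from the model
#'
#' Draws latent points from the standard normal prior, decodes them, and
#' samples (or argmaxes) the V gene, J gene and each CDR3 site. Gap
#' symbols are stripped to produce the CDR3 string; with
#' `strictGaps = TRUE`, draws whose gaps do not form a contiguous central
#' block (or whose CDR3 is empty) are rejected and redrawn within a
#' bounded retry budget.
#'
#' @param model a \linkS4class{TcrVae}.
#' @param n number of sequences.
#' @param seed integer seed.
#' @param mode `"sample"` (draw every categorical) or `"argmax"`.
#' @param strictGaps reject non-central gap patterns instead of stripping.
#' @param z optional matrix of latent points to decode instead of prior
#'   draws (rows must equal `n`).
#' @param maxTries retry budget multiplier for `strictGaps`.
#' @return data.frame of generated triples.
#' @export
generateTcrs <- function(model, n, seed = 1L, mode = c("sample", "argmax"),
                         strictGaps = FALSE, z = NULL, maxTries = 50L) {
  mode <- match.arg(mode)
  L <- model@config$latent_dim
  withSeed(seed, {
    out <- NULL
    todo <- n
    zFixed <- z
    tries <- 0L
    while (todo > 0L) {
      tries <- tries + 1L
      if (tries > maxTries) {
        stop("generation retry budget exhausted under strict gap handling",
             call. = FALSE)
      }
      zz <- if (is.null(zFixed)) {
        matrix(stats::rnorm(todo * L), nrow = todo)
      } else zFixed
      draw <- decodeDraws(model, zz, mode)
      if (strictGaps) {
        stripped <- gsub("-", "", draw$padded, fixed = TRUE)
        nonEmpty <- nchar(stripped) >= 1L
        ok <- nonEmpty &
          draw$padded == padMiddle(ifelse(nonEmpty, stripped, "A"))
      } else {
        ok <- nchar(gsub("-", "", draw$padded, fixed = TRUE)) >= 1L
      }
      keep <- data.frame(
        amino_acid = gsub("-", "", draw$padded[ok], fixed = TRUE),
        v_gene = draw$v[ok], j_gene = draw$j[ok], stringsAsFactors = FALSE)
      out <- rbind(out, keep)
      todo <- n - nrow(out)
      if (!is.null(zFixed)) zFixed <- zFixed[!ok, , drop = FALSE]
      if (!is.null(zFixed) && nrow(zFixed) == 0L) break
    }
    rownames(out) <- NULL
    out[seq_len(min(n, nrow(out))), , drop = FALSE]
  })
}

#' @rdname generateTcrs
#' @export
sampleTcr <- function(model, z, mode = c("sample", "argmax"), seed = 1L,
                      strictGaps = FALSE) {
  generateTcrs(model, n = 1L, seed = seed, mode = match.arg(mode),
               strictGaps = strictGaps, z = matrix(z, nrow = 1L))
}

# Decode latent points into component draws (consumes the RNG stream).
decodeDraws <- function(model, zz, mode) {
  n <- nrow(zz)
  reg <- model@registry
  dec <- if (model@config$model_kind == "count_match") {
    # two-pass: pick genes from a germline-free pass, then condition
    d0 <- decoderForward(model, cbind(zz, matrix(0, n, 2L * model@config$germline_width * 21L)))
    v0 <- drawCat(d0$pv, mode); j0 <- drawCat(d0$pj, mode)
    gdf <- data.frame(v_gene = reg@vGenes[v0], j_gene = reg@jGenes[j0])
    d1 <- decoderForward(model, cbind(zz, germBlock(gdf, model@germline,
                                                    model@config$germline_width)))
    d1$vFixed <- v0; d1$jFixed <- j0
    d1
  } else decoderForward(model, zz)
  vIdx <- if (!is.null(dec$vFixed)) dec$vFixed else drawCat(dec$pv, mode)
  jIdx <- if (!is.null(dec$jFixed)) dec$jFixed else drawCat(dec$pj, mode)
  sIdx <- drawCat(dec$pcSites, mode)
  symbols <- aaAlphabet(TRUE)
  padded <- vapply(seq_len(n), function(i) {
    paste(symbols[sIdx[i + (seq_len(cdr3Width) - 1L) * n]], collapse = "")
  }, character(1))
  list(v = reg@vGenes[vIdx], j = reg@jGenes[jIdx], padded = padded)
}

drawCat <- function(probs, mode) {
  if (mode == "argmax") return(max.col(probs, ties.method = "first"))
  u <- stats::runif(nrow(probs))
  cum <- t(apply(probs, 1L, cumsum))
  max.col(cum >= u, ties.method = "first")
}

## -- serialization ----------------------------------------------------------

#' Save / load a TcrVae model
#'
#' Writes a plain-text weights file (`<prefix>.weights`, one value per
#' line at full precision) and a JSON metadata sidecar (`<prefix>.json`)
#' recording the configuration, parameter shapes, alphabet order, gene
#' catalogs and germline table. `loadVae` fails loudly if the weights file
#' does not match the metadata.
#'
#' @param model a \linkS4class{TcrVae}.
#' @param prefix path prefix for the two files.
#' @return `saveVae` returns `prefix` invisibly; `loadVae` the restored
#'   model.
#' @export
saveVae <- function(model, prefix) {
  p <- model@params
  cfg <- model@config
  cfg$loss_weights <- as.list(cfg$loss_weights)  # keep names through JSON
  meta <- list(
    package = "tcrvae", format = 1L,
    config = cfg,
    shapes = lapply(p, function(m) if (is.matrix(m)) dim(m) else length(m)),
    alphabet = aaAlphabet(TRUE),
    v_genes = model@registry@vGenes, j_genes = model@registry@jGenes,
    aliases = as.list(model@registry@aliases),
    blacklist = model@registry@blacklist,
    germline = model@germline, trained = model@trained)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(sprintf("%.17g", unlist(p, use.names = FALSE)),
             paste0(prefix, ".weights"))
  invisible(prefix)
}

#' @rdname saveVae
#' @export
loadVae <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(meta$package, "tcrvae")) {
    stop("metadata sidecar is not a tcrvae model file", call. = FALSE)
  }
  if (!identical(as.character(meta$alphabet), aaAlphabet(TRUE))) {
    stop("model alphabet does not match this package's encoding order", call. = FALSE)
  }
  vals <- as.numeric(readLines(paste0(prefix, ".weights")))
  sizes <- vapply(meta$shapes, prod, numeric(1))
  if (length(vals) != sum(sizes)) {
    stop(sprintf("weights file has %d values but metadata implies %d",
                 length(vals), sum(sizes)), call. = FALSE)
  }
  offs <- cumsum(c(0, sizes))
  params <- lapply(seq_along(meta$shapes), function(i) {
    v <- vals[(offs[i] + 1L):offs[i + 1L]]
    s <- meta$shapes[[i]]
    if (length(s) == 2L) matrix(v, nrow = s[1L], ncol = s[2L]) else v
  })
  names(params) <- names(meta$shapes)
  cfg <- meta$config
  cfg$latent_dim <- as.integer(cfg$latent_dim)
  cfg$hidden_dims <- as.integer(cfg$hidden_dims)
  cfg$v_embedding_dim <- as.integer(cfg$v_embedding_dim)
  cfg$germline_width <- as.integer(cfg$germline_width)
  cfg$loss_weights <- unlist(cfg$loss_weights)
  reg <- geneRegistry(as.character(meta$v_genes), as.character(meta$j_genes),
                      blacklist = as.character(meta$blacklist))
  germ <- as.data.frame(meta$germline, stringsAsFactors = FALSE)
  if (!nrow(germ)) {
    germ <- data.frame(gene = character(), segment = character(),
                       cdr3_seq = character(), stringsAsFactors = FALSE)
  }
  model <- methods::new("TcrVae", config = cfg, params = params, registry = reg,
                        germline = germ, trained = isTRUE(meta$trained))
  model
}
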