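# Amino-acid-level VDJ recombination simulator with exactly computable
# generation probabilities. Serves as the built-in PgenProvider: small
# enough to enumerate, rich enough to train models on.

#' Construct a recombination spec
#'
#' @param vIds,jIds segment names.
#' @param vProbs,jProbs usage probabilities.
#' @param vPrefixes,jSuffixes germline CDR3 prefix/suffix per segment.
#' @param vTrimPmfs,jTrimPmfs list of named pmfs over trimmed residue
#'   counts (names "0", "1", ...), one per segment; a single pmf is
#'   recycled.
#' @param insLenPmf named pmf over insertion lengths.
#' @param insResPmf named pmf over inserted residues.
#' @param maxCdr3Length draws longer than this are rejected and redrawn
#'   (probabilities are renormalized accordingly).
#' @return a \linkS4class{RecombSpec}.
#' @export
recombSpec <- function(vIds, vProbs, vPrefixes, vTrimPmfs,
                       jIds, jProbs, jSuffixes, jTrimPmfs,
                       insLenPmf, insResPmf, maxCdr3Length = 30L) {
  recycle <- function(pmfs, k) {
    if (!is.list(pmfs)) pmfs <- list(pmfs)
    if (length(pmfs) == 1L) pmfs <- rep(pmfs, k)
    pmfs
  }
  methods::new("RecombSpec",
    vIds = vIds, vProbs = vProbs / sum(vProbs), vPrefixes = vPrefixes,
    vTrimPmfs = recycle(vTrimPmfs, length(vIds)),
    jIds = jIds, jProbs = jProbs / sum(jProbs), jSuffixes = jSuffixes,
    jTrimPmfs = recycle(jTrimPmfs, length(jIds)),
    insLenPmf = insLenPmf / sum(insLenPmf),
    insResPmf = insResPmf / sum(insResPmf),
    maxCdr3Length = as.integer(maxCdr3Length))
}

#' Default desk-scale recombination spec
#'
#' Four V segments and three J segments with 4-5 residue germline CDR3
#' contributions, trims of 0-2 residues, insertions of 0-6 residues with a
#' mode at 2, and an insertion-residue distribution enriched for G/S/A (as
#' junctional insertions tend to be). CDR3 lengths range 4-15. Small enough
#' that (V, J, length) key marginals are exact, rich enough (~10^7-scale
#' sequence support) that VAE training on its output is non-trivial.
#'
#' @return a \linkS4class{RecombSpec}.
#' @export
defaultRecombSpec <- function() {
  trim <- c("0" = 0.5, "1" = 0.3, "2" = 0.2)
  resP <- c(G = 0.14, S = 0.12, A = 0.10, L = 0.08, P = 0.07, R = 0.07,
            T = 0.06, E = 0.05, Q = 0.05, D = 0.04, V = 0.04, N = 0.03,
            F = 0.03, Y = 0.03, I = 0.02, K = 0.02, H = 0.02, W = 0.01,
            M = 0.01, C = 0.01)
  recombSpec(
    vIds = c("TCRBV01-01", "TCRBV02-01", "TCRBV03-01", "TCRBV04-01"),
    vProbs = c(0.4, 0.3, 0.2, 0.1),
    vPrefixes = c("CASS", "CASR", "CAWS", "CSVE"),
    vTrimPmfs = list(trim),
    jIds = c("TCRBJ01-01", "TCRBJ01-02", "TCRBJ02-01"),
    jProbs = c(0.5, 0.3, 0.2),
    jSuffixes = c("NTEAF", "NYGYTF", "NEQFF"),
    jTrimPmfs = list(trim),
    insLenPmf = c("0" = 0.10, "1" = 0.18, "2" = 0.25, "3" = 0.20,
                  "4" = 0.14, "5" = 0.08, "6" = 0.05),
    insResPmf = resP,
    maxCdr3Length = 30L)
}

#' Tiny fully enumerable recombination spec
#'
#' Two V and two J segments, insertions of 0-2 residues drawn from a
#' two-letter alphabet: the entire sequence support can be enumerated with
#' [enumerateTriples()], which makes it the oracle configuration for
#' brute-force tests.
#'
#' @return a \linkS4class{RecombSpec}.
#' @export
toyRecombSpec <- function() {
  recombSpec(
    vIds = c("V1", "V2"), vProbs = c(0.6, 0.4),
    vPrefixes = c("CAS", "CAT"),
    vTrimPmfs = list(c("0" = 0.7, "1" = 0.3)),
    jIds = c("J1", "J2"), jProbs = c(0.7, 0.3),
    jSuffixes = c("SF", "TF"),
    jTrimPmfs = list(c("0" = 0.8, "1" = 0.2)),
    insLenPmf = c("0" = 0.4, "1" = 0.4, "2" = 0.2),
    insResPmf = c(S = 0.5, T = 0.5),
    maxCdr3Length = 30L)
}

# Probability that a raw draw has CDR3 length in [1, maxCdr3Length];
# the sampler conditions on this event, so pgen divides by it.
specAcceptanceMass <- function(spec) {
  sc <- scenarioTable(spec)
  sum(sc$prob[sc$length >= 1L & sc$length <= spec@maxCdr3Length])
}

# All (V, vTrim, J, jTrim, insertion length) scenarios with probabilities
# (pre-conditioning) and resulting CDR3 lengths.
scenarioTable <- function(spec) {
  rows <- list()
  insLens <- as.integer(names(spec@insLenPmf))
  for (vi in seq_along(spec@vIds)) {
    vTrims <- as.integer(names(spec@vTrimPmfs[[vi]]))
    for (tvi in seq_along(vTrims)) {
      kv <- nchar(spec@vPrefixes[vi]) - vTrims[tvi]
      pv <- spec@vProbs[vi] * spec@vTrimPmfs[[vi]][[tvi]]
      for (ji in seq_along(spec@jIds)) {
        jTrims <- as.integer(names(spec@jTrimPmfs[[ji]]))
        for (tji in seq_along(jTrims)) {
          kj <- nchar(spec@jSuffixes[ji]) - jTrims[tji]
          pj <- spec@jProbs[ji] * spec@jTrimPmfs[[ji]][[tji]]
          rows[[length(rows) + 1L]] <- data.frame(
            v = vi, j = ji, vTrim = vTrims[tvi], jTrim = jTrims[tji],
            ins = insLens, kv = kv, kj = kj, length = kv + kj + insLens,
            prob = pv * pj * unname(spec@insLenPmf))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' @describeIn sampleTriples draws from the recombination process:
#'   choose and trim a V segment, choose and trim a J segment, insert a
#'   random number of random residues in between; draws with CDR3 length
#'   outside `[1, maxCdr3Length]` are rejected and redrawn.
#' @export
setMethod("sampleTriples", "RecombSpec", function(object, n, seed = 1L, ...) {
  stopifnot(isCount(n))
  if (specAcceptanceMass(object) <= 0) {
    stop("spec can never produce a CDR3 of valid length", call. = FALSE)
  }
  withSeed(seed, {
    acc <- list(); got <- 0L
    while (got < n) {
      m <- max(n - got, 1000L)
      draw <- drawRecombBatch(object, m)
      ok <- nchar(draw$amino_acid) >= 1L & nchar(draw$amino_acid) <= object@maxCdr3Length
      draw <- draw[ok, , drop = FALSE]
      acc[[length(acc) + 1L]] <- draw
      got <- got + nrow(draw)
    }
    out <- do.call(rbind, acc)[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
})

# One unconditioned batch of recombination draws (consumes the RNG stream).
drawRecombBatch <- function(spec, m) {
  vIdx <- sample.int(length(spec@vIds), m, replace = TRUE, prob = spec@vProbs)
  jIdx <- sample.int(length(spec@jIds), m, replace = TRUE, prob = spec@jProbs)
  drawTrim <- function(idx, pmfs) {
    tr <- integer(m)
    for (k in unique(idx)) {
      sel <- idx == k
      pmf <- pmfs[[k]]
      tr[sel] <- as.integer(names(pmf))[
        sample.int(length(pmf), sum(sel), replace = TRUE, prob = pmf)]
    }
    tr
  }
  vTrim <- drawTrim(vIdx, spec@vTrimPmfs)
  jTrim <- drawTrim(jIdx, spec@jTrimPmfs)
  insLen <- as.integer(names(spec@insLenPmf))[
    sample.int(length(spec@insLenPmf), m, replace = TRUE, prob = spec@insLenPmf)]
  resPool <- names(spec@insResPmf)[
    sample.int(length(spec@insResPmf), sum(insLen), replace = TRUE,
               prob = spec@insResPmf)]
  ends <- cumsum(insLen)
  middles <- substring(paste(resPool, collapse = ""), ends - insLen + 1L, ends)
  keptV <- substring(spec@vPrefixes[vIdx], 1L, nchar(spec@vPrefixes[vIdx]) - vTrim)
  sufLen <- nchar(spec@jSuffixes[jIdx])
  keptJ <- substring(spec@jSuffixes[jIdx], jTrim + 1L, sufLen)
  data.frame(
    amino_acid = paste0(keptV, middles, keptJ),
    v_gene = spec@vIds[vIdx], j_gene = spec@jIds[jIdx],
    stringsAsFactors = FALSE)
}

#' @describeIn pgen exact generation probability under the
#'   simulator: sums `P(V) P(vTrim) P(J) P(jTrim) P(insLen) prod
#'   P(residue)` over every trim scenario consistent with the observed
#'   CDR3, renormalized by the probability of producing a valid length.
#'   Returns 0 when no scenario is consistent.
#' @export
setMethod("pgen", "RecombSpec", function(object, triples, ...) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  Z <- specAcceptanceMass(object)
  vapply(seq_len(nrow(triples)), function(i) {
    exactPgenOne(object, triples$amino_acid[i], triples$v_gene[i],
                 triples$j_gene[i]) / Z
  }, numeric(1))
})

exactPgenOne <- function(spec, cdr3, vGene, jGene) {
  vi <- match(vGene, spec@vIds); ji <- match(jGene, spec@jIds)
  if (is.na(vi) || is.na(ji)) return(0)
  L <- nchar(cdr3)
  if (L < 1L || L > spec@maxCdr3Length) return(0)
  pref <- spec@vPrefixes[vi]; suf <- spec@jSuffixes[ji]
  total <- 0
  for (tv in as.integer(names(spec@vTrimPmfs[[vi]]))) {
    kv <- nchar(pref) - tv
    if (kv > L) next
    if (substring(cdr3, 1L, kv) != substring(pref, 1L, kv)) next
    for (tj in as.integer(names(spec@jTrimPmfs[[ji]]))) {
      kj <- nchar(suf) - tj
      m <- L - kv - kj
      if (m < 0L) next
      if (substring(cdr3, L - kj + 1L, L) != substring(suf, tj + 1L, nchar(suf))) next
      pIns <- spec@insLenPmf[as.character(m)]
      if (is.na(pIns)) next
      pRes <- 1
      if (m > 0L) {
        mid <- strsplit(substring(cdr3, kv + 1L, kv + m), "")[[1]]
        probs <- spec@insResPmf[mid]
        if (anyNA(probs)) next
        pRes <- prod(probs)
      }
      total <- total + spec@vProbs[vi] * spec@vTrimPmfs[[vi]][[as.character(tv)]] *
        spec@jProbs[ji] * spec@jTrimPmfs[[ji]][[as.character(tj)]] *
        unname(pIns) * pRes
    }
  }
  unname(total)
}

#' @describeIn keyMarginals exact (V, J, CDR3 length) marginals by
#'   enumerating trim and insertion-length scenarios (residue choices sum
#'   out); probabilities sum to 1.
#' @export
setMethod("keyMarginals", "RecombSpec", function(object, ...) {
  sc <- scenarioTable(object)
  sc <- sc[sc$length >= 1L & sc$length <= object@maxCdr3Length, , drop = FALSE]
  sc$prob <- sc$prob / sum(sc$prob)
  agg <- stats::aggregate(prob ~ v + j + length, data = sc, FUN = sum)
  out <- data.frame(
    v_gene = object@vIds[agg$v], j_gene = object@jIds[agg$j],
    cdr3_length = as.integer(agg$length), probability = agg$prob,
    stringsAsFactors = FALSE)
  out[order(out$v_gene, out$j_gene, out$cdr3_length), , drop = FALSE]
})

#' Enumerate the full sequence support of a spec
#'
#' Expands every trim/insertion scenario into concrete sequences; only
#' feasible for toy configurations (the expansion size is checked against
#' `maxRows`). Probabilities sum to 1 over the returned support.
#'
#' @param spec a \linkS4class{RecombSpec}.
#' @param maxRows guard on the enumeration size.
#' @return data.frame `amino_acid`, `v_gene`, `j_gene`, `pgen`.
#' @export
enumerateTriples <- function(spec, maxRows = 2e6) {
  sc <- scenarioTable(spec)
  sc <- sc[sc$length >= 1L & sc$length <= spec@maxCdr3Length, , drop = FALSE]
  res <- names(spec@insResPmf)
  nExp <- sum(length(res)^sc$ins)
  if (nExp > maxRows) {
    stop("support too large to enumerate (", format(nExp), " rows)", call. = FALSE)
  }
  Z <- sum(sc$prob)
  rows <- vector("list", nrow(sc))
  for (r in seq_len(nrow(sc))) {
    keptV <- substring(spec@vPrefixes[sc$v[r]], 1L,
                       nchar(spec@vPrefixes[sc$v[r]]) - sc$vTrim[r])
    suf <- spec@jSuffixes[sc$j[r]]
    keptJ <- substring(suf, sc$jTrim[r] + 1L, nchar(suf))
    if (sc$ins[r] == 0L) {
      mids <- ""; pMid <- 1
    } else {
      grid <- expand.grid(rep(list(res), sc$ins[r]), stringsAsFactors = FALSE)
      mids <- do.call(paste0, grid)
      pMid <- apply(as.matrix(grid), 1L, function(ch) prod(spec@insResPmf[ch]))
    }
    rows[[r]] <- data.frame(
      amino_acid = paste0(keptV, mids, keptJ),
      v_gene = spec@vIds[sc$v[r]], j_gene = spec@jIds[sc$j[r]],
      pgen = sc$prob[r] * pMid / Z, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(pgen ~ amino_acid + v_gene + j_gene, data = df, FUN = sum)
  agg[order(-agg$pgen), , drop = FALSE]
}

#' Sample from a recombination spec under a planted selection factor
#'
#' Ground-truth generator for selection-recovery experiments: proposals
#' from [sampleTriples()] are accepted with probability
#' `Q(V, J, length) / qMax`, yielding draws from the distribution
#' proportional to `pgen * Q`.
#'
#' @param spec a \linkS4class{RecombSpec}.
#' @param qstar a \linkS4class{QTable} of planted selection factors.
#' @param n number of accepted draws.
#' @param seed integer seed.
#' @return data.frame of sampled triples.
#' @export
sampleWithSelection <- function(spec, qstar, n, seed = 1L) {
  rejectionSample(spec, qstar, n, seed = seed)
}

#' A default planted selection factor for a spec
#'
#' Selection factors favouring mid-length CDR3s — a Gaussian bell over the
#' spec's reachable length range, centred at its midpoint with standard
#' deviation a quarter of the range — combined with a V-gene usage
#' modulation, bounded in `[0.2, qMax]`: a deliberate, known-truth
#' departure from the generation distribution, in the shape thymic
#' selection is usually modelled.
#'
#' @param spec a \linkS4class{RecombSpec}.
#' @param qMax envelope constant for the planted table.
#' @return a \linkS4class{QTable} with one entry per reachable key.
#' @export
plantedQTable <- function(spec = defaultRecombSpec(), qMax = 4) {
  km <- keyMarginals(spec)
  mid <- (max(km$cdr3_length) + min(km$cdr3_length)) / 2
  sigma <- max((max(km$cdr3_length) - min(km$cdr3_length)) / 4, 1)
  lenFac <- exp(-((km$cdr3_length - mid)^2) / (2 * sigma^2))
  vFac <- 0.5 + match(km$v_gene, spec@vIds) / length(spec@vIds)
  q <- pmax(0.2, pmin(qMax, qMax * lenFac * vFac / max(lenFac * vFac)))
  qTable(data.frame(v_gene = km$v_gene, j_gene = km$j_gene,
                    cdr3_length = km$cdr3_length, q = q), qMax = qMax)
}
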