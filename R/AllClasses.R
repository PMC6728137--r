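#' Gene registry for TCR beta V and J segments
#'
#' Holds the ordered V- and J-gene catalogs that define the one-hot encoding
#' dimensions (67 V and 13 J by default), an alias map between gene-name
#' dialects (IMGT-style `TRBV5-1` vs Adaptive-style `TCRBV05-01`), and a
#' blacklist of genes whose records are excluded during filtering.
#' Blacklisted genes keep their encoding slot so that encoder dimensions are
#' independent of the filtering rules.
#'
#' @slot vGenes ordered character vector of canonical V-gene names.
#' @slot jGenes ordered character vector of canonical J-gene names.
#' @slot aliases named character vector mapping dialect names to canonical
#'   names (allele suffixes such as `*01` are stripped before lookup).
#' @slot blacklist character vector of genes excluded by
#'   [filterRepertoire()] (default `TCRBJ02-05`, `TCRBJ02-07`).
#' @seealso [geneRegistry()], [defaultGeneRegistry()], [canonicalizeGene()]
#' @export
setClass("GeneRegistry",
  representation(
    vGenes = "character",
    jGenes = "character",
    aliases = "character",
    blacklist = "character"
  )
)

setValidity("GeneRegistry", function(object) {
  msg <- character()
  if (anyDuplicated(object@vGenes)) msg <- c(msg, "duplicated V gene names")
  if (anyDuplicated(object@jGenes)) msg <- c(msg, "duplicated J gene names")
  if (any(is.na(object@vGenes)) || any(is.na(object@jGenes))) {
    msg <- c(msg, "NA gene names")
  }
  if (length(object@aliases) && is.null(names(object@aliases))) {
    msg <- c(msg, "aliases must be a named character vector")
  }
  if (length(msg)) msg else TRUE
})

#' TCR repertoire of (V, J, CDR3) triples with occurrence counts
#'
#' The modeling unit throughout the package is the amino-acid triple
#' (V gene, J gene, CDR3 sequence). A `TcrRepertoire` stores one row per
#' distinct record with a positive integer occurrence count, plus optional
#' per-row metadata columns (e.g. `frame_type`, `templates`) carried from
#' parsing. Cohort count vectors are represented by the same class, with
#' rows aggregated to unique triples.
#'
#' @slot triples data.frame with columns `amino_acid`, `v_gene`, `j_gene`,
#'   `count`, and optionally further metadata columns.
#' @slot sourceId character label identifying the origin of the rows.
#' @seealso [tcrRepertoire()], [readImmunoSeq()], [buildCohortCounts()]
#' @export
setClass("TcrRepertoire",
  representation(triples = "data.frame", sourceId = "character")
)

setValidity("TcrRepertoire", function(object) {
  tr <- object@triples
  need <- c("amino_acid", "v_gene", "j_gene", "count")
  if (!all(need %in% names(tr))) {
    return(paste("triples must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(tr) && (any(tr$count <= 0) || any(tr$count != floor(tr$count)))) {
    return("counts must be positive integers")
  }
  TRUE
})

#' Per-rule exclusion tally from repertoire filtering
#'
#' Records, for each filtering rule in its fixed attribution order, how many
#' input rows it excluded; a row failing several rules is attributed to the
#' first. Retained + sum(excluded) always equals the number of input rows.
#'
#' @slot excluded named integer vector of per-rule exclusion counts.
#' @slot retained integer count of rows that passed every rule.
#' @slot input integer count of input rows.
#' @seealso [filterRepertoire()]
#' @export
setClass("FilterReport",
  representation(excluded = "integer", retained = "integer", input = "integer")
)

setValidity("FilterReport", function(object) {
  if (sum(object@excluded) + object@retained != object@input) {
    return("retained + sum(excluded) must equal input rows")
  }
  TRUE
})

#' Virtual parent class for generation-probability providers
#'
#' A provider supplies [pgen()] (pre-selection generation probability of a
#' triple), [sampleTriples()] (draws from the generation distribution) and
#' [keyMarginals()] (probabilities of (V, J, CDR3 length) keys). The
#' built-in \linkS4class{RecombSpec} simulator implements the contract
#' exactly; an external OLGA installation can be wrapped with
#' [olgaProvider()].
#'
#' @export
setClass("PgenProvider", representation("VIRTUAL"))

#' Amino-acid-level VDJ recombination simulator with exact probabilities
#'
#' A desk-scale generative model of CDR3 formation: a V segment contributes
#' a germline-encoded CDR3 prefix, a J segment a germline suffix; each is
#' trimmed by a random number of residues, and a random number of random
#' residues is inserted in between. Working at the amino-acid level keeps
#' the model exactly enumerable: [pgen()] sums over every (V trim, J trim)
#' scenario consistent with an observed CDR3, so the simulator doubles as a
#' ground-truth oracle for the selection and evaluation machinery.
#'
#' @slot vIds,jIds character vectors of segment names.
#' @slot vProbs,jProbs segment usage probabilities (each sums to 1).
#' @slot vPrefixes,jSuffixes germline-encoded CDR3 prefix/suffix per segment.
#' @slot vTrimPmfs,jTrimPmfs list of named numeric pmfs over the number of
#'   residues trimmed (names "0", "1", ...); trims never exceed the segment.
#' @slot insLenPmf named numeric pmf over insertion lengths.
#' @slot insResPmf named numeric pmf over inserted residues.
#' @slot maxCdr3Length maximum CDR3 length; longer draws are rejected and
#'   redrawn.
#' @seealso [recombSpec()], [defaultRecombSpec()], [toyRecombSpec()],
#'   [sampleWithSelection()], [enumerateTriples()]
#' @export
setClass("RecombSpec",
  contains = "PgenProvider",
  representation(
    vIds = "character", vProbs = "numeric", vPrefixes = "character",
    vTrimPmfs = "list",
    jIds = "character", jProbs = "numeric", jSuffixes = "character",
    jTrimPmfs = "list",
    insLenPmf = "numeric", insResPmf = "numeric",
    maxCdr3Length = "integer"
  )
)

setValidity("RecombSpec", function(object) {
  msg <- character()
  chkPmf <- function(p, what) {
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      paste(what, "must be a named pmf summing to 1")
    } else NULL
  }
  msg <- c(msg,
    if (abs(sum(object@vProbs) - 1) > 1e-8) "vProbs must sum to 1",
    if (abs(sum(object@jProbs) - 1) > 1e-8) "jProbs must sum to 1",
    chkPmf(object@insLenPmf, "insLenPmf"), chkPmf(object@insResPmf, "insResPmf"))
  nv <- length(object@vIds)
  if (length(object@vProbs) != nv || length(object@vPrefixes) != nv ||
      length(object@vTrimPmfs) != nv) {
    msg <- c(msg, "V slots must have one entry per V segment")
  }
  nj <- length(object@jIds)
  if (length(object@jProbs) != nj || length(object@jSuffixes) != nj ||
      length(object@jTrimPmfs) != nj) {
    msg <- c(msg, "J slots must have one entry per J segment")
  }
  for (i in seq_len(nv)) {
    tp <- object@vTrimPmfs[[i]]
    m <- chkPmf(tp, sprintf("vTrimPmfs[[%d]]", i))
    if (!is.null(m)) msg <- c(msg, m)
    else if (max(as.integer(names(tp))) > nchar(object@vPrefixes[i])) {
      msg <- c(msg, sprintf("V trim exceeds prefix length for %s", object@vIds[i]))
    }
  }
  for (i in seq_len(nj)) {
    tp <- object@jTrimPmfs[[i]]
    m <- chkPmf(tp, sprintf("jTrimPmfs[[%d]]", i))
    if (!is.null(m)) msg <- c(msg, m)
    else if (max(as.integer(names(tp))) > nchar(object@jSuffixes[i])) {
      msg <- c(msg, sprintf("J trim exceeds suffix length for %s", object@jIds[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Selection-factor table over (V gene, J gene, CDR3 length) keys
#'
#' Stores the multiplicative selection factors Q that convert a
#' pre-selection generation probability into a post-selection repertoire
#' probability: `P(x) proportional to pgen(x) * Q(V, J, length)`. Factors
#' are maximum-likelihood ratios of empirical to model key frequencies,
#' truncated at `qMax` (default 100) for numerical stability.
#'
#' @slot table data.frame with columns `v_gene`, `j_gene`, `cdr3_length`,
#'   `q`.
#' @slot qMax truncation bound; all stored factors are <= qMax.
#' @slot unseenQ factor applied to keys absent at fit time (default 0, the
#'   maximum-likelihood estimate).
#' @seealso [fitQ()], [scoreTriples()], [rejectionSample()]
#' @export
setClass("QTable",
  representation(table = "data.frame", qMax = "numeric", unseenQ = "numeric")
)

setValidity("QTable", function(object) {
  need <- c("v_gene", "j_gene", "cdr3_length", "q")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns", paste(need, collapse = ", ")))
  }
  if (object@qMax <= 0) return("qMax must be positive")
  if (nrow(object@table) && any(object@table$q > object@qMax + 1e-9)) {
    return("stored Q values must not exceed qMax")
  }
  if (nrow(object@table) && any(object@table$q < 0)) return("Q values must be >= 0")
  TRUE
})

#' beta-VAE model over TCR triples
#'
#' Encoder and decoder are small dense networks. The encoder maps the
#' one-hot triple (after per-component learned linear embeddings; V genes
#' are projected to 30 dimensions) through two ELU layers to the mean and
#' log-variance of a diagonal normal over the latent space (20-dimensional
#' by default, standard normal prior). The decoder maps a latent point
#' through two ELU layers to categorical distributions over V (67), J (13)
#' and each of the 30 CDR3 sites (21 channels: 20 amino acids + gap). The
#' `count_match` variant additionally receives the germline CDR3
#' prefix/suffix of the true genes at the decoder input and carries three
#' auxiliary regression heads (V-match count, J-match count, CDR3 length)
#' used only in the training loss.
#'
#' @slot config model configuration list, see [vaeConfig()].
#' @slot params named list of weight matrices and bias vectors.
#' @slot registry the \linkS4class{GeneRegistry} fixing encoding dimensions.
#' @slot germline germline CDR3 prefix/suffix table (data.frame with columns
#'   `gene`, `segment`, `cdr3_seq`); required for `count_match`.
#' @slot trained logical flag set by [trainVae()].
#' @seealso [tcrVae()], [trainVae()], [logPvae()], [generateTcrs()]
#' @export
setClass("TcrVae",
  representation(
    config = "list", params = "list", registry = "GeneRegistry",
    germline = "data.frame", trained = "logical"
  )
)

#' Training run report
#'
#' @slot history data.frame with per-epoch `phase`, `epoch`, `beta`,
#'   `train_loss`, `val_loss`.
#' @slot chosenPhase index of the pre-training phase whose weights seeded
#'   the full run.
#' @slot stoppingEpoch epoch at which the full run stopped.
#' @slot bestValLoss minimum validation loss observed (the restored
#'   checkpoint).
#' @slot finalBeta the annealed beta value in force at the end of training.
#' @seealso [trainVae()]
#' @export
setClass("TrainReport",
  representation(
    history = "data.frame", chosenPhase = "integer",
    stoppingEpoch = "integer", bestValLoss = "numeric", finalBeta = "numeric"
  )
)

## -- show methods -----------------------------------------------------------

setMethod("show", "GeneRegistry", function(object) {
  cat(sprintf("GeneRegistry: %d V genes, %d J genes, %d aliases, %d blacklisted\n",
              length(object@vGenes), length(object@jGenes),
              length(object@aliases), length(object@blacklist)))
})

setMethod("show", "TcrRepertoire", function(object) {
  cat(sprintf("TcrRepertoire '%s': %d records, total count %d\n",
              object@sourceId, nrow(object@triples),
              as.integer(sum(object@triples$count))))
  if (nrow(object@triples)) {
    print(utils::head(object@triples[, c("amino_acid", "v_gene", "j_gene", "count")], 5L))
    if (nrow(object@triples) > 5L) cat("...\n")
  }
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d input, %d retained\n", object@input, object@retained))
  for (nm in names(object@excluded)) {
    cat(sprintf("  %-22s %d\n", nm, object@excluded[[nm]]))
  }
})

setMethod("show", "RecombSpec", function(object) {
  cat(sprintf(paste0("RecombSpec: %d V x %d J segments, insertions %s-%s, ",
                     "max CDR3 length %d\n"),
              length(object@vIds), length(object@jIds),
              min(names(object@insLenPmf)), max(names(object@insLenPmf)),
              object@maxCdr3Length))
})

setMethod("show", "QTable", function(object) {
  cat(sprintf("QTable: %d (V, J, length) keys, qMax = %g, unseen Q = %g\n",
              nrow(object@table), object@qMax, object@unseenQ))
})

setMethod("show", "TcrVae", function(object) {
  cfg <- object@config
  cat(sprintf("TcrVae (%s): latent %d, hidden %s, beta %g, %s\n",
              cfg$model_kind, cfg$latent_dim,
              paste(cfg$hidden_dims, collapse = "x"), cfg$beta,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "TrainReport", function(object) {
  cat(sprintf(paste0("TrainReport: pre-training phase %d selected, stopped at ",
                     "epoch %d, best validation loss %.4f, final beta %g\n"),
              object@chosenPhase, object@stoppingEpoch, object@bestValLoss,
              object@finalBeta))
})

## -- simple accessors -------------------------------------------------------

#' @rdname GeneRegistry-class
#' @export
setMethod("vGenes", "GeneRegistry", function(object) object@vGenes)

#' @rdname GeneRegistry-class
#' @export
setMethod("jGenes", "GeneRegistry", function(object) object@jGenes)

#' @rdname TcrRepertoire-class
#' @export
setMethod("triples", "TcrRepertoire", function(object) object@triples)

#' @rdname TcrRepertoire-class
#' @export
setMethod("nTriples", "TcrRepertoire", function(object) nrow(object@triples))
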