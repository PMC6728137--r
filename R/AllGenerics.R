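#' Generation probability of TCR triples under a recombination model
#'
#' @param object a generation-probability provider (e.g. a
#'   \linkS4class{RecombSpec} or an [olgaProvider()]).
#' @param triples data.frame with columns `amino_acid`, `v_gene`, `j_gene`.
#' @param ... passed to methods.
#' @return numeric vector of pre-selection generation probabilities, one per
#'   row of `triples`; 0 where the model cannot produce the sequence.
#' @export
setGeneric("pgen", function(object, triples, ...) standardGeneric("pgen"))

#' Sample TCR triples from a generation-probability provider
#'
#' @param object the provider.
#' @param n number of triples to draw.
#' @param seed integer seed; draws are deterministic given the seed.
#' @param ... passed to methods.
#' @return data.frame with columns `amino_acid`, `v_gene`, `j_gene`.
#' @export
setGeneric("sampleTriples", function(object, n, seed = 1L, ...)
  standardGeneric("sampleTriples"))

#' Exact or estimated (V, J, CDR3 length) key marginals of a provider
#'
#' @param object the provider.
#' @param ... passed to methods (Monte Carlo fallback size, seed).
#' @return data.frame with columns `v_gene`, `j_gene`, `cdr3_length`,
#'   `probability`. For providers with enumerable trim/insertion structure
#'   the probabilities are exact and sum to 1.
#' @export
setGeneric("keyMarginals", function(object, ...) standardGeneric("keyMarginals"))

#' @rdname GeneRegistry-class
#' @param object a GeneRegistry.
#' @export
setGeneric("vGenes", function(object) standardGeneric("vGenes"))

#' @rdname GeneRegistry-class
#' @export
setGeneric("jGenes", function(object) standardGeneric("jGenes"))

#' @rdname TcrRepertoire-class
#' @param object a TcrRepertoire.
#' @export
setGeneric("triples", function(object) standardGeneric("triples"))

#' @rdname TcrRepertoire-class
#' @export
setGeneric("nTriples", function(object) standardGeneric("nTriples"))
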