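# Selection layer over a generation-probability provider: Q-factor
# estimation on (V, J, CDR3 length) keys, scoring, and rejection sampling.
# Generic over any PgenProvider (the built-in simulator or external OLGA).

#' Construct a QTable
#'
#' @param table data.frame with columns `v_gene`, `j_gene`, `cdr3_length`,
#'   `q`.
#' @param qMax truncation bound (default 100).
#' @param unseenQ factor for keys absent from the table (default 0, the
#'   maximum-likelihood estimate; set a small positive floor when finite
#'   log scores are needed).
#' @return a \linkS4class{QTable}.
#' @export
qTable <- function(table, qMax = 100, unseenQ = 0) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$cdr3_length <- as.integer(table$cdr3_length)
  methods::new("QTable", table = table, qMax = qMax, unseenQ = unseenQ)
}

keyString <- function(v, j, len) paste(v, j, len, sep = "\r")

# Q values for triples (or key columns), applying the unseen policy.
qLookup <- function(qtable, v, j, len) {
  idx <- match(keyString(v, j, len),
               keyString(qtable@table$v_gene, qtable@table$j_gene,
                         qtable@table$cdr3_length))
  q <- qtable@table$q[idx]
  q[is.na(q)] <- qtable@unseenQ
  q
}

#' Key marginals of a provider, exact when available
#'
#' Uses the provider's exact [keyMarginals()] when implemented; otherwise
#' falls back to Monte Carlo frequencies of `n_samples` provider draws.
#'
#' @param provider a \linkS4class{PgenProvider}.
#' @param n_samples Monte Carlo fallback size.
#' @param seed seed for the fallback draws.
#' @return data.frame `v_gene`, `j_gene`, `cdr3_length`, `probability`.
#' @export
estimateKeyMarginals <- function(provider, n_samples = 1e5, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  exact <- tryCatch(keyMarginals(provider), error = function(e) NULL)
  if (!is.null(exact)) return(exact)
  draws <- sampleTriples(provider, as.integer(n_samples), seed = seed)
  empiricalKeyFreq(draws)
}

empiricalKeyFreq <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  key <- data.frame(v_gene = df$v_gene, j_gene = df$j_gene,
                    cdr3_length = nchar(df$amino_acid), stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(probability = rep(1, nrow(key))), key, FUN = sum)
  agg$probability <- agg$probability / nrow(key)
  agg$cdr3_length <- as.integer(agg$cdr3_length)
  agg[order(agg$v_gene, agg$j_gene, agg$cdr3_length), , drop = FALSE]
}

#' Fit selection factors from training sequences
#'
#' The maximum-likelihood selection factor for a (V, J, CDR3 length) key
#' is the ratio of its empirical frequency in the training data to its
#' probability under the recombination model, truncated at `qMax`
#' (default 100) for numerical stability. Keys the model assigns zero
#' probability but that occur in the data get `qMax` with a warning; keys
#' unseen in training follow `unseenQ`.
#'
#' @param train data.frame of training triples (or a
#'   \linkS4class{TcrRepertoire}).
#' @param provider a \linkS4class{PgenProvider}.
#' @param qMax truncation bound.
#' @param unseenQ policy for keys absent from training.
#' @param marginals optional precomputed provider key marginals.
#' @param ... passed to [estimateKeyMarginals()].
#' @return a \linkS4class{QTable}.
#' @export
fitQ <- function(train, provider, qMax = 100, unseenQ = 0, marginals = NULL, ...) {
  if (methods::is(train, "TcrRepertoire")) {
    df <- triples(train)
    train <- df[rep(seq_len(nrow(df)), df$count), c("amino_acid", "v_gene", "j_gene")]
  }
  train <- as.data.frame(train, stringsAsFactors = FALSE)
  if (!nrow(train)) stop("training data is empty", call. = FALSE)
  emp <- empiricalKeyFreq(train)
  if (is.null(marginals)) marginals <- estimateKeyMarginals(provider, ...)
  idx <- match(keyString(emp$v_gene, emp$j_gene, emp$cdr3_length),
               keyString(marginals$v_gene, marginals$j_gene, marginals$cdr3_length))
  modelP <- marginals$probability[idx]
  zero <- is.na(modelP) | modelP <= 0
  if (any(zero)) {
    warning(sum(zero), " key(s) with empirical support have zero model ",
            "probability; assigned qMax")
  }
  q <- ifelse(zero, qMax, pmin(emp$probability / ifelse(zero, 1, modelP), qMax))
  qTable(data.frame(v_gene = emp$v_gene, j_gene = emp$j_gene,
                    cdr3_length = emp$cdr3_length, q = q),
         qMax = qMax, unseenQ = unseenQ)
}

#' Score triples under the recombination-selection model
#'
#' The (unnormalized) selection-model density `pgen(x) * Q(V, J, length)`.
#'
#' @param x data.frame of triples.
#' @param provider a \linkS4class{PgenProvider}.
#' @param qtable a fitted \linkS4class{QTable}.
#' @return non-negative numeric vector.
#' @export
scoreTriples <- function(x, provider, qtable) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  pgen(provider, x) * qLookup(qtable, x$v_gene, x$j_gene, nchar(x$amino_acid))
}

#' Normalize scores over a finite collection
#'
#' Rescales a vector of per-sequence scores (from one estimator) to sum
#' to 1 across the collection, e.g. before comparing estimators on a
#' common sequence panel.
#'
#' @param scores non-negative numeric vector.
#' @return numeric vector summing to 1.
#' @export
normalizeScores <- function(scores) {
  s <- sum(scores)
  if (s <= 0) stop("scores sum to zero; nothing to normalize", call. = FALSE)
  scores / s
}

#' Rejection sampling from the recombination-selection distribution
#'
#' Proposes from the provider's generation distribution and accepts each
#' proposal with probability `Q(V, J, length) / qMax`, yielding exactly
#' `n` draws from the distribution proportional to `pgen * Q`.
#'
#' @param provider a \linkS4class{PgenProvider}.
#' @param qtable a fitted \linkS4class{QTable} (its `qMax` is the
#'   envelope constant).
#' @param n accepted draws required.
#' @param seed integer seed.
#' @param minAcceptance abort if the observed acceptance rate falls below
#'   this floor after a probe batch (suggests an oversized `qMax`).
#' @return data.frame of `n` sampled triples.
#' @export
rejectionSample <- function(provider, qtable, n, seed = 1L,
                            minAcceptance = 1e-4) {
  stopifnot(isCount(n))
  acc <- list(); got <- 0L; proposed <- 0L; round <- 0L
  while (got < n) {
    round <- round + 1L
    m <- max(2L * (n - got), 2000L)
    prop <- sampleTriples(provider, m, seed = deriveSeed(seed, round))
    u <- withSeed(deriveSeed(seed, round + 1000000L), stats::runif(m))
    keep <- u < qLookup(qtable, prop$v_gene, prop$j_gene,
                        nchar(prop$amino_acid)) / qtable@qMax
    acc[[round]] <- prop[keep, , drop = FALSE]
    got <- got + sum(keep)
    proposed <- proposed + m
    if (proposed >= 1e4 && got / proposed < minAcceptance) {
      stop("rejection acceptance rate below ", minAcceptance,
           "; consider a smaller qMax", call. = FALSE)
    }
  }
  out <- do.call(rbind, acc)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a QTable
#'
#' CSV columns `v_gene`, `j_gene`, `cdr3_length`, `q`; `qMax` and
#' `unseenQ` ride along in a JSON sidecar when writing JSON.
#'
#' @param qtable a \linkS4class{QTable}.
#' @param path output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `writeQTable` returns `path` invisibly; `readQTable` a
#'   \linkS4class{QTable}.
#' @export
writeQTable <- function(qtable, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(qMax = qtable@qMax, unseenQ = qtable@unseenQ,
                              table = qtable@table),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(qtable@table, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeQTable
#' @param qMax,unseenQ used when reading the CSV form (the JSON form
#'   stores them).
#' @export
readQTable <- function(path, qMax = 100, unseenQ = 0) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    qTable(obj$table, qMax = obj$qMax, unseenQ = obj$unseenQ)
  } else {
    qTable(utils::read.csv(path, stringsAsFactors = FALSE),
           qMax = qMax, unseenQ = unseenQ)
  }
}
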