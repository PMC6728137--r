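# Repertoire summary statistics and divergence comparisons, plus the
# cohort-frequency regression and the latent-space PCA.

.scalesCache <- new.env(parent = emptyenv())

#' Amino-acid physicochemical scale table
#'
#' Kyte-Doolittle hydropathy, Zimmerman bulkiness and Grantham polarity,
#' shipped as an editable CSV fixture (`inst/extdata/aa_scales.csv`).
#'
#' @return data.frame keyed by one-letter code.
#' @export
aaScales <- function() {
  if (is.null(.scalesCache$tab)) {
    .scalesCache$tab <- utils::read.csv(
      system.file("extdata", "aa_scales.csv", package = "tcrvae", mustWork = TRUE),
      stringsAsFactors = FALSE)
  }
  .scalesCache$tab
}

# Side-chain pKa values (EMBOSS set) for the Henderson-Hasselbalch net
# charge; termini are excluded since the CDR3 is an internal loop.
sideChainPka <- c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

#' Per-sequence CDR3 summary statistics
#'
#' Computes, per CDR3: acidity (fraction of D/E), aliphatic index (Ikai:
#' `x_A + 2.9 x_V + 3.9 (x_I + x_L)` on residue fractions), aromaticity
#' (fraction of F/W/Y), basicity (fraction of K/R/H), bulkiness (mean
#' Zimmerman), length in residues, net charge at pH 7
#' (Henderson-Hasselbalch on side-chain pKa values), GRAVY (mean
#' Kyte-Doolittle hydropathy) and polarity (mean Grantham).
#'
#' @param cdr3 character vector of CDR3 strings, or a data.frame of
#'   triples (its `amino_acid` column is used).
#' @return data.frame of the nine named statistics, one row per sequence.
#' @examples
#' sequenceSummaries("V")$gravy  # 4.2, the Kyte-Doolittle value of valine
#' @export
sequenceSummaries <- function(cdr3) {
  if (is.data.frame(cdr3)) cdr3 <- cdr3$amino_acid
  if (!length(cdr3) || any(nchar(cdr3) == 0L)) {
    stop("empty CDR3 sequence", call. = FALSE)
  }
  sc <- aaScales()
  counts <- t(vapply(strsplit(cdr3, "", fixed = TRUE), function(ch) {
    tabulate(match(ch, sc$aa), nbins = nrow(sc))
  }, integer(nrow(sc))))
  colnames(counts) <- sc$aa
  L <- nchar(cdr3)
  frac <- counts / L
  pH <- 7
  pos <- rowSums(sweep(counts[, c("R", "K", "H"), drop = FALSE], 2L,
                       1 / (1 + 10^(pH - sideChainPka[c("R", "K", "H")])), "*"))
  neg <- rowSums(sweep(counts[, c("D", "E", "C", "Y"), drop = FALSE], 2L,
                       1 / (1 + 10^(sideChainPka[c("D", "E", "C", "Y")] - pH)), "*"))
  data.frame(
    acidity = frac[, "D"] + frac[, "E"],
    aliphatic_index = frac[, "A"] + 2.9 * frac[, "V"] +
      3.9 * (frac[, "I"] + frac[, "L"]),
    aromaticity = frac[, "F"] + frac[, "W"] + frac[, "Y"],
    basicity = frac[, "K"] + frac[, "R"] + frac[, "H"],
    bulkiness = as.vector(frac %*% sc$zimmerman_bulkiness),
    cdr3_length = L,
    charge = pos - neg,
    gravy = as.vector(frac %*% sc$kyte_doolittle),
    polarity = as.vector(frac %*% sc$grantham_polarity)
  )
}

#' l1 divergence between two categorical distributions
#'
#' `sum(|p_i - q_i|)` over the shared support; bounded by \[0, 2\].
#'
#' @param p,q named numeric mass vectors (or `SummaryDistribution`-style
#'   lists with `support` and `masses`). Supports must match as sets.
#' @return scalar in \[0, 2\].
#' @export
l1Divergence <- function(p, q) {
  pq <- alignSupports(p, q)
  sum(abs(pq$p - pq$q))
}

#' Jensen-Shannon divergence (natural log)
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q)/2`; bounded by
#' \[0, log 2\].
#'
#' @inheritParams l1Divergence
#' @return scalar in \[0, log(2)\].
#' @export
jsDivergence <- function(p, q) {
  pq <- alignSupports(p, q)
  m <- (pq$p + pq$q) / 2
  klTerm <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz]))
  }
  0.5 * klTerm(pq$p) + 0.5 * klTerm(pq$q)
}

alignSupports <- function(p, q) {
  if (is.list(p) && !is.null(p$masses)) {
    p <- stats::setNames(p$masses, p$support)
  }
  if (is.list(q) && !is.null(q$masses)) {
    q <- stats::setNames(q$masses, q$support)
  }
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) stop("mismatched support", call. = FALSE)
    return(list(p = p, q = q))
  }
  if (!setequal(names(p), names(q))) {
    stop("mismatched support: distributions must share bins/categories",
         call. = FALSE)
  }
  q <- q[names(p)]
  list(p = p, q = q)
}

# Mass vectors over shared equal-width bins computed from the pooled pair,
# so the comparison is symmetric in its arguments.
binPair <- function(a, b, nBins = 30L) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  cut2 <- function(x) {
    i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(i, nbins = nBins) / length(x)
  }
  nm <- paste0("bin", seq_len(nBins))
  list(p = stats::setNames(cut2(a), nm), q = stats::setNames(cut2(b), nm))
}

categoricalPair <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  list(p = table(factor(a, lev)) / length(a),
       q = table(factor(b, lev)) / length(b))
}

kmerCounts <- function(cdr3, k = 2L) {
  seqs <- cdr3[nchar(cdr3) >= k]
  kmers <- unlist(lapply(seqs, function(s) {
    substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))
  }), use.names = FALSE)
  kmers
}

# Within-set Levenshtein distance distributions (nearest-neighbor excludes
# self-matches; pairwise takes the upper triangle), on a subsample. The
# subsample seed is derived from the set's own content so that identical
# repertoires yield identical subsamples (self-comparison is exactly 0).
levenshteinDists <- function(cdr3, maxSeqs, seed) {
  if (length(cdr3) > maxSeqs) {
    sub <- contentSeed(seed, paste(sort(cdr3), collapse = ""))
    cdr3 <- cdr3[withSeed(sub, sample.int(length(cdr3), maxSeqs))]
  }
  D <- utils::adist(cdr3)
  diag(D) <- NA
  list(nn = apply(D, 1L, min, na.rm = TRUE),
       pw = D[upper.tri(D)])
}

#' Divergence report between two repertoires
#'
#' Computes the 15-statistic comparison panel between repertoires `a` and
#' `b`: Jensen-Shannon divergence on the binned distributions of acidity,
#' aliphatic index, aromaticity, basicity, bulkiness, CDR3 length, charge,
#' GRAVY, nearest-neighbor Levenshtein distance, pairwise Levenshtein
#' distance and polarity, and l1 divergence on CDR3 2-mer frequencies,
#' CDR3 amino-acid frequencies, J gene frequencies and V gene frequencies.
#' Numeric statistics are binned with `nBins` equal-width bins over the
#' pooled range of the pair, so the report is symmetric in its arguments.
#'
#' To obtain the train-baseline variant (how far a random training draw
#' sits from the reference), pass a random subset of the training data as
#' `a`.
#'
#' @param a,b data.frames of triples (e.g. generated vs held-out).
#' @param nBins bins for numeric summaries.
#' @param levenshteinSample per-side subsample cap for the quadratic
#'   Levenshtein statistics.
#' @param seed seed for the Levenshtein subsample.
#' @return data.frame with columns `statistic`, `kind` (`js` or `l1`) and
#'   `divergence`; attributes `n_a`, `n_b` record the sample sizes.
#' @export
divergenceReport <- function(a, b, nBins = 30L, levenshteinSample = 2000L,
                             seed = 1L) {
  a <- as.data.frame(a, stringsAsFactors = FALSE)
  b <- as.data.frame(b, stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) stop("both repertoires must be non-empty", call. = FALSE)
  sa <- sequenceSummaries(a)
  sb <- sequenceSummaries(b)
  numericStats <- c("acidity", "aliphatic_index", "aromaticity", "basicity",
                    "bulkiness", "cdr3_length", "charge", "gravy", "polarity")
  rows <- list()
  for (st in numericStats) {
    pq <- binPair(sa[[st]], sb[[st]], nBins)
    rows[[st]] <- data.frame(statistic = st, kind = "js",
                             divergence = jsDivergence(pq$p, pq$q))
  }
  la <- levenshteinDists(a$amino_acid, levenshteinSample, seed)
  lb <- levenshteinDists(b$amino_acid, levenshteinSample, seed)
  for (st in c("nearest_neighbor_levenshtein", "pairwise_levenshtein")) {
    da <- if (st == "nearest_neighbor_levenshtein") la$nn else la$pw
    db <- if (st == "nearest_neighbor_levenshtein") lb$nn else lb$pw
    pq <- binPair(da, db, nBins)
    rows[[st]] <- data.frame(statistic = st, kind = "js",
                             divergence = jsDivergence(pq$p, pq$q))
  }
  catStats <- list(
    cdr3_2mer_freq = list(kmerCounts(a$amino_acid), kmerCounts(b$amino_acid)),
    cdr3_aa_freq = list(kmerCounts(a$amino_acid, 1L), kmerCounts(b$amino_acid, 1L)),
    j_gene_freq = list(a$j_gene, b$j_gene),
    v_gene_freq = list(a$v_gene, b$v_gene))
  for (st in names(catStats)) {
    pq <- categoricalPair(catStats[[st]][[1L]], catStats[[st]][[2L]])
    rows[[st]] <- data.frame(statistic = st, kind = "l1",
                             divergence = l1Divergence(c(pq$p), c(pq$q)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_a") <- nrow(a)
  attr(out, "n_b") <- nrow(b)
  out
}

#' Log-log regression of cohort frequency on model probability
#'
#' Ordinary least squares of log frequency on log probability over the
#' finite pairs; pairs with non-finite values (e.g. zero probabilities)
#' are dropped and counted. A constant predictor yields R-squared 0 by
#' convention.
#'
#' @param log_freq,log_prob paired numeric vectors.
#' @return list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `n_dropped`.
#' @export
cohortFrequencyFit <- function(log_freq, log_prob) {
  stopifnot(length(log_freq) == length(log_prob))
  ok <- is.finite(log_freq) & is.finite(log_prob)
  nDropped <- sum(!ok)
  x <- log_prob[ok]; y <- log_freq[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::var(x) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n_used = length(x), n_dropped = nDropped))
  }
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n_used = length(x), n_dropped = nDropped)
}

#' PCA of latent embeddings
#'
#' Standard principal components analysis of mean-centered latent mean
#' vectors, reduced to the top two components. Re-run it on a filtered
#' subset (e.g. sequences using one (V, J) pair) to expose the next level
#' of latent organization.
#'
#' @param embeddings numeric matrix of latent vectors (rows = sequences),
#'   e.g. `vaeEncode(model, data)$mean`.
#' @param labels optional vector of per-sequence labels carried into the
#'   output.
#' @return list with `projection` (n x 2), `explained_variance_ratio`
#'   (length 2), `rotation` (orthonormal columns) and `labels`.
#' @export
latentPca <- function(embeddings, labels = NULL) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("need at least 2 embeddings", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(embeddings)) {
    stop("labels must match the number of embeddings", call. = FALSE)
  }
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  list(projection = pc$x[, seq_len(k), drop = FALSE],
       explained_variance_ratio = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       labels = labels)
}
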