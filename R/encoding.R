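# Deterministic conversion between TCR triples and the fixed-width one-hot
# representation: 30 CDR3 sites x 21 channels (20 amino acids + gap), plus
# one-hot V (67 by default) and J (13) blocks. The learned linear input
# embeddings live in the model, not here.

cdr3Width <- 30L

#' Amino-acid alphabet used throughout the package
#'
#' @param withGap include the gap symbol `-` as the final (21st) channel.
#' @return character vector of one-letter codes, alphabetical, gap last.
#' @export
aaAlphabet <- function(withGap = FALSE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (withGap) c(aa, "-") else aa
}

#' Pad a CDR3 sequence with central gaps to the fixed width
#'
#' The left (V-proximal) segment keeps `ceiling(L/2)` residues and the
#' right (J-proximal) segment `floor(L/2)` — one extra on the left for odd
#' lengths — with gaps in between totalling `30 - L`.
#'
#' @param cdr3 character vector of CDR3 amino-acid strings, each of length
#'   1 to 30.
#' @return character vector of width-30 padded strings over the 21-symbol
#'   alphabet.
#' @examples
#' padMiddle("CASSF")  # "CAS" + 25 gaps + "SF"
#' @export
padMiddle <- function(cdr3) {
  L <- nchar(cdr3)
  if (any(L < 1L | L > cdr3Width)) {
    stop("CDR3 length must be between 1 and 30", call. = FALSE)
  }
  left <- ceiling(L / 2)
  paste0(substring(cdr3, 1L, left),
         strrep("-", cdr3Width - L),
         substring(cdr3, left + 1L, L))
}

#' Remove gap padding from a padded CDR3
#'
#' @param padded character vector of width-30 padded strings.
#' @param strict if `TRUE`, error unless the gaps form the single central
#'   block that [padMiddle()] produces; if `FALSE`, gaps are stripped
#'   wherever they occur.
#' @return character vector of unpadded CDR3 strings.
#' @export
unpadCdr3 <- function(padded, strict = TRUE) {
  if (any(nchar(padded) != cdr3Width)) {
    stop("padded CDR3 must have exactly 30 symbols", call. = FALSE)
  }
  out <- gsub("-", "", padded, fixed = TRUE)
  if (strict) {
    ok <- padded == padMiddle(ifelse(nchar(out) >= 1L, out, "A"))
    ok[nchar(out) < 1L] <- FALSE
    if (any(!ok)) {
      stop("gaps are not a contiguous central block consistent with padMiddle",
           call. = FALSE)
    }
  }
  out
}

#' One-hot encode a single TCR triple
#'
#' @param triple list or one-row data.frame with `amino_acid`, `v_gene`,
#'   `j_gene` (canonical names).
#' @param registry a \linkS4class{GeneRegistry}.
#' @return list with `cdr3_block` (30 x 21 matrix, one 1 per row; gap is
#'   channel 21), `v_block` (length 67) and `j_block` (length 13).
#' @export
oneHotEncode <- function(triple, registry = defaultGeneRegistry()) {
  flat <- encodeTriples(as.data.frame(triple, stringsAsFactors = FALSE), registry)
  nv <- length(registry@vGenes); nj <- length(registry@jGenes)
  list(
    cdr3_block = matrix(flat[1L, seq_len(cdr3Width * 21L)], nrow = cdr3Width,
                        ncol = 21L, byrow = TRUE,
                        dimnames = list(NULL, aaAlphabet(TRUE))),
    v_block = stats::setNames(flat[1L, cdr3Width * 21L + seq_len(nv)], registry@vGenes),
    j_block = stats::setNames(flat[1L, cdr3Width * 21L + nv + seq_len(nj)], registry@jGenes)
  )
}

#' Encode triples as a flat one-hot matrix
#'
#' Row layout: 630 CDR3 indicators (site-major: site 1 channels 1..21,
#' then site 2, ...), then the V block, then the J block; 710 columns for
#' the default 67 V / 13 J registry.
#'
#' @param df data.frame with columns `amino_acid`, `v_gene`, `j_gene`.
#' @param registry a \linkS4class{GeneRegistry}.
#' @return numeric matrix, one row per triple.
#' @export
encodeTriples <- function(df, registry = defaultGeneRegistry()) {
  n <- nrow(df)
  symbols <- aaAlphabet(TRUE)
  vIdx <- match(df$v_gene, registry@vGenes)
  jIdx <- match(df$j_gene, registry@jGenes)
  if (any(is.na(vIdx)) || any(is.na(jIdx))) {
    bad <- unique(c(df$v_gene[is.na(vIdx)], df$j_gene[is.na(jIdx)]))
    stop("gene(s) not in registry: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  padded <- padMiddle(df$amino_acid)
  chars <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = cdr3Width, byrow = TRUE)
  chanIdx <- matrix(match(chars, symbols), nrow = n)
  if (any(is.na(chanIdx))) {
    stop("CDR3 contains residues outside the 20-letter alphabet", call. = FALSE)
  }
  nv <- length(registry@vGenes); nj <- length(registry@jGenes)
  out <- matrix(0, nrow = n, ncol = cdr3Width * 21L + nv + nj)
  rows <- rep(seq_len(n), times = cdr3Width)
  sites <- rep(seq_len(cdr3Width), each = n)
  out[cbind(rows, (sites - 1L) * 21L + as.vector(chanIdx))] <- 1
  out[cbind(seq_len(n), cdr3Width * 21L + vIdx)] <- 1
  out[cbind(seq_len(n), cdr3Width * 21L + nv + jIdx)] <- 1
  out
}

#' Decode a flat one-hot (or categorical-probability) matrix by argmax
#'
#' Inverse of [encodeTriples()] on valid encodings; on probability matrices
#' it takes the per-block argmax. Gap symbols are stripped from the CDR3
#' (non-strictly, so argmax decoding always yields a string).
#'
#' @param mat numeric matrix with the [encodeTriples()] column layout.
#' @param registry a \linkS4class{GeneRegistry}.
#' @return data.frame with columns `amino_acid`, `v_gene`, `j_gene`.
#' @export
decodeOneHot <- function(mat, registry = defaultGeneRegistry()) {
  n <- nrow(mat)
  symbols <- aaAlphabet(TRUE)
  nv <- length(registry@vGenes); nj <- length(registry@jGenes)
  cdr3 <- vapply(seq_len(n), function(i) {
    site <- matrix(mat[i, seq_len(cdr3Width * 21L)], nrow = cdr3Width, byrow = TRUE)
    paste(symbols[max.col(site, ties.method = "first")], collapse = "")
  }, character(1))
  vIdx <- max.col(mat[, cdr3Width * 21L + seq_len(nv), drop = FALSE],
                  ties.method = "first")
  jIdx <- max.col(mat[, cdr3Width * 21L + nv + seq_len(nj), drop = FALSE],
                  ties.method = "first")
  data.frame(
    amino_acid = gsub("-", "", cdr3, fixed = TRUE),
    v_gene = registry@vGenes[vIdx],
    j_gene = registry@jGenes[jIdx],
    stringsAsFactors = FALSE
  )
}
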