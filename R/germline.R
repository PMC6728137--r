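# Germline-encoded CDR3 prefixes (V) and suffixes (J), and the
# germline-match counts used by the count_match model.

#' Germline CDR3 prefix/suffix table
#'
#' A germline table is a data.frame with columns `gene`, `segment` ("V" or
#' "J") and `cdr3_seq`: the amino acids a gene contributes to the CDR3
#' before trimming (the prefix from the conserved C for V genes, the suffix
#' up to the conserved F for J genes; possibly the empty string).
#'
#' `germlineTable` derives the exact table from a \linkS4class{RecombSpec};
#' `readGermlineTable` reads one from CSV. The packaged table for the
#' default real-gene registry
#' (`inst/extdata/germline_cdr3_synthetic.csv`) is a synthetic stand-in
#' with plausible motifs, intended for smoke tests only — substitute
#' IMGT-derived boundaries for real analyses.
#'
#' @param spec a \linkS4class{RecombSpec}.
#' @return data.frame with columns `gene`, `segment`, `cdr3_seq`.
#' @export
germlineTable <- function(spec) {
  stopifnot(methods::is(spec, "RecombSpec"))
  data.frame(
    gene = c(spec@vIds, spec@jIds),
    segment = c(rep("V", length(spec@vIds)), rep("J", length(spec@jIds))),
    cdr3_seq = c(spec@vPrefixes, spec@jSuffixes),
    stringsAsFactors = FALSE
  )
}

#' @rdname germlineTable
#' @param path CSV file with columns `gene`, `segment`, `cdr3_seq`.
#' @export
readGermlineTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "segment", "cdr3_seq")
  if (!all(need %in% names(df))) {
    stop("germline table must have columns gene, segment, cdr3_seq", call. = FALSE)
  }
  df$cdr3_seq[is.na(df$cdr3_seq)] <- ""
  df
}

#' @rdname germlineTable
#' @export
defaultGermlineTable <- function() {
  readGermlineTable(system.file("extdata", "germline_cdr3_synthetic.csv",
                                package = "tcrvae", mustWork = TRUE))
}

#' Germline-match counts at the CDR3 ends
#'
#' For each triple, the number of contiguous amino acids at the 5' end of
#' the CDR3 identical to the assigned V gene's germline CDR3 prefix, and
#' analogously at the 3' end against the J gene's germline suffix. These
#' are the regression targets of the count_match model.
#'
#' @param df data.frame with columns `amino_acid`, `v_gene`, `j_gene`.
#' @param germline a germline table, see [germlineTable()]. Genes without
#'   an entry count as empty germline (match 0).
#' @return data.frame with integer columns `v_match` and `j_match`.
#' @export
germlineMatchCounts <- function(df, germline) {
  vSeq <- germline$cdr3_seq[germline$segment == "V"][
    match(df$v_gene, germline$gene[germline$segment == "V"])]
  jSeq <- germline$cdr3_seq[germline$segment == "J"][
    match(df$j_gene, germline$gene[germline$segment == "J"])]
  vSeq[is.na(vSeq)] <- ""
  jSeq[is.na(jSeq)] <- ""
  prefixMatch <- function(a, b) {
    k <- min(nchar(a), nchar(b))
    if (k == 0L) return(0L)
    ac <- strsplit(substring(a, 1L, k), "")[[1]]
    bc <- strsplit(substring(b, 1L, k), "")[[1]]
    miss <- which(ac != bc)
    if (length(miss)) miss[1L] - 1L else k
  }
  revStr <- function(s) {
    vapply(strsplit(s, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
  }
  vm <- mapply(prefixMatch, df$amino_acid, vSeq, USE.NAMES = FALSE)
  jm <- mapply(prefixMatch, revStr(df$amino_acid), revStr(jSeq), USE.NAMES = FALSE)
  data.frame(v_match = as.integer(vm), j_match = as.integer(jm))
}
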