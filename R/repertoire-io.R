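# Parsing, filtering and counting of TCR repertoire files.

#' Construct a TcrRepertoire from a data.frame of triples
#'
#' @param triples data.frame with columns `amino_acid`, `v_gene`, `j_gene`
#'   and optionally `count` (default 1 per row) plus metadata columns.
#' @param sourceId label for provenance.
#' @return a \linkS4class{TcrRepertoire}.
#' @export
tcrRepertoire <- function(triples, sourceId = "repertoire") {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (!"count" %in% names(triples)) triples$count <- rep(1L, nrow(triples))
  methods::new("TcrRepertoire", triples = triples, sourceId = sourceId)
}

# Default column map for the Adaptive ImmunoSEQ dialect. Each entry lists
# header spellings tried in order; `templates` and `frame_type` are optional.
immunoseqColumnMap <- function() {
  list(
    amino_acid = c("amino_acid", "aminoAcid", "cdr3_amino_acid"),
    v_gene     = c("v_gene", "vGeneName", "v_resolved"),
    j_gene     = c("j_gene", "jGeneName", "j_resolved"),
    frame_type = c("frame_type", "frameType", "sequenceStatus"),
    templates  = c("templates", "count (templates/reads)", "count", "reads")
  )
}

#' Parse an ImmunoSEQ-dialect repertoire export
#'
#' Reads a tab-separated export, resolves the required columns through a
#' configurable column map, and canonicalizes gene names against the
#' registry. Gene calls that cannot be resolved (unknown, family-ambiguous,
#' multi-gene) become `NA` and are tallied later by [filterRepertoire()];
#' parsing never fails on them. Frame annotation and template abundance are
#' carried as metadata columns; every record gets occurrence count 1
#' (template abundance is deliberately not used as a count).
#'
#' @param path path to a TSV file with a header row.
#' @param registry a \linkS4class{GeneRegistry}.
#' @param columnMap named list of candidate header spellings per field;
#'   see `tcrvae:::immunoseqColumnMap()` for the defaults.
#' @return a \linkS4class{TcrRepertoire} with metadata columns `frame_type`
#'   and `templates` when present in the file.
#' @export
readImmunoSeq <- function(path, registry = defaultGeneRegistry(),
                          columnMap = immunoseqColumnMap()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(field, required) {
    hit <- intersect(columnMap[[field]], names(raw))
    if (length(hit)) return(raw[[hit[1L]]])
    if (required) {
      stop(sprintf("required column '%s' not found (tried: %s)", field,
                   paste(columnMap[[field]], collapse = ", ")), call. = FALSE)
    }
    NULL
  }
  out <- data.frame(
    amino_acid = as.character(pick("amino_acid", TRUE)),
    v_gene = canonicalizeGene(as.character(pick("v_gene", TRUE)), registry),
    j_gene = canonicalizeGene(as.character(pick("j_gene", TRUE)), registry),
    stringsAsFactors = FALSE
  )
  ft <- pick("frame_type", FALSE)
  if (!is.null(ft)) out$frame_type <- as.character(ft)
  tm <- pick("templates", FALSE)
  if (!is.null(tm)) out$templates <- as.numeric(tm)
  out$count <- rep(1L, nrow(out))
  tcrRepertoire(out, sourceId = basename(path))
}

#' Read / write the canonical repertoire CSV
#'
#' The canonical interchange format is a CSV with header
#' `amino_acid,v_gene,j_gene,count`.
#'
#' @param path file path.
#' @param sourceId label attached to the repertoire on read.
#' @return `readRepertoireCsv` returns a \linkS4class{TcrRepertoire};
#'   `writeRepertoireCsv` returns `path` invisibly.
#' @export
readRepertoireCsv <- function(path, sourceId = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("amino_acid", "v_gene", "j_gene")
  if (!all(need %in% names(df))) {
    stop("canonical CSV must have columns amino_acid, v_gene, j_gene", call. = FALSE)
  }
  tcrRepertoire(df, sourceId = sourceId)
}

#' @rdname readRepertoireCsv
#' @param x a \linkS4class{TcrRepertoire} or a data.frame of triples.
#' @export
writeRepertoireCsv <- function(x, path) {
  df <- if (methods::is(x, "TcrRepertoire")) triples(x) else as.data.frame(x)
  keep <- intersect(c("amino_acid", "v_gene", "j_gene", "count"), names(df))
  utils::write.csv(df[, keep, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fixed attribution order of the filtering rules; a record failing several
# rules is tallied under the first, so FilterReports are reproducible.
filterRuleNames <- c("out_of_frame", "cdr3_no_leading_C", "cdr3_bad_ending",
                     "cdr3_too_long", "cdr3_nonstandard_residue",
                     "ambiguous_gene", "blacklisted_gene")

#' Filter a parsed repertoire
#'
#' Applies the standard record-exclusion rules for TCR beta ImmunoSEQ data,
#' in a fixed attribution order: out-of-frame rearrangements; CDR3s not
#' beginning with the conserved C; CDR3s with a non-canonical ending; CDR3s
#' longer than `maxLength` (30); CDR3s containing non-standard residues;
#' ambiguous (unresolved) V or J calls; and records using a blacklisted
#' gene (by default `TCRBJ02-05`, which upstream pipelines annotate
#' incorrectly, and `TCRBJ02-07`).
#'
#' The canonical-ending rule is ambiguous in the field's usual phrasing
#' ("end with an F or YV"); both readings are available: `"F_or_YV"` (the
#' default; terminal residue F, or terminal two residues YV) and `"F_Y_V"`
#' (terminal residue is any of F, Y, V).
#'
#' @param x a \linkS4class{TcrRepertoire} as returned by [readImmunoSeq()].
#' @param registry a \linkS4class{GeneRegistry}.
#' @param endingRule `"F_or_YV"` or `"F_Y_V"`, see Details.
#' @param maxLength maximum CDR3 length retained (default 30, the padded
#'   encoding width).
#' @return list with elements `repertoire` (filtered
#'   \linkS4class{TcrRepertoire}) and `report` (\linkS4class{FilterReport}).
#' @export
filterRepertoire <- function(x, registry = defaultGeneRegistry(),
                             endingRule = c("F_or_YV", "F_Y_V"),
                             maxLength = 30L) {
  stopifnot(methods::is(x, "TcrRepertoire"))
  endingRule <- match.arg(endingRule)
  df <- triples(x)
  n <- nrow(df)
  cdr3 <- df$amino_acid
  last1 <- substring(cdr3, nchar(cdr3), nchar(cdr3))
  last2 <- substring(cdr3, pmax(nchar(cdr3) - 1L, 1L), nchar(cdr3))
  badEnd <- if (endingRule == "F_or_YV") {
    !(last1 == "F" | last2 == "YV")
  } else {
    !(last1 %in% c("F", "Y", "V"))
  }
  inFrame <- if ("frame_type" %in% names(df)) {
    tolower(df$frame_type) %in% c("in", "in-frame", "inframe")
  } else rep(TRUE, n)
  fails <- cbind(
    out_of_frame = !inFrame,
    cdr3_no_leading_C = substring(cdr3, 1L, 1L) != "C",
    cdr3_bad_ending = badEnd,
    cdr3_too_long = nchar(cdr3) > maxLength,
    cdr3_nonstandard_residue = grepl(sprintf("[^%s]", paste(aaAlphabet(), collapse = "")), cdr3),
    ambiguous_gene = is.na(df$v_gene) | is.na(df$j_gene),
    blacklisted_gene = (!is.na(df$v_gene) & df$v_gene %in% registry@blacklist) |
      (!is.na(df$j_gene) & df$j_gene %in% registry@blacklist)
  )
  firstFail <- apply(fails, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else 0L
  })
  if (n == 0L) firstFail <- integer(0)
  excluded <- vapply(seq_along(filterRuleNames),
                     function(i) sum(firstFail == i), integer(1))
  names(excluded) <- filterRuleNames
  keep <- firstFail == 0L
  report <- methods::new("FilterReport", excluded = excluded,
                         retained = sum(keep), input = n)
  list(repertoire = tcrRepertoire(df[keep, , drop = FALSE], sourceId = x@sourceId),
       report = report)
}

#' Write a FilterReport as JSON
#'
#' @param report a \linkS4class{FilterReport}.
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(
    list(input = report@input, retained = report@retained,
         excluded = as.list(report@excluded)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Build a cohort count vector from filtered repertoires
#'
#' Counts occurrences of each amino-acid triple across all repertoires:
#' every input row contributes its `count` (1 per parsed record), so
#' distinct nucleotide records of the same protein triple contribute
#' separately, and template abundance is ignored.
#'
#' @param repertoires list of \linkS4class{TcrRepertoire} objects (a single
#'   object is accepted).
#' @return a \linkS4class{TcrRepertoire} with one row per unique triple and
#'   aggregated counts (the cohort count vector).
#' @export
buildCohortCounts <- function(repertoires) {
  if (methods::is(repertoires, "TcrRepertoire")) repertoires <- list(repertoires)
  dfs <- lapply(repertoires, function(r) {
    triples(r)[, c("amino_acid", "v_gene", "j_gene", "count")]
  })
  df <- do.call(rbind, dfs)
  if (is.null(df) || nrow(df) == 0L) {
    return(tcrRepertoire(data.frame(amino_acid = character(), v_gene = character(),
                                    j_gene = character(), count = integer()),
                         sourceId = "cohort"))
  }
  agg <- stats::aggregate(count ~ amino_acid + v_gene + j_gene, data = df, FUN = sum)
  agg <- agg[order(agg$amino_acid, agg$v_gene, agg$j_gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  tcrRepertoire(agg, sourceId = "cohort")
}

#' Split a cohort count vector over unique triples
#'
#' Partitions the unique triples (irrespective of abundance) into train and
#' test halves: key sets are disjoint and exhaustive, and the partition is
#' deterministic given the seed.
#'
#' @param cohort a \linkS4class{TcrRepertoire} (cohort count vector).
#' @param fraction proportion of unique triples assigned to the first part.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitCohort <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(methods::is(cohort, "TcrRepertoire"), fraction > 0, fraction < 1)
  n <- nTriples(cohort)
  if (n == 0L) stop("cannot split an empty cohort", call. = FALSE)
  idx <- withSeed(seed, sample.int(n, size = round(fraction * n)))
  df <- triples(cohort)
  list(train = tcrRepertoire(df[sort(idx), , drop = FALSE], sourceId = "train"),
       test = tcrRepertoire(df[setdiff(seq_len(n), idx), , drop = FALSE],
                            sourceId = "test"))
}

#' Multinomial sample of triples from a cohort count vector
#'
#' Draws `n` triples with replacement, with probability proportional to the
#' cohort counts.
#'
#' @param cohort a \linkS4class{TcrRepertoire}.
#' @param n number of draws.
#' @param seed integer seed.
#' @return data.frame of sampled triples (`amino_acid`, `v_gene`, `j_gene`).
#' @export
sampleMultinomial <- function(cohort, n, seed = 1L) {
  stopifnot(methods::is(cohort, "TcrRepertoire"), isCount(n))
  df <- triples(cohort)
  if (nrow(df) == 0L || sum(df$count) <= 0) {
    stop("cohort has no positive counts to sample from", call. = FALSE)
  }
  idx <- withSeed(seed, sample.int(nrow(df), size = n, replace = TRUE,
                                   prob = df$count))
  out <- df[idx, c("amino_acid", "v_gene", "j_gene"), drop = FALSE]
  rownames(out) <- NULL
  out
}
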