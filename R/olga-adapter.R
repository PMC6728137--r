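# Optional adapter wrapping an external OLGA installation (the nucleotide-
# level human TRB recombination model) behind the PgenProvider contract.
# The package builds and tests fully without it; construction fails with a
# clear message when the `olga` Python package is absent.

#' External OLGA generation-probability provider
#'
#' Wraps the `olga` Python package (human TRB model) as a
#' \linkS4class{PgenProvider}: [pgen()] evaluates amino-acid Pgen for
#' (CDR3, V, J) queries and [sampleTriples()] draws from the recombination
#' model. Gene names are translated from the package's Adaptive-style
#' canonical form to OLGA's IMGT-style names. [keyMarginals()] is not
#' exact for OLGA; [estimateKeyMarginals()] falls back to Monte Carlo.
#'
#' @slot python path to the Python interpreter with `olga` installed.
#' @export
setClass("OlgaProvider", contains = "PgenProvider",
         representation(python = "character"))

#' @rdname OlgaProvider-class
#' @param python Python interpreter to use.
#' @return an `OlgaProvider`.
#' @export
olgaProvider <- function(python = "python") {
  ok <- suppressWarnings(system2(python, c("-c", shQuote("import olga")),
                                 stdout = FALSE, stderr = FALSE))
  if (!identical(ok, 0L)) {
    stop("the 'olga' Python package is not importable from ", python,
         "; install it to use the OLGA adapter", call. = FALSE)
  }
  methods::new("OlgaProvider", python = python)
}

# Adaptive-style canonical name -> IMGT-style name OLGA expects.
toImgt <- function(x) {
  m <- regexec("^TCRB([VJ])0*([0-9]+)-0*([0-9]+)$", x)
  vapply(seq_along(x), function(i) {
    g <- regmatches(x[i], m[i])[[1L]]
    if (length(g) == 4L) paste0("TRB", g[2L], g[3L], "-", g[4L]) else x[i]
  }, character(1))
}

olgaScript <- function(mode) {
  c("import sys, csv",
    "import olga.load_model as load_model",
    "import olga.generation_probability as gp",
    "import olga.sequence_generation as sg",
    "import os",
    "d = os.path.join(os.path.dirname(load_model.__file__), 'default_models', 'human_T_beta')",
    "gen = load_model.GenomicDataVDJ(); gen.load_igor_genomic_data(os.path.join(d,'model_params.txt'), os.path.join(d,'V_gene_CDR3_anchors.csv'), os.path.join(d,'J_gene_CDR3_anchors.csv'))",
    "mod = load_model.GenerativeModelVDJ(); mod.load_and_process_igor_model(os.path.join(d,'model_marginals.txt'))",
    if (mode == "pgen") c(
      "pg = gp.GenerationProbabilityVDJ(mod, gen)",
      "w = csv.writer(sys.stdout)",
      "for row in csv.reader(open(sys.argv[1])):",
      "    cdr3, v, j = row",
      "    try:",
      "        p = pg.compute_aa_CDR3_pgen(cdr3, v, j)",
      "    except Exception:",
      "        p = 0.0",
      "    w.writerow([p])"
    ) else c(
      "import numpy as np",
      "np.random.seed(int(sys.argv[2]))",
      "sq = sg.SequenceGenerationVDJ(mod, gen)",
      "w = csv.writer(sys.stdout)",
      "for _ in range(int(sys.argv[1])):",
      "    nt, aa, vi, ji = sq.gen_rnd_prod_CDR3()",
      "    w.writerow([aa, gen.genV[vi][0].split('*')[0], gen.genJ[ji][0].split('*')[0]])"
    ))
}

#' @describeIn pgen amino-acid Pgen from the external OLGA human TRB
#'   model; sequences OLGA cannot generate receive probability 0.
#' @export
setMethod("pgen", "OlgaProvider", function(object, triples, ...) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  qfile <- tempfile(fileext = ".csv"); sfile <- tempfile(fileext = ".py")
  on.exit(unlink(c(qfile, sfile)))
  utils::write.table(
    data.frame(triples$amino_acid, toImgt(triples$v_gene), toImgt(triples$j_gene)),
    qfile, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(olgaScript("pgen"), sfile)
  out <- system2(object@python, c(sfile, qfile), stdout = TRUE)
  as.numeric(out)
})

#' @describeIn sampleTriples draws productive CDR3s from the external OLGA
#'   human TRB model.
#' @export
setMethod("sampleTriples", "OlgaProvider", function(object, n, seed = 1L, ...) {
  sfile <- tempfile(fileext = ".py")
  on.exit(unlink(sfile))
  writeLines(olgaScript("sample"), sfile)
  out <- system2(object@python, c(sfile, as.character(n), as.character(seed)),
                 stdout = TRUE)
  df <- utils::read.csv(text = out, header = FALSE,
                        col.names = c("amino_acid", "v_gene", "j_gene"),
                        stringsAsFactors = FALSE)
  df
})

#' @describeIn keyMarginals not available in closed form for OLGA; errors
#'   so that [estimateKeyMarginals()] uses its Monte Carlo fallback.
#' @export
setMethod("keyMarginals", "OlgaProvider", function(object, ...) {
  stop("OLGA has no exact key marginals; use estimateKeyMarginals()",
       call. = FALSE)
})
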