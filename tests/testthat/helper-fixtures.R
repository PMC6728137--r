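# Shared fixtures, built in code. Heavy objects (the trained model used by
# the end-to-end checks) are memoized so the suite trains once.

.fixtures <- new.env(parent = emptyenv())

toySpec <- function() toyRecombSpec()

toyReg <- function() {
  sp <- toySpec()
  geneRegistry(sp@vIds, sp@jIds, blacklist = character())
}

defaultSpecReg <- function() {
  sp <- defaultRecombSpec()
  geneRegistry(sp@vIds, sp@jIds, blacklist = character())
}

# A small untrained model on the toy registry.
tinyModel <- function(kind = "basic", latent = 3L, seed = 3L) {
  sp <- toySpec()
  tcrVae(vaeConfig(kind, latent_dim = latent, hidden_dims = c(7L, 6L),
                   v_embedding_dim = 4L, germline_width = 4L),
         toyReg(), germlineTable(sp), seed = seed)
}

# The basic model trained on 5,000 draws from the default spec under the
# planted selection, plus its held-out evaluation data. Used by the
# stability and frequency-prediction checks.
plantedFit <- function() {
  if (is.null(.fixtures$plantedFit)) {
    sp <- defaultRecombSpec()
    qstar <- plantedQTable(sp)
    train <- sampleWithSelection(sp, qstar, 5000L, seed = 11L)
    test <- sampleWithSelection(sp, qstar, 500L, seed = 12L)
    fit <- trainVae(train, modelConfig = vaeConfig("basic"),
                    config = trainConfig(seed = 21L, max_epochs = 150L),
                    registry = defaultSpecReg())
    .fixtures$plantedFit <- list(spec = sp, qstar = qstar, train = train,
                                 test = test, model = fit$model,
                                 report = fit$report)
  }
  .fixtures$plantedFit
}

# An ImmunoSEQ-dialect TSV exercising every filter rule.
writeImmunoseqFixture <- function(path) {
  lines <- c(
    "aminoAcid\tvGeneName\tjGeneName\tsequenceStatus\tcount (templates/reads)",
    "CASSLGQGAETQYF\tTCRBV05-01\tTCRBJ02-05\tIn\t500",   # blacklisted J
    "CASSLGQGAETQYF\tTCRBV05-01\tTCRBJ02-03\tIn\t500",   # retained
    "CASSLGQGAETQYF\tTCRBV05-01\tTCRBJ02-03\tIn\t2",     # retained (dup protein)
    "CASSLGQGAETQYF\tTCRBV05-01\tTCRBJ02-03\tOut\t1",    # out of frame
    "ASSLGQGAETQYF\tTCRBV05-01\tTCRBJ02-03\tIn\t1",      # no leading C
    "CASSLGQGAETQYA\tTCRBV05-01\tTCRBJ02-03\tIn\t1",     # bad ending
    "CASSLGQGAETGYV\tTRBV5-1\tTRBJ2-3\tIn\t1",           # retained (YV, aliases)
    paste0("C", strrep("A", 30), "F\tTCRBV05-01\tTCRBJ02-03\tIn\t1"), # too long
    "CASSLG*GAETQYF\tTCRBV05-01\tTCRBJ02-03\tIn\t1",     # nonstandard residue
    "CASSLGQGAETQYF\tTCRBV12-03/12-04\tTCRBJ02-03\tIn\t1" # ambiguous V
  )
  writeLines(lines, path)
  path
}
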