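Package: tcrvae
Title: Variational Autoencoder Models of T Cell Receptor Beta Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative probability models for T cell receptor beta chains
    represented as (V gene, J gene, CDR3 amino acid sequence) triples.
    Implements beta-VAE models ('basic' and 'count_match') with a
    KL-annealing training schedule, importance-sampling estimation of the
    marginal sequence probability (P_VAE), a recombination-plus-selection
    baseline with maximum-likelihood selection factors over (V, J, CDR3
    length) triples and rejection sampling, repertoire summary-statistic
    divergences (l1 and Jensen-Shannon), and an exactly enumerable
    amino-acid-level VDJ recombination simulator used as a test oracle.
    Parses Adaptive ImmunoSEQ repertoire exports and applies the standard
    CDR3/frame/gene filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'registry.R'
    'repertoire-io.R'
    'encoding.R'
    'germline.R'
    'synthetic.R'
    'vae-model.R'
    'vae-train.R'
    'pvae.R'
    'selection.R'
    'summaries.R'
    'olga-adapter.R'
    'cli.R'
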