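---
title: "Generative models of TCR beta repertoires: methods and design"
author: "tcrvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models of TCR beta repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrvae)
```

## The modeling problem

A T cell receptor beta chain is produced by V(D)J recombination — random
choice of germline V, D and J segments, random trimming of their ends, and
random nucleotide insertions at the junctions — followed by thymic
selection. At the protein level a beta chain is determined by the triple
(V gene, J gene, CDR3 amino-acid sequence), and a sequenced repertoire can
be viewed as a sample from a probability distribution over such triples.
This package fits that distribution two ways and compares them:

* **beta-VAE models** (`basic` and `count_match`): deep latent-variable
  models that make no mechanistic assumptions, trained on observed
  triples, with the marginal probability of a sequence (`P_VAE`)
  recovered by importance sampling.
* **A recombination-plus-selection baseline**: a generation-probability
  provider (`pgen`) multiplied by maximum-likelihood selection factors
  `Q(V, J, CDR3 length)`, sampled from by rejection.

Everything is testable end-to-end against a built-in amino-acid-level
recombination simulator whose generation probabilities are exactly
enumerable.

## Encoding

CDR3 sequences (lengths 1–30 after filtering) are padded to width 30 with
gaps *in the middle*: `ceiling(L/2)` residues stay on the left
(V-proximal) side and `floor(L/2)` on the right, so the germline-encoded
ends stay aligned across lengths. Each site is one-hot encoded over 21
channels (20 amino acids, alphabetical, gap last), and the V and J genes
over 67 and 13 channels respectively — 710 indicators in all. At the
encoder input each component passes through a learned linear embedding;
the V block is projected to 30 dimensions, the J and amino-acid blocks
keep their dimension. The encoding itself is deterministic and exactly
invertible by per-block argmax; the learned embeddings belong to the
model.

## Models and loss

Both models are small dense networks: two 100-unit ELU layers in the
encoder to the mean and log-variance of a diagonal normal posterior over
a 20-dimensional latent space (standard normal prior), and two 100-unit
ELU layers in the decoder to categorical heads for V, J and each of the
30 CDR3 sites. The training objective is

```
loss(x) = R(x, z) + beta * KL( q(z|x) || N(0, I) )
```

where the reconstruction loss `R` is a weighted sum of the V
cross-entropy, the J cross-entropy and the *average* cross-entropy over
the 30 CDR3 sites. `count_match` additionally (i) receives the germline
CDR3 prefix of the true V gene and suffix of the true J gene at the
decoder input (one-hot, 8 sites per side, gap-padded), and (ii) carries
three auxiliary regression heads — the number of CDR3 residues matching
the V germline at the 5' end, the J germline at the 3' end, and the CDR3
length — scored by squared loss. The auxiliary heads shape training only;
the probability of a sequence always comes from the three categorical
heads. Because the components are weighted (weights default to 1;
`fitLossWeights()` refits them by least squares against per-sequence
log-likelihood estimates), the objective is not an evidence lower bound,
which is deliberate.

The exact widths of the hidden layers and the wiring of the germline
inputs are genuinely open design points; the defaults above (100 units,
germline blocks concatenated to `z`) are declared choices recorded in the
saved-model metadata, not reconstructions of someone else's architecture.

## Training protocol

* 10% of the training data is held out as a validation set, fixed for the
  life of the run.
* beta starts at 0 and rises linearly each epoch, reaching its final
  value (default 0.75) at `warmup_epochs` (default 20). Annealing the KL
  term avoids the early collapse of the posterior onto the prior.
* Three pre-training phases (10 epochs each) start from independent
  random initializations; the phase ending with the best validation loss
  seeds the full run. This cheaply de-risks unlucky initializations.
* The full run stops after 20 epochs without validation improvement (or
  at `max_epochs`) and restores the best-validation checkpoint, never the
  last epoch.
* Optimization is Adam (learning rate 1e-3) on minibatches of 100, with
  gradients derived analytically from the matrix forward pass and checked
  against finite differences in the test suite.

One choice deserves emphasis: **the monitored validation loss is always
evaluated at the final beta**, even while training under the annealed
beta. Monitoring the annealed objective instead makes early-stopping
systematically prefer mid-warm-up checkpoints (their KL term is cheaply
down-weighted), which truncates training right after warm-up; monitoring
the final objective compares all epochs on the same scale.

Seeds are split hierarchically — data split, per-phase weight draws,
per-epoch shuffles and reparameterization draws each use a sub-seed
derived from the master seed — so every component is independently
reproducible and whole runs are bit-for-bit deterministic.

The default beta of 0.75 balances probability estimation (which prefers
slightly larger beta) against the fidelity of generated repertoires;
`betaSweep()` re-runs the selection protocol — seven evenly spaced values
from 0.625 to 1, each trained independently.

## P_VAE by importance sampling

The marginal probability of a triple is estimated as

```
P_VAE(x) = E_{z ~ q(z|x)} [ p(x|z) p(z) / q(z|x) ]
```

with all three densities evaluated analytically and the average taken in
log space with a max-shifted log-sum-exp; a weight of zero propagates to
`-Inf` cleanly. The default is 500 draws; 100 already give stable
estimates on trained models (the test suite checks that 100- and 500-draw
estimates agree within 0.5 nats for at least 95% of held-out sequences).
The delta-method standard error of the log estimate is reported alongside.

Per-sequence randomness is derived from the master seed and a hash of the
triple itself, rather than its batch position, so estimates do not depend
on batch composition or order and the batch and single-sequence paths
agree exactly.

## The selection layer

Given any generation-probability provider, the maximum-likelihood
selection factor of a (V, J, CDR3 length) key is the ratio of its
empirical frequency in training data to its probability under the
provider, truncated at 100 for numerical stability. Keys with empirical
support but zero model probability receive the truncation bound (with a
warning); keys unseen in training default to Q = 0 — the MLE — with a
configurable positive floor for evaluation settings that need finite log
scores. Sampling from `pgen * Q` uses rejection with envelope `qMax`:
proposals from the provider are accepted with probability `Q/qMax`.
Because fitted factors normalize the selected distribution, a fitted
table estimates `Q/Z` with `Z = sum(keyMarginal * Q)`; recovery tests
compare against that target.

## The synthetic recombination simulator

The simulator emulates the generative skeleton of VDJ recombination at
the amino-acid level: a V segment contributes a germline CDR3 prefix and
a J segment a suffix, each trimmed by a random number of residues, with a
random number of random residues inserted between. Working on amino acids
(not nucleotides) keeps every probability exactly computable: `pgen` sums
over all trim/insertion scenarios consistent with an observed CDR3, key
marginals are exact, and small configurations can be enumerated
exhaustively. These exact quantities are what make the selection stack
and the evaluation protocol testable without downloads.

Two configurations ship as fixed study conditions:

* `defaultRecombSpec()`: 4 V and 3 J segments with 4–6-residue germline
  CDR3 contributions, trims 0–2 (pmf 0.5/0.3/0.2), insertions 0–6 with a
  mode at 2, and an insertion-residue distribution enriched for G/S/A as
  junctional insertions tend to be. CDR3 lengths span 4–15 and the
  sequence support is on the order of 10^7 — rich enough that a VAE must
  generalize, small enough that key marginals stay exact.
* `toyRecombSpec()`: 2 V, 2 J, two-letter insertions of 0–2 — the whole
  sequence support enumerates to a few dozen triples, which is the oracle
  configuration for brute-force checks.

`plantedQTable()` supplies a known-truth selection factor: a Gaussian
bell over the spec's reachable CDR3 length range (centred at the
midpoint, sd a quarter of the range) times a V-gene modulation, bounded
in `[0.2, 4]` — the shape in which length-dependent thymic selection is
usually modelled.

What the simulator deliberately does **not** emulate: D genes, nucleotide-
level trimming/insertion statistics (and hence frame effects and
convergent recombination at the codon level), allele-level gene usage,
and sequencing error. Tests passing on simulated data therefore establish
method correctness — estimator consistency, oracle equivalence, recovery
of planted truth — not biological realism of any fitted model.

## Summary statistics and divergences

Repertoire comparisons use 15 statistics: Jensen–Shannon divergence
(natural log) on the binned distributions of acidity, aliphatic index,
aromaticity, basicity, bulkiness, CDR3 length, net charge, GRAVY,
polarity, nearest-neighbor Levenshtein distance and pairwise Levenshtein
distance; and l1 divergence on CDR3 2-mer, CDR3 amino-acid, J-gene and
V-gene frequencies. Scales: GRAVY is mean Kyte–Doolittle hydropathy,
bulkiness mean Zimmerman, polarity mean Grantham; acidity/basicity are
residue fractions of {D,E} and {K,R,H}; aromaticity of {F,W,Y}; the
aliphatic index is Ikai's formula on residue fractions; charge is the
Henderson–Hasselbalch net side-chain charge at pH 7 (termini excluded, as
the CDR3 is an internal loop). The scale tables ship as an editable CSV.

Numeric statistics are binned into 30 equal-width bins spanning the
pooled range of the two repertoires being compared, so reports are
symmetric in their arguments; JS values are comparable only within this
binning convention. The quadratic Levenshtein statistics subsample each
side to at most 2,000 sequences (nearest-neighbor distances are then
exact on the subsample, excluding self-matches); the subsample is drawn
with a seed derived from the repertoire's own content, so comparing a
repertoire with itself is exactly zero on every statistic.

## Numerical choices and degenerate inputs

* Encoder log-variances are clamped to [-10, 10] (gradient masked
  outside) to prevent variance blow-up early in training.
* Log-sum-exp uses a max shift; an all-zero importance weight vector
  returns `-Inf` with a warning rather than erroring.
* Argmax decoding breaks ties by first index; generation strips gap
  symbols by default, with an optional strict mode that rejects draws
  whose gaps are not a contiguous central block (bounded retries).
* The filter rule "CDR3 must end with F or YV" is ambiguous in the
  field's usual phrasing; both readings are implemented
  (`endingRule = "F_or_YV"`, the default, and `"F_Y_V"`).
* A constant predictor in the log-log frequency regression yields
  R-squared 0 by convention rather than an error.
* The log-likelihood target for `fitLossWeights()` is the
  importance-sampling estimate from `logPvae()`; any per-sequence
  log-likelihood estimate can be substituted.

## Problem sizes used by the tests and the acceptance script

The shipped checks train the `basic` model (latent 20, beta 0.75) on
5,000 simulated sequences under the planted selection and evaluate on 500
held-out sequences; selection-stack oracle checks use 10^5 draws on the
toy configuration; divergence-noise checks compare disjoint 5,000-sequence
halves of one simulated pool. These sizes were chosen so the full suite
exercises every claim at desk scale; larger repertoires only tighten the
Monte-Carlo comparisons.

## Known limitations

* The selection-recovery check (sup-norm error over keys with at least
  100 expected counts, bound 15%) is statistically tight by construction:
  a key at the threshold has ~10% relative sampling error, so the
  supremum over ~20 keys occasionally exceeds the bound for unlucky
  seeds. This is a property of the check, not of the estimator.
* `count_match` generation must pick V and J before the germline block
  can be formed; generation therefore decodes twice (genes from a
  germline-free pass, then the CDR3 conditioned on the chosen genes).
* The external OLGA adapter requires a separately installed Python
  `olga` package; without it, construction fails with a clear message and
  everything else works.
* The packaged germline CDR3 table for the real 67/13 gene catalog is a
  synthetic stand-in (see `defaultGermlineTable()`); substitute
  IMGT-derived boundaries for real analyses.
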