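---
title: "Stacked generalization for imbalanced peptide-activity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked generalization for imbalanced peptide-activity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackpep)
```

## The problem

Experimentally confirmed immunomodulatory peptides — for example peptides
that induce interleukin-13 release from T cells — are scarce compared to
the peptides that do not, so a realistic benchmark is heavily imbalanced
(on the order of 300 positives against 2900 negatives). A classifier that
predicts "not inducing" for everything already reaches an accuracy of
N_neg / (N_neg + N_pos) ≈ 0.90, which is why this package treats accuracy
as a *baseline to beat*, relies on rank-based measures (AUC, AUPRC) and the
Matthews correlation coefficient (MCC), and tunes the decision threshold to
maximize MCC rather than fixing it at 0.5.

`stackpep` implements the full workflow as reusable pieces:

1. **Encoding.** A peptide sequence is turned into fixed-width numeric
   descriptors under ~20 schemes: k-mer compositions (AAC/DPC/TPC, 20, 400
   and 8000 features), gapped pair composition (CKSAAP, 2400 features at
   gaps 0–5), grouped compositions over a five-class physicochemical
   alphabet (GAAC/GDPC/GTPC: 5/25/125), conjoint triads (343),
   composition/transition/distribution descriptors over 13 three-group
   properties (CTDC/CTDT/CTDD: 39/39/195), pseudo-amino-acid composition
   (PAAC, 20 + λ), per-residue one-hot/BLOSUM62/z-scale/sliding-window
   profiles, mean AAindex physicochemical profiles (531 complete indices),
   skip-gram k-mer embeddings, and a protein-language-model adapter.
2. **Base models.** Each (encoding, classifier) pair is one
   *single-feature model*, trained by stratified 5-fold cross-validation;
   the concatenated held-out predictions form its out-of-fold (OOF)
   probability vector.
3. **Stacking.** The OOF vectors become the columns of a probability
   matrix on which a meta-classifier (logistic regression by default) is
   trained. For the LR meta-model the predicted probability satisfies the
   log-odds identity ln(p/(1−p)) = β₀ + Σᵢ βᵢxᵢ, and |βᵢ| — the absolute
   weight coefficient (AWCLR) — measures the importance of base model i.
4. **Selection.** Three algorithms choose a base-model subset: SAAUC
   (sequential addition in CV-AUC order), SAWC (sequential addition in
   AWCLR order, ranking computed once), and SDIWC (sequential deletion of
   the minimum-AWCLR model with the ranking recomputed after every
   deletion). An optional pre-filter first removes base models whose CV
   accuracy does not reach the all-negative baseline.

## The default grid

`default_grid()` enumerates 168 cells: 7 classical classifiers (RF, XGB,
LGBM, SVM, KN, NB, LR) × 21 fixed-vector encodings, plus 3 deep
classifiers (TX, CNN, BLSTM) × 7 sequence encodings. The deep learners are
an optional plugin: the grid enumerates their cells, but the core training
path is classical-only (deep cells are skipped, or served by classical
fallback learners on the flattened encodings). This mirrors the finding
that the best-selected stacks contain no deep members, so nothing in the
default workflow needs a GPU or a model download.

Backend notes: the LGBM slot is served by a histogram-based, leaf-wise
(lossguide) gradient-boosting configuration of xgboost — a deliberate
backend choice recorded in each model artifact, since any
histogram-boosting implementation satisfying the probability contract is
acceptable for this grid position. KN probabilities are the fraction of
the k nearest neighbours voting positive. LR (base and meta) is ridge
logistic regression with penalty λ = 1/n, which matches the common
"L2, strength 1.0" convention of scikit-learn-style implementations.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `test_fraction` | 0.2 | Per-class held-out fraction; `floor` on the test side, so 313/2908 gives a 62/581 test set |
| `n_folds` | 5 | Stratified CV folds; per-fold class counts differ by ≤ 1 |
| CKSAAP `k_max` | 5 | Largest residue gap; 400·(k_max+1) features |
| PAAC `lam`, `w` | 5, 0.05 | Correlation ranks (fixing 25 features) and sequence-order weight |
| EAAC `window` | 5 | Sliding-window width (residues) |
| W2V `dim`, `window`, `epochs` | 128, 40, 100 | Skip-gram embedding size, context window (tokens) and epochs; `sg = 1` only |
| meta `lambda` | 1/n | Ridge penalty of the LR meta-classifier |

Per-residue encodings (BE, EAAC, BLOSUM62, ZSCALE) are zero-padded to a
configured `L_max`, by default the longest training sequence; classical
classifiers consume the flattened vector. Features are standardized
(training folds only) for SVM/LR/KN; tree ensembles are left unscaled.
Probability columns entering the meta-classifier are *not* standardized:
they already share the [0, 1] scale, and rescaling would change the
meaning of the AWCLR importances.

## Design choices in the open points

* **Meta-level cross-validation reuses the base-level fold assignment.**
  All 168 base models share one fold assignment per run; the meta
  learner's OOF probabilities are produced fold-by-fold on those same
  folds. Re-randomizing folds at the meta level would let the meta learner
  see base-model predictions for samples those base models were trained
  on, which is exactly the leakage stacking must avoid.
* **Threshold rule.** Candidate thresholds are the distinct OOF meta
  probabilities plus 0 and 1; the smallest candidate maximizing MCC wins
  ties. A "positive" call means probability ≥ threshold. Test-set metrics
  always use the training-derived threshold.
* **Best subset size.** Published selection curves are read by eye
  ("plateau", "peak"); the package uses the deterministic rule
  argmax-validation-AUC with smallest-X tie-break, plus a reported plateau
  detector (AUC within 0.002 of the maximum for ≥ 3 consecutive sizes) for
  cases where the curve saturates rather than peaks.
* **Tie-breaks.** AUC ranking ties: lexicographic model key. SDIWC
  deletion ties on the minimum AWCLR: the lexicographically last key is
  deleted. These are artifact decisions — the published procedure defines
  no tie rules.
* **CTD property census.** The descriptor prose tradition speaks of seven
  properties, but the printed dimensions (39/39/195) force 13 three-group
  properties; the 13 standard groupings of the iLearn convention are
  bundled, and the tests pin the partition property (each grouping covers
  the 20-letter alphabet exactly once).
* **CTDD percentiles.** The positions reported per group are the 1st
  occurrence and the occurrences at ⌈0.25N⌉, ⌈0.5N⌉, ⌈0.75N⌉ and N,
  expressed as % of sequence length; a group absent from the sequence
  contributes zeros. The exact rounding convention varies between
  published toolkits; this one is fixed here and pinned by brute-force
  positional tests.
* **Zero-denominator conventions.** MCC is 0 when any confusion marginal
  is empty; an undefined precision is reported as 0 with a flag. CKSAAP
  blocks whose gap exceeds the sequence emit an all-zero block with a
  warning, keeping short peptides encodable.
* **Non-standard residues** (B, J, O, U, X, Z) reject the record by
  default; a `drop` policy discards such records silently.

## Numerical choices

The skip-gram trainer (compiled code) uses a self-contained xorshift RNG,
single-threaded updates and a linearly decaying learning rate, so a seed
fixes the embedding bit-for-bit across platforms. Ridge LR fits use a
tight convergence tolerance (1e-12) so coefficient *orderings* — which
drive SAWC/SDIWC — are stable against an independent IRLS implementation.
glmnet requires two columns, so single-column meta fits carry a zero pad
column whose coefficient is discarded. Constant feature columns are pruned
per fit (they carry no information and break naive-Bayes variance
estimates); the pruned columns keep a zero weight in the reported
coefficient vector. Gaussian naive Bayes variances are floored at 1e-6.

## What the synthetic generator emulates — and what it does not

`generate_peptides()` draws negatives i.i.d. from a background residue
distribution (uniform by default; a database-like frequency preset is
bundled) with lengths uniform in 9–25, and implants fixed motifs into
positives at random positions with a per-motif probability; defaults
reproduce the 313/2908 imbalance structure, so the all-negative baseline
accuracy ≥ 0.902 emerges from the class ratio, not from a constant.
`make_complementary_signals()` splits the positives into two disjoint
motif-carrying halves, creating the situation where each single-motif
detector is partially informative (AUC strictly between 0.5 and 1) but
their stack is strongly informative — the property that motivates
stacking in the first place.

What this does **not** emulate: real epitopes have positional and
chemical context, homology structure between peptides, label noise, and
class-conditional length distributions. Passing the synthetic suites
therefore demonstrates that the *machinery* (encoders, OOF construction,
stacking, selection, thresholding) is correct and leak-free — not that
any particular AUC will transfer to a real cytokine-induction dataset.

## Problem sizes used by the checks

The bundled verification suites run at deliberately small scale, chosen
so the full battery stays fast while remaining statistically meaningful:
selection-oracle comparisons use toy probability matrices of up to 6
columns × 60 samples; stacking-dominance runs use 60/240-sample
complementary datasets over 5 seeds; the end-to-end recovery check trains
a 12-cell mini-grid (AAC, DPC, GAAC, CTDC × LR, RF, NB) on 200/800
motif-implanted peptides over 5 seeds and asks for held-out AUC ≥ 0.85 in
at least 4 of them. The W2V and language-model columns are exercised with
small dimensions; scaling `dim`, `epochs` and the grid back up to the full
168 cells changes cost, not code paths.

## Known limitations

* The deep plugin (TX/CNN/BLSTM) is not implemented; the NN encoding has
  no fixed-vector form and is only meaningful to that plugin.
* The default W2V corpus is the training split; embeddings trained on a
  large external corpus (as a production system would) must be supplied
  via the config hook.
* The language-model adapter ships only with a deterministic synthetic
  stub provider; a real transformer checkpoint must be registered by the
  user.
* Exhaustive subset search and SHAP-style attribution are out of scope;
  AWCLR is the only importance measure implemented.
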