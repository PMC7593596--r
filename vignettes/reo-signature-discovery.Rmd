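---
title: "Reversal gene-pair signatures from relative expression orderings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversal gene-pair signatures from relative expression orderings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(REOsig)
```

## The model

REOsig classifies samples by the *relative expression ordering* (REO) of
gene pairs within each sample: for genes i and j, the only information
used is whether `Gi > Gj` or `Gi < Gj`. An REO is invariant under any
strictly increasing transform applied to one sample's values, which is
exactly the class of distortions produced by array normalization
differences, batch effects and, to a first approximation, platform
changes (microarray intensities versus RNA-seq abundances). The method
therefore assumes nothing about the marginal distribution of expression
values — only that within-sample orderings of biologically coupled gene
pairs flip between the two diagnostic classes.

Discovery proceeds in stages:

1. **Stable pairs per group.** In a group of n samples, pair (i, j) is
   stable with direction `Gi > Gj` when
   `#{samples with Gi > Gj} / n > t`, and symmetrically for `<`. The
   default threshold `t = 0.85` is interpreted *strictly*: support of
   exactly 0.85 does not qualify. Ties contribute to neither direction's
   numerator but remain in the denominator, so a tied sample counts as
   evidence against stability.
2. **Consistency across subgroups.** Each class may contain several
   groups (tumor: carcinoma and tumor-adjacent tissue; control:
   pancreatitis and normal pancreas). A class's pair set is the
   intersection of its subgroup sets with direction equality, support
   recorded as the minimum — a pair must behave identically in every
   tissue context of the class.
3. **Reversal pairs.** Pairs consistent in both classes with opposite
   directions are the candidate signature. Reversal is a *qualitative*
   event: within a control sample gene i sits below gene j, within a
   tumor sample above, regardless of measurement scale.
4. **Encoding.** Samples become ternary vectors over the candidate
   pairs: 0 (`Gi > Gj`), 1 (`Gi < Gj`), −1 (gene absent or tie). −1 is a
   legitimate third symbol downstream, not missing data: absence of a
   signature gene on an assay is itself informative of nothing, and the
   classifier learns to treat it neutrally.
5. **mRMR.** Candidates are ranked by greedy forward selection under the
   difference form of the minimum-redundancy-maximum-relevance
   criterion: the first feature maximizes `MI(v, C)`; each next feature
   maximizes `MI(v, C) − mean(MI(v, s))` over the already-selected s.
   Mutual information is the plug-in discrete estimator in natural-log
   units. The alphabet is tiny ({0, 1, −1} × {tumor, non-tumor}), so the
   plug-in estimator is the natural choice; continuous MI estimators are
   out of scope. Exact set optimization of the mRMR functional is
   exponential; the greedy incremental solution is the canonical one and
   is deterministic here, with exact ties broken by original pair order.
6. **IFS.** For k = 1..K the top-k prefix is scored by stratified
   k-fold cross-validation (default fivefold), pooling held-out
   predictions into one confusion matrix. The optimal k maximizes pooled
   accuracy, ties resolved toward the smaller k. The full metric set —
   accuracy, sensitivity, specificity, MCC — is recorded per k so the
   curve can also be read on MCC, the better-behaved metric under the
   class imbalance typical of these cohorts.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.85 | minimal (strict) REO support per group; raising it never adds pairs |
| `kFolds` | 5 | CV folds for grid search, IFS and reporting |
| `C`, `gamma` | 32, 0.03125 | RBF-SVM cost and kernel width; both on the default powers-of-two grids (`2^-5..2^15`, `2^-15..2^3`) searched by `gridSearchSvm()` |
| `testFraction` | 0.2 | held-out fraction per group in `stratifiedSplit()`; train size is `floor(0.8 · n)`, remainder to test |
| `nBoot` | 2000 | stratified bootstrap resamples for the AUC 95% CI |

The SVM consumes the raw ternary codes without rescaling: they are
already bounded and symmetric, and rescaling would only reparameterize
`gamma`.

## The synthetic generator

`generateDataset()` emulates the structure the analysis relies on, not
the biology it comes from:

* **Groups and imbalance.** Default sizes 80/20/8/40 (tumor,
  tumor-adjacent, pancreatitis, normal) preserve the roughly 10:3:1:5
  imbalance of real PDAC compendia at desk scale.
* **Planted reversal pairs** follow their class direction in exactly
  `ceiling(stability · n)` samples of every group (default stability
  0.95). Conformity is assigned by construction, not by sampling, so
  recovery tests are exact rather than flaky.
* **Band separation.** Every planted pair (reversal or
  consistent-background) occupies its own value band, disjoint from the
  background range and from other bands; background noise is truncated
  at ±4 sd so it cannot cross into a band. Consequence: the planted
  reversal pairs are *exactly* the reversal pairs present, and
  precision/recall of discovery are well-defined against the truth. This
  is the deliberate idealization that makes the generator a measurement
  instrument; real reversal pairs sit inside the bulk of the expression
  distribution and compete with correlated neighbors.
* **Distortions.** Per-sample strictly increasing maps — affine or a
  signed power law — model batch and platform effects at the level where
  the REO robustness claim is literally true.
  `generateCrossplatformTestset()` redraws cohorts from the same planted
  truth under a harsher, wider-dynamic-range distortion family and can
  remove genes to exercise the −1 encoding path.
* **Redundancy.** `nRedundantPairs` planted pairs copy the
  conform/violate pattern of earlier pairs, giving mRMR genuine
  redundancy to demote.

What the generator does **not** model: gene–gene correlation structure,
count-based RNA-seq noise (beyond a monotone map), probe-level artifacts,
and reversal pairs embedded in the background bulk. Passing tests
demonstrate the pipeline's correctness and its invariances, not expected
performance on real tissue.

## Numerical and design choices

* **Strict threshold inequality** (`support > t`, not `≥`): a pair
  supported in exactly 85% of samples is excluded.
* **Ties** are counted in the stability denominator and encoded −1. The
  alternative (dropping tied samples from the denominator) inflates
  support estimates precisely for low-information pairs.
* **Canonical pair keys**: gene i precedes gene j in radix-sorted
  (locale-independent) order; `(j, i, less)` is the same object as
  `(i, j, greater)`. All outputs are sorted, all ties broken by fixed
  rules, every stochastic step seeded — reruns are byte-identical, and
  the discovery manifest deliberately carries no timestamps.
* **Streaming pair scan**: candidate pairs are counted in compiled code
  and only passing pairs are materialized, so a 20,000-gene universe
  (~2·10⁸ candidates) never allocates the full pair table. A
  variance-based universe pre-filter (`topVariableGenes()`) is available
  for interactive work.
* **Pooled CV metrics**: held-out predictions from all folds form one
  confusion matrix; this yields a single training-set number per k
  rather than a fold average with its own variance.
* **Zero-denominator MCC is 0** (the standard convention); undefined
  sensitivity/specificity on single-class cohorts is reported as absent
  (`NA`, omitted from JSON reports), never as 0.
* **AUC CI** by stratified bootstrap (seeded) rather than a closed-form
  method: one mechanism covers all cohort shapes, and reproducibility is
  guaranteed by the seed.
* **"Bayes net" comparator**: no discrete Bayes-network learner is among
  the package's dependencies; the slot is served by a structure-free
  discrete Bayes classifier (naive Bayes), and fitted models carry a
  note saying so. The comparator table is qualitative, so exact parity
  with any particular Bayes-net implementation is out of scope.
* **Train/test split arithmetic**: per group, training receives
  `floor((1 − testFraction) · n)` and the remainder goes to the test
  set, so a 573/153/10/74 cohort at 0.2 yields test groups of
  115/31/2/15. The split is seeded; any historical split made without a
  published seed cannot be reproduced exactly, only re-instantiated.

## Problem sizes in the test suite

Unit and property tests run on matrices up to 60 genes × 30 samples
against exhaustive double-loop oracles; planted-recovery runs use 500
genes with 16 planted pairs over 148 samples; the end-to-end pipeline
checks use 300 genes over 600 samples with 9 informative + 7 redundant
planted pairs; cross-platform transfer pools 2000 predictions over ten
seeds. These sizes exercise every code path, including the blocked scan,
at interactive cost.

## Limitations

* Discovery requires a complete expression matrix over the gene
  universe; gene absence is only meaningful at signature-application
  time. Missing values must be handled upstream.
* Stability is a plain fraction threshold; binomial-test formulations of
  REO stability are not implemented.
* Binary classification only; the group structure informs stability and
  stratification, not the decision function.
* The mRMR ranking is the greedy incremental solution; it does not
  certify global optimality of the selected set.
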