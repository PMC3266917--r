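---
title: "Predicting protein interaction partners from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein interaction partners from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadppi)
```

This vignette documents the statistical model behind `triadppi`, the
assumptions it rests on, the tunable parameters and why their defaults
are what they are, and the design choices made where the method family
leaves the details open.

## The model

The working hypothesis of sequence-only interaction prediction is that
the amino-acid sequence alone carries enough signal about a protein's
binding behavior to estimate whether two proteins interact. `triadppi`
operationalizes this in three stages.

**Featurization.** The 20 amino acids are collapsed into 7
physicochemical classes (grouped by dipole moment and side-chain
volume): {A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C}.
Cysteine sits alone because its ability to form disulfide bonds is
unlike any other residue. A sequence of length $L$ yields $L-2$
overlapping windows of three consecutive residues; counting the class
triple of every window gives a raw spectrum $f$ over the $7^3 = 343$
possible triads. The spectrum is normalized min–max over its 343
components,

$$d_i = \frac{f_i - \min_j f_j}{\max_j f_j},$$

so that descriptors of short and long proteins are comparable; for any
sequence short enough that some triad never occurs (every realistic
protein), $\min_j f_j = 0$ and the largest component is exactly 1. An
ordered pair of proteins is described by the concatenation
$[d^{(A)} \,\|\, d^{(B)}] \in [0,1]^{686}$.

**Classification.** A support vector machine with an RBF kernel is
trained on labeled pairs. The choice of kernel is a design decision of
this package: the family of methods this implements does not prescribe
one, and the RBF kernel on bounded descriptors is the standard,
well-understood default. Pair descriptors are ordered, but physical
interaction is not: order invariance is recovered at prediction time by
averaging the probabilities of the two orderings, which is the simplest
contract that makes `predict(A, B)` and `predict(B, A)` agree to
machine precision without constraining the kernel.

**Calibration.** SVM decision values $f(x)$ are turned into posterior
probabilities with Platt scaling,

$$P(\text{interact} \mid f) = \frac{1}{1 + \exp(A f + B)},$$

where $(A, B)$ minimize the negative log-likelihood of the training
labels with Platt's regularized targets
$t_+ = (N_+ + 1)/(N_+ + 2)$ and $t_- = 1/(N_- + 2)$ (these keep the
optimum finite even on separable data). When larger decision values
accompany the interacting class, the fitted $A$ is negative; a positive
fitted $A$ signals anti-learning and triggers a warning. Crucially, the
sigmoid is fitted to *out-of-sample* decision values, collected over an
internal 3-fold split of the training pairs, not to the decision values
of the final fit — calibrating on training-set decision values is known
to produce overconfident probabilities.

## Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| residue class table | 7-class dipole/volume grouping | TSV, editable | the canonical conjoint-triad reduction; ships as data so alternatives can be tried |
| ambiguity policy | `skip` | skip / strict | real FASTA contains B, J, O, U, X, Z; windows containing them are simply not counted rather than inventing a class |
| SVM `cost` | 10 | > 0 | mid-range soft margin; grid-selectable |
| SVM `gamma` | 0.05 | > 0 | median heuristic: typical squared distance between two pair descriptors is ≈ 20–30, so γ ≈ its reciprocal; the default sits at the center of the plateau where held-out SE and SP are jointly high |
| `hyperparams = NULL` | grid `cost` ∈ {1, 10, 100} × `gamma` ∈ {0.01, 0.05, 0.25} | — | selected on one stratified inner 2/3-holdout by held-out accuracy |
| calibration folds | 3 | ≥ 2 | standard Platt-calibration practice; 3 keeps two-thirds of the data in each calibration fit |
| decision threshold | probability > 0.5, strict | — | a candidate at exactly 50% is *not* a positive; the same rule is used in ranking, path search and cross-validation |
| CV folds | 5, stratified | ≥ 2 | the conventional evaluation protocol for this method family |
| network expansion depth | 1 ring of known neighbors | 0–2 | one ring shows the immediate known context of the predictions without flooding the graph |

## The synthetic benchmark

Public interactome collections are moving targets, so the package's
benchmark is generated, not downloaded. `fixture_spec()` defines the
study conditions; its defaults are the conditions under which the
package's end-to-end claims are tested:

* 200 proteins of 60–150 residues, i.i.d. uniform over the 20 standard
  residues (a `natural`-composition mode exists);
* 80% of proteins carry a planted motif, split evenly between the two
  motifs of a complementary pair (defaults `CKCCKKCKCKCC` /
  `WHWWHHWHWHWW` — 12-mers built from rare class combinations so their
  triad signature stands out from background);
* 800 labeled pairs at 1:1 class balance: a pair is a true positive
  exactly when one protein carries motif A and the other motif B;
* 5% independent label noise, the regime of a curated but imperfect
  interaction database.

The complementary-motif rule was chosen deliberately: motif content is
exactly the kind of signal a triad spectrum can represent, so the
planted interactome is learnable *by the implemented featurization* and
a failing classifier test indicts the code, not the benchmark. Sequence
lengths are kept under 345 residues so the min–max normalization
invariant (some triad absent, maximum component exactly 1) always
holds.

What the generator does **not** emulate: real interactome topology
(hubs, degree distributions, modularity), homology between proteins,
domain-level binding (motifs here are exact substrings), and
composition bias of real proteomes (unless `background = "natural"`).
Passing tests therefore demonstrate that the pipeline recovers a
planted, representable signal under label noise — they do not certify
accuracy on any real interactome.

On these defaults the package asserts 5-fold cross-validated
sensitivity and specificity of at least 0.8 each, and that
label-shuffled data scores within 0.1 of chance accuracy; the test
suite and `scripts/acceptance.R` compute both.

## Numerical choices

* The calibration objective is minimized by damped Newton iteration
  with backtracking line search (Armijo constant $10^{-4}$), a
  $10^{-12}$ ridge on the Hessian, convergence at gradient max-norm
  $10^{-10}$, at most 100 iterations. The log-likelihood is evaluated
  via `log1p(exp(·))` on the appropriate tail so it is stable for
  arbitrarily large $|Af + B|$. The implementation is checked in the
  tests against an independent refining grid-search minimizer of the
  same objective.
* Ranking ties (equal probabilities) are broken lexicographically by
  accession, so search output is a pure function of (query, database
  content, model) and independent of storage order.
* Indirect paths are scored by the product of edge probabilities —
  the natural choice if edges were independent — and intermediates must
  be distinct from each other and from the queries. The score function
  is intentionally simple; paths carry their per-edge probabilities so
  callers can re-score.
* Edge-list exports print weights with 17 significant digits, the
  round-trip-safe precision for IEEE doubles; hit tables print 4
  decimals, the conventional reporting precision for these
  probabilities.
* Undefined evaluation ratios (zero denominator, e.g. precision with no
  positive predictions) are reported as missing values, never as 0.
* Every stochastic step (fixture generation, fold assignment, inner
  splits) takes an explicit integer seed and restores the caller's RNG
  state, so identical seeds reproduce fixtures, models and reports
  bit-for-bit.

## Open design points, and how they were decided

* **Negative training pairs.** Interaction databases publish positives;
  how negatives were sampled is usually unstated. The generator emits
  explicit negatives at a configurable class balance (default 1:1), and
  the class balance is a spec knob rather than a hidden constant.
* **Pair-level vs protein-disjoint cross-validation.** Pair-level
  stratified splitting is the default, matching common practice;
  `split = "protein"` assigns whole proteins to folds so train and test
  share no protein. On the synthetic benchmark the two modes score
  similarly — the planted signal is motif content, which does not
  leak through protein identity — but on real data, where proteins
  recur across many pairs, the disjoint mode is the honest one.
* **Known interactions in path search.** Whether indirect-path edges
  should come from predictions, the known-PPI set, or both is
  genuinely ambiguous; prediction-only is the default and
  `use_known_edges = TRUE` unions in known edges at probability 1.0.
* **Mean-of-folds vs pooled metrics.** Both are computed; the
  unweighted fold mean is the headline (it weights folds equally), the
  pooled counts are reported alongside.

## Problem sizes

The shipped tests run the full pipeline at the default benchmark scale
(200 proteins / 800 pairs) once for the end-to-end claims, and use a
60-protein / 160-pair fixture for the search, network and filter
oracles; the triad-counting oracle covers 1,000 random sequences of
length 3–200 and the calibration recovery 20 replicates of $n = 2000$.
These sizes were chosen so the whole suite exercises every claim at
meaningful scale while remaining comfortable to run on a laptop.

## Known limitations

* The features see sequence composition and local order only; they are
  blind to structure, post-translational modification, localization and
  condition-specific interaction.
* A trained model is species- and database-specific; scoring sequences
  from a distant proteome amounts to extrapolation.
* The indirect-path search scores each edge independently; it does not
  model the joint plausibility of a chain.
* Exact-duplicate accessions are rejected, but no sequence-redundancy
  filtering is performed; heavily redundant databases will bias both
  training and ranking.
* With `skip`-policy ambiguity codes, a sequence dominated by ambiguous
  residues can silently contribute very few windows; strict mode exists
  for pipelines that prefer a hard failure.
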