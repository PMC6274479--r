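---
title: "ASMTP: model, screening protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASMTP: model, screening protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmtp)
```

## The problem

Ligand-based virtual screening (LBVS) ranks a database of compounds by
similarity to reference structures with known biological activity, on the
premise that structurally similar molecules tend to share activity. The
molecules are encoded as *count fingerprints*: fixed-length integer vectors
(here $M = 1024$ after folding) whose entries count occurrences of circular
substructure features. These vectors are extremely sparse — roughly 90% of
the entries of a typical folded circular fingerprint are zero — which makes
the choice of similarity coefficient consequential: a measure must reward
shared features, react sensibly to count differences, and not be swamped by
the overwhelming number of jointly absent features.

## The ASMTP similarity measure

ASMTP adapts a document-retrieval similarity to count fingerprints. For
molecules $m_1, m_2$ with counts $m_{1j}, m_{2j}$ at feature $j$:

$$
N^*(m_{1j}, m_{2j}) =
\begin{cases}
\tfrac{1}{2}\!\left(1 + \exp\!\left[-\left(\frac{m_{1j}-m_{2j}}{\mu_j}\right)^2\right]\right)
  & m_{1j} m_{2j} > 0 \\
0 & m_{1j} = m_{2j} = 0 \\
-\lambda & \text{otherwise,}
\end{cases}
$$

with $N^\cup = 0$ when both counts are zero and $1$ otherwise. Then
$F = \sum_j N^* / \sum_j N^\cup$ and the reported score is
$S = (F + \lambda)/(1 + \lambda)$.

The three cases encode the measure's guiding properties: a feature present
in both molecules contributes a Gaussian in the count difference with lower
bound $1/2$ (presence alone is worth half the maximum credit); a feature
present in exactly one molecule is penalised by the constant $\lambda$
regardless of magnitude; a feature absent from both contributes nothing and
is excluded from the normalisation, so the ~90% of jointly-zero features
cannot dilute the score.

**The scale $\mu_j$** is the mean of the *non-zero* values of feature $j$
across the screened dataset, computed once over the whole database with
references included (`compute_feature_scaling()`). Features with large
typical counts therefore tolerate proportionally larger count differences.
The original text-processing formulation scaled by the standard deviation
of the non-zero values instead; that variant is kept behind
`scaling_mode = "nonzero-stddev"` for comparison, with the sentinel scale
1.0 substituted where fewer than two non-zero values exist or the spread is
exactly zero. In mean mode the sentinel covers only never-seen features and
is provably never consumed when both molecules come from the dataset,
because the Gaussian branch requires the feature to be present in both.

**$\lambda$** (default $10^{-4}$, the published test value; working range
$10^{-4}$–$10^{-2}$) sets the presence/absence penalty and simultaneously
the score offset: disjoint-support pairs get $F = -\lambda$, hence
$S = 0$ exactly, and identical fingerprints get $S = 1$ exactly.
`similarity_config()` accepts any positive value but warns above 0.01.

### Numerical choices

* $S$ is evaluated as
  $(\,\sum_{\text{shared}} N^* + \lambda c\,) / (\,u (1+\lambda)\,)$, where
  $c$ is the number of shared features and $u$ the union size. This is
  algebraically identical to $(F+\lambda)/(1+\lambda)$ but exact at the
  boundaries; the naive form returns values like $-10^{-20}$ for disjoint
  pairs through floating-point cancellation.
* A pair whose support union is empty (two all-zero fingerprints) is an
  error, not a score: the defining ratio is $0/0$ and no property fixes a
  value. During database ranking such molecules are warned about and placed
  at the bottom instead of aborting the screen.
* BEDROC's closed form overshoots 1 by ~$10^{-15}$ at a perfect ranking
  (independent implementations show the same round-off); the returned score
  is clamped to $[0,1]$.

## Comparison coefficients

The registry (`similarity_measures()`) also provides the conventional
baselines, all on the raw count vectors: continuous Tanimoto
$\frac{x\cdot y}{\|x\|^2+\|y\|^2-x\cdot y}$ (the standard fingerprint
coefficient; identical to the text-retrieval "extended Jaccard"), binary
Tanimoto $c/(a+b-c)$ after binarisation, Dice, cosine, and Euclidean
distance (ranked ascending). The pairwise-adaptive and information-theoretic
text measures are not implemented: their document-collection-specific terms
have no canonical analogue for fingerprints.

## Screening protocol

`screen()` reproduces the simulated-screening design used in LBVS
benchmarking:

1. For every activity class, `n_references = 10` actives are drawn at
   random under a seeded generator. The draw depends only on dataset, class
   and seed — never on the measure — so different measures screened under
   one seed query *unified* reference sets.
2. Each reference is used as a query; every molecule of the database
   (references included) is scored and ranked in decreasing similarity
   (increasing distance), ties broken by ascending molecule id so runs are
   byte-reproducible.
3. Per-query metrics are averaged over each class's ten references
   (`evaluate_screen()`), and measures are compared per class
   (`summarize_evaluations()`), crediting every measure tied for the best
   class mean — the "shaded cells" tally of the benchmarking literature.

Two conventions were genuinely open and are resolved as follows:

* **References stay in the database and count as retrievable actives.**
  Nothing in the protocol's description excludes them, and class recall
  denominators are whole-class sizes. `evaluate_screen(exclude_references
  = TRUE)` switches to the exclusive convention.
* **"ROC/AUC at a cutoff"** is read as the full-ranking ROC reported
  alongside the cutoff-recall experiment; a truncated ROC (area over
  `fpr <= max_fpr`, normalised by `max_fpr`) is implemented but
  non-default, since the phrase admits both readings.

## Evaluation metrics

* **Recall@p%**: percentage of the class's actives in the top
  $k = \max(1, \operatorname{round}(pN/100))$ ranked molecules. The
  rounding rule is undefined in the protocol description; round-half-even
  (R's default) is used and documented. Ties at position $k$ are resolved
  by the deterministic ranking order, not fractionally.
* **Sensitivity / specificity** of a top-$k$ selection:
  $TP/(TP+FN)$ and $TN/(TN+FP)$.
* **ROC/AUC**: descending-threshold sweep; equal scores form a single
  threshold step; trapezoid area (equivalent to the Mann–Whitney statistic
  with ties counted one half — the property the test oracle checks).
* **Enrichment factor**: $(a/k)/(A/N)$, 1 by construction at 100%.
* **BEDROC** (Truchon–Bayly): exponentially weighted active ranks,
  $\alpha = 20$ by default (weight concentrated in roughly the first 8% of
  the list).

## The synthetic data generator

Licensed benchmark databases (MDDR) and commercial fingerprint software
cannot ship with a package, so `generate_dataset()` builds a synthetic
world with the statistical shape that matters to the method, and the test
suite runs entirely on it:

* **Sparsity 0.90**: every molecule gets exactly
  $\operatorname{round}(M(1-s))$ non-zero features (102 at the defaults),
  matching the ~90%-zeros regime of folded circular count fingerprints.
* **Class structure**: each activity class owns a random disjoint *core*
  of `class_core_size = 60` features; an active keeps each core feature
  with probability `core_retention` and fills the remainder with uniform
  background features. Retention 0.9 emulates a structurally homogeneous
  class, 0.5 a heterogeneous one (`retention_preset()`). Decoys draw
  background features only.
* **Counts**: shifted geometric, mean 2 — a heavy-tailed stand-in for
  circular-fingerprint count distributions, which no benchmark description
  specifies. Defaults of 5 classes × 50 actives + 2000 decoys keep a full
  screen around a minute on one CPU.

What a green test on this world does *not* establish: real fingerprint
features are correlated (substructures nest), decoys in curated benchmarks
are property-matched to actives, and class cores here are disjoint while
real activity classes overlap. The generator supports relative claims
("ASMTP separates structured classes, agrees with its oracle, beats random
ranking") — not absolute recall levels from any published benchmark.

## Known limitations

* The SMILES adapter (`smiles_to_fingerprints()`) uses open-source hashed
  Morgan count fingerprints of radius 2; it approximates, and is not
  bit-compatible with, commercial ECFC_4 pipelines.
* Scores of molecules never seen by `compute_feature_scaling()` are well
  defined but use the sentinel scale for features unseen in the dataset;
  recompute the scaling after extending a database.
* No fusion rules (MAX/SUM over multiple references) — each reference is
  ranked independently and metrics are averaged, as in the protocol this
  package implements.
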