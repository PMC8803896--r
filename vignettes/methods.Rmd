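---
title: "Models and methods behind protscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protscreen)
```

protscreen classifies proteins into a binary functional class (the
motivating application is antioxidant-protein recognition and virtual
screening of candidate drug-target enzymes) using nothing but the primary
sequence. This vignette explains the models the package implements, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not demonstrate.

## Sequence hygiene

All encoders operate on the 20-letter standard amino-acid alphabet.
`validate_sequence()` rejects, rather than repairs, anything else —
ambiguity codes (B, X, Z), the rare translated residues (U, O), gaps and
stop characters — mirroring how curated training corpora for this problem
are assembled. Lowercase input is uppercased on read (FASTA dialects
vary), so validation applies a single canonical alphabet. Each operation
declares its own minimum length: composition features need $L \ge 1$,
while a gap-$k$ pair count needs $N \ge k + 2$ so that at least one pair
exists; the pipeline therefore uses $\max(k) + 2$ as its default filter.

## The 188-dimensional descriptor

The descriptor concatenates amino-acid composition with
composition–transition–distribution (CTD) features over eight
physicochemical partitions of the alphabet (hydrophobicity, van der Waals
volume, polarity, polarizability, charge, surface tension,
secondary-structure propensity, solvent accessibility), shipped verbatim
as `inst/extdata/aa_property_groups.tsv` and validated at load time to be
exact 3-way partitions of the alphabet.

For a sequence of length $L$ and a property with groups I–III:

* **Composition (20):** $F_a = n_a / L$ for each residue $a$, in fixed
  alphabetical order.
* **Content (3):** $CS_i / L$, with $CS_i$ the count of group-$i$
  residues. We read $CS_i$ as a count — the only reading under which
  $CS_i/L$ is a frequency.
* **Distribution (15):** for each group, the 1-based positions of the
  first and of the $\lceil 0.25\,CS_i\rceil$-th,
  $\lceil 0.50\,CS_i\rceil$-th, $\lceil 0.75\,CS_i\rceil$-th and
  $CS_i$-th occurrences, each divided by $L$. This is the standard
  CTD-distribution convention (five quantile positions per group,
  ceilings for fractional ranks). An absent group contributes five zeros
  rather than missing values, keeping every feature in $[0,1]$ and
  matrices dense.
* **Transition (3):** counts of adjacent residue pairs bridging groups
  \{I,II\}, \{I,III\}, \{II,III\} in either order, divided by $L$. The
  conventional denominator for transitions is $L-1$ (the number of
  adjacent pairs); the package defaults to $L$ for compatibility with the
  descriptor lineage it implements and exposes
  `transition_denominator = "L-1"` as a switch. With $L$ the features
  remain in $[0,1]$ either way.

The blocks are ordered composition first, then the eight property blocks
in the order of `property_groups()`. Since the historical block order is
ambiguous, every one of the 188 entries carries a self-describing name
(`aac.A`, `hydrophobicity.dist.g2.p75`, ...), so column identity never
depends on position.

## CKSAAP

The composition of $k$-spaced amino-acid pairs counts ordered pairs
$(i, j)$ with $i$ at position $p$ and $j$ at position $p + k + 1$:

$$F_{ij} = \frac{n_{ij}}{N - k - 1}, \qquad p \in [1,\, N-k-1].$$

Pairs are ordered ($400 = 20^2$ features per gap), and the denominator is
the general pair count $N - k - 1$, which specializes to $N-4$ at the
pipeline default $k = 3$ — the gap empirically most informative for
antioxidant proteins. The combined default vector is
$188 + 400 = 588$ features.

## MRMD feature selection

Each feature $i$ is scored $MR_i + MD_i$:

* $MR_i = |\mathrm{PCC}(F_i, C)|$, the absolute Pearson correlation with
  the class vector ($C$: positive = 1, negative = 0). A zero-variance
  feature gets $MR_i = 0$.
* $MD_i$ is the mean distance between feature column $i$ and every other
  feature column: euclidean, cosine ($1 - \cos$), tanimoto
  ($1 - \frac{x \cdot y}{\lVert x\rVert^2 + \lVert y\rVert^2 - x \cdot y}$),
  or — the default — the mean of the three. Distances are taken
  feature-to-feature (a feature scores high when it is *far from*, i.e.
  non-redundant with, the rest of the feature set).

Two numerical choices matter. First, feature columns are min-max scaled
to $[0,1]$ before distances are computed; without this the euclidean
component is dominated by whichever features happen to have large
magnitudes, and the sum $MR + MD$ adds quantities on incompatible scales.
The scaling can be disabled (`scale = FALSE`) for comparison with
implementations that skip it. Second, similarities against an all-zero
(scaled-constant) column are defined as 0 (distance 1), avoiding 0/0.

Ranking is by descending score with deterministic tie-breaks (larger
$MR$, then input column order). `select_subset()` then evaluates ranking
prefixes by stratified CV accuracy of the pipeline classifier and keeps
the smallest prefix attaining the peak — "highest accuracy, fewest
features". Strict one-at-a-time stepping is selectable (`step = 1`) but
quadratic in cost; the default steps by 1 below 100 features and by 5
above, and the larger analyses in this package use coarser grids (the
acceptance workflow uses a prefix grid of 100 over 588 features), since
the accuracy profile is flat over wide prefix ranges and a coarse grid
finds the same plateau at a fraction of the cost.

## Class rebalancing

Training corpora for this problem are typically 1:2 or worse.
`random_undersample()` discards a uniform random subset of the majority
class, without replacement, down to `ratio` times the minority count
(default 1:1); the minority class is never touched and nothing synthetic
is ever added. The operation permutes nothing — retained rows keep their
input order — and acts on either raw sequence datasets or encoded
matrices, so it can run before extraction (the pipeline default, matching
the reference stage order undersample → extract → select → classify) or
after, for ablation. More elaborate undersampling schemes
(condensed/edited nearest-neighbour variants) are deliberately out of
scope; the operation signature is a strategy interface an adapter can
implement.

## Classification and evaluation

The classifier is a random forest (`randomForest`), default 100 trees —
forest size mainly trades compute for variance here, and results are
insensitive over the 50–500 range. A sample's score is its positive-vote
fraction; scores at exactly the threshold (default 0.5) are called
positive, the choice that favours sensitivity.

Metrics are the field's standard five: SN, SP, ACC, MCC and ROC AUC. AUC
is computed as the tie-corrected Mann–Whitney statistic, identical to
trapezoidal integration of the ROC curve over all thresholds.
Cross-validation is stratified; metrics are computed **once on the pooled
out-of-fold scores** rather than averaged across folds, because MCC and
AUC are biased when averaged over small folds. Per-fold reports are
available via `per_fold = TRUE`. Degenerate confusion denominators yield
0 by convention and are flagged in the report rather than silently
dropped.

## The synthetic benchmark

`generate_dataset()` draws negatives i.i.d. uniformly over the alphabet
and positives from a tilted distribution: mass $\delta$ is moved onto a
designated group (default CVLIMFW, the hydrophobic group), so each group
residue has probability $(1-\delta)/20 + \delta/7$. The expected group
content of positives exceeds negatives by exactly
$\delta\,(1 - 7/20) = 0.65\,\delta$, which makes the planted signal
analytically checkable — the reason a uniform background was chosen over
natural amino-acid frequencies. An optional `pair_effect` plants a fixed
$k$-spaced pair in positives at a per-position rate, giving the CKSAAP
block a signal of its own. Default class sizes (710:1552, about 1:2.2)
mirror the scale and imbalance of curated antioxidant corpora so the
rebalancing stage is exercised realistically.

The reference study conditions used by the test suite are $\delta = 0.15$
with 300 sequences per class, lengths 50–200 (seed 42); under them the
default pipeline's pooled 5-fold CV reaches ACC ≈ 0.86 and AUC ≈ 0.92,
and at $\delta = 0$ it sits at chance. Note what this does and does not
show: the generator plants a *compositional* signal with i.i.d. residues,
so it validates the machinery (encoders, selection, rebalancing,
evaluation) end to end, but it has none of the positional motifs,
domain structure, length–class correlations or phylogenetic redundancy of
real proteins. Absolute benchmark figures on real antioxidant data depend
on the original corpora and cannot be reproduced from synthetic input.

## Problem sizes and reproducibility

The package's own analyses are sized for a single CPU: the acceptance
workflow (`scripts/acceptance.R`) runs the full design at the reference
scale — 710+1552 generated sequences, stratified 4:1 split, 568:568 after
undersampling, 588 features, MRMD selection over a prefix grid of 100,
pooled 5-fold CV, held-out test evaluation — in about a minute. Every
source of randomness (generation, splitting, undersampling, fold
assignment, forest fitting) is seeded from a single master seed, and the
pipeline emits a config snapshot from which a run can be reproduced
bit-for-bit.

## Known limitations

* Only random undersampling is bundled; no oversampling (SMOTE-style)
  strategies.
* Only the random forest is bundled as a classifier; the train/predict
  contract accepts drop-in alternatives but none ship.
* The "secondary structure" property is a fixed residue grouping, not a
  structure prediction.
* MRMD's euclidean component grows with sample count $\sqrt{n}$, so the
  $MR$ term matters relatively less at large $n$ even after column
  scaling; the `method` argument allows cosine/tanimoto-only distances if
  that is a concern.
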