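# protscreen

Sequence-based binary classification of proteins, built for problems like
recognising antioxidant proteins and virtually screening candidate
drug-target enzymes from primary sequence alone. Given two FASTA files
(a positive and a negative class), the package encodes each sequence as a
fixed-length numeric descriptor, rebalances the training set, selects an
informative feature subset, fits a random forest, and reports the standard
evaluation suite. Everything is testable offline: a synthetic-sequence
generator plants a controllable compositional signal so the whole pipeline
can be exercised without any external databases.

## The method

**Feature encoding.** Each protein sequence of length *L* over the 20
standard amino acids is mapped to:

* **Amino-acid composition (20):** residue frequencies *n<sub>a</sub>/L*.
* **CTD descriptors (8 × 21 = 168):** for each of eight physicochemical
  properties (hydrophobicity, van der Waals volume, polarity,
  polarizability, charge, surface tension, secondary-structure propensity,
  solvent accessibility) the alphabet is partitioned into three groups and
  the sequence is summarised by 3 *content* features (group frequency
  CS<sub>i</sub>/L), 15 *distribution* features (normalized positions of
  the 1st, 25%, 50%, 75% and 100% occurrences of each group), and 3
  *transition* features (frequencies of adjacent residue pairs bridging
  two different groups). Together with the composition block this is the
  classical 188-dimensional descriptor.
* **CKSAAP (400 per gap k):** the composition of k-spaced amino-acid
  pairs, F<sub>ij</sub> = n<sub>ij</sub>/(N−k−1), counting ordered residue
  pairs separated by exactly k intervening residues. The pipeline default
  is the combined 188D + CKSAAP(k = 3) vector of 588 features.

**Feature selection (MRMD).** Each feature *i* receives a
Max-Relevance-Max-Distance score MR<sub>i</sub> + MD<sub>i</sub>, where
MR<sub>i</sub> = |PCC(F<sub>i</sub>, C)| is the absolute Pearson
correlation with the class vector and MD<sub>i</sub> is the mean distance
of the (min-max scaled) feature column to all other feature columns —
euclidean, cosine, tanimoto, or their mean (the default). Features are
ranked by descending score and prefixes of the ranking are evaluated by
stratified cross-validation accuracy; the smallest prefix attaining the
peak accuracy is kept.

**Rebalancing.** Random undersampling discards a uniform random subset of
the majority class down to a configurable majority:minority ratio
(default 1:1), before feature selection.

**Classification and evaluation.** A random forest (default 100 trees)
votes on each sample; the score is the positive-vote fraction. Reports
include sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP),
accuracy, the Matthews correlation coefficient, and the ROC AUC
(tie-corrected Mann-Whitney), computed on pooled out-of-fold predictions
for cross-validation.

## Worked example

```r
library(protscreen)

# a labeled synthetic dataset: positives carry extra hydrophobic residues
spec  <- synthetic_spec(n_pos = 120, n_neg = 240,
                        length_range = c(50, 150), delta = 0.15, seed = 7)
data  <- generate_dataset(spec)
train <- random_undersample(data, ratio = 1, seed = 7)
train
#> labeled_dataset: 240 sequences (120 positive, 120 negative)

fm <- encode_dataset(train, features = "combined", ks = 3)  # 240 x 588
cv <- cross_validate(fm, folds = 5, n_trees = 100, seed = 7)
cv
#> SN 0.817  SP 0.850  ACC 0.833  MCC 0.667  AUC 0.871
#> counts: TP 98  FP 18  TN 102  FN 22
```

The positives were generated with 15% of their residue mass shifted onto
the hydrophobic group CVLIMFW, so a pooled 5-fold CV of the default
pipeline recovers the planted class signal well above chance (ACC 0.83,
AUC 0.87 here); with `delta = 0` the same pipeline sits at chance. Feature
ranking and screening work the same way:

```r
rk    <- rank_features(fm)               # MRMD ranking (name, mr, md, score)
sel   <- select_subset(rk, fm, folds = 5, seed = 7)
model <- train_model(fm[c("id", "label", sel$chosen)], seed = 7)
predict_score(model, fm, sort = TRUE)    # ranked screening report
```

`run_pipeline()` chains every stage (read → split → undersample → encode →
rank/select → cross-validate → train → test) and writes all artifacts —
feature matrix, ranking, selection report, model, metric JSONs — to an
output directory, reproducibly from its seed. A thin command-line front
end with the same stages as subcommands lives at
`inst/cli/protscreen.R` (`Rscript protscreen.R --help`).

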