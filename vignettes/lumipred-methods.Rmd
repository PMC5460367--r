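---
title: "Predicting bioluminescent proteins from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bioluminescent proteins from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumipred)
```

## The problem

Bioluminescent proteins (BLPs) — luciferases, photoproteins and their
relatives — convert chemical energy into light.  They occur in bacteria,
eukaryota and archaea, share little overall sequence similarity, and keep
being discovered in new clades, so annotating candidate BLPs by homology
alone is unreliable.  lumipred treats the problem as supervised binary
classification from the primary sequence: a protein is encoded as a fixed
vector of sequence-derived features and scored by an RBF-kernel support
vector machine.  Because compositional preferences differ markedly between
lineages (bacterial BLPs are enriched for buried residues, eukaryotic ones
for aliphatic and aromatic residues, and so on), the package also trains
lineage-specific classifiers and dispatches queries by lineage tag, with a
universal model as fallback.

## Feature encodings

Four blocks are concatenated in a fixed order with stable string names, so
feature-subset masks survive serialization:

* **AAC** (20 values): relative frequencies of the residues,
  $f_{AAC}(i) = n_i / L$.
* **DC** (400 values): relative frequencies of ordered adjacent residue
  pairs, $f_{DC}(i,j) = n_{ij} / (L-1)$, row-major over the alphabet with
  the first residue on the N-terminal side.
* **MTF** (one value per catalogued motif, 10 by default): binary presence
  indicators for discriminative gapped motifs discovered from the training
  data (below).
* **PCP** (9 values): for each physicochemical property scale $p$, the
  sequence mean $\bar p = \frac1L \sum_j p(a_j)$ min-max normalised by the
  smallest and largest of that property's 20 per-residue values:
  $f_{PCP}(p) = (\bar p - \min_a p(a)) / (\max_a p(a) - \min_a p(a))$.

The PCP normalisation domain was a genuinely open design point: applying
min/max to anything other than the 20 per-residue scale values fails to
give a fixed $[0,1]$ range per protein, so that reading is implemented.
The nine scales shipped in `inst/extdata/pcp_scales_default.tsv` are
standard published ones (Kyte-Doolittle hydrophobicity, Hopp-Woods
hydrophilicity, Grantham polarity, Charton polarizability, Janin transfer
free energy, Chothia solvent contact area, a charge indicator,
Bhaskaran-Ponnuswamy flexibility) except the ninth, a protein-kinase-A
substrate propensity, for which no canonical public scale exists; the
shipped values are a synthetic default constructed for this package
(weight on S/T acceptors and the upstream basic residues of the PKA
consensus).  Any 20-column TSV with non-degenerate rows can be substituted
via `load_property_table()`; conclusions that depend on exact PCP values
should use the user's own table.

## Gapped motif discovery by difference of information gains

The motif space is deliberately small: 2–4 literal residues with 0 or 1
wildcard between consecutive literals, and 2-literal patterns forced to
carry the wildcard (ungapped pairs already live in the DC block).  This is
the smallest space containing the motif strings this method family reports
(e.g. `EHH`, `EH-H`, `L-S-GR`, `G-T-G-P`, `A-A-T-D`), with spans of at
most 7 residues.  "Frequency" always means the fraction of sequences
containing at least one match, never occurrence counts.

Discovery proceeds in two stages:

1. **Screen**: every pattern whose frequency in the positive class strictly
   exceeds a threshold $T$ (default 0.10) is a candidate.  The
   implementation screens patterns *occurring* in the positive sequences,
   which is exactly equivalent to enumerating the full space, because a
   pattern occurring in no positive sequence has frequency 0 and can never
   pass a strict threshold.
2. **Score**: with $H_0$ the base-2 entropy of the class proportions over
   the pooled set, each candidate $P$ is scored by
   $\mathrm{DIG}(P) = IG_B(P) - IG_N(P)$, where $IG_B$ is the information
   gained by splitting the pooled set into {positives containing $P$}
   versus everything else, and $IG_N$ the gain for {negatives containing
   $P$} versus everything else ($0\log 0 := 0$ throughout).

DIG rewards positive-enriched patterns: a pattern in every positive and no
negative scores the full class entropy (1 bit on balanced data), a pattern
equally present in both classes scores 0 by symmetry, and the score is
monotone in positive-class frequency at fixed negative-class frequency.
The top `top_k` (default 10) candidates by DIG, ties broken
lexicographically by pattern string for reproducibility, form the catalog;
scoring involves no randomness, so discovery is deterministic given the
input.  The catalogued patterns then become the binary MTF block.

## Feature selection

A filter-then-wrapper strategy:

* `fisher_markov_rank()` scores each standardized feature by
  $d_j^2 - \gamma w_j$ (squared class-mean gap minus $\gamma$ times pooled
  within-class variance, default $\gamma = 0$).  This is a fully specified
  two-class linear variant of the Fisher-Markov family; an exact published
  selector can be dropped in through the same interface.
* `sbs_select()` walks backwards from the full set, eliminating the
  lowest-ranked remaining feature and re-evaluating a cross-validated mean
  MCC criterion after each elimination, on fold partitions fixed by the
  seed so all comparisons are paired.  The selected subset is the smallest
  one whose criterion is within `slack` of the walk's maximum.

The `slack` parameter (default 0.02) deserves a note, because the naive
rule — accept an elimination only if the criterion does not decrease —
turned out to be structurally broken during development: at the validation
sizes the wrapper runs on, a single flipped prediction moves the mean fold
MCC by about 0.02, so roughly half of all pure-noise eliminations get
"rejected" by chance and the walk stalls immediately, defeating backward
elimination entirely.  Walking the full ranking (the default
`patience = Inf`) and then choosing the smallest subset within one
flipped-prediction's worth of the maximum makes the procedure robust to
this granularity while guaranteeing the final criterion is never more than
`slack` below the all-features criterion.  Setting `slack = 0` recovers
the strict argmax subset.

## Classifier, grid search and calibration

The classifier is an RBF-kernel SVM (libsvm via e1071).  `grid_search_train()`
evaluates every $(C, \gamma)$ pair by stratified k-fold CV (default 5
folds) and picks the pair maximizing mean CV MCC, breaking ties toward
smaller $C$ then smaller $\gamma$; the default grid is the canonical
coarse one, $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ in log-steps of 2.
`fast_config()` provides a reduced 4×4 grid bracketing $\gamma = 1/d$ for
this package's feature dimensionalities; the bundled simulations and
examples use it.  Standardization parameters are learned from training
data only and stored with the model.

Propensity scores in $[0,1]$ come from a Platt-style sigmoid fitted by
logistic regression of the training labels on the SVM decision values.
libsvm's own probability machinery was deliberately not used: its internal
cross-validation consumes a C-level random stream that cannot be seeded
from R, which would break the package's bit-reproducibility guarantees
(identical predictions after save/load, identical metrics for identical
seeds).  Since any monotone calibration leaves ROC ordering unchanged, AUC
is unaffected by this choice; classification labels use the 0.5 score
threshold.

## Evaluation protocol

`compute_metrics()` implements sensitivity, specificity, accuracy and MCC
from the confusion counts, with MCC defined as 0 whenever a marginal is
zero (the standard convention that keeps the statistic total).
`roc_auc()` uses the rank (Mann-Whitney) formulation with midrank ties.
`kfold_cv()` re-runs the *entire* pipeline — motif discovery, feature
assembly, optional selection, grid search — inside each training fold, so
no information from a validation fold leaks into the catalog or the
scaling; passing a pre-built catalog through `config$catalog` deliberately
emulates the laxer protocol where motifs are discovered once on all data.
Folds are stratified: the smallest lineage datasets would otherwise risk
single-class folds.  `repeated_undersample_eval()` evaluates a fitted
model on repeated balanced under-samples (or fractional draws) of an
imbalanced set, keeping per-repeat metric vectors; reported `±` values are
standard deviations across folds or repeats.

`compare_methods()` implements the normality-gated paired test: Shapiro-Wilk
on both metric vectors at α = 0.05, then a paired t-test if both pass and
the Wilcoxon signed-rank test otherwise, two-sided, significant at
p < 0.05.  Identical vectors return p = 1 by convention.  Under a normal
null this protocol holds its nominal 5% type-I error (checked by
simulation in the test suite).

Routine cross-validation in this package does not run the SBS wrapper
inside every fold (`do_sbs = FALSE` by default): the wrapper multiplies
training cost by the feature count, and its contribution is assessed by
its own parameter-recovery simulation instead.  Setting `do_sbs = TRUE`
in the config restores the full filter+wrapper pipeline per fold.

## The synthetic-data generator

`simulate_dataset()` draws i.i.d. sequences from a residue background
(uniform 1/20 by default — the tests care about relative class differences,
not naturalistic composition), applies an additive per-residue composition
shift to the positive class (rescaling unshifted residues to keep the
distribution proper), and plants gapped motifs at Bernoulli rates per
class, overwriting background residues at a uniform random position so
lengths are unchanged.  `make_benchmark_suite()` fixes three regimes:

* **separable** — 100+100 sequences of length 120–180; positives carry a
  +0.05 shift on E and K (echoing the charged-residue enrichment reported
  for real BLPs) and an `EHH` motif at 70% vs 2%.  The fixture is
  calibrated so that its defining property — five-fold CV MCC above 0.8
  for the trained pipeline — holds robustly across seeds.
* **null** — identical sizes, no class signal; CV MCC stays within ±0.2
  of zero.
* **lineage_heterogeneous** — three lineages of 60+60 (length 100–140)
  with disjoint planted motifs (`EHH`, `G-T-G-P`, `DGW`, 50% vs 5%) and
  *opposing* composition shifts (bacteria +K/−D, eukaryota −K/+D, archaea
  +W/−L), so pooled training blurs signals that lineage-specific training
  exploits — reproducing the direction of the lineage-specific scheme's
  advantage.

What the generator does **not** emulate: homology structure and redundancy
(real benchmark sets require clustering at 30–40% identity before
training; see below), naturalistic residue composition, length/composition
correlations, and domain architecture.  Passing tests on these fixtures
therefore demonstrates that the machinery recovers the statistical signals
it targets, not that any particular accuracy will be achieved on real
proteins.

## Numerical and degenerate-input choices

* Entropy base 2, $0\log 0 := 0$; DIG ties broken lexicographically.
* MCC denominator zero → MCC 0; undefined sensitivity/specificity → `NA`.
* Constant feature columns standardize to zero (scale factor 1), score
  $-\gamma w = 0$ at $\gamma = 0$, never `NaN`.
* Non-standard residues (B, J, O, U, X, Z, gaps): dropped with a warning
  and per-record count by default, or rejected under `policy = "reject"`;
  sequences shorter than 2 residues after sanitization are rejected (DC is
  undefined at $L = 1$).
* Grid-search ties: smaller $C$, then smaller $\gamma$.
* Degenerate property scales (max = min) are refused at table load.

## Problem sizes used by the bundled evaluations

The test suite and `scripts/acceptance.R` run entirely on generated data:
benchmark fixtures of 200 sequences (separable/null) and 360 (three
lineages), 20 discovery runs of 100+100 sequences of length 200 for
planted-motif recovery, 10 seeds of a 100 × 60 informative-plus-noise
matrix for selection recovery, 10 seeds of the lineage fixture for the
ensemble comparison, and 1000 replicates for the type-I-error check.
These sizes give stable pass/fail behaviour for the properties above while
keeping a full run in the minutes range on one CPU.

## Known limitations

* Redundancy reduction (CD-HIT/BLASTClust-style clustering) is out of
  scope; users should cluster their own datasets before training, or
  performance estimates will be optimistic.
* The shipped PCP table is a reasonable default, not an authoritative one;
  the ninth scale is synthetic (see above).
* The DIG definition implemented here is one principled reconstruction of
  a difference-of-information-gains score; other reconstructions (e.g.
  symmetric presence splits) would rank some patterns differently.
* Motif wildcards are exactly one position; variable-length gaps and
  position-weight matrices are out of scope.
* Evolutionary-profile features (PSSMs) are deliberately absent — the
  method is sequence-only by design.
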