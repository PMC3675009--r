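---
title: "Methods: combinatorial clustering of binding-site residue triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial clustering of binding-site residue triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Protein families such as the kinases share highly similar binding sites,
which makes whole-site comparison a blunt instrument for predicting which
family members bind a given small molecule.  triadclust implements a
semi-supervised approach built on a different unit of comparison: the
*residue triad*.  Given a set of structures mapped to a common alignment
and a selection of P binding-site columns, every one of the
$\binom{P}{3}$ 3-column subsets is examined in isolation.  Three residues
are the smallest unit that admits a unique rigid-body superposition in
3-D, which keeps the geometric term of the comparison well defined while
still decomposing the site into local features.

For one subset, every pair of structures is compared with the combined
dissimilarity

$$D(a, b) \;=\; w_s \cdot \mathrm{lRMSD}(a, b)
  \;+\; w_p \sum_{i=1}^{3} \Phi\!\big(t_{a,i},\, t_{b,i}\big),$$

where lRMSD is the least RMSD over the three side-chain centroids under an
optimal proper rigid superposition (correspondence fixed by alignment
column, no residue matching), and $\Phi$ is a symmetric 20x20
pharmacophore dissimilarity between residue types.  Both weights default
to 1; the exact weighting of the two terms in the original formulation is
not recoverable, so they are exposed as configuration together with the
matrix itself.  The default matrix counts differing binary pharmacophore
features (H-bond donor, H-bond acceptor, aromatic, positively ionizable,
negatively ionizable, hydrophobic) per residue pair, a scale commensurate
with Angstrom-level RMSD values; a replacement matrix can be supplied as a
CSV (`read_pharm_matrix()`).

The N x N distance matrix of a subset is redundant; its rows are treated
as feature vectors and projected by principal components
(`embed_rows()`), keeping the smallest dimensionality that explains 90%
of variance, capped at 10.  The embedded points are clustered with a
Gaussian mixture model selected by BIC (`cluster_gmm()`), because the
number of structural versions of a triad is not known in advance.  Label
information plays no role up to this point: the clustering pass
(`cluster_subsets()`) is entirely unsupervised and is therefore computed
once per dataset and shared across compounds, cross-validation folds and
permutation tests.

## Highly predictive clusters and label transfer

For one compound, each sequence carries a label true / false / unknown
(e.g. a dissociation constant binned at 10 uM, binding-inclusive at the
boundary).  A cluster's *purity* is the fraction of its known labels equal
to the most frequent one, unknowns disregarded.  A cluster is a *highly
predictive cluster* (HPC) when its purity reaches the threshold (default
1.0, the strictest possible), its mean silhouette is non-negative
(negative-silhouette clusters are malformed), and it contains at least one
known label.  Every structure falling inside an HPC receives one vote for
the HPC's majority label; across all subsets a structure accumulates a
2-D vote vector bounded by $\binom{P}{3}$.  A linear-kernel SVM trained on
the labeled vote vectors supplies the decision boundary; unlabeled
structures are classified by hyperplane side, and per-sequence calls are
means over the sequence's structures.  Structures that never enter any
HPC carry no evidence and are excluded from metrics but reported as
`no-evidence`.

Confidence values are calibrated probabilities from a logistic (sigmoid)
fit of the training labels on the training decision values.  The original
formulation ranked predictions by p-values produced inside its SVM
library; the calibration machinery there is unspecified, so this package
uses the explicit sigmoid fit.  Only the *ranking* of confidences feeds
the enrichment factor, so any monotone calibration gives the same EF.

## Evaluation

Cross-validation groups sequences by single-linkage at 70% pairwise
identity (computed over the provided domain alignment as matches /
columns where neither sequence is gapped) and uses each group as one
fold.  Single linkage is exactly the closure guaranteeing that no test
sequence shares at-or-above-threshold identity with any training
sequence.  In each fold the test sequences' labels are masked to unknown
*before* HPC selection, so no test label can touch any purity value; the
suite asserts this by flipping a held-out sequence's label and checking
its own fold's prediction is unchanged.  Metrics are pooled across folds
(fold sizes are non-uniform, so micro-averaging is the stable choice):
ROC AUC via the rank (Mann-Whitney) formula with tie averaging, PR AUC by
trapezoidal integration, and the enrichment factor of the top 5% of
confidence-ranked predictions, with a ceiling top bucket so the bucket is
never empty and an `ef_max` for the perfect ranking.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `w_struct`, `w_pharm` | 1, 1 | - | unweighted sum; original weights unrecoverable |
| `variance_target` | 0.90 | fraction | embedding keeps most structure, drops redundancy |
| `d_max` | 10 | dims | caps mixture dimensionality |
| `k_max` | 25 | clusters | generous ceiling; BIC picks far fewer on conserved subsets |
| `purity_threshold` | 1.0 | fraction | strictest selection; only unanimously labeled clusters vote |
| `min_mean_silhouette` | 0.0 | - | removes malformed (negative) clusters, retains zero |
| `C` | 1.0 | - | SVM regularisation; vote space is low-dimensional and well separated |
| `identity_threshold` | 0.70 | fraction | non-redundant fold construction |
| Kd threshold | 10000 | nM | 10 uM, the largest Kd treated as meaningful binding; boundary maps to true |
| `max_gap_fraction` | 0.5 | fraction | definition of a "highly gapped" alignment column |

## Numerical choices

- **Superposition.** Closed-form SVD solution on the 3-point centroid
  sets; the determinant sign guard restricts to proper rotations.  Note
  that three points are always coplanar, so a mirrored triad is reachable
  by a proper rotation; the guard matters for degenerate cases.  Glycine
  contributes its CA as centroid; residues with no side-chain heavy atoms
  and no CA are malformed.  Unresolved side chains at selected columns
  are treated as gaps and the structure is excluded - the conservative
  reading of the gap filter.  Alternate conformers resolve to the
  highest-occupancy copy.
- **Embedding determinism.** Principal-component signs follow a canonical
  convention (largest-magnitude loading positive), making runs
  byte-identical.  Rows are weighted by 1/(structures per sequence) in
  the fit, so heavily crystallised sequences do not dominate the
  components; the same correction appears in purity counting, where each
  sequence contributes one vote regardless of structure count
  (structure-level counting is available via `weight = "structure"`).
- **Mixture fitting.** mclust performs the EM fits with its deterministic
  model-based hierarchical initialisation - replacing random restarts
  with a reproducible initialiser.  Covariance families cover spherical,
  diagonal and full shapes (EII, VII, VVI, VVV; E/V in one dimension).
  EII is included specifically because an equal-variance spherical
  component is the only family that can represent a singleton cluster
  (an outlier conformation) without a degenerate covariance.  The K grid
  (1..25, capped at N-1) is explored in blocks with early stopping once a
  whole block fails to improve the best BIC; BIC ties resolve to the
  smaller K, then the simpler family (parsimony and determinism).
- **Silhouettes.** Standard definition in embedding space; singleton
  clusters and single-cluster partitions score 0 by convention.  The
  implementation is checked against `cluster::silhouette()`.
- **Ties.** Purity ties pick the label ordered first (false before true),
  so a 50/50 cluster can never become a true-HPC; decision values exactly
  on the hyperplane, and zero sequence-level means, resolve to false -
  the conservative call for a binding claim.
- **Determinism contract.** Every per-subset fit derives its seed from
  the master seed and the subset's column tuple, so the clustering pass
  is reproducible regardless of how the subset loop is partitioned.
- **Fold re-scoring.** Because clusterings are label-free, folds and
  permutation nulls re-score the same membership tables; a flattened
  integer-index engine (`vote_engine()`) makes each re-scoring a few
  `tabulate()` passes and is asserted identical to the reference
  `select_hpcs()` + `tally_votes()` path.

## The synthetic generator

`synth_generate()` emulates the statistical structure the method assumes,
not protein physics: several structures per sequence with skewed counts
(1 + geometric, mean 2, mimicking the uneven crystallographic coverage of
real kinases), a shared background geometry with per-structure jitter
(0.5 A) and uniform background residue types per sequence, and a small
number of *signal* subsets where each class (true/false binders) adopts
one of several geometric/residue archetypes.  Archetype constellations
are sampled near the column anchors within a +/-5 A box under a minimum
mutual lRMSD margin of max(5 x noise sd, 2 A), capped at 3.5 A - the
largest margin reliably attainable inside the box; beyond that cap, rising
noise genuinely swamps the planted separation, which is what the
noise-degradation property tests.  Families are assigned round-robin so
archetypes span families and cross-family counting is exercised.
Configurable fractions of labels are masked to unknown or flipped.

The study-scale defaults are 60 sequences, P = 27 positions, two signal
subsets with two archetypes per class, and 0.1 A signal jitter, with half
the sequences true binders and a quarter unlabeled.  At these sizes one
full pass over the 2925 subsets plus cross-validation completes in
minutes on a single core, which is the problem size the acceptance
checks run at.  What passing these checks shows is that the pipeline
recovers planted, well-separated substructure signal and collapses to
chance under label permutation; it does not show robustness to the things
real data add - correlated backbone motion, alignment errors, assay
noise, and archetypes that are not well-separated Gaussians.

## Known limitations

- Labels are flat binary (plus unknown) per compound; hierarchical label
  schemes are out of scope, and no information is shared across
  compounds by design.
- The pharmacophore matrix is a feature-count default, not a transcription
  of any published matrix; results depending on fine chemical distinctions
  should supply their own matrix.
- The identity-fold construction needs an alignment covering the domain;
  with highly divergent synthetic sequences every sequence becomes its own
  fold, which is the leave-one-sequence-out limit of the scheme.
- Very small datasets (N around 10) make BIC conservative about
  singleton components; the equal-variance spherical family mitigates but
  does not eliminate under-segmentation.
- With highly divergent sequences the identity folds degenerate to
  leave-one-sequence-out, and pooled held-out scores then carry the
  well-known pessimistic bias of leave-one-out evaluation under label
  permutation: each fold's training set is slightly depleted in the
  held-out sequence's permuted class, so permutation-null ROC AUCs tend
  to sit somewhat below 0.5 rather than on it.  Recovery AUCs on planted
  signal are unaffected (the signal dwarfs the bias); interpret
  permutation nulls with this in mind.
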