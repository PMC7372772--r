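---
title: "Methods: drug–cluster association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug–cluster association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcanet)
```

This vignette documents the model implemented by `dcanet`, the assumptions
behind each stage, the numerical conventions that make results reproducible,
and the design decisions that were genuinely open. It is the package's own
account; nothing here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

Drug binding to a DNA-binding protein is treated as a local event at the
binding site. The unit of local information is the amino-acid **trimer**: a
window of three consecutive residues of the assembled site sequence, with a
central (major) residue and two flanking (subordinate) residues whose
left/right order carries no information. Trimers of similar physicochemical
character are pooled into clusters, and the observable is the bipartite
**drug–cluster association** graph: drug and cluster are linked when some
complex of that drug shows a site trimer of that cluster. Prediction is pure
link prediction on this graph — no chemical features of the drugs are used —
with bipartite-adapted common-neighbours (CN′), Jaccard (JA′) and
preferential-attachment (PA) indices. Since a drug's neighbors are clusters
while a cluster's neighbors are drugs, the classical one-hop indices are
degenerate; the cluster side is therefore widened to its two-hop
neighborhood Γ̂(y), the set of clusters co-occurring with y through at least
one shared drug. Γ̂ uses **set semantics** (each co-occurring cluster counts
once); a multiset variant weighting by the number of shared drugs is
available through `score_all(..., gamma_hat = "multiset")` for sensitivity
analysis but is not the default, because the definition of the neighborhood
is a *set* of clusters.

## Assembling sites and trimers

Binding-site residues are usually discontinuous in sequence. They are
concatenated in residue-number order — the only reproducible order available
without structures; spatial ordering is out of scope. Sites shorter than
three residues cannot yield a window and are rejected (or skipped with a
count, in the network builder): padding would fabricate residues.
Nonstandard residue codes are rejected rather than imputed, since the
property table covers exactly the 20 standard amino acids.

Trimer identity is the **canonical key**: the window rewritten with its
flanks sorted (`NGM` and `MGN` → `MGN`). This matches the flank symmetry of
the trimer vector below — two windows that embed identically must not appear
as two distinct cluster members — and makes canonicalization idempotent. Raw
windows are retained for provenance.

## Embedding

The property table is a 20 × P matrix (default P = 237). Columns are
standardized to zero mean and unit variance over the 20 amino acids before
PCA because the descriptors mix units (Å³, kcal/mol, dimensionless indices);
without standardization the leading components would simply track the
largest-unit properties. Zero-variance columns are dropped first (their
indices are recorded in the model) to avoid division by zero.

The covariance of the standardized columns is eigen-decomposed and the top
five eigenpairs kept. Coordinates follow the **score convention**: an amino
acid's vector is the projection of its standardized row onto the unit
eigenvectors, so the variance of component *i* across the 20 amino acids
equals λᵢ and the full score matrix factors as (√λ₁E₁, …, √λ₅E₅). Two
numerical conventions pin the result down across linear-algebra backends:
eigenvalues are sorted descending, and each axis's sign is chosen so its
largest-magnitude loading is positive. The trimer vector is
`X(center) + (X(flank₁) + X(flank₂))/4`, symmetric in the flanks by
construction; the quarter weight keeps the central residue dominant.

Internal-consistency checks (component variances equal eigenvalues, trace
conservation, distance contraction under projection, invariance to column
permutation) are the verifiable contract of this stage; whether any given
published coordinate set standardized first is generally not stated, so the
package asserts its own convention rather than third-party coordinates.

## Clustering

Distinct trimer vectors are clustered agglomeratively with Euclidean
distance and the tree is cut at exactly *k* clusters; *k* defaults to the
number of distinct drugs in the data (97 at the reference scale), recomputed
from the input rather than hard-coded. **Average linkage** is the default:
the description of iteratively merging nearest trimers leaves the linkage
open, single linkage chains badly in a continuous 5-d space, and the
interpretation of clusters as compact chemical "groups" argues for an
averaging criterion. Single, complete and Ward linkage remain available.

Determinism: trimers are sorted by canonical key before the distance matrix
is built, so the partition is independent of input order; exact distance
ties are measure-zero for continuous embeddings, and the key ordering
resolves the residual ambiguity in practice. Cluster indices are 1-based (R
convention) and assigned by decreasing cluster size with ties broken by the
smallest member key. Centroids are member means; unseen trimers (e.g. an
independent test set of complexes) are assigned to the nearest centroid,
ties to the lowest index. The package does not claim to reproduce any
specific published partition, whose linkage is unstated; the test suite
instead checks agreement with an independently coded cubic-time
agglomeration oracle and the nesting of successive cuts.

## Network and prediction conventions

Edges are binary — multiplicity of supporting trimers lives in the evidence
table, not in the adjacency — and drugs appearing in several complexes pool
their evidence. Empty clusters are retained with degree zero so the n × m
shape is stable across cross-validation folds. Known edges are scored like
any other pair (they are only masked during evaluation), and y is not
excluded from Γ̂(y).

Significance thresholding is configuration, not estimation: an absolute
cutoff on the score, with the *important* subset either an absolute cutoff
or the top fraction (default 20%) of the significant set, using
`ceiling(fraction × n)` and including boundary ties so the rule is
deterministic. Published instances of such cutoffs (e.g. "average standard
error" values) are dataset-specific and not reproducibly defined, so the
package additionally offers `significance_cutoff_se()`: remove each of 10
edge folds in turn, rescore all pairs, and take the mean per-pair standard
deviation of the resulting scores as an automatic cutoff — an estimate of
how much a score moves under resampling of the observed edges.

Prediction expansion walks the evidence: a significant (drug, cluster) pair
yields every member trimer of the cluster seen at any site, and every
protein carrying such a trimer; novelty flags mark pairs not already
supported by a known complex. Evidence-free synthetic networks are rejected
here by design.

## Evaluation

Ten-fold cross-validation partitions the known edges with **floor-division
fold sizing**: every test fold has exactly `floor(n/10)` edges and the
remainder (`n mod 10`) stays in all training sets — the only convention
consistent with 217-edge folds from 2174 edges. Test-positive edges are
removed from the adjacency before scoring; leaving them in would let CN see
the answer through Γ(x). Negatives are sampled uniformly without replacement
from non-edges, one per positive by default.

Curves sweep the threshold over the distinct observed scores, calling a pair
positive when its score is ≥ the threshold; tied scores share a single
threshold step, which makes the trapezoidal ROC area identical to the
rank-statistic AUC with ties counted one half (an identity the suite checks
to 1e-10). Scalar F1/sensitivity/specificity need a threshold convention
that reports at the per-fold max-F1 threshold (ties to the more conservative,
higher threshold) and the full curves are serialized so any other convention
can be recovered. Metrics with zero denominators are reported `NA`, never 0.

The benchmark baseline repeats the evaluation with deliberately invalid
interactions: each of (by default) 100 repetitions replaces the test
positives with an equal-size uniform sample of non-edges, keeps the matched
negative sampling disjoint from those fake positives, and evaluates
identically; the baseline curve is the vertical average of ROC curves on a
0.01-spaced FPR grid. Because fake positives are non-edges, the network is
unchanged and the score matrix is computed once per network. A
degree-preserving variant (fake positives drawn proportional to k_x·k_y) is
available behind a flag. Adjusted metrics subtract the baseline per metric.
All stochastic steps derive from a single seed via one RNG stream, so every
report is bit-reproducible from (configuration, seed).

## The synthetic-data generator

The generator emulates the reference dataset's scale — 97 drugs, 110
complexes, sites of 20–40 residues, a 20 × 237 property table — with a
planted, recoverable signal. Property tables have rank-5 latent structure
(5 factors × random loadings) plus 10% relative Gaussian noise, so reduction
to five components is meaningful and, at zero noise, exact. Complexes follow
a latent-group model: drugs belong to one of 8 groups, each group owns 5
trimer motifs (built from a group consensus with 50% residue retention), and
a site is assembled by appending a group motif with probability 0.9 or three
random residues with probability 0.1 until the drawn length is reached.

The unstated signal parameters (group count, motifs per group, similarity,
noise) were fixed once by a design-time power simulation over a parameter
grid. The deciding observation: at realistic densities the two-hop
neighborhood Γ̂(y) of a cluster saturates — it reaches most of the 97
clusters — unless each group's cluster signature stays compact, because
every noise edge of every adjacent drug inflates it. Small motif pools and a
low noise fraction keep signatures compact, which is what makes held-out
edges recoverable at all; with those defaults the end-to-end pipeline
recovers held-out drug–cluster edges with cross-validated CN AUC above 0.7
and exceeds its own randomized baseline by more than 0.15 (the recovery
property asserted in the acceptance tests).

What the generator does *not* emulate: real amino-acid property
correlations beyond low-rank structure; the heavier-tailed trimer multiplicity
and degree distributions of curated data (the synthetic network is sparser,
density ≈ 0.15 versus ≈ 0.23, with fewer drugs in the 15–30 degree band);
binding-site spatial geometry; and any chemistry of the drugs themselves.
Passing the recovery tests therefore demonstrates that the pipeline's
machinery — embedding, clustering, network assembly, indices, evaluation —
transmits a planted co-occurrence signal faithfully; it does not certify
performance on real structure-derived datasets (e.g. binding sites curated
from scPDB), where results depend on the curation and clustering conventions
used to build the tables.

## Problem sizes and runtime

The test suite runs the full pipeline at the reference scale (97 drugs, 110
complexes, ~1500 distinct trimers, 97 clusters) in a few seconds; oracle
comparisons use up to 200 random graphs of at most 15 × 15 and a cubic
agglomeration oracle at n = 30, sizes chosen so every oracle remains
obviously correct by inspection. The acceptance script's benchmark (97 × 97
network, 100 repetitions) completes in seconds because the score matrix is
shared across repetitions.

## Known limitations

* The clustering reproduces a *convention*, not a published partition;
  different linkage choices give different cluster systems and hence
  different networks.
* Significance cutoffs are configuration; no null distribution is claimed
  for them.
* The model ignores drug chemistry entirely — two drugs with identical
  cluster neighborhoods are indistinguishable.
* Binding sites are consumed as pre-extracted sequences; no structure
  parsing or pocket detection is attempted.
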