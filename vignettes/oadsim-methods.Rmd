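---
title: "Methods: ontology-aware disease similarity and network analysis"
author: "oadsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-aware disease similarity and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oadsim)
```

This vignette documents the models and procedures implemented in `oadsim`,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the methodology left room.

## Classification repository

Disease classification systems disagree both on which diseases are AIIDs and
on the autoimmune (AD) vs autoinflammatory (AID) polarity.  `computeACS()`
counts +1 per source labeling a disease AD and −1 per AID label; diseases
labeled both ways anywhere are *contested* (CA) and excluded from the AD/AID
tallies.  `computeACSNorm()` is the confidence-weighted mean
$\mathrm{ACS}_{norm} = \sum_i w_i s_i / \sum_i w_i$ with
$s_i \in \{+1, 0, -1\}$ and default weights Mondo 1.0, DO 0.8, MeSH 0.7,
ICD 0.7, expert lists 1.0, and the specialized knowledge bases (AA, ARI,
GAI) 1.0 — higher weight encodes broader coverage, maintenance and community
endorsement.  Two points were genuinely open:

* **Denominator membership.**  Whether a source that covers a disease
  without labeling it should dilute the score is not determined by the
  formula alone.  We let such sources contribute $s_i = 0$ *only* when
  explicitly passed via `covered`; by default only labeling sources enter.
  Both behaviors are exact special cases of the formula.
* **Same-source double labels** contribute net zero and mark the disease CA
  regardless of its score, since the contradiction is internal to a source.

Diseases never labeled AD/AID but carrying the HPO autoimmunity phenotype
(HP:0002960) become *AIID-associated* (AA).  Matching diseases across
sources by name is out of scope: inputs must share one id namespace, because
string matching of disease names is a curation task, not an algorithm.

## Wang similarity on ontology DAGs

`loadOntology()` parses OBO 1.2/1.4 `[Term]` stanzas into a validated DAG
(acyclicity checked by topological sort; the error names a cycle member).
Obsolete terms are dropped with a logged count; annotations to them are
remapped through `replaced_by` when available (`remapTerms()`), else
discarded.  Term ids are compared case-sensitively as exact strings.

For a term $t$, the S-value of ancestor $a$ is the maximal product of edge
contribution factors along any path from $t$ up to $a$, with
$S_t(t) = 1$; factors default to 0.8 (`is_a`) and 0.6 (`part_of`), the
standard constants of the method.  Similarity is

$$\mathrm{sim}(t_1, t_2) =
\frac{\sum_{a \in A_1 \cap A_2} S_{t_1}(a) + S_{t_2}(a)}
     {SV(t_1) + SV(t_2)},$$

where $SV$ is a term's summed S-values.  The implementation propagates
S-values by queue relaxation (monotone because factors are < 1, so it
terminates on any DAG) and caches per-term S-value vectors when building
matrices.  Consequences worth knowing: similarity is symmetric, equals 1
exactly on the diagonal, decreases monotonically toward the root along a
chain, and is strictly positive for any two terms of a single-rooted
ontology (they share at least the root).

We apply the same machinery to all three ontologies, including the Cell
Ontology, as the cell-ontology similarity literature does not pin down a
distinct algorithm; this is a stated proxy.

## FunSimAvg disease similarity

`funSimAvg()` aggregates a term-similarity matrix over two diseases' term
sets as the symmetric best-match average.  The weighted variant (used for
transcriptomic and cellular profiles) makes two changes: each term-pair
similarity is multiplied by a coupling $g(w_t, w_u) = \sqrt{w_t w_u}$
(arithmetic mean available via `coupling = "arithmetic"`), and the outer
means become weight-weighted means.  Weights are min-max rescaled to
$[0, 1]$ within each disease beforehand, so that

* uniform weights reduce the weighted score *exactly* to the unweighted one
  (tested to $10^{-12}$),
* rescaling one disease's weights (e.g. halving them) changes nothing,
* the weakest term of a disease (weight 0 after rescaling) drops out.

The exact weighting formula was an open design point; geometric coupling was
chosen because it is symmetric, bounded by the weaker weight, and reduces to
1 at uniform weights.  dC weights may be negative Z-scores; we use $|Z|$
min-max rescaled per disease (`normalizeDcWeights()`), reading dC as
dysregulation *magnitude*, not direction.

The top-20-terms rule applies to transcriptomic profiles only (it belongs to
the dysregulated-gene pipeline); genetic and phenotypic profiles keep all
mapped terms.  Ties at the top-k boundary break by lexicographic term id for
determinism.  `pairwiseOADS()` computes whole matrices in compiled code;
`funSimAvg()` is the pure-R reference, and the suite asserts elementwise
equality between the two routes.

## Permutation significance

`shuffleAnnotations()` permutes the pooled (term, weight) slots across
diseases: every disease keeps its term count, the global term multiset is
conserved, and weights travel with their slots — an exact bipartite
permutation, the strictest reading of "preserving term counts and
distributions".  All disease pairs are scored on the same shuffled datasets
(one shared stream per modality), which matches recomputing whole matrices
and is hundreds of times cheaper than per-pair shuffles.  P-values use the
add-one estimator $p = (1 + \#\{null \ge obs\}) / (1 + B)$ so that $p = 0$
is impossible at finite $B$; the default $B = 500$.  Under an exchangeable
synthetic null the p-values are approximately uniform (KS statistic < 0.1)
and the type-I error at nominal 0.05 sits within binomial tolerance
[0.03, 0.07]; the suite checks this at 21 diseases (210 pairs, 200
permutations) and 46 diseases (1035 pairs).

## Networks, topology, WiND

`buildNetwork()` keeps pairs whose similarity is *strictly above* the given
percentile (default 90) of all off-diagonal upper-triangle scores and whose
p-value is below `alpha` (default 0.05); isolated diseases are dropped but
recorded.  The percentile uses R's default quantile definition (type 7).

`topologySummary()` reports node/edge counts, average degree, density,
global transitivity, the maximal k-core (both k and its size are stored,
though summaries usually print one number), average local clustering,
average shortest path length, diameter, component count, and per-node
degree/betweenness/closeness/eigenvector centralities.  Distances are hop
counts.  One definitional choice matters on disconnected graphs: WiND over
all nodes must equal the average shortest path length (that identity is how
whole-network WiND is defined), so the average path length is computed over
*all connected node pairs* of the graph rather than only the largest
component; the diameter stays on the largest component.

`wind()` averages shortest-path lengths (measured in the full network) over
a member set's connected pairs; disconnected pairs are excluded from sum
and count rather than treated as infinite.  Because how "pair count" is
reported varies between connected pairs and direct links, both are
returned (`pairCount`, `directLinkCount`).  `windRatio()` divides a
category's WiND by the network's; values below 1 mean the category is more
tightly connected than average.

### Power-law diagnosis

`powerlawClassify()` fits a discrete power law by the Clauset recipe
(`xmin` by KS minimization, exponent by maximum likelihood, via igraph's
plfit) and compares it on the tail against a discrete exponential
(closed-form MLE) and a discretised lognormal (numerical MLE) with a Vuong
normalized likelihood-ratio test.  A degree sequence is called
`random-like` when an alternative wins at p < 0.1, **or** when the fitted
exponent exceeds 3.5: on homogeneous (Poisson-like) degree sequences the
`xmin` search retreats to a short, steep tail where a truncated power law
with an implausibly large exponent mimics exponential decay and the LR test
cannot decide; an exponent far outside the empirical scale-free range is
itself evidence against scale-freeness.  The suite verifies exponent
recovery (α ∈ [2.3, 2.7] on 2000 draws at α = 2.5) and regime calls on
preferential-attachment vs Erdős–Rényi graphs.  The Hurwitz zeta
normalizer is computed by Euler–Maclaurin summation.

## Communities and consensus

`wardClusters()` runs Ward agglomeration (ward.D2) on distance
1 − similarity; the matrix is internally row-sorted by disease id so the
induced partition is invariant to input row order.  `leidenClusters()`
optimizes modularity at the given resolution (default 1.0) with a recorded
seed.  The number of HC clusters is chosen to match the Leiden community
count of the same modality by default (`runPipeline()` does this), since no
principled cut rule is part of the method; it is overridable.

`robustCommunities()` links two diseases iff they share a cluster in
*every* partition and takes connected components of size ≥ 4.  This is the
strictest natural reading of "consistently clustered"; a relaxed
`agreeAtLeast` (any k of m partitions) is available.  Output is invariant
to partition order, and composition counts per community always sum to the
community size.  `featureEnrichment()` builds, per community and feature,
the 2×2 table against all other robust-community diseases, applies a
one-sided (greater) Fisher exact test — enrichment has a direction — and
adjusts per community with Benjamini–Hochberg (a global adjustment is a
one-line change on the output columns).

`adjustedRandIndex()` implements the pair-counting ARI (cross-checked in
the tests against an independent implementation), and
`kendallConsistency()` reports Kendall τ-b between disease-pair rankings
of different modalities.

## Integration

`snfFuse()` follows the standard similarity-network-fusion scheme: scaled
exponential kernels on distance 1 − similarity with per-pair bandwidth from
the K-nearest-neighbor mean distances (μ = 0.5), a row-stochastic full
kernel and a row-normalized KNN kernel per view, then t rounds of
cross-diffusion $P_v \leftarrow S_v \bar P_{-v} S_v^\top$ with identity
regularization, and a symmetrized mean as output (monotonically rescaled
into [0, 1]).  Defaults K = 10, t = 20.  The fusion is order-invariant and
preserves structure its inputs share; a practical caveat found while
validating: a *single* informative view paired with an equally weighted
structureless view is not reliably recovered by the published algorithm —
cross-diffusion lets the structureless view rescramble half the mass each
round — so the robustness test asserts the demonstrated regime (majority
informative views) and above-chance contrast retention for the 1 + 1 case.

`buildMST()` filters to significant pairs (same rule as the networks),
converts to distance 1 − similarity, and grows a Prim spanning tree per
connected component, with equal-weight edges resolved by lexicographic
disease-id pair so the tree is deterministic; a disconnected filter result
yields a spanning forest with a logged component count.  Only
filter-surviving pairs are candidate tree edges — the filter would be
pointless otherwise.  Optimality is cross-checked against an independent
Kruskal union-find oracle and igraph's MST.

## The synthetic-data generator

`genOntology()` creates single-rooted DAGs whose non-root terms attach to
1..`maxParents` earlier terms (acyclic by construction); with `nBranches`
set, the first terms become root-level branch heads and later terms attach
within an assigned branch, giving well-separated subtrees.
`genAnnotations()` assigns each planted community a term pool inside one
branch so that *Wang similarity*, not just raw overlap, separates
communities — the signal travels through the hierarchy exactly as in real
ontologies.  Per-term noise replaces a term with a uniform random one.

The default scenario — the reference study condition used by the test
suite — is 5 communities × 20 diseases, noise 0.05, with per-modality pool
breadth and overlap: genetic pools broad (30 terms) and mostly
community-specific (overlap 0.1, emulating sparse and uneven
genetic-association knowledge), phenotypic intermediate (18, 0.25), and
transcriptomic pools small (7) and fully shared (overlap 1.0) — emulating
dysregulated genes concentrating in common immune pathway modules, with
diseases differing mainly in dysregulation magnitude (half-normal dC
weights, Z-scored per disease).  By construction the mean similarity is
ordered transcriptomic > phenotypic > genetic, and the transcriptomic layer
is concentrated and community-poor while genetic and phenotypic layers
carry recoverable community structure — the qualitative layer differences
the method is designed around.  Cellular profiles are per-community
Dirichlet proportions over a fixed cell-type set.  Classification labels:
each disease gets a true polarity (AD with probability 0.8, matching the
preponderance of ADs in curated repositories); each of 7 sources labels
correctly with probability `sourceAgreement` (default 0.8), wrongly or not
at all with equal shares of the remainder.

What the generator does **not** emulate: real expression matrices and the
differential co-expression computation itself (dC values are consumed, not
computed), curation noise that is correlated across sources, ontology term
frequency biases (annotation hubs), and the extreme sparsity of real
genetic-association knowledge.  Passing tests therefore demonstrate
algorithmic correctness and end-to-end recoverability of planted structure,
not performance claims on real cohorts.

## Problem sizes and runtime choices

The suite exercises: Wang properties on 60–120-term ontologies and 1000
random term pairs; brute-force similarity equivalence at 10 diseases;
permutation calibration at 210 and 1035 pairs × 200 permutations;
WiND/topology identities on 50 random graphs; power-law recovery at
n = 2000 samples and 1000-node graphs; end-to-end community recovery on the
default 100-disease scenario with 100 permutations per modality; SNF at
20–30 diseases; MST cross-checks on 30 random instances.  These sizes keep
the full suite under a minute on one core while leaving every statistical
check well-powered.  The pipeline default of 500 permutations is the
study-scale setting; tests use 40–200 because the add-one estimator's
granularity (1/(B+1)) is the only thing that changes.

## Known limitations

* OBO parsing covers `[Term]` stanzas with `is_a`/`relationship` edges —
  not OWL, typedefs, or cross-ontology bridges.
* The Cell Ontology similarity is the same Wang machinery, a stated proxy.
* Empirical p-values from one shared permutation stream are dependent
  across pairs; calibration holds marginally, not jointly.
* WiND on disconnected member sets silently drops disconnected pairs; the
  pair count in the output makes this visible.
* The power-law call is a model comparison on the fitted tail, not a
  goodness-of-fit certificate; very small networks (< 10 positive degrees)
  are rejected.
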