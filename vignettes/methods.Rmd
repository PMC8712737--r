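---
title: "Methods: multiplex-heterogeneous pathway prioritization and ceRNA-SNP networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex-heterogeneous pathway prioritization and ceRNA-SNP networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhnpath)
```

## The model

`mhnpath` treats pathway relevance as network proximity. Four edge sets are
assembled into one node space: a weighted mRNA interaction layer, a
weighted miRNA functional-similarity layer, bipartite miRNA–mRNA couplings
from validated target interactions (treated as undirected: regulation is
evidence of functional association in both directions), and unit-weight
pathway-membership links. Nodes are registered in a deterministic order
(sorted mRNAs, sorted miRNAs, sorted pathway ids) so that every downstream
matrix is reproducible from the input tables alone.

The network becomes a single column-stochastic transition matrix. Out of a
molecule node, probability mass splits by *edge class*:

* `lambda` (default 0.2) to the node's pathway neighbors,
* `delta` (default 0.3) across the bipartite coupling,
* the remaining `1 - delta - lambda` within the node's own layer,

each share distributed proportionally to edge weight. Two boundary rules
complete the construction. First, when an edge class is absent at a node,
its share is renormalized over the classes that are present — a gene with
no known miRNA regulator should not leak probability. Second, a node with
no edges at all (a pathway whose members fall outside the gene layer, for
instance) receives a unit self-loop; this keeps the matrix exactly
stochastic without introducing global teleportation, which would blur
proximity for every node to fix a problem of a few. Normalization happens
once, over the full node set including pathway nodes. Columns are verified
to sum to 1 within 1e-12 at construction time and the build aborts
otherwise.

`delta` and `lambda` are genuine modeling dials: `delta` controls how much
miRNA evidence bleeds into gene proximity and vice versa, `lambda` how
strongly pathway nodes pull their members together. The defaults (0.3,
0.2) leave half the mass inside a node's own layer, which keeps layer
topology the dominant signal; both are exposed in `walk_params()` and the
pipeline configuration, and `delta + lambda < 1` is enforced. Edge weights
are consumed as-is — STRING-style and similarity scores are already on a
comparable confidence scale, and rescaling them would silently change the
walk.

By default pathway nodes link only to member mRNAs; miRNAs reach pathways
through their targets. An optional rule (`link_mirna_pathways`) adds
direct pathway–miRNA links for miRNAs targeting at least `k` members
(default `k = 3`), for users who want miRNA walkers to hit pathways in one
hop. It is off by default because it double-counts the coupling evidence.

## Random walk and embedding

The walk with restart iterates `p <- (1 - r) T p + r p0` to its fixed
point. The restart probability defaults to `r = 0.7`, the common choice in
biological-network walks: high enough that proximity stays local to the
seed, low enough that multi-hop structure matters. Numerically, systems up
to 2,000 nodes are solved exactly via the dense linear system
`(I - (1 - r) T) p = r p0`; larger systems use power iteration with an L1
stopping rule (`tol = 1e-10`, `max_iter = 10000`). Non-convergence is an
error, never a silently truncated result. The iterative and direct paths
are verified against each other to 1e-8 across random networks in the test
suite, and the two-node closed form `p_seed = 1/(2 - r)` pins down the
fixed-point algebra.

Stacking the walk from every seed gives the proximity matrix P (rows =
seeds, row sums 1 within 1e-8). P is factorized by truncated SVD; node i's
*source* vector is row i of `U_d sqrt(S_d)` and its *target* vector is row
i of `V_d sqrt(S_d)`. The square-root split balances the norms of the two
roles, so neither side of a cosine is dominated by the singular values.
Molecule-to-pathway relevance uses the molecule's source vector against
the pathway's target vector — the walk runs *from* molecules *toward*
pathways; a `symmetrize` option averages P with its transpose first for
role-free vectors. The factorization is applied to the raw proximity
matrix; a `log_transform` (log1p) option exists but is off by default,
since compressing the dynamic range also compresses exactly the
seed-locality the restart created. SVD signs are fixed deterministically
(largest-magnitude component of each left singular vector made positive)
so embeddings are identical across runs and platforms. The default
dimension is `min(128, n - 1)`; at full rank the factors reconstruct P to
1e-8 in Frobenius norm, which the tests assert.

## Scores, ranks and significance

The correlation score of a risk set is the arithmetic mean of its
molecules' cosines to the pathway (`max` and `sum` are available; the mean
is the default because it does not grow with catalog size). Pathway
collections from different source databases differ greatly in size, so raw
within-database ranks are not comparable. The ranking score

`ranking_score = -log2(rank_in_db / (N_db + 1))`

is this package's size-correcting convention: it is monotone in the rank,
roughly 0 at the bottom of any database, and a value of 6 always marks the
top 1/64 quantile (rank 1 of 63 scores exactly 6.0). Ties get competition
("min") ranks, so tied top scores share the maximal ranking score. One
structural consequence is worth stating plainly: a ranking score of `s`
requires a database of at least `2^s - 1` pathways, so the conventional
significance threshold of 6 is only attainable in collections of 63 or
more pathways per database; with small collections the threshold must be
chosen relative to `log2(N_db + 1)`.

Empirical p-values permute the *molecule set*: N random sets matching the
risk set's mRNA and miRNA counts are drawn from the network's molecule
nodes, rescored identically, and `p = (1 + b) / (1 + N)` with `b` the
number of null scores at least as large as the observed one. The add-one
correction keeps p strictly positive (floor `1/(1+N)`). Type-matched
uniform sampling is the default null; it asks "is this score surprising
for an arbitrary set of this composition?". Degree-matched nulls were
deliberately not made the default: they answer a different question and
require a binning choice that would itself be a tunable. Calibration is
tested: with random risk sets, the fraction of p-values at or below 0.05
stays within [0.02, 0.10] over 200 replicates.

The classical baseline is the one-sided hypergeometric tail
`P(X >= overlap)` on the membership overlap, cut at 0.05 — retained both
as a comparison method and as an exactly checkable computation (the tests
compare it against direct tail summation on small universes, including the
worked case 1126/15504).

## ceRNA regulations and regulatory SNPs

Within a significant pathway, a ceRNA regulation is a triple
lncRNA → miRNA → mRNA with both interaction edges evidenced, the mRNA a
pathway member, and all three molecules in the admitted risk catalog. By
default the catalog is restricted to the feature under analysis
(`feature_strict`); the permissive flag admits risk molecules of any
feature, reflecting that overlapping pathways genuinely mix features.

Three SNP location classes are *regulatory* — they sit where ceRNA binding
happens: the mRNA's 3'UTR, the mature miRNA's seed region, and the miRNA
binding site on the lncRNA. Attachment respects partners: a binding-site
SNP attaches only to regulations with its exact (lncRNA, miRNA) pair; a
seed SNP to every regulation through its miRNA; a 3'UTR SNP to regulations
targeting its mRNA, restricted to the named partner miRNA when one is
given (a partnerless record attaches to all of them — a deliberate
conservative superset, since absence of a partner annotation is not
evidence of irrelevance). SNPs in the lncRNA gene body or in pri-/pre-miRNA
are carried as host annotations and never counted as regulatory.

Per network, `snp_ratio` is the fraction of regulations carrying a
regulatory SNP and `snp_density` the number of regulatory SNPs per
SNP-carrying regulation. Density counts *distinct* rsIDs by default (an
rsID shared by several regulations counts once); attachment counting is
available by flag. With no SNP-carrying regulation the density is
undefined and reported `NA` with a warning rather than 0 — zero would
wrongly suggest a measured absence. Switch candidates are the regulations
with regulatory SNPs on *both* edges; positioning a target gene as
"upstream" in its pathway is a curation judgment, so the filter accepts an
optional user-supplied upstream-gene list rather than guessing topology.

## The synthetic generator

`generate_bundle()` emits every input table the pipeline reads, from one
seed (R's default Mersenne-Twister; the caller's RNG state is saved and
restored). It emulates: two Erdős–Rényi intra-layer networks with uniform
confidence weights in 0.3–1; uniform miRNA targeting; pathway gene sets
drawn over two synthetic source databases; a one-feature risk catalog; and
a classified SNP table filled per eligible edge at `snp_rate_per_edge`.
The planted signal is *topological*: the planted pathway's members are
densified into a module (within-module edge probability 0.8 against a 0.02
background) and module miRNAs each target several members; the risk
catalog draws fraction `f` (default 0.7) of its mRNAs from the module and
of its miRNAs from the module-targeting miRNAs. Planting by weight
inflation was rejected — it would let recovery tests pass by reading
weights rather than walking topology.

Default sizes — 200 mRNAs, 50 miRNAs, 10 lncRNAs, 20 pathways of 10–25
members, a risk catalog of 25 mRNAs / 8 miRNAs / 4 lncRNAs — scale the
shape of a curated disease catalog (a few hundred genes, tens of miRNAs, a
handful of lncRNAs) down to sizes where exact dense linear algebra is the
reference path; the test suite and acceptance script use these, with
smaller variants (60–100 mRNAs) where a check needs hundreds of
replicates. `expected_stats()` recounts triples and SNP attachments by
plain nested loops over the emitted tables, providing an oracle that
shares no code with the network builders.

What the generator does *not* emulate: scale-free degree distributions,
realistic STRING/MISIM weight distributions, multi-feature catalogs with
correlated overlaps, or identifier noise. Passing recovery tests therefore
demonstrates that the algorithm finds planted topological signal at
realistic sparsity — not that it ranks real curated catalogs the way the
original study's curated inputs would.

## Degenerate inputs and tie-breaks

Self-edges are dropped at read time with a warning; duplicate undirected
edges merge keeping the maximum weight (confidence semantics). Coupling
edges with unregistered endpoints are dropped and counted. A pathway with
no linkable members stays in the node set with a self-loop, so its scores
are defined (and poor) rather than missing. Zero-norm vectors get cosine 0
with a warning. Ranking ties share the minimum rank. The significance
filter is inclusive at both thresholds. All sorting uses explicit keys
(feature, then empirical p ascending, then ranking score descending) so
output tables are stable across platforms.

## Known limitations

No multiplicity correction is applied beyond the two thresholds (ranking
score and empirical p); with many features and databases users should
consider an FDR layer on the empirical p-values. Identifier mapping is out
of scope — inputs must share one namespace. The commixture construction
and the ranking-score transform are this package's own conventions for
widely used but under-specified practice; both are isolated behind
`walk_params()` and `rank_and_score()` so alternatives are one edit away.
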