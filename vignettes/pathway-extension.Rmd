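---
title: "Extending pathway gene sets on an interaction network: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending pathway gene sets on an interaction network: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathextend)
options(pathextend.verbose = FALSE)
```

## The problem

Pathway databases assign proteins to processes one at a time, based on
heterogeneous experiments and a curator's judgement of importance. As a
result, canonical gene sets miss many closely associated regulators and
effectors that large-scale interaction screens clearly tie to the pathway
core. `pathextend` treats a curated gene set as a *seed* inside a
protein–protein interaction network and asks: which neighbouring proteins
are so densely interconnected with the seed that the set is more coherent
with them than without?

The answer has two stages — a local filter and a global greedy criterion —
and everything downstream of it (topological profiling, cross-validation,
semantic-similarity and enrichment comparisons) exists to check whether the
added proteins behave like genuine pathway members.

## The model and its assumptions

The network is an undirected simple graph over opaque protein identifiers.
We assume the user supplies a pre-harmonised edge list: no identifier
translation is attempted, and self-loops and duplicate pairs are dropped at
load time (a protein is not its own binary interaction partner for the edge
counts below). Edges are unweighted; confidence scores, directions and
interaction types are outside the model.

### Stage 1: the candidate filter

Candidates are the direct neighbours of the mapped seed members. A
candidate $v$ for pathway $p$ must satisfy condition (1) and at least one
of (2)–(4):

$$\mathrm{(1)}\; \deg(v) > 1 \qquad
\mathrm{(2)}\; \frac{\mathrm{process\_links}(v,p)}{\mathrm{outside\_links}(v,p)} > T_1 \qquad
\mathrm{(3)}\; \frac{\mathrm{triangle\_links}(v,p)}{\mathrm{possible\_triangles}(v,p)} > T_2 \qquad
\mathrm{(4)}\; \frac{\mathrm{process\_links}(v,p)}{\mathrm{process\_nodes}(p)} > T_3$$

With $T_1 = 1$, condition (2) is the classical *strong community* criterion:
the candidate has more links into the pathway than into the rest of the
network. Condition (3) rewards candidates embedded in triangles with a
member and another candidate; condition (4) rewards candidates linked to a
substantial fraction of the members, and its threshold must stay below 1
because full coverage is the maximum.

Three points in these definitions were genuinely open and are fixed as
follows:

* **possible_triangles** counts the pairs (in-set neighbour of $v$) ×
  (candidate neighbour of $v$), i.e. the triangles that *would* close if
  the member–candidate edge existed. Under this reading the condition-(3)
  ratio is a well-defined fraction in $[0,1]$.
* **All inequalities are strict.** A candidate with 2 links in and 2 out
  fails condition (2); a candidate with no outside links and at least one
  process link passes it (the ratio is $+\infty$).
* **process_nodes(p)** is the number of *mapped* members — members absent
  from the network cannot be linked to and are excluded from the
  denominator of condition (4).

The filter is evaluated once, against the original mapped set; the
candidate pool is not re-expanded with neighbours of added proteins. This
preserves the two-stage structure (filter, then compactness) and keeps the
extension anchored to the curated definition rather than drifting along the
network.

### Stage 2: greedy compactness

The compactness score of a set $P$ is the mean shortest-path length over
all unordered member pairs, measured in the *full* network:

$$\mathrm{compact\_score}(P) = \frac{\sum_{i<j} d(P_i, P_j)}{|P|(|P|-1)/2}$$

Full-network distances matter: a candidate can shorten paths between seed
members precisely because routes may pass through non-members, and a
candidate that connects two disconnected parts of a pathway should be
creditable for it. For the same reason an unreachable pair contributes a
penalty equal to the number of network nodes $|V|$ (mode `node_count`,
the default): any candidate that joins two components then strictly lowers
the score. A fixed penalty constant is available (`penalty_mode = "fixed"`)
when comparisons across networks of different sizes are needed.

Admitted candidates are added greedily — the candidate producing the lowest
new score first — and only while the score strictly decreases. Ties are
broken towards the lexicographically smallest identifier, making the
algorithm fully deterministic. A candidate that leaves the score unchanged
is not added.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t1` | 1.0 | strong-community ratio threshold (condition 2), dimensionless |
| `t2` | 0.1 | triangle-density threshold (condition 3), fraction in (0,1) |
| `t3` | 0.3 | coverage threshold (condition 4), fraction in (0,1) |
| `min_set_size` | 10 | minimum *original* membership for a set to be examined |
| `penalty_mode` | `node_count` | unreachable-pair distance in the score |

The threshold defaults trade off how many sets get extended against how
large extensions grow; they are the method's standard operating point, and
raising any of them makes the filter stricter. `min_set_size` applies to
the pre-mapping membership; independently, at least two *mapped* members
are required, since the compactness score needs a pair.

## The validation apparatus

**Topological profiling.** Five descriptors (degree, local clustering
coefficient, raw betweenness, eigenvector centrality, within-set shortest
path) are averaged over a node set and compared against size-matched
uniform random sets. Betweenness is unnormalised with endpoints excluded —
only comparisons between sets on the same network are meaningful, and any
affine normalisation would rescale both sides. The within-set shortest-path
mean skips unreachable pairs: as a *descriptive* statistic it should not be
dominated by the penalty constant that the *optimisation* score needs
(deliberately different conventions).

**Cross-validation.** Per pathway, 10% of members (among those connected to
at least one other member; eligibility recomputed after every removal,
quota $\lceil 0.1\,n \rceil$) are deleted, the reduced set is extended, and
the number of recovered deleted members is compared with 100 random draws
of the same size from the reduced set's candidate pool. The pooled
empirical p-value is the fraction of pathway × draw cases in which the
random draw recovered strictly *more* — ties favour the method, and the raw
relative frequency is reported without a pseudo-count, so a zero means
"never exceeded at resolution $1/(n_{\mathrm{sets}} \cdot n_{\mathrm{random}})$".

**Semantic similarity.** Added proteins are compared with the original
members through Jiang–Conrath distance,
$d(t_1,t_2) = \mathrm{IC}(t_1) + \mathrm{IC}(t_2) - 2\,\mathrm{IC}(\mathrm{MICA})$,
with $\mathrm{IC}(t) = -\ln p(t)$ estimated from the annotation corpus under
the standard ancestor closure. Two choices were open: distances are turned
into similarities by $s = 1/(1+d)$ (bounded, monotone, $s = 1$ iff $d = 0$),
and averaging runs over the *distinct term pairs* of the two sets, not over
protein pairs — duplicating an identically-annotated protein does not change
the value. The null model draws same-size protein sets from the pathway's
candidate pool excluding the extended membership.

**Enrichment.** One-tailed Fisher ORA (upper-tail hypergeometric) of a gene
list against each set, with Benjamini–Hochberg adjustment applied to the
original family and the extended family separately, so each set carries a
paired before/after q-value. The default universe is the set of network
proteins.

## What the synthetic generator emulates — and what it does not

`generate_planted_network()` draws a stochastic block model: 5 communities
of 20 proteins, 100 background proteins, within-community edge probability
0.3, between-community and background probability 0.01. The block model is
the natural ground truth here because the filter conditions are
community-style criteria. `emit_incomplete_gmt()` hides 10% of each
community, emulating incomplete curation; `generate_toy_ontology()` builds
a small rooted tree and annotates each community within one subtree, with
background proteins annotated uniformly at random (annotated but
unspecific, as a null should be); `generate_gene_list()` plants a
"mutated gene" list among the hidden members plus random background.

Real interactomes are not block models: they have heavy-tailed degree
distributions, hubs that join many pathways, study bias in edge coverage,
and pathways that overlap heavily. Passing tests on planted fixtures
therefore demonstrates *algorithmic correctness* (the implementation
computes the defined quantities, and the method recovers planted structure
far above a random baseline) — not that extensions on a specific real
network are biologically right. The defaults were chosen once to represent
a clearly detectable but non-trivial community structure and are not
adjusted per analysis.

## Numerical choices and degenerate inputs

* Shortest paths and all counts are integer-valued, so greedy score
  comparisons (integers divided by a fixed binomial coefficient) are exact
  in double precision; the strict-decrease test is not affected by
  floating-point noise.
* Eigenvector centrality is computed per connected component by power
  iteration on $A + I$: the shift leaves the principal eigenvector
  unchanged and prevents the period-2 oscillation that plain iteration
  exhibits on bipartite components. Scores are non-negative,
  Euclidean-normalised per component; tolerance $10^{-8}$, at most 1000
  iterations, with an error naming the component on non-convergence.
  An isolated node scores 1 (its component's unit vector).
* Local clustering is 0 for nodes of degree < 2; a gene set with no
  connected pair reports `NA` for its mean within-set distance.
* Deletion eligibility can empty out before the quota is met (e.g. a star
  loses its centre); the deletion then stops, and sets reduced below two
  members are skipped.
* Cross-validation and the semantic-similarity null derive per-set RNG
  seeds from the base seed and the set identifier, so reports are invariant
  under reordering of the input collection.
* In the discrete recovery-count setting, the self-null exceedance
  probability $P(X > Y)$ for iid draws is $(1 - P(X = Y))/2$, well below
  one half whenever ties are common — a property the test suite asserts in
  this form rather than in its continuous-case idealisation.

## Problem sizes used in the test suite

The suite validates the implementation against independent brute-force
oracles (explicit path enumeration via adjacency-matrix powers,
Floyd–Warshall, dense eigendecomposition, exhaustive filter and greedy
re-evaluation, hypergeometric tail summation, longhand step-up adjustment,
recursive ancestor enumeration) on hundreds of random graphs of up to 12
nodes, and runs the full pipeline on the default 200-node planted fixture —
sizes at which the oracles are exact and the whole suite completes in well
under a minute.

## Known limitations

* Unweighted, undirected binary interactions only; no confidence weighting.
* The filter is evaluated once against the original set; a protein that
  becomes strongly associated only *after* other additions is not
  reconsidered.
* Greedy optimisation of the compactness score is not globally optimal; the
  added list is an ordered heuristic, not a certified optimum.
* Identifier harmonisation across interaction databases is the user's
  responsibility.
* The Jiang–Conrath similarity uses the annotation corpus supplied; IC
  estimates from small corpora are coarse, and terms annotating no protein
  have undefined IC and are excluded.
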