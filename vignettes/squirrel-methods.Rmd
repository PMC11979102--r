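---
title: "Reconstructing semi-directed level-1 networks from tf-quarnets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing semi-directed level-1 networks from tf-quarnets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squirrel)
```

## The problem

Secondary contact and introgression produce evolutionary histories that are
trees with localized reticulations.  When the root location is not
identifiable from the data, the natural object is a *semi-directed level-1
network*: an unrooted network in which only the edges entering reticulation
vertices carry direction, every reticulation lies on exactly one cycle, and
cycles are vertex-disjoint.  This package reconstructs binary, triangle-free
networks of this kind from a *dense* set of weighted *tf-quarnets* — one
four-leaf network per 4-subset of the taxa, each either a quartet tree
`ab|cd` or a 4-cycle with a designated reticulation leaf, with a confidence
weight in $[0,1]$.  Dense tf-quarnet sets are known to encode triangle-free
level-1 networks uniquely, which is what makes the puzzling approach sound.

## The algorithm

Given a dense weighted tf-quarnet set $Q$ on $n$ taxa the driver
(`squirrel()`) proceeds in three stages.

**Candidate blobtrees** (`candidate_blobtrees()`).  The quartet-tree members
$Q'$ of $Q$ are condensed into the Q\*-tree $T^*$: the unique most refined
tree such that every 2+2 quartet induced by one of its splits occurs in $Q'$
with the matching split.  $T^*$ is then refined with an adaptation of
QuartetJoining: at every vertex of degree $\ge 4$, each pair of neighbour
components $\{X_i, X_j\}$ is scored by the mean $\omega$-value over splits
$x x' | y y'$ with $x \in X_i$, $x' \in X_j$ and $y, y'$ in two distinct
other components, where $\omega(ab|cd)$ is the weight of the quartet tree
`ab|cd` in $Q$ (0 if absent); the best pair is made siblings, and the process
repeats.  Each internal edge $uv$ of the refined tree $T_1$, inducing the
split $A|B$, is assigned the support
$$\mathrm{supp}(uv) = \frac{w(Q'(A|B))}{w(Q(A|B))},$$
the weighted fraction of the quarnets with two leaves on each side whose
quartet split agrees with $A|B$.  Contracting the $i-1$ least supported edges
of $T_1$ yields candidate blobtree $T_i$, for $i = 1, \dots, n-3$.

**Cycle expansion** (`expand_tree()`).  In each candidate, every internal
vertex $v$ of degree $s \ge 4$ (largest degree first) is replaced by an
$s$-cycle.  The branches around $v$ partition the taxa into $Y_1|\dots|Y_s$;
every input quarnet with one leaf in each of four distinct parts votes, after
relabeling leaves by their part, for one of the six skeletons on those four
parts (three quartet splits, three undirected 4-cycles).  The heaviest
skeleton becomes the representative tf-quarnet with weight
$w(t)/w(\text{multiset})$; a winning 4-cycle's reticulation leaf is the
modal reticulation among its voters.  Pairwise distances between parts are
then accumulated as
$$\tau_q(a,b) = \tfrac{1}{2}(3 - w(q)) \text{ (same side / neighbours)},
\qquad \tfrac{1}{2}(3 + w(q)) \text{ (otherwise)},$$
summed over the representative quarnets containing both leaves, and a
travelling-salesman tour on this matrix gives the cyclic ordering (these
distances form a Kalmanson metric when the quarnets come from one network,
which is why the optimal tour recovers the true ordering).  The reticulation
is placed at the first entry of the *reticulation ranking* — parts ordered by
the weighted count of representative 4-cycles in which they sit below the
reticulation — that leaves the partial network rootable (and rootable at the
outgroup if one was specified); iterating through the ranking guarantees
termination.

**Scoring.**  Every candidate network $N_i$ is scored by the weighted
tf-quarnet consistency
$$C'(Q, N_i) = \frac{w(Q \cap Q(N_i))}{w(Q)},$$
and the highest-scoring candidate is returned (first in candidate order on
ties, i.e. the most resolved blobtree).  The unweighted scores
$C = |Q(N) \cap Q(M)|/|Q(N)|$ and $S = |Q(N) \cap Q(M)|/|Q(N) \cup Q(M)|$
are available for comparing two networks.

With a dense unit-weight quarnet set induced by a triangle-free level-1
network, this procedure returns a network isomorphic to the original: the
blobtree equals $T^*$ and survives into the candidate sequence (true splits
have support 1, spurious refinements strictly less), the representative
quarnets are the induced quarnets of the blob, and the exact TSP tour
recovers each cycle's ordering.  The test suite checks this end to end on
200 random networks.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tsp_mode` | `"auto"` | exact Held–Karp up to 13 cycle leaves, simulated annealing above; `"exact"` forces optimality (needed for the combinatorial guarantee), `"anneal"` forces the heuristic |
| `seed` | none | drives every stochastic tie-break (skeleton votes, rankings, annealing); identical input + seed gives identical output |
| `lambda` | 0.3 | delta-heuristic treelikeness threshold: 4-subsets with $\delta \ge \lambda$ become quartet trees, the rest 4-cycles |
| `outgroup` | none | taxon whose pendant edge must be a valid root location of every candidate |
| `rank_mode` | `"ret"` | how "appears in a 4-cycle" is counted in the reticulation ranking (see below) |

Simulated annealing uses a 2-opt neighbourhood, geometric cooling with factor
0.995, $20 s^2$ iterations and the best of 3 restarts; the annealing
parameters are not prescribed by the method and were fixed once for
desk-scale determinism.

## The delta-heuristic

`infer_tf_quarnets()` turns an alignment into a dense weighted quarnet set.
Pairwise normalized Hamming distances are computed on the gap-free columns of
each pair (a hard error if a pair shares no such column; ambiguity codes
count as mismatches).  For each 4-subset, with the three pair-sum distances
relabeled $h_{ab|cd} \ge h_{ac|bd} \ge h_{ad|bc}$, the statistic
$$\delta = \frac{h_{ab|cd} - h_{ac|bd}}{h_{ab|cd} - h_{ad|bc}}$$
(0 when all three sums are equal) is thresholded at $\lambda = 0.3$:
$\delta \ge \lambda$ yields the quartet tree on the *largest*-sum split;
$\delta < \lambda$ yields the 4-cycle $(a, c, b, d)$, the arrangement whose
two reticulation-edge deletions produce the two smaller-sum splits.  Weights
are $|\delta - \lambda|/\lambda$ below the threshold and
$|\delta - \lambda|/(1 - \lambda)$ above it — piecewise linear, 0 exactly at
$\lambda$, 1 at $\delta \in \{0, 1\}$.  Each 4-cycle's reticulation leaf is
its member with the highest mean $\delta(x)$ over all 4-subsets containing
$x$.

Two caveats are worth stating plainly.  First, this convention is the
*opposite* of the classical delta-plot reading, where treelike data gives
$\delta$ near 0 (under the four-point condition the two largest pair sums
are nearly equal).  We implement the method as specified and do not "fix"
it; the package's own simulations confirm that on Kimura-2-parameter data
most treelike 4-subsets receive small $\delta$ and are classified as
4-cycles, so sequence-level consistency scores are modest.  The heuristic is
not statistically consistent and should be treated as a fast exploratory
companion to the combinatorial pipeline, not as a model-based inference.
Second, $\delta$ is computed from overall pairwise distances, so it cannot
separate within-subset signal from rate heterogeneity.

## Synthetic data

`random_network(n)` grows a random rooted binary tree by sequential random
leaf insertion, draws $r$ uniformly from $\{0, \dots, \lfloor n/3 \rfloor\}$
and adds $r$ reticulations by subdividing two random edges and joining them,
rejecting joins that would create a directed cycle, intersecting cycles, a
cycle shorter than 4, or a cycle that unrooting would shorten into a
triangle; the result is unrooted.  $r$ is drawn once per network so that
rejections do not bias its marginal distribution (verified by a chi-squared
test).  This generator is a stand-in with the stated marginal properties —
binary, triangle-free, level-1, rootable, $r$ uniform — not a reproduction
of any particular published generator.

`perturb_quarnets(Q, eps)` redraws the skeleton of `round(eps * C(n,4))`
quarnets uniformly from the 5 alternative skeletons (the star is excluded as
degenerate, the identity because a perturbation must change the topology),
giving new 4-cycles a uniform-random reticulation leaf.

`simulate_alignment(net, k)` roots the network uniformly at random among its
valid root edges, assigns the edge entering $v$ the length $0.3/p(u,v)$
where $p(u,v)$ is the mean edge-count of root-to-leaf paths through the
edge (so root-to-leaf path lengths are about 0.3 substitutions), simulates
equal shares of the $k$ sites under Kimura-2-parameter with
transition/transversion rate ratio 4 along each of the $2^r$ displayed
trees, and concatenates.  The generator emulates concatenated displayed-tree
evolution; it does **not** model incomplete lineage sorting, rate variation
across sites, indels, or base-composition bias, so a green sequence-level
test establishes correct implementation of this generative model, not
robustness to real-data violations of it.

## Numerical and design choices

* **Q\*-tree rule.**  "No conflicting induced quartet" alone does not make
  the most refined tree unique once 4-subsets may be absent from $Q'$
  (absent subsets can leave two incompatible splits both unconflicted).  We
  therefore require every induced 2+2 quartet to be *present with the
  matching split*; retained splits are then automatically pairwise
  compatible, the tree is unique, and on network-induced input it is exactly
  the blobtree.  Candidate clusters are harvested as
  $W(a;z) = \{a\} \cup \{w : aw|z x_1 \in Q'\}$ over all ordered pairs and
  verified exhaustively; on noisy data this can under-refine $T^*$, which is
  harmless because QuartetJoining refines further.
* **Zero-support joins.**  QuartetJoining joins a pair only when its score is
  strictly positive.  Without this rule the candidate sequence
  $T_1, \dots, T_{n-3}$ of a pure-cycle network could never contain the star
  blobtree and the combinatorial guarantee would fail; with it, $T_1$ is
  binary whenever the data provide any positive guidance, and the tail of
  the sequence repeats the fully contracted tree when $T_1$ has fewer than
  $n-3$ internal edges, keeping the candidate count at exactly $n-3$.
* **Tie-breaks.**  Equal supports are contracted in lexicographic order of
  the split's smaller side; equal QuartetJoining scores join the
  lexicographically smallest component pair; skeleton and reticulation vote
  ties are resolved by the seeded RNG; equal-degree vertices expand in order
  of their smallest reachable taxon.  All randomness flows from one seed.
* **Reticulation ranking count.**  "How often a leaf appears in a 4-cycle"
  is read as the weighted count of representative quarnets in which the leaf
  *is the reticulation leaf* (default `rank_mode = "ret"`), since the
  ranking's purpose is to choose the leaf below the reticulation and plain
  membership barely discriminates on dense sets; the literal membership
  count is available as `rank_mode = "member"`.
* **Fast induction.**  Restricting a network to four leaves is defined by a
  five-operation reduction fixpoint (`induced_tf_quarnet()`); the set-level
  `induced_quarnets()` instead classifies each 4-subset by cycle attachment
  analysis (a 4-subset yields a 4-cycle iff some cycle separates it into
  four parts *and* the reticulation is one of the four attachment points)
  plus the four-point rule on blobtree distances.  The two routes are
  cross-checked on random networks in the test suite, including a reduction
  confluence check under shuffled operation order.
* **Rooting.**  An edge is a valid root location iff it is not a
  reticulation edge and, for every cycle, it does not lie in the region
  hanging below that cycle's reticulation; this closed-form test is verified
  in the tests against a brute-force orient-and-check oracle.  Without an
  outgroup an arbitrary valid edge (the first in edge order) is used and the
  choice is reported only through the serialization.
* **Exact TSP bound.**  Held–Karp memory grows as $2^s s$; instances above
  20 vertices are refused in exact mode rather than silently degraded.
* **Partition caching.**  The same vertex partition recurs across the
  candidate sequence, so the driver caches each partition's TSP tour and
  reticulation ranking.  This only changes how many random draws are
  consumed; results remain a deterministic function of input and seed.

## Known limitations

Non-binary networks, level-2 or higher networks, branch-length inference,
non-dense quarnet sets, and model-based quarnet inference are out of scope.
The weighted consistency score is a relative measure for ranking candidates:
a value near 1 means the heavy quarnets are compatible with the network, not
that the network is correct with that probability.
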