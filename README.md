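# squirrel

Reconstruction of binary triangle-free **semi-directed level-1 phylogenetic
networks** from dense sets of weighted **tf-quarnets** (four-leaf networks),
for biologists studying hybridization, introgression and other forms of
secondary contact where a bifurcating tree is the wrong model and the root is
not identifiable from the data.

A semi-directed level-1 network is an unrooted network in which only the
edges entering reticulation vertices are directed, every reticulation lies on
exactly one cycle, and cycles are vertex-disjoint.  A dense tf-quarnet set
contains, for each of the C(n,4) subsets of four taxa, either a quartet tree
`ab|cd` or a 4-cycle (circular order plus the leaf below the reticulation),
with a weight in [0,1] modelling confidence.  Such a set uniquely encodes the
network it came from, so networks can be *puzzled together* from quarnets:

1. build the Q\*-tree of the quartet-tree members and refine it
   QuartetJoining-style into a binary tree T1; contract its least supported
   edges one by one (support = weighted fraction of agreeing quarnets,
   `supp(A|B) = w(Q'(A|B)) / w(Q(A|B))`) to get n−3 **candidate blobtrees**;
2. expand every multifurcation of each candidate into a cycle: representative
   quarnets vote on skeletons, their τ-distances
   (τ = (3∓w)/2 for near/far leaf pairs) feed a travelling-salesman solver
   (exact Held–Karp up to 13 leaves, seeded simulated annealing above) whose
   tour fixes the cyclic ordering, and a reticulation ranking fixes the
   reticulation, iterating until the network is rootable (at the outgroup, if
   given);
3. return the candidate maximizing the weighted tf-quarnet consistency
   `C'(Q,N) = w(Q ∩ Q(N)) / w(Q)`.

The procedure is *combinatorially consistent*: applied to the full
unit-weight quarnet set of a triangle-free semi-directed level-1 network it
returns that network (checked on 200 random networks in the test suite).
A fast **δ-heuristic** turns a multiple sequence alignment directly into a
dense weighted quarnet set, and a simulation module (random level-1
networks, quarnet skeleton perturbation, Kimura-2-parameter sequence
simulation along displayed trees) supports validation experiments.  Networks
are exchanged as eNewick; quarnet sets as a plain-text format
(`T a b c d a,b|c,d 0.9` / `C a b c d a,b,c,d a 0.57`).

## Worked example

```r
library(squirrel)

# a random 7-taxon network with one reticulation
net <- random_network(7, seed = 5)
length(reticulations(net))
#> [1] 1

Q <- induced_quarnets(net)   # dense: choose(7,4) = 35 unit-weight quarnets
Q
#> dense tf-quarnet set: 7 taxa, 35 quarnets (15 quartet trees, 20 4-cycles)

res <- squirrel(Q, tsp_mode = "exact", seed = 1)
res
#> Squirrel result: 4 candidate networks
#> best candidate: #4, weighted tf-quarnet consistency C' = 1.0000
#> reticulations in best network: 1
network_isomorphic(res$network, net)
#> [1] TRUE

round(res$scores, 3)         # all n-3 = 4 candidates, most resolved first
#> [1] 0.600 0.771 0.886 1.000

write_enewick(root_network(res$network, outgroup = "t01"))
#> [1] "(((t07,(t06,(t04,(t02)#H1))),(t03,(t05,#H1))),t01);"
```

The scores mean: the network has a 6-cycle, so its blobtree is far from
binary; only candidate 4 (three least-supported edges of T1 contracted, then
expanded into a cycle) induces every input quarnet and *is* the generating
network, while the fully resolved candidate 1 explains only 60% of the input
weight.
Perturbing half of the quarnet skeletons still leaves the reconstruction
close (this is the package's stochastic acceptance experiment):

```r
res <- run_noise_experiment(ns = c(10, 15, 20, 25), eps_list = 0.5,
                            reps = 10, seed = 1)
c(C = mean(res$C), S = mean(res$S), dr = mean(abs(res$dr)))
#>     C     S    dr
#> 0.953 0.915 0.975
```

From an alignment instead of quarnets (δ-heuristic, threshold λ = 0.3):

```r
aln <- read_alignment("seqs.fasta")
Q   <- infer_tf_quarnets(aln, lambda = 0.3, seed = 1)
res <- squirrel(Q, outgroup = "Mus_musculus", seed = 1)
```

A command-line interface covers the same surface:

```sh
Rscript -e 'squirrel::run_cli()' simulate quarnets -n 10 --eps 0.3 --seed 7 --out noisy.tfq
Rscript -e 'squirrel::run_cli()' infer --quarnets noisy.tfq --outgroup t01 --out net.enwk
Rscript -e 'squirrel::run_cli()' score --net net.enwk --net other.enwk
```

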