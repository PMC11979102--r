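test_that("representative voting reproduces the 4-of-7 worked example", {
  # components A = {a1..a7}, B, C, D; the 7 crossing quarnets on {ai,b,c,d}:
  # four 4-cycles with skeleton (a,b,c,d) (modal reticulation a), one 4-cycle
  # with a different skeleton, two quartet trees
  taxa <- c(paste0("a", 1:7), "b", "c", "d")
  base <- induced_quarnets(caterpillar(taxa))
  overrides <- list(
    tfq_cycle(c("a1", "b", "c", "d"), "a1"),
    tfq_cycle(c("a2", "b", "c", "d"), "a2"),
    tfq_cycle(c("a3", "b", "c", "d"), "a3"),
    tfq_cycle(c("a4", "b", "c", "d"), "b"),
    tfq_cycle(c("a5", "c", "b", "d"), "b"),   # different skeleton
    tfq_quartet(c("a6", "b"), c("c", "d")),
    tfq_quartet(c("a7", "b"), c("c", "d")))
  Q <- override_quarnets(base, overrides)
  f <- setNames(c(rep("a", 7), "b", "c", "d"), taxa)
  set.seed(1)
  rep_set <- squirrel:::representative_from_f(Q, f)
  r <- rep_set$tab[rep_set$tab$key == "a|b|c|d", ]
  expect_identical(r$type, "cycle4")
  expect_identical(r$skel, "C:a,b,c,d")
  expect_identical(r$ret, "a")         # modal: 3x a vs 1x b
  expect_equal(r$weight, 4 / 7)
  # single-element multiset normalises to weight 1
  Qw <- override_quarnets(base, list(tfq_quartet(c("a1", "b"), c("c", "d"), 0.4)))
  one <- squirrel:::representative_from_f(
    Qw, setNames(c("a", rep("z", 6), "b", "c", "d"), taxa))
  # components: a (a1), z (a2..a7), b, c, d; subset {a,b,c,d} multiset has
  # only the weight-0.4 quartet
  rr <- one$tab[one$tab$key == "a|b|c|d", ]
  expect_equal(rr$weight, 1)
  expect_identical(rr$canon, "Q:a,b|c,d")
})

test_that("quarnet distances match brute-force tau summation", {
  # single unit 4-cycle: D = tau values directly
  Q1 <- induced_quarnets(cycle_network(letters[1:4], "a"))
  D1 <- quarnet_distances(Q1)
  expect_equal(D1["a", "b"], 1)
  expect_equal(D1["a", "c"], 2)
  expect_equal(D1["b", "d"], 2)
  expect_equal(unname(diag(D1)), rep(0, 4))
  # dense sets: compare against a direct double loop with tau()
  set.seed(53)
  net <- random_network(6)
  Q <- induced_quarnets(net)
  Q$tab$weight <- round(runif(nrow(Q$tab)), 2)
  D <- quarnet_distances(Q)
  expect_equal(D, t(D))
  taxa <- Q$taxa
  for (a in taxa) for (b in taxa) {
    if (a >= b) next
    tot <- 0
    for (j in seq_len(nrow(Q$tab))) {
      lv <- strsplit(Q$tab$key[j], "|", fixed = TRUE)[[1]]
      if (all(c(a, b) %in% lv))
        tot <- tot + tau(squirrel:::row_to_quarnet(Q$tab[j, ]), a, b)
    }
    expect_equal(D[a, b], tot)
  }
})

test_that("Held-Karp finds optimal tours (brute-force oracle)", {
  set.seed(59)
  for (s in c(5, 6, 7)) {
    D <- matrix(0, s, s, dimnames = list(letters[1:s], letters[1:s]))
    D[upper.tri(D)] <- runif(s * (s - 1) / 2, 1, 10)
    D <- D + t(D)
    tour <- solve_tsp(D, mode = "exact")
    best <- min(apply(gtools_perms(s - 1), 1L, function(p)
      squirrel:::tour_length(D, c(1L, p + 1L))))
    expect_equal(squirrel:::tour_length(D, match(tour, rownames(D))), best)
  }
})

test_that("TSP recovers the cycle order of single-cycle networks", {
  for (s in 5:8) {
    taxa <- letters[1:s]
    net <- cycle_network(taxa, taxa[1])
    D <- quarnet_distances(induced_quarnets(net))
    tour <- solve_tsp(D, mode = "exact")
    # the optimal tour is the original circular order up to rotation/reflection
    rot <- function(v, k) v[((seq_along(v) + k - 1) %% length(v)) + 1]
    cands <- c(lapply(0:(s - 1), rot, v = taxa),
               lapply(0:(s - 1), rot, v = rev(taxa)))
    expect_true(any(vapply(cands, identical, TRUE, y = tour)))
  }
  # annealing is deterministic under seed and near-optimal on cycles
  net <- cycle_network(letters[1:14], "a")
  D <- quarnet_distances(induced_quarnets(net))
  set.seed(3); t1 <- solve_tsp(D, mode = "anneal")
  set.seed(3); t2 <- solve_tsp(D, mode = "anneal")
  expect_identical(t1, t2)
})

test_that("reticulation ranking follows the 4-cycle counts", {
  # |Y| = 4 with a single 4-cycle: its reticulation leaf first
  Q4 <- induced_quarnets(cycle_network(letters[1:4], "c"))
  set.seed(2)
  expect_identical(reticulation_ranking(Q4)[1], "c")
  # |Y| = 4 quartet tree: a permutation (seeded)
  Qt <- induced_quarnets(caterpillar(letters[1:4]))
  set.seed(2)
  expect_setequal(reticulation_ranking(Qt), letters[1:4])
  # |Y| = 5 from a 5-cycle with reticulation below "b"
  Q5 <- induced_quarnets(cycle_network(letters[1:5], "b"))
  set.seed(2)
  expect_identical(reticulation_ranking(Q5)[1], "b")
})

test_that("expand_tree reconstructs cycles and respects rootability", {
  # binary tree input: unchanged
  tr <- caterpillar(letters[1:6])
  Q <- induced_quarnets(tr)
  expect_same_network(expand_tree(tr, Q), tr)
  # star on 4 leaves + a single 4-cycle quarnet -> that 4-cycle network
  cyc <- cycle_network(letters[1:4], "a")
  Qc <- induced_quarnets(cyc)
  star4 <- structure(list(
    edges = data.frame(v1 = 5L, v2 = 1:4, directed = FALSE),
    labels = setNames(1:4, letters[1:4])), class = "sdnet")
  set.seed(5)
  expect_same_network(expand_tree(star4, Qc), cyc)
  # blobtree(N) + Q(N) -> N, with the right reticulation count
  set.seed(61)
  for (i in 1:8) {
    net <- random_network(sample(6:10, 1))
    out <- expand_tree(blobtree(net), induced_quarnets(net), tsp_mode = "exact")
    expect_same_network(out, net)
    expect_equal(length(reticulations(out)), length(net_cycles(net)))
    expect_gt(length(valid_root_edges(out)), 0)
  }
})
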