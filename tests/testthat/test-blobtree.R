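test_that("Q*-tree: trees are recovered, networks give their blobtree", {
  tree <- caterpillar(letters[1:6])
  Q <- induced_quarnets(tree)
  expect_same_network(build_qstar_tree(Q), tree)
  set.seed(41)
  for (i in 1:6) {
    net <- random_network(sample(5:9, 1))
    Q <- induced_quarnets(net)
    expect_same_network(build_qstar_tree(Q), blobtree(net))
  }
})

test_that("Q*-tree: conflicting quartets kill the separating split", {
  taxa <- letters[1:5]
  qs <- list(tfq_quartet(c("a", "b"), c("c", "d")),
             tfq_quartet(c("a", "c"), c("b", "d")))
  t0 <- build_qstar_tree(qs, taxa = taxa)
  ids <- vapply(network_splits(t0, nontrivial_only = TRUE), `[[`, "", "id")
  expect_false(any(grepl("^a,b\\|", ids) | grepl("\\|a,b$", ids)))
})

test_that("omega collects quartet weights and ignores 4-cycles", {
  net <- cycle_network(letters[1:5], "a")
  Q <- induced_quarnets(net)
  Q$tab$weight[Q$tab$type == "quartet"] <- 0.4
  om <- omega_from_quarnets(Q)
  expect_equal(nrow(om), 1L) # only the subset avoiding the reticulation leaf
  expect_equal(omega_value(om, c("b", "c"), c("d", "e")), 0.4)
  expect_equal(omega_value(om, c("b", "d"), c("c", "e")), 0)
  expect_equal(omega_value(om, c("a", "b"), c("c", "d")), 0)
})

test_that("QuartetJoining resolves stars toward the omega optimum", {
  # star on 4 leaves with omega(ab|cd) = 1 only -> binary tree ab|cd
  star4 <- structure(list(
    edges = data.frame(v1 = 5L, v2 = 1:4, directed = FALSE),
    labels = setNames(1:4, letters[1:4])), class = "sdnet")
  om <- omega_from_quarnets(dense_quarnets(list(
    tfq_quartet(c("a", "b"), c("c", "d")))))
  t1 <- refine_quartetjoining(star4, om)
  expect_same_network(t1, caterpillar(letters[1:4]))
  # star on 6 leaves with omega from a caterpillar's quartets -> caterpillar;
  # oracle: exhaustive search over all 105 binary trees for the maximum
  # summed omega of induced quartets
  cat6 <- caterpillar(letters[1:6])
  Q6 <- induced_quarnets(cat6)
  om6 <- omega_from_quarnets(Q6)
  star6 <- structure(list(
    edges = data.frame(v1 = 7L, v2 = 1:6, directed = FALSE),
    labels = setNames(1:6, letters[1:6])), class = "sdnet")
  t6 <- refine_quartetjoining(star6, om6)
  expect_same_network(t6, cat6)
  all6 <- phangorn::allTrees(6, tip.label = letters[1:6])
  scores <- vapply(all6, function(ph) {
    QT <- induced_quarnets(sdnet_from_phylo(ph))
    sum(vapply(seq_len(nrow(QT$tab)), function(j) {
      r <- QT$tab[j, ]
      omega_value(om6, c(r$x1, r$x2), c(r$x3, r$x4))
    }, 0))
  }, 0)
  best <- all6[[which.max(scores)]]
  expect_same_network(sdnet_from_phylo(best), cat6)
  # with no positive evidence the star stays unresolved
  omempty <- omega_from_quarnets(induced_quarnets(cycle_network(letters[1:4], "a")))
  expect_same_network(refine_quartetjoining(star4, omempty), star4)
})

test_that("split support matches direct evaluation", {
  tree <- caterpillar(letters[1:6])
  Q <- induced_quarnets(tree)
  expect_equal(split_support(Q, c("a", "b")), 1)
  expect_equal(split_support(Q, c("a", "b", "c")), 1)
  # all relevant quarnets 4-cycles -> 0
  cyc <- cycle_network(letters[1:4], "a")
  expect_equal(split_support(induced_quarnets(cyc), c("a", "b")), 0)
  # two relevant quarnets, unit weights, one supporting -> 0.5
  Q2 <- override_quarnets(Q, list(
    tfq_quartet(c("a", "c"), c("b", "d")))) # break ab|cd support on one subset
  A <- c("a", "b")
  lm <- do.call(rbind, strsplit(Q2$tab$key, "|", fixed = TRUE))
  rel <- rowSums(matrix(lm %in% A, ncol = 4)) == 2
  good <- sum(Q2$tab$type[rel] == "quartet" &
                ((Q2$tab$x1[rel] %in% A) == (Q2$tab$x2[rel] %in% A)) &
                ((Q2$tab$x3[rel] %in% A) == (Q2$tab$x4[rel] %in% A)))
  expect_equal(split_support(Q2, A), good / sum(rel))
  expect_error(split_support(Q, c("a")), "nontrivial")
})

test_that("candidate sequences have the right shape and chain structure", {
  # n = 4: a single candidate
  Q4 <- induced_quarnets(caterpillar(letters[1:4]))
  cb4 <- candidate_blobtrees(Q4)
  expect_length(cb4$trees, 1L)
  # quarnets from a binary tree: T1 = tree, every support 1
  tr <- caterpillar(letters[1:7])
  cb <- candidate_blobtrees(induced_quarnets(tr))
  expect_length(cb$trees, 4L)
  expect_same_network(cb$trees[[1]], tr)
  expect_true(all(cb$support$support == 1))
  # refinement chain: every Ti+1 is a contraction of Ti (its splits are a
  # subset of Ti's splits)
  set.seed(47)
  net <- random_network(8)
  Q <- induced_quarnets(net)
  cb <- candidate_blobtrees(Q)
  split_set <- function(tr)
    vapply(network_splits(tr, nontrivial_only = TRUE), `[[`, "", "id")
  for (i in seq_along(cb$trees)[-1])
    expect_true(all(split_set(cb$trees[[i]]) %in% split_set(cb$trees[[i - 1]])))
  # on quarnet sets induced by a network the blobtree appears in the sequence
  for (i in 1:5) {
    net <- random_network(sample(5:9, 1))
    cb <- candidate_blobtrees(induced_quarnets(net))
    bt <- blobtree(net)
    expect_true(any(vapply(cb$trees, network_isomorphic, TRUE, b = bt)))
  }
})
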