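test_that("cycle canonicalisation identifies all 8 rotations/reflections", {
  base <- c("b", "d", "a", "c")
  rots <- lapply(0:3, function(k) base[((seq_len(4) + k - 1) %% 4) + 1])
  all8 <- c(rots, lapply(rots, rev))
  canons <- vapply(all8, function(o) quarnet_canon(tfq_cycle(o, "a")), "")
  expect_length(unique(canons), 1L)
  # but a different cyclic order is distinguished
  expect_false(quarnet_canon(tfq_cycle(c("a", "b", "c", "d"), "a")) ==
                 quarnet_canon(tfq_cycle(c("a", "c", "b", "d"), "a")))
  # and the reticulation leaf is part of the identity
  expect_false(quarnet_canon(tfq_cycle(base, "a")) ==
                 quarnet_canon(tfq_cycle(base, "b")))
})

test_that("quartet equality is split equality", {
  a <- tfq_quartet(c("b", "a"), c("d", "c"))
  b <- tfq_quartet(c("c", "d"), c("a", "b"), weight = 0.2)
  expect_identical(quarnet_canon(a), quarnet_canon(b))
  expect_false(quarnet_canon(a) ==
                 quarnet_canon(tfq_quartet(c("a", "c"), c("b", "d"))))
})

test_that("tau matches the unit-weight table and the weighted formula", {
  # unit-weight quartet ab|cd: same side 1, across 2
  q <- tfq_quartet(c("a", "b"), c("c", "d"))
  expect_equal(tau(q, "a", "b"), 1)
  expect_equal(tau(q, "c", "d"), 1)
  expect_equal(tau(q, "a", "c"), 2)
  expect_equal(tau(q, "b", "d"), 2)
  # unit-weight 4-cycle: neighbours 1, opposite 2
  cy <- tfq_cycle(c("a", "b", "c", "d"), "b")
  expect_equal(tau(cy, "a", "b"), 1)
  expect_equal(tau(cy, "d", "a"), 1)
  expect_equal(tau(cy, "a", "c"), 2)
  expect_equal(tau(cy, "b", "d"), 2)
  # weighted: (3 -/+ w)/2 across w in {0, 0.5, 1}
  for (w in c(0, 0.5, 1)) {
    qw <- tfq_quartet(c("a", "b"), c("c", "d"), w)
    cw <- tfq_cycle(c("a", "b", "c", "d"), "a", w)
    expect_equal(tau(qw, "a", "b"), (3 - w) / 2)
    expect_equal(tau(qw, "a", "c"), (3 + w) / 2)
    expect_equal(tau(cw, "b", "c"), (3 - w) / 2)
    expect_equal(tau(cw, "b", "d"), (3 + w) / 2)
  }
  expect_error(tau(q, "a", "a"), "distinct")
})

test_that("consistency scores match hand-derived values", {
  tree <- caterpillar(letters[1:5])
  Q <- induced_quarnets(tree)
  expect_equal(consistency_score(Q, Q), 1)
  expect_equal(symmetric_consistency(Q, Q), 1)
  # flip 2 of the 5 subsets: C = 3/5, S = 3/7
  flip <- lapply(1:2, function(i) {
    r <- Q$tab[i, ]
    tfq_cycle(c(r$x1, r$x2, r$x3, r$x4), r$x1)
  })
  Q2 <- override_quarnets(Q, flip)
  expect_equal(consistency_score(Q, Q2), 0.6)
  expect_equal(symmetric_consistency(Q, Q2), 3 / 7)
  # disagreeing everywhere: 0
  allflip <- lapply(seq_len(nrow(Q$tab)), function(i) {
    r <- Q$tab[i, ]
    tfq_cycle(c(r$x1, r$x2, r$x3, r$x4), r$x1)
  })
  Q3 <- override_quarnets(Q, allflip)
  expect_equal(consistency_score(Q, Q3), 0)
  expect_error(consistency_score(Q, induced_quarnets(caterpillar(letters[2:6]))),
               "taxon sets differ")
})

test_that("S <= C on random dense pairs", {
  set.seed(101)
  for (i in 1:5) {
    a <- random_network(7)
    b <- random_network(7)
    QA <- induced_quarnets(a); QB <- induced_quarnets(b)
    expect_lte(symmetric_consistency(QA, QB), consistency_score(QA, QB))
  }
})

test_that("weighted consistency handles weights and degenerate input", {
  tree <- caterpillar(letters[1:5])
  Q <- induced_quarnets(tree)
  expect_equal(weighted_consistency(Q, tree), 1)
  # weights (0.5, 1) with the 0.5-row flipped: C' = 1 / 1.5
  tab <- Q$tab
  tab$weight <- 0
  tab$weight[1] <- 0.5; tab$weight[2] <- 1
  Qw <- squirrel:::new_dense_quarnets(Q$taxa, tab)
  r <- Qw$tab[1, ]
  Qw <- override_quarnets(Qw, list(tfq_cycle(c(r$x1, r$x2, r$x3, r$x4),
                                             r$x1, 0.5)))
  expect_equal(weighted_consistency(Qw, tree), 1 / 1.5)
  # matching nothing: 0
  cyc <- cycle_network(letters[1:5], "a")
  expect_equal(weighted_consistency(Qw, cyc), 0.5 / 1.5) # only flipped row matches
  tab$weight <- 0
  Q0 <- squirrel:::new_dense_quarnets(Q$taxa, tab)
  expect_error(weighted_consistency(Q0, tree), "degenerate")
})

test_that("quarnet file round-trips and rejects malformed input", {
  net <- random_network(6, seed = 5)
  Q <- induced_quarnets(net)
  Q$tab$weight <- round(runif(nrow(Q$tab)), 3)
  path <- tempfile()
  write_quarnets(Q, path)
  Q2 <- read_quarnets(path)
  expect_identical(Q$tab$canon, Q2$tab$canon)
  expect_equal(Q$tab$weight, Q2$tab$weight)
  # explicit line formats
  p2 <- tempfile()
  writeLines(c("taxa: a b c d", "# comment", "T a b c d a,b|c,d 1.0"), p2)
  Qt <- read_quarnets(p2)
  expect_identical(Qt$tab$type, "quartet")
  writeLines(c("C a b c d a,b,c,d a 0.571"), p2)
  Qc <- read_quarnets(p2)
  expect_identical(Qc$tab$canon, "C:a,b,c,d;a")
  expect_equal(Qc$tab$weight, 0.571)
  # non-dense, bad weight, unknown taxon
  writeLines(c("T a b c d a,b|c,d 1.0", "T a b c d a,c|b,d 1.0"), p2)
  expect_error(read_quarnets(p2), "duplicate")
  writeLines("T a b c d a,b|c,d 1.7", p2)
  expect_error(read_quarnets(p2), "weight")
  writeLines(c("taxa: a b c d", "T a b c e a,b|c,e 1.0"), p2)
  expect_error(read_quarnets(p2), "unknown taxon")
})
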