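test_that("random networks satisfy the stated invariants", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    net <- random_network(n)
    expect_silent(validate_network(net)) # binary, level-1, triangle-free
    expect_lte(length(reticulations(net)), floor(n / 3))
    expect_gt(length(valid_root_edges(net)), 0)
    cyc <- net_cycles(net)
    expect_equal(length(cyc), length(reticulations(net)))
    expect_true(all(vapply(cyc, function(cc) length(cc$vs), 0L) >= 4L))
  }
})

test_that("the reticulation count is uniform on {0..floor(n/3)} (chi-squared)", {
  set.seed(107)
  draws <- vapply(1:300, function(i)
    length(reticulations(random_network(6))), 0L)
  tab <- table(factor(draws, levels = 0:2))
  p <- stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 1e-3)
})

test_that("perturbation changes exactly the requested skeleton count", {
  net <- random_network(10, seed = 109)
  Q <- induced_quarnets(net)
  expect_identical(perturb_quarnets(Q, 0)$tab$canon, Q$tab$canon)
  for (eps in c(0.25, 0.5, 1)) {
    Qe <- perturb_quarnets(Q, eps, seed = 11)
    expect_equal(sum(Qe$tab$skel != Q$tab$skel), round(eps * nrow(Q$tab)))
    expect_identical(Qe$tab$key, Q$tab$key)
    expect_equal(Qe$tab$weight, Q$tab$weight)
  }
  # epsilon = 1: every skeleton differs
  Q1 <- perturb_quarnets(Q, 1, seed = 12)
  expect_true(all(Q1$tab$skel != Q$tab$skel))
})

test_that("displayed trees: 2^r rooted trees on the same leaves", {
  tree <- caterpillar(letters[1:5])
  rt <- root_network(tree, outgroup = "a")
  expect_length(displayed_trees(rt), 1L)
  set.seed(113)
  for (i in 1:5) {
    net <- random_network(8)
    r <- length(reticulations(net))
    rn <- root_network(net)
    dts <- displayed_trees(rn)
    expect_length(dts, 2^r)
    for (dt in dts) {
      expect_setequal(names(dt$labels), names(net$labels))
      # a tree: no vertex with in-degree 2, binary out-degrees
      expect_true(all(table(dt$edges$child) == 1L))
    }
  }
})

test_that("branch lengths give root-to-leaf path lengths near 0.3", {
  set.seed(127)
  for (i in 1:5) {
    net <- random_network(9)
    rn <- squirrel:::assign_branch_lengths(root_network(net))
    ed <- rn$edges
    expect_true(all(ed$len > 0))
    # average total length of root-to-leaf paths, per leaf, within [0.2, 0.4]
    for (lf in unname(rn$labels)) {
      lens <- c()
      walk <- function(v, acc) {
        if (v == lf) { lens <<- c(lens, acc); return(invisible()) }
        for (j in which(ed$parent == v)) walk(ed$child[j], acc + ed$len[j])
      }
      walk(rn$root, 0)
      expect_gt(mean(lens), 0.2)
      expect_lt(mean(lens), 0.4)
    }
  }
})

test_that("K2P simulation matches the closed-form substitution probabilities", {
  # two taxa, one branch: compare observed transition/transversion fractions
  # with the analytic K2P probabilities at kappa = 4
  d <- 0.3
  p <- squirrel:::k2p_probs(d, kappa = 4)
  expect_equal(sum(p["same"], p["ts"], 2 * p["tv"]), 1)
  expect_gt(p[["ts"]] / (2 * p[["tv"]]), 1) # transitions enriched
  set.seed(131)
  L <- 60000L
  anc <- sample.int(4L, L, replace = TRUE)
  der <- squirrel:::k2p_evolve(anc, d, kappa = 4)
  ts_pairs <- matrix(c(1, 2, 2, 1, 3, 4, 4, 3), ncol = 2, byrow = TRUE)
  is_ts <- (anc != der) & ((anc <= 2 & der <= 2) | (anc >= 3 & der >= 3))
  is_tv <- anc != der & !is_ts
  expect_equal(mean(is_ts), p[["ts"]], tolerance = 0.03)
  expect_equal(mean(is_tv), 2 * p[["tv"]], tolerance = 0.05)
  # zero-length branches: no substitutions at all
  same <- squirrel:::k2p_evolve(anc, 0)
  expect_identical(same, anc)
})

test_that("simulated alignments are deterministic and well formed", {
  net <- random_network(7, seed = 137)
  a1 <- simulate_alignment(net, 1234, seed = 5)
  a2 <- simulate_alignment(net, 1234, seed = 5)
  expect_identical(a1$seqs, a2$seqs)
  expect_equal(nchar(a1$seqs), rep(1234L, 7), ignore_attr = TRUE)
  expect_setequal(a1$labels, names(net$labels))
  # k smaller than the number of displayed trees still yields k columns
  r <- length(reticulations(net))
  if (r > 0) {
    a3 <- simulate_alignment(net, 1, seed = 6)
    expect_equal(nchar(a3$seqs[1]), 1L)
  }
})

test_that("noise experiment table has the expected shape; eps = 0 is perfect", {
  res <- run_noise_experiment(ns = c(6, 7), eps_list = c(0, 0.1), reps = 2,
                              seed = 139)
  expect_equal(nrow(res), 2 * 2 * 2)
  z <- res[res$eps == 0, ]
  expect_true(all(z$C == 1))
  expect_true(all(z$S == 1))
  expect_true(all(z$dr == 0))
})
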