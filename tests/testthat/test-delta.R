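test_that("pairwise Hamming distances use gap-free columns only", {
  aln <- msa(c(a = "AAAA", b = "TTTT", c = "AA-A", d = "ATTA"))
  h <- pairwise_hamming(aln)
  expect_equal(h$h["a", "a"], 0)
  expect_equal(h$h["a", "b"], 1)
  expect_equal(h$h["c", "d"], 1 / 3) # 3 gap-free columns, 1 mismatch
  expect_equal(h$len["c", "d"], 3L)
  # all-gap overlap is a hard error naming the pair
  bad <- msa(c(a = "AA--", b = "--TT", c = "ACGT", d = "ACGT"))
  expect_error(pairwise_hamming(bad), "'a' and 'b'")
  # ambiguity codes mismatch unless identical
  amb <- msa(c(a = "NN", b = "NA", c = "AC", d = "AG"))
  expect_equal(pairwise_hamming(amb)$h["a", "b"], 0.5)
})

test_that("delta values match hand-computed cases", {
  aln <- msa(c(a = "AAAA", b = "TTTT", c = "AATT", d = "TTAA"))
  h <- pairwise_hamming(aln)
  expect_equal(delta_value(h, c("a", "b", "c", "d")), 1)
  # identical sequences: all sums equal -> 0 by the side condition
  same <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  expect_equal(delta_value(pairwise_hamming(same), letters[1:4]), 0)
  # numerator-zero (top two sums equal) -> 0
  hm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  hm["a", "b"] <- hm["b", "a"] <- 0.5
  hm["c", "d"] <- hm["d", "c"] <- 0.5   # s1 = 1
  hm["a", "c"] <- hm["c", "a"] <- 0.6
  hm["b", "d"] <- hm["d", "b"] <- 0.4   # s2 = 1
  hm["a", "d"] <- hm["d", "a"] <- 0.2
  hm["b", "c"] <- hm["c", "b"] <- 0.2   # s3 = 0.4
  expect_equal(delta_value(hm, letters[1:4]), 0)
})

test_that("the quarnet weight is piecewise linear in delta, zero at lambda", {
  lam <- 0.3
  w <- function(d) ifelse(d <= lam, abs(d - lam) / lam, abs(d - lam) / (1 - lam))
  expect_equal(w(lam), 0)
  expect_equal(w(0), 1)
  expect_equal(w(1), 1)
  # infer_tf_quarnets agrees with delta_value + the weight formula
  set.seed(89)
  net <- random_network(6)
  aln <- simulate_alignment(net, 500)
  Q <- infer_tf_quarnets(aln, seed = 1)
  h <- pairwise_hamming(aln)
  lm <- do.call(rbind, strsplit(Q$tab$key, "|", fixed = TRUE))
  for (j in seq_len(nrow(Q$tab))) {
    d <- delta_value(h, lm[j, ])
    expect_equal(Q$tab$weight[j], w(d), tolerance = 1e-12)
    expect_identical(Q$tab$type[j],
                     if (d >= lam) "quartet" else "cycle4")
  }
})

test_that("the delta = 1 worked example yields quartet ab|cd with weight 1", {
  aln <- msa(c(a = "AAAA", b = "TTTT", c = "AATT", d = "TTAA"))
  Q <- infer_tf_quarnets(aln, seed = 1)
  expect_identical(Q$tab$canon, "Q:a,b|c,d")
  expect_equal(Q$tab$weight, 1)
  # four identical sequences: delta = 0 -> 4-cycle with weight 1
  same <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  Qs <- infer_tf_quarnets(same, seed = 1)
  expect_identical(Qs$tab$type, "cycle4")
  expect_equal(Qs$tab$weight, 1)
})

test_that("output is dense, weights in [0,1], and column order irrelevant", {
  set.seed(97)
  net <- random_network(7)
  aln <- simulate_alignment(net, 400)
  Q <- infer_tf_quarnets(aln, seed = 2)
  expect_equal(nrow(Q$tab), choose(7, 4))
  expect_true(all(Q$tab$weight >= 0 & Q$tab$weight <= 1))
  # permuting alignment columns changes nothing
  perm <- sample(nchar(aln$seqs[1]))
  aln2 <- msa(vapply(strsplit(aln$seqs, ""), function(x)
    paste(x[perm], collapse = ""), ""), aln$labels)
  Q2 <- infer_tf_quarnets(aln2, seed = 2)
  expect_identical(Q$tab$canon, Q2$tab$canon)
  expect_equal(Q$tab$weight, Q2$tab$weight)
  # the chosen quartet split always carries the largest pair-sum
  h <- pairwise_hamming(aln)$h
  qt <- Q$tab[Q$tab$type == "quartet", ]
  for (j in seq_len(nrow(qt))) {
    r <- qt[j, ]
    s_split <- h[r$x1, r$x2] + h[r$x3, r$x4]
    s_alt1 <- h[r$x1, r$x3] + h[r$x2, r$x4]
    s_alt2 <- h[r$x1, r$x4] + h[r$x2, r$x3]
    expect_gte(s_split + 1e-12, max(s_alt1, s_alt2))
  }
})

test_that("FASTA and NEXUS readers produce the same alignment", {
  set.seed(5)
  net <- random_network(5)
  aln <- simulate_alignment(net, 100)
  fp <- tempfile(fileext = ".fasta")
  write_fasta(aln, fp)
  back <- read_alignment(fp)
  expect_setequal(back$labels, aln$labels)
  expect_identical(back$seqs[match(aln$labels, back$labels)], aln$seqs)
  np <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", 5, 100),
               "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
               paste(aln$labels, aln$seqs), ";", "END;"), np)
  nx <- read_alignment(np)
  expect_identical(toupper(nx$seqs[match(aln$labels, nx$labels)]), aln$seqs)
})
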