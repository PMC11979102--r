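# fixtures are built in code; no data files

# unrooted caterpillar tree with leaves in the given order
caterpillar <- function(taxa) {
  n <- length(taxa)
  stopifnot(n >= 4L)
  nwk <- paste0("(", taxa[1], ",", taxa[2], ",")
  for (k in 3:(n - 1)) nwk <- paste0(nwk, "(", taxa[k], ",")
  nwk <- paste0(nwk, taxa[n], paste(rep(")", n - 2), collapse = ""), ";")
  sdnet_from_phylo(ape::read.tree(text = nwk))
}

# dense set from a list of tf-quarnets, overriding rows of a base set
override_quarnets <- function(base, quarnets) {
  tab <- base$tab
  for (q in quarnets) {
    i <- match(squirrel:::subset_key(q$leaves), tab$key)
    stopifnot(!is.na(i))
    tab$type[i] <- q$type
    tab$x1[i] <- q$x[1]; tab$x2[i] <- q$x[2]
    tab$x3[i] <- q$x[3]; tab$x4[i] <- q$x[4]
    tab$ret[i] <- q$ret
    tab$weight[i] <- q$weight
  }
  squirrel:::new_dense_quarnets(base$taxa, squirrel:::finish_tab(tab))
}

expect_same_network <- function(a, b) expect_true(network_isomorphic(a, b))

# all permutations of 1..k (small k); brute-force oracle helper
gtools_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) cbind(i, sub + (sub >= i))))
}
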