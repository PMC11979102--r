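# Step A1: the Q*-tree of the quartet trees in a dense tf-quarnet set.
#
# A split A|B is retained iff every 4-subset with two leaves on each side is
# present among the input quartet trees *with the matching split* (the strong
# combinatorial-evidence rule).  Under this rule retained splits are
# automatically pairwise compatible (a conflict would require two different
# splits on the same 4-subset), so the most refined tree displaying them is
# unique; on a quarnet set induced by a level-1 network it is the network's
# blobtree.

# hashed lookup: subset key -> canonical split string ("Q:a,b|c,d")
quartet_lookup <- function(Q) {
  tab <- Q$tab
  qi <- tab$type == "quartet"
  env <- new.env(parent = emptyenv(), size = sum(qi) * 2L)
  keys <- tab$key[qi]; canon <- tab$canon[qi]
  for (i in seq_along(keys)) assign(keys[i], canon[i], envir = env)
  env
}

split_key4 <- function(a, b, c_, d) {
  # canonical strings of subset {a,b,c,d} and of split ab|cd
  s <- sort(c(a, b, c_, d))
  x <- canon_split(c(a, b), c(c_, d))
  list(key = paste(s, collapse = "|"),
       canon = quartet_canon_str(x[1], x[2], x[3], x[4]))
}

# is split A | X\A supported by every induced 2+2 quartet?
cluster_admissible <- function(A, taxa, env) {
  B <- setdiff(taxa, A)
  if (length(A) < 2L || length(B) < 2L) return(FALSE)
  pa <- combn(A, 2L); pb <- combn(B, 2L)
  for (i in seq_len(ncol(pa))) for (j in seq_len(ncol(pb))) {
    sk <- split_key4(pa[1, i], pa[2, i], pb[1, j], pb[2, j])
    got <- get0(sk$key, envir = env)
    if (is.null(got) || got != sk$canon) return(FALSE)
  }
  TRUE
}

#' Q*-tree of a set of quartet trees
#'
#' The unique most refined tree whose every induced 2+2 quartet occurs, with
#' the same split, among the quartet trees of `Q`.  Collapses toward the star
#' tree as conflicts (or 4-cycles) accumulate.
#'
#' @param Q a `dense_quarnets` object (only its quartet-tree members are
#'   used), or a list of quartet-type `tf_quarnet`s together with `taxa`.
#' @param taxa taxon set (required when `Q` is a plain list).
#' @return an `sdnet` tree (possibly multifurcating).
#' @export
build_qstar_tree <- function(Q, taxa = NULL) {
  if (inherits(Q, "dense_quarnets")) {
    taxa <- Q$taxa
    env <- quartet_lookup(Q)
  } else {
    stopifnot(!is.null(taxa))
    env <- new.env(parent = emptyenv())
    for (q in Q) {
      if (q$type != "quartet") next
      k <- subset_key(q$leaves)
      prev <- get0(k, envir = env)
      cn <- quarnet_canon(q)
      # contradictory quartets on one subset cancel each other
      assign(k, if (is.null(prev) || prev == cn) cn else "conflict", envir = env)
    }
  }
  taxa <- sort(taxa)
  n <- length(taxa)
  ref <- taxa[1]
  others <- taxa[-1]
  # candidate clusters W(a; z) = {a} + {w : quartet aw|z,ref present}
  cands <- list(); seen <- character()
  for (a in others) for (z in setdiff(others, a)) {
    W <- a
    for (w in setdiff(others, c(a, z))) {
      sk <- split_key4(a, w, z, ref)
      got <- get0(sk$key, envir = env)
      if (!is.null(got) && got == sk$canon) W <- c(W, w)
    }
    W <- sort(W)
    if (length(W) < 2L || length(W) >= n - 2L + 1L) next
    id <- paste(W, collapse = ",")
    if (id %in% seen) next
    seen <- c(seen, id)
    cands[[length(cands) + 1L]] <- W
  }
  good <- Filter(function(A) cluster_admissible(A, taxa, env), cands)
  tree_from_clusters(taxa, good, ref)
}
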