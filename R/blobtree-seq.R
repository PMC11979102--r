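# Step A3: split supports on T1 and the contraction sequence of candidate
# blobtrees.

# cached N x 4 matrix of each quarnet's taxa (from the subset keys)
qs_leaf_matrix <- function(Q) {
  do.call(rbind, strsplit(Q$tab$key, "|", fixed = TRUE))
}

#' Split support of a nontrivial split under a dense quarnet set
#'
#' `supp(A|B) = w(Q'(A|B)) / w(Q(A|B))` where `Q(A|B)` are the quarnets with
#' exactly two leaves on each side and `Q'(A|B)` its quartet-tree members
#' whose split restricts the split `A|B`.
#'
#' @param Q a `dense_quarnets` object.
#' @param A one side of the split (character vector of taxa, `2 <= |A| <= n-2`).
#' @return numeric in `[0, 1]`.
#' @export
split_support <- function(Q, A) {
  taxa <- Q$taxa
  stopifnot(all(A %in% taxa))
  B <- setdiff(taxa, A)
  if (length(A) < 2L || length(B) < 2L)
    stop("split_support() needs a nontrivial split")
  inA <- setNames(taxa %in% A, taxa)
  lm <- qs_leaf_matrix(Q)
  cnt <- inA[lm[, 1]] + inA[lm[, 2]] + inA[lm[, 3]] + inA[lm[, 4]]
  rel <- cnt == 2L
  stopifnot(any(rel)) # dense sets always have relevant quarnets
  tab <- Q$tab
  good <- rel & tab$type == "quartet" &
    (inA[tab$x1] == inA[tab$x2]) & (inA[tab$x3] == inA[tab$x4])
  wrel <- sum(tab$weight[rel])
  if (wrel == 0) stop("degenerate weights: no weight on relevant quarnets")
  sum(tab$weight[good]) / wrel
}

#' Candidate blobtree sequence
#'
#' Builds the Q*-tree (Step A1), refines it by adapted QuartetJoining
#' (Step A2), computes the split support of every internal edge of the refined
#' tree T1 and returns the sequence `T1, ..., T(n-3)` where `Ti` contracts the
#' `i-1` least supported internal edges of T1 (Step A3).  Equal supports are
#' contracted in lexicographic order of the split's smaller side.  If T1 has
#' fewer than `n-3` internal edges (omega gave no guidance somewhere), the
#' tail of the sequence repeats the fully contracted tree so the length is
#' always exactly `n-3`.
#'
#' @param Q a `dense_quarnets` object on `n >= 4` taxa.
#' @return a list with `trees` (list of `sdnet` trees, length `n-3`) and
#'   `support` (data.frame of T1's internal edges: vertex pair, support and
#'   the smaller split side).
#' @export
candidate_blobtrees <- function(Q) {
  n <- length(Q$taxa)
  stopifnot(n >= 4L)
  tstar <- build_qstar_tree(Q)
  omega <- omega_from_quarnets(Q)
  t1 <- refine_quartetjoining(tstar, omega)
  ie <- tree_internal_edges(t1)
  sup <- data.frame(v1 = integer(), v2 = integer(), support = numeric(),
                    side = character(), stringsAsFactors = FALSE)
  for (i in ie) {
    A <- edge_split_side(t1, i)
    B <- setdiff(Q$taxa, A)
    small <- if (length(A) < length(B) ||
                 (length(A) == length(B) && paste(A, collapse = ",") <=
                    paste(B, collapse = ","))) A else B
    sup <- rbind(sup, data.frame(
      v1 = t1$edges$v1[i], v2 = t1$edges$v2[i],
      support = split_support(Q, A),
      side = paste(small, collapse = ","), stringsAsFactors = FALSE))
  }
  ord <- order(sup$support, sup$side)
  trees <- vector("list", n - 3L)
  trees[[1L]] <- t1
  cur <- t1
  vmap <- identity_map(t1)
  for (i in seq_len(n - 3L)[-1L]) {
    if (i - 1L <= nrow(sup)) {
      k <- ord[i - 1L]
      u <- resolve_vertex(vmap, sup$v1[k]); v <- resolve_vertex(vmap, sup$v2[k])
      cur <- contract_tree_edge(cur, u, v)
      vmap[as.character(v)] <- u
    }
    trees[[i]] <- cur
  }
  list(trees = trees, support = sup)
}

identity_map <- function(tree) {
  vs <- net_vertices(tree)
  setNames(vs, as.character(vs))
}

resolve_vertex <- function(vmap, v) {
  repeat {
    w <- vmap[[as.character(v)]]
    if (w == v) return(v)
    v <- w
  }
}
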