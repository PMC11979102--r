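# Small utilities for unrooted leaf-labeled trees represented as `sdnet`
# objects with no directed edges.

# Build a tree from a laminar family of clusters (sides of splits not
# containing the reference taxon `ref`).  Clusters are character vectors of
# taxa; singletons and the full set need not be supplied.
tree_from_clusters <- function(taxa, clusters, ref = sort(taxa)[1]) {
  taxa <- sort(taxa)
  others <- setdiff(taxa, ref)
  clusters <- unique(lapply(clusters, sort))
  # keep proper clusters of `others` with 2 <= |A| < |others|
  clusters <- Filter(function(a) all(a %in% others) && length(a) >= 2L &&
                       length(a) < length(others), clusters)
  fam <- unique(c(list(others), clusters, as.list(others)))
  sizes <- vapply(fam, length, 0L)
  ord <- order(-sizes)
  fam <- fam[ord]; sizes <- sizes[ord]
  keys <- vapply(fam, paste, "", collapse = ",")
  nfam <- length(fam)
  # parent = smallest strictly-containing cluster (laminar family)
  parent <- rep(NA_integer_, nfam)
  for (i in seq_len(nfam)[-1L]) {
    best <- NA_integer_
    for (j in seq_len(nfam)) {
      if (sizes[j] <= sizes[i] || !all(fam[[i]] %in% fam[[j]])) next
      if (is.na(best) || sizes[j] < sizes[best]) best <- j
    }
    stopifnot(!is.na(best))
    parent[i] <- best
  }
  # one vertex per cluster; ref attached as a pendant leaf at the top
  refv <- nfam + 1L
  e <- data.frame(v1 = c(parent[-1L], 1L), v2 = c(seq_len(nfam)[-1L], refv),
                  directed = FALSE)
  labels <- setNames(c(match(others, keys), refv), c(others, ref))
  tree <- structure(list(edges = e, labels = labels), class = "sdnet")
  suppress_degree2(tree)
}

# suppress all degree-2 vertices of an undirected sdnet tree
suppress_degree2 <- function(tree) {
  repeat {
    e <- tree$edges
    deg <- net_degree(tree)
    v2s <- as.integer(names(deg)[deg == 2L])
    v2s <- setdiff(v2s, unname(tree$labels))
    if (!length(v2s)) return(tree)
    v <- v2s[1]
    idx <- which(e$v1 == v | e$v2 == v)
    nb <- ifelse(e$v1[idx] == v, e$v2[idx], e$v1[idx])
    e <- e[-idx, , drop = FALSE]
    e <- rbind(e, data.frame(v1 = nb[1], v2 = nb[2], directed = FALSE))
    tree$edges <- e
  }
}

# leaf sets of the branches around vertex v; returns list with `nb` (neighbour
# vertex ids) and `comps` (list of character taxon vectors, parallel to nb)
tree_components <- function(tree, v) {
  e <- tree$edges
  idx <- which(e$v1 == v | e$v2 == v)
  nb <- ifelse(e$v1[idx] == v, e$v2[idx], e$v1[idx])
  comps <- lapply(nb, function(b) {
    reach <- net_reach(tree, b, drop_vertex = v)
    sort(names(tree$labels)[tree$labels %in% reach])
  })
  list(nb = nb, comps = comps, edge_idx = idx)
}

# indices of internal edges (both endpoints unlabeled)
tree_internal_edges <- function(tree) {
  leaves <- unname(tree$labels)
  e <- tree$edges
  which(!(e$v1 %in% leaves) & !(e$v2 %in% leaves))
}

# contract the edge joining vertices u and v (u survives)
contract_tree_edge <- function(tree, u, v) {
  e <- tree$edges
  j <- which((e$v1 == u & e$v2 == v) | (e$v1 == v & e$v2 == u))
  stopifnot(length(j) == 1L)
  e <- e[-j, , drop = FALSE]
  e$v1[e$v1 == v] <- u
  e$v2[e$v2 == v] <- u
  tree$edges <- e
  tree$labels[tree$labels == v] <- u
  tree
}

# taxa on the v1 side of edge i
edge_split_side <- function(tree, i) {
  comp <- net_reach(tree, tree$edges$v1[i], drop_edges = i)
  sort(names(tree$labels)[tree$labels %in% comp])
}

# Newick serialisation of an unrooted tree (rooted arbitrarily); debug aid
tree_newick <- function(tree) {
  e <- tree$edges
  taxa_of <- setNames(names(tree$labels), tree$labels)
  inc <- net_incidence(tree)
  start <- tree$edges$v1[1]
  rec <- function(v, from) {
    idx <- inc[[as.character(v)]]
    kids <- character()
    for (j in idx) {
      u <- if (e$v1[j] == v) e$v2[j] else e$v1[j]
      if (!is.null(from) && u == from) next
      kids <- c(kids, rec(u, v))
    }
    lab <- taxa_of[as.character(v)]
    if (!length(kids)) return(unname(lab))
    paste0("(", paste(kids, collapse = ","), ")",
           if (!is.na(lab)) lab else "")
  }
  paste0(rec(start, NULL), ";")
}
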