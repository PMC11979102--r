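# Semi-directed level-1 networks.
#
# A network is a mixed graph: undirected edges plus directed reticulation
# edges (pointing at reticulation vertices).  One source of truth: edges carry
# a `directed` flag; reticulation vertices are derived (two directed in-edges),
# never stored.

#' Construct a semi-directed network
#'
#' @param edges a data.frame with integer columns `v1`, `v2` and logical
#'   column `directed` (`TRUE` means the edge points `v1 -> v2`).
#' @param labels named integer vector mapping taxon labels to leaf vertex ids.
#' @param validate check the level-1 invariants (default `TRUE`).
#' @param triangle_free additionally forbid 3-cycles when validating.
#' @return an object of class `sdnet`.
#' @export
semidirected_network <- function(edges, labels, validate = TRUE,
                                 triangle_free = TRUE) {
  edges <- data.frame(v1 = as.integer(edges$v1), v2 = as.integer(edges$v2),
                      directed = as.logical(edges$directed))
  net <- structure(list(edges = edges, labels = labels), class = "sdnet")
  if (validate) validate_network(net, triangle_free = triangle_free)
  net
}

#' @export
print.sdnet <- function(x, ...) {
  cat(sprintf("semi-directed network: %d leaves, %d vertices, %d edges, %d reticulations\n",
              length(x$labels), length(net_vertices(x)), nrow(x$edges),
              length(reticulations(x))))
  invisible(x)
}

net_vertices <- function(net) sort(unique(c(net$edges$v1, net$edges$v2)))

net_degree <- function(net) {
  vs <- c(net$edges$v1, net$edges$v2)
  tab <- table(vs)
  setNames(as.integer(tab), names(tab))
}

# adjacency structure: for each vertex (as character id) the incident edge
# indices
net_incidence <- function(net) {
  n <- nrow(net$edges)
  split(c(seq_len(n), seq_len(n)),
        as.character(c(net$edges$v1, net$edges$v2)))
}

#' Reticulation vertices of a network
#'
#' @param net an `sdnet`.
#' @return integer vector of vertex ids with two incoming directed edges.
#' @export
reticulations <- function(net) {
  e <- net$edges
  heads <- e$v2[e$directed]
  as.integer(names(which(table(heads) == 2L)))
}

# BFS over the underlying undirected graph, optionally with some edges or a
# vertex removed.  Returns the set of reached vertices.
net_reach <- function(net, from, drop_edges = integer(), drop_vertex = NULL) {
  e <- net$edges
  keep <- setdiff(seq_len(nrow(e)), drop_edges)
  if (!is.null(drop_vertex))
    keep <- keep[e$v1[keep] != drop_vertex & e$v2[keep] != drop_vertex]
  inc <- split(c(keep, keep), c(e$v1[keep], e$v2[keep]))
  seen <- as.character(from)
  frontier <- from
  while (length(frontier)) {
    ei <- unique(unlist(inc[as.character(frontier)], use.names = FALSE))
    nb <- unique(c(e$v1[ei], e$v2[ei]))
    frontier <- nb[!as.character(nb) %in% seen]
    seen <- c(seen, as.character(frontier))
  }
  as.integer(seen)
}

# shortest path between two vertices avoiding a vertex; NULL if none
net_path <- function(net, from, to, drop_vertex = NULL) {
  e <- net$edges
  keep <- seq_len(nrow(e))
  if (!is.null(drop_vertex))
    keep <- keep[e$v1[keep] != drop_vertex & e$v2[keep] != drop_vertex]
  inc <- split(c(keep, keep), c(e$v1[keep], e$v2[keep]))
  prev <- new.env(parent = emptyenv())
  assign(as.character(from), 0L, envir = prev)
  frontier <- from
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (ei in inc[[as.character(v)]]) {
        u <- if (e$v1[ei] == v) e$v2[ei] else e$v1[ei]
        if (!is.null(get0(as.character(u), envir = prev))) next
        assign(as.character(u), v, envir = prev)
        if (u == to) {
          path <- u
          while (path[1] != from) path <- c(get(as.character(path[1]), envir = prev), path)
          return(path)
        }
        nxt <- c(nxt, u)
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Cycles of a level-1 network
#'
#' @param net an `sdnet`.
#' @return a list with one entry per reticulation: `list(vs, ret, edge_idx)`
#'   where `vs` is the cycle's vertex sequence in cyclic order starting at the
#'   reticulation, and `edge_idx` the indices of the cycle's edges.
#' @export
net_cycles <- function(net) {
  e <- net$edges
  rets <- reticulations(net)
  lapply(rets, function(r) {
    par <- e$v1[e$directed & e$v2 == r]
    stopifnot(length(par) == 2L)
    path <- if (par[1] == par[2]) par[1] else net_path(net, par[1], par[2], drop_vertex = r)
    if (is.null(path)) stop("reticulation ", r, " lies on no cycle")
    vs <- c(r, path)
    k <- length(vs)
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    want <- pair_key(vs, vs[c(2:k, 1)])
    idx <- match(want, pair_key(e$v1, e$v2))
    stopifnot(!anyNA(idx))
    list(vs = vs, ret = r, edge_idx = idx)
  })
}

#' Validate the semi-directed level-1 network invariants
#'
#' Checks connectivity, absence of parallel edges, binary degrees, the
#' reticulation structure, vertex-disjointness of cycles, and (optionally)
#' triangle-freeness.
#'
#' @param net an `sdnet`.
#' @param triangle_free forbid 3-cycles.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_network <- function(net, triangle_free = TRUE) {
  e <- net$edges
  if (anyDuplicated(paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))))
    stop("parallel edges present")
  if (any(e$v1 == e$v2)) stop("self-loop present")
  deg <- net_degree(net)
  vs <- net_vertices(net)
  leaves <- unname(net$labels)
  if (anyDuplicated(net$labels) || anyDuplicated(names(net$labels)))
    stop("taxon labels must be unique")
  if (!all(deg[as.character(leaves)] == 1L))
    stop("labeled leaves must have degree 1")
  internal <- setdiff(vs, leaves)
  if (!all(deg[as.character(internal)] == 3L))
    stop("internal vertices must have degree 3")
  if (any(deg[as.character(internal)] == 1L))
    stop("unlabeled leaf present")
  if (length(net_reach(net, vs[1])) != length(vs)) stop("network not connected")
  rets <- reticulations(net)
  heads <- e$v2[e$directed]
  if (!all(table(heads) == 2L)) stop("directed edge whose head is not a reticulation")
  if (length(rets) != nrow(e) - length(vs) + 1L)
    stop("cycle count does not match reticulation count (not level-1)")
  cyc <- net_cycles(net)
  cyc_vs <- unlist(lapply(cyc, `[[`, "vs"))
  if (anyDuplicated(cyc_vs)) stop("cycles are not vertex-disjoint (not level-1)")
  if (any(vapply(cyc, function(cc) length(cc$vs), 0L) < 3L))
    stop("degenerate cycle")
  if (triangle_free && any(vapply(cyc, function(cc) length(cc$vs), 0L) == 3L))
    stop("network contains a triangle")
  invisible(TRUE)
}

#' Splits of a semi-directed network
#'
#' All splits realised by removing a single edge (reticulation edges included,
#' ignoring direction).  Edges on cycles do not disconnect the network and
#' yield no split.
#'
#' @param net an `sdnet`.
#' @param nontrivial_only drop splits with a side of size < 2.
#' @return a list of splits, each a list with sorted character vectors `A` and
#'   `B` (`A` contains the overall smallest taxon) and a canonical `id` string.
#' @export
network_splits <- function(net, nontrivial_only = FALSE) {
  e <- net$edges
  taxa <- sort(names(net$labels))
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(e))) {
    comp <- net_reach(net, e$v1[i], drop_edges = i)
    if (e$v2[i] %in% comp) next
    inA <- net$labels %in% comp
    A <- sort(names(net$labels)[inA]); B <- sort(names(net$labels)[!inA])
    if (length(A) == 0L || length(B) == 0L) next
    if (nontrivial_only && min(length(A), length(B)) < 2L) next
    if (!taxa[1] %in% A) { tmp <- A; A <- B; B <- tmp }
    id <- paste(paste(A, collapse = ","), paste(B, collapse = ","), sep = "|")
    if (id %in% seen) next
    seen <- c(seen, id)
    out[[length(out) + 1L]] <- list(A = A, B = B, id = id)
  }
  out
}

#' Blobtree (tree of blobs) of a level-1 network
#'
#' Every cycle is collapsed to a single vertex; the result is an unrooted,
#' possibly multifurcating, leaf-labeled tree with no degree-2 vertices.
#'
#' @param net an `sdnet`.
#' @return an `sdnet` that is a tree (no directed edges).
#' @export
blobtree <- function(net) {
  e <- net$edges
  vs <- net_vertices(net)
  grp <- setNames(vs, as.character(vs))  # representative per vertex
  cyc <- net_cycles(net)
  for (cc in cyc) grp[as.character(cc$vs)] <- min(cc$vs)
  cyc_edges <- unlist(lapply(cyc, `[[`, "edge_idx"))
  keep <- setdiff(seq_len(nrow(e)), cyc_edges)
  ne <- data.frame(v1 = unname(grp[as.character(e$v1[keep])]),
                   v2 = unname(grp[as.character(e$v2[keep])]),
                   directed = FALSE)
  labels <- setNames(unname(grp[as.character(net$labels)]), names(net$labels))
  structure(list(edges = ne, labels = labels), class = "sdnet")
}

# taxa attached to each vertex of a cycle: remove the cycle's edges and find,
# for each cycle vertex, the taxa in its component.  Returns a named integer
# vector att[taxon] = position (1-based, along cc$vs) of its attachment.
cycle_attachments <- function(net, cc) {
  att <- integer(length(net$labels))
  names(att) <- names(net$labels)
  for (k in seq_along(cc$vs)) {
    comp <- net_reach(net, cc$vs[k], drop_edges = cc$edge_idx)
    hit <- net$labels %in% comp
    att[hit] <- k
  }
  stopifnot(all(att > 0L))
  att
}

# ---- rooting ----------------------------------------------------------------

#' Valid root edges of a semi-directed network
#'
#' An edge is a valid root location if subdividing it with a root and orienting
#' all undirected edges away from the root yields a valid rooted network while
#' keeping the given directions of the reticulation edges.  For a level-1
#' network this holds iff the edge is not itself a reticulation edge and, for
#' every cycle, the edge does not lie in the part of the network hanging below
#' that cycle's reticulation.
#'
#' @param net an `sdnet` (partially expanded networks, i.e. trees with some
#'   cycles, are fine).
#' @param outgroup optional taxon; restricts candidates to its pendant edge.
#' @return integer vector of edge indices into `net$edges` (possibly empty).
#' @export
valid_root_edges <- function(net, outgroup = NULL) {
  e <- net$edges
  cand <- which(!e$directed)
  if (!is.null(outgroup)) {
    lv <- net$labels[[outgroup]]
    if (is.null(lv)) stop("unknown outgroup taxon: ", outgroup)
    pend <- which((e$v1 == lv | e$v2 == lv))
    cand <- intersect(cand, pend)
  }
  if (!length(cand)) return(integer())
  cyc <- net_cycles(net)
  bad <- integer()
  for (cc in cyc) {
    comp <- net_reach(net, cc$ret, drop_edges = cc$edge_idx)
    below <- which(e$v1 %in% comp & e$v2 %in% comp)
    bad <- union(bad, setdiff(below, cc$edge_idx))
  }
  setdiff(cand, bad)
}

#' Root a semi-directed network
#'
#' Subdivides an edge with a new root vertex and orients every edge away from
#' it.  With an outgroup the root is placed on the outgroup's pendant edge;
#' without one, an arbitrary valid edge is chosen (the first in edge order).
#'
#' @param net an `sdnet`.
#' @param outgroup optional taxon label.
#' @param edge optional explicit edge index (overrides `outgroup`).
#' @return an object of class `rooted_net` with fields `edges` (data.frame
#'   `parent`, `child`), `root` and `labels`.
#' @export
root_network <- function(net, outgroup = NULL, edge = NULL) {
  if (is.null(edge)) {
    ok <- valid_root_edges(net, outgroup)
    if (!length(ok))
      stop(if (is.null(outgroup)) "network has no valid root edge"
           else paste0("no valid root at outgroup '", outgroup, "'"))
    edge <- ok[1]
  }
  r <- try_root_at_edge(net, edge)
  if (is.null(r)) stop("edge ", edge, " is not a valid root location")
  r
}

# Orient-and-check: subdivide edge i with a root, orient away from it by BFS.
# Returns a rooted_net, or NULL if the orientation is not a valid rooted
# network.  Used both by root_network() and, independently, as the brute-force
# oracle for valid_root_edges() in the tests.
try_root_at_edge <- function(net, i) {
  e <- net$edges
  if (e$directed[i]) return(NULL)
  root <- max(net_vertices(net)) + 1L
  e2 <- rbind(e[-i, , drop = FALSE],
              data.frame(v1 = root, v2 = e$v1[i], directed = FALSE),
              data.frame(v1 = root, v2 = e$v2[i], directed = FALSE))
  m <- nrow(e2)
  parent <- integer(m); child <- integer(m)
  done <- logical(m)
  visited <- root
  repeat {
    progressed <- FALSE
    for (j in seq_len(m)) {
      if (done[j]) next
      a <- e2$v1[j]; b <- e2$v2[j]
      if (e2$directed[j]) {
        if (a %in% visited) {
          parent[j] <- a; child[j] <- b; done[j] <- TRUE
          if (!b %in% visited) visited <- c(visited, b)
          progressed <- TRUE
        }
      } else if (a %in% visited) {
        parent[j] <- a; child[j] <- b; done[j] <- TRUE
        if (!b %in% visited) visited <- c(visited, b)
        progressed <- TRUE
      } else if (b %in% visited) {
        parent[j] <- b; child[j] <- a; done[j] <- TRUE
        if (!a %in% visited) visited <- c(visited, a)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  if (!all(done)) return(NULL)
  rn <- structure(list(edges = data.frame(parent = parent, child = child),
                       root = root, labels = net$labels),
                  class = "rooted_net")
  if (!rooted_valid(rn, net)) return(NULL)
  rn
}

# validity of an orientation: degree pattern + preserved reticulation edges
rooted_valid <- function(rn, net) {
  ed <- rn$edges
  indeg <- table(factor(ed$child, levels = unique(c(ed$parent, ed$child))))
  outdeg <- table(factor(ed$parent, levels = unique(c(ed$parent, ed$child))))
  vs <- unique(c(ed$parent, ed$child))
  leaves <- unname(rn$labels)
  for (v in vs) {
    iv <- indeg[[as.character(v)]]; ov <- outdeg[[as.character(v)]]
    ok <- if (v == rn$root) iv == 0L && ov == 2L
          else if (v %in% leaves) iv == 1L && ov == 0L
          else (iv == 1L && ov == 2L) || (iv == 2L && ov == 1L)
    if (!ok) return(FALSE)
  }
  # original directed edges must keep their orientation
  e <- net$edges
  for (j in which(e$directed)) {
    hit <- which(ed$parent == e$v1[j] & ed$child == e$v2[j])
    if (!length(hit)) return(FALSE)
  }
  # acyclicity: topological order must exist
  is_dag(ed, rn$root)
}

is_dag <- function(ed, root) {
  vs <- unique(c(ed$parent, ed$child))
  indeg <- setNames(tabulate(match(ed$child, vs), length(vs)), vs)
  queue <- vs[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(ed$parent == v)
    for (j in out) {
      c_ <- as.character(ed$child[j])
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, ed$child[j])
    }
  }
  seen == length(vs)
}

#' @export
print.rooted_net <- function(x, ...) {
  cat(sprintf("rooted network: %d leaves, %d edges, root vertex %d\n",
              length(x$labels), nrow(x$edges), x$root))
  invisible(x)
}

#' Un-root a rooted network back to its semi-directed topology
#'
#' The root is suppressed (its two child edges are merged) and all edges except
#' those entering reticulations are undirected.
#'
#' @param rooted a `rooted_net`.
#' @return an `sdnet`.
#' @export
as_semidirected <- function(rooted) {
  ed <- rooted$edges
  rets <- as.integer(names(which(table(ed$child) == 2L)))
  at_root <- which(ed$parent == rooted$root)
  stopifnot(length(at_root) == 2L)
  ch <- ed$child[at_root]
  keep <- ed[-at_root, , drop = FALSE]
  e <- data.frame(v1 = keep$parent, v2 = keep$child,
                  directed = keep$child %in% rets)
  # joining edge between the root's former children
  join_dir <- ch %in% rets
  stopifnot(sum(join_dir) <= 1L)
  if (join_dir[2]) {
    e <- rbind(e, data.frame(v1 = ch[1], v2 = ch[2], directed = TRUE))
  } else if (join_dir[1]) {
    e <- rbind(e, data.frame(v1 = ch[2], v2 = ch[1], directed = TRUE))
  } else {
    e <- rbind(e, data.frame(v1 = ch[1], v2 = ch[2], directed = FALSE))
  }
  semidirected_network(e, rooted$labels, validate = FALSE)
}

# ---- isomorphism ------------------------------------------------------------

#' Label-respecting isomorphism of semi-directed networks
#'
#' Vertices are coloured by taxon identity (leaves), reticulation status
#' (internal); because the direction of reticulation edges is determined by
#' which vertex is the reticulation, VF2 on the coloured underlying undirected
#' graph decides isomorphism of the semi-directed networks.
#'
#' @param a,b two `sdnet` objects.
#' @return logical.
#' @export
network_isomorphic <- function(a, b) {
  if (!setequal(names(a$labels), names(b$labels))) return(FALSE)
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  taxa <- sort(names(a$labels))
  colorize <- function(net) {
    vs <- net_vertices(net)
    col <- integer(length(vs)) # 0 = internal tree vertex
    col[match(reticulations(net), vs)] <- 1L
    col[match(unname(net$labels), vs)] <- 1L + match(names(net$labels), taxa)
    g <- igraph::graph_from_edgelist(
      cbind(match(net$edges$v1, vs), match(net$edges$v2, vs)),
      directed = FALSE)
    list(g = g, col = col)
  }
  ga <- colorize(a); gb <- colorize(b)
  igraph::is_isomorphic_to(ga$g, gb$g, method = "vf2",
                           vertex.color1 = ga$col, vertex.color2 = gb$col)
}

# ---- convenience constructors ----------------------------------------------

#' Convert an ape "phylo" tree to a semi-directed network
#'
#' @param phy an `ape::phylo` object (will be unrooted; must be binary).
#' @return an `sdnet` with no reticulations.
#' @export
sdnet_from_phylo <- function(phy) {
  phy <- ape::unroot(phy)
  e <- data.frame(v1 = phy$edge[, 1], v2 = phy$edge[, 2], directed = FALSE)
  labels <- setNames(seq_along(phy$tip.label), phy$tip.label)
  semidirected_network(e, labels, validate = FALSE)
}

#' Single-cycle network with pendant leaves
#'
#' Builds the level-1 network consisting of one cycle of length
#' `length(order)` whose vertices each carry one pendant leaf, labeled in the
#' given cyclic order, with the reticulation at the attachment of `ret`.
#'
#' @param order character vector (length >= 4) of taxa in cyclic order.
#' @param ret the taxon whose attachment vertex is the reticulation.
#' @return an `sdnet`.
#' @export
cycle_network <- function(order, ret) {
  s <- length(order)
  stopifnot(s >= 4L, ret %in% order, !anyDuplicated(order))
  leaf <- seq_len(s)              # leaf i  <-> order[i]
  cyc <- s + seq_len(s)           # cycle vertex i above leaf i
  ri <- match(ret, order)
  nb <- function(i) cyc[(i - 1L) %% s + 1L]
  e <- data.frame(v1 = integer(), v2 = integer(), directed = logical())
  for (i in seq_len(s)) {
    e <- rbind(e, data.frame(v1 = cyc[i], v2 = leaf[i], directed = FALSE))
    a <- cyc[i]; b <- nb(i + 1L)
    dir_to <- if (b == cyc[ri]) b else if (a == cyc[ri]) a else NA
    if (is.na(dir_to)) {
      e <- rbind(e, data.frame(v1 = a, v2 = b, directed = FALSE))
    } else {
      e <- rbind(e, data.frame(v1 = setdiff(c(a, b), dir_to), v2 = dir_to,
                               directed = TRUE))
    }
  }
  semidirected_network(e, setNames(leaf, order), validate = FALSE)
}
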