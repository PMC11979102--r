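# Step B3 / Algorithm level: expanding high-degree blobtree vertices into
# cycles to obtain a semi-directed level-1 network.

#' Expand the multifurcations of a candidate blobtree into cycles
#'
#' Every internal vertex of degree `s >= 4` (processed in decreasing order of
#' degree) is replaced by an `s`-cycle: representative quarnets give pairwise
#' distances, a TSP tour gives the circular ordering, and the reticulation is
#' placed at the highest entry of the reticulation ranking that leaves the
#' partial network rootable (at the outgroup when one is given).
#'
#' @param tree an `sdnet` tree (candidate blobtree).
#' @param Q a `dense_quarnets` object on the tree's taxa.
#' @param outgroup optional taxon; all returned networks are rootable at its
#'   pendant edge.
#' @param tsp_mode `"auto"`, `"exact"` or `"anneal"` (see [solve_tsp()]).
#' @param rank_mode passed to [reticulation_ranking()].
#' @return an `sdnet`: a binary triangle-free semi-directed level-1 network.
#' @export
expand_tree <- function(tree, Q, outgroup = NULL,
                        tsp_mode = c("auto", "exact", "anneal"),
                        rank_mode = "ret", cache = NULL) {
  tsp_mode <- match.arg(tsp_mode)
  net <- tree
  repeat {
    deg <- net_degree(net)
    internal <- setdiff(as.integer(names(deg)[deg >= 4L]), unname(net$labels))
    if (!length(internal)) break
    # decreasing degree; ties by smallest taxon reachable (determinism)
    mintax <- vapply(internal, function(v) {
      tc <- tree_components(net, v)
      min(vapply(tc$comps, function(x) x[1], ""))
    }, "")
    v <- internal[order(-deg[as.character(internal)], mintax)][1L]
    net <- expand_vertex(net, v, Q, outgroup, tsp_mode, rank_mode, cache)
  }
  validate_network(net)
  net
}

expand_vertex <- function(net, v, Q, outgroup, tsp_mode, rank_mode,
                          cache = NULL) {
  tc <- tree_components(net, v)
  s <- length(tc$nb)
  f <- character(length(Q$taxa)); names(f) <- Q$taxa
  for (cmp in tc$comps) f[cmp] <- cmp[1]
  # the tour and ranking depend only on the partition (and Q), which recurs
  # across the candidate sequence; cache them when the driver provides one
  ckey <- paste(f, collapse = "|")
  hit <- if (!is.null(cache)) get0(ckey, envir = cache) else NULL
  if (!is.null(hit)) {
    theta <- hit$theta; rho <- hit$rho
  } else {
    rep_set <- representative_from_f(Q, f)
    D <- quarnet_distances(rep_set)
    theta <- solve_tsp(D, mode = tsp_mode)
    rho <- reticulation_ranking(rep_set, mode = rank_mode)
    if (!is.null(cache))
      assign(ckey, list(theta = theta, rho = rho), envir = cache)
  }
  comp_labels <- vapply(tc$comps, function(x) x[1], "")
  nb_of <- setNames(tc$nb, comp_labels)      # component label -> branch vertex
  base <- net
  base$edges <- base$edges[-tc$edge_idx, , drop = FALSE]
  cyc_ids <- max(net_vertices(net)) + seq_len(s)
  names(cyc_ids) <- theta                    # cycle vertex per component label
  for (j in seq_along(rho)) {
    cand <- base
    e <- cand$edges
    for (k in seq_len(s)) {
      lab <- theta[k]
      e <- rbind(e, data.frame(v1 = cyc_ids[[lab]], v2 = nb_of[[lab]],
                               directed = FALSE))
    }
    retv <- cyc_ids[[rho[j]]]
    for (k in seq_len(s)) {
      a <- cyc_ids[[theta[k]]]
      b <- cyc_ids[[theta[if (k == s) 1L else k + 1L]]]
      if (b == retv) {
        e <- rbind(e, data.frame(v1 = a, v2 = b, directed = TRUE))
      } else if (a == retv) {
        e <- rbind(e, data.frame(v1 = b, v2 = a, directed = TRUE))
      } else {
        e <- rbind(e, data.frame(v1 = a, v2 = b, directed = FALSE))
      }
    }
    cand$edges <- e
    if (length(valid_root_edges(cand, outgroup))) return(cand)
  }
  stop("no reticulation placement leaves the network rootable (should not happen)")
}
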