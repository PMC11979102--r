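# Step A2: refining the Q*-tree with an adaptation of QuartetJoining.
#
# At each internal vertex of degree >= 4, every pair of neighbour components
# {Xi, Xj} is scored by the mean omega-value over all splits x x'|y y' with
# x in Xi, x' in Xj and y, y' in two distinct other components; the best pair
# is made siblings.  A pair is only joined when its score is strictly
# positive: with no positive evidence the vertex stays unresolved (this is
# what lets the blobtree of a pure-cycle network survive into the candidate
# sequence).

#' Split-weight function omega from a dense quarnet set
#'
#' Every quartet tree `ab|cd` of weight `w` contributes `omega(ab|cd) = w`;
#' all other 4-leaf splits have weight 0 (4-cycles contribute nothing).
#'
#' @param Q a `dense_quarnets` object.
#' @return an object of class `split_weights`: a data.frame with the split
#'   columns `x1..x4` ( split `{x1,x2}|{x3,x4}` ) and `w`.
#' @export
omega_from_quarnets <- function(Q) {
  tab <- Q$tab[Q$tab$type == "quartet", , drop = FALSE]
  out <- data.frame(x1 = tab$x1, x2 = tab$x2, x3 = tab$x3, x4 = tab$x4,
                    w = tab$weight, stringsAsFactors = FALSE)
  class(out) <- c("split_weights", "data.frame")
  out
}

#' Look up omega for one split
#'
#' @param omega a `split_weights` object.
#' @param side1,side2 the two sides (length-2 character vectors).
#' @return numeric weight (0 for unseen splits).
#' @export
omega_value <- function(omega, side1, side2) {
  x <- canon_split(side1, side2)
  hit <- omega$x1 == x[1] & omega$x2 == x[2] & omega$x3 == x[3] & omega$x4 == x[4]
  if (any(hit)) sum(omega$w[hit]) else 0
}

# score all component pairs at a vertex in one pass over the omega table.
# comp: named integer vector taxon -> component id (1..s); sizes: per comp.
# Returns an s x s matrix of mean scores (NA on the diagonal).
qj_pair_scores <- function(omega, comp, sizes) {
  s <- length(sizes)
  num <- matrix(0, s, s)
  if (nrow(omega)) {
    c1 <- comp[omega$x1]; c2 <- comp[omega$x2]
    c3 <- comp[omega$x3]; c4 <- comp[omega$x4]
    ok12 <- c1 != c2 & c3 != c4 & c3 != c1 & c3 != c2 & c4 != c1 & c4 != c2
    # each split contributes to the pair of its first side and (symmetrically)
    # to the pair of its second side; same validity condition either way
    k <- which(ok12 & omega$w != 0)
    if (length(k)) {
      li <- c((c2[k] - 1L) * s + c1[k], (c1[k] - 1L) * s + c2[k],
              (c4[k] - 1L) * s + c3[k], (c3[k] - 1L) * s + c4[k])
      agg <- rowsum(rep(omega$w[k], times = 4L), li)
      num[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  tot <- sum(sizes)
  prodsum_all <- (tot^2 - sum(sizes^2)) / 2
  den <- matrix(NA_real_, s, s)
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    rest <- prodsum_all - sizes[i] * (tot - sizes[i]) -
      sizes[j] * (tot - sizes[j]) + sizes[i] * sizes[j]
    den[i, j] <- den[j, i] <- sizes[i] * sizes[j] * rest
  }
  sc <- num / den
  diag(sc) <- NA_real_
  sc
}

#' Refine a tree by adapted QuartetJoining
#'
#' Resolves internal vertices of degree >= 4 by repeatedly joining the pair of
#' neighbour components with the highest positive mean omega score.  Ties are
#' broken by the lexicographically smallest component labels (a component is
#' labeled by its smallest taxon).  Vertices with no positively scored pair
#' are left unresolved.
#'
#' @param tstar an `sdnet` tree (e.g. from [build_qstar_tree()]).
#' @param omega a `split_weights` object (see [omega_from_quarnets()]).
#' @return an `sdnet` tree refining `tstar`; binary whenever omega provides
#'   positive guidance at every multifurcation.
#' @export
refine_quartetjoining <- function(tstar, omega) {
  tree <- tstar
  repeat {
    deg <- net_degree(tree)
    internal <- setdiff(as.integer(names(deg)[deg >= 4L]), unname(tree$labels))
    if (!length(internal)) break
    progressed <- FALSE
    for (v in sort(internal)) {
      tree2 <- qj_resolve_vertex(tree, v, omega)
      if (!is.null(tree2)) { tree <- tree2; progressed <- TRUE }
    }
    if (!progressed) break
  }
  tree
}

# resolve vertex v as far as positive evidence allows; NULL if nothing joined
qj_resolve_vertex <- function(tree, v, omega) {
  changed <- FALSE
  repeat {
    tc <- tree_components(tree, v)
    s <- length(tc$nb)
    if (s <= 3L) break
    comp <- integer(length(tree$labels))
    names(comp) <- names(tree$labels)
    for (i in seq_len(s)) comp[tc$comps[[i]]] <- i
    sizes <- vapply(tc$comps, length, 0L)
    sc <- qj_pair_scores(omega, comp, sizes)
    best <- max(sc, na.rm = TRUE)
    if (!is.finite(best) || best <= 0) break
    # candidates at the max; tie-break by sorted component labels
    labs <- vapply(tc$comps, function(x) x[1], "")
    idx <- which(sc >= best - 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    keys <- apply(idx, 1L, function(r) paste(sort(labs[r]), collapse = "\r"))
    pickrow <- idx[order(keys)[1L], ]
    i <- pickrow[1]; j <- pickrow[2]
    # join components i and j under a new vertex
    w <- max(net_vertices(tree)) + 1L
    e <- tree$edges
    e <- e[-tc$edge_idx[c(i, j)], , drop = FALSE]
    e <- rbind(e,
               data.frame(v1 = v, v2 = w, directed = FALSE),
               data.frame(v1 = w, v2 = tc$nb[i], directed = FALSE),
               data.frame(v1 = w, v2 = tc$nb[j], directed = FALSE))
    tree$edges <- e
    changed <- TRUE
  }
  if (changed) tree else NULL
}
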