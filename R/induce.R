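# Restriction of a network to four leaves (tf-quarnet induction).
#
# Two routes are provided.  induced_tf_quarnet() applies the five reduction
# operations (delete unlabeled leaves, delete degree-2 reticulations, suppress
# nonreticulate degree-2 vertices, suppress parallel edges, suppress
# triangles) to a fixpoint, which is the defining construction.
# induced_quarnets() computes the whole dense set with an equivalent
# combinatorial shortcut (cycle attachments + four-point rule on blobtree
# distances); the two routes are cross-checked in the test suite.

#' Restrict a network to four taxa (reduction fixpoint)
#'
#' @param net an `sdnet`.
#' @param taxa4 a 4-subset of the network's taxa.
#' @param shuffle apply the reduction operations in random order (used to
#'   check confluence); the default applies them in a fixed order.
#' @return a `tf_quarnet` of weight 1.
#' @export
induced_tf_quarnet <- function(net, taxa4, shuffle = FALSE) {
  taxa4 <- unique(taxa4)
  if (length(taxa4) != 4L || !all(taxa4 %in% names(net$labels)))
    stop("taxa4 must be a 4-subset of the network's taxa")
  e <- net$edges
  labels <- net$labels[taxa4]
  repeat {
    e <- undirect_nonret(e)
    ops <- find_reductions(e, labels)
    if (!length(ops)) break
    op <- if (shuffle) ops[[sample.int(length(ops), 1L)]] else ops[[1L]]
    e <- apply_reduction(e, op)
  }
  classify_quarnet(e, labels)
}

# undirect any directed edge whose head is no longer a reticulation
undirect_nonret <- function(e) {
  repeat {
    indeg <- table(e$v2[e$directed])
    fix <- e$directed & !(as.character(e$v2) %in% names(indeg)[indeg == 2L])
    if (!any(fix)) return(e)
    e$directed[fix] <- FALSE
  }
}

find_reductions <- function(e, labels) {
  ops <- list()
  vs <- sort(unique(c(e$v1, e$v2)))
  deg <- tabulate(match(c(e$v1, e$v2), vs), length(vs))
  indeg2 <- names(which(table(e$v2[e$directed]) == 2L))
  is_ret <- vs %in% as.integer(indeg2)
  # 1. unlabeled leaves
  for (v in vs[deg == 1L & !(vs %in% labels)])
    ops[[length(ops) + 1L]] <- list(op = "leaf", v = v)
  # 2. degree-2 reticulations
  for (v in vs[deg == 2L & is_ret])
    ops[[length(ops) + 1L]] <- list(op = "deg2ret", v = v)
  # 3. parallel edges
  pk <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
  dup <- which(duplicated(pk))
  for (j in dup)
    ops[[length(ops) + 1L]] <- list(op = "parallel", j = j)
  # 4. suppress nonreticulate degree-2 vertices (not between parallel edges)
  for (v in vs[deg == 2L & !is_ret]) {
    idx <- which(e$v1 == v | e$v2 == v)
    nb <- ifelse(e$v1[idx] == v, e$v2[idx], e$v1[idx])
    if (nb[1] == nb[2]) next # parallel pair; handled above
    ops[[length(ops) + 1L]] <- list(op = "suppress", v = v)
  }
  # 5. triangles
  tri <- find_triangle(e)
  if (!is.null(tri)) ops[[length(ops) + 1L]] <- list(op = "triangle", vs = tri)
  ops
}

find_triangle <- function(e) {
  pk <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
  for (j in seq_len(nrow(e))) {
    a <- e$v1[j]; b <- e$v2[j]
    # common neighbours of a and b
    nb_a <- c(e$v2[e$v1 == a], e$v1[e$v2 == a])
    nb_b <- c(e$v2[e$v1 == b], e$v1[e$v2 == b])
    com <- setdiff(intersect(nb_a, nb_b), c(a, b))
    if (length(com)) return(c(a, b, com[1]))
  }
  NULL
}

apply_reduction <- function(e, op) {
  switch(op$op,
    leaf = {
      e[e$v1 != op$v & e$v2 != op$v, , drop = FALSE]
    },
    deg2ret = {
      e[e$v1 != op$v & e$v2 != op$v, , drop = FALSE]
    },
    parallel = {
      j <- op$j
      pk <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
      twin <- setdiff(which(pk == pk[j]), j)[1]
      same_head <- e$directed[j] && e$directed[twin] && e$v2[j] == e$v2[twin]
      if (!same_head) e$directed[twin] <- FALSE
      e[-j, , drop = FALSE]
    },
    suppress = {
      v <- op$v
      idx <- which(e$v1 == v | e$v2 == v)
      stopifnot(length(idx) == 2L)
      ends <- integer(2); head <- NA_integer_
      for (k in 1:2) {
        j <- idx[k]
        other <- if (e$v1[j] == v) e$v2[j] else e$v1[j]
        ends[k] <- other
        if (e$directed[j]) {
          stopifnot(e$v1[j] == v) # after normalisation only out-edges remain
          stopifnot(is.na(head))
          head <- other
        }
      }
      e <- e[-idx, , drop = FALSE]
      newe <- if (is.na(head))
        data.frame(v1 = ends[1], v2 = ends[2], directed = FALSE)
      else
        data.frame(v1 = setdiff(ends, head)[1], v2 = head, directed = TRUE)
      rbind(e, newe)
    },
    triangle = {
      keepv <- min(op$vs); drop <- setdiff(op$vs, keepv)
      inside <- (e$v1 %in% op$vs) & (e$v2 %in% op$vs)
      e <- e[!inside, , drop = FALSE]
      e$v1[e$v1 %in% drop] <- keepv
      e$v2[e$v2 %in% drop] <- keepv
      e
    },
    stop("unknown reduction"))
}

classify_quarnet <- function(e, labels) {
  e <- undirect_nonret(e)
  vs <- sort(unique(c(e$v1, e$v2)))
  deg <- tabulate(match(c(e$v1, e$v2), vs), length(vs))
  stopifnot(all(labels %in% vs), all(deg[match(labels, vs)] == 1L))
  taxa_of <- setNames(names(labels), labels)
  if (!any(e$directed)) {
    stopifnot(length(vs) == 6L, nrow(e) == 5L)
    internal <- vs[deg == 3L]
    stopifnot(length(internal) == 2L)
    side <- function(iv) {
      nb <- c(e$v2[e$v1 == iv], e$v1[e$v2 == iv])
      taxa_of[as.character(intersect(nb, labels))]
    }
    tfq_quartet(unname(side(internal[1])), unname(side(internal[2])), 1)
  } else {
    stopifnot(length(vs) == 8L, nrow(e) == 8L)
    tmp <- structure(list(edges = e, labels = labels), class = "sdnet")
    cyc <- net_cycles(tmp)
    stopifnot(length(cyc) == 1L, length(cyc[[1]]$vs) == 4L)
    pend <- vapply(cyc[[1]]$vs, function(v) {
      nb <- c(e$v2[e$v1 == v], e$v1[e$v2 == v])
      as.character(intersect(nb, labels))
    }, "")
    ord <- unname(taxa_of[pend])
    tfq_cycle(ord, ord[1], 1) # cycle vs starts at the reticulation
  }
}

# ---- fast dense induced set --------------------------------------------------

# pairwise topological leaf distances in a tree (sdnet with no reticulations)
tree_leaf_distances <- function(tree) {
  e <- tree$edges
  vs <- net_vertices(tree)
  idx <- function(v) match(v, vs)
  adj <- vector("list", length(vs))
  for (j in seq_len(nrow(e))) {
    a <- idx(e$v1[j]); b <- idx(e$v2[j])
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  n <- length(tree$labels)
  taxa <- sort(names(tree$labels))
  D <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (t in taxa) {
    d <- rep(NA_integer_, length(vs))
    s <- idx(tree$labels[[t]])
    d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (u in adj[[v]]) if (is.na(d[u])) {
        d[u] <- d[v] + 1L; nxt <- c(nxt, u)
      }
      frontier <- nxt
    }
    D[t, ] <- d[idx(tree$labels[taxa])]
  }
  D
}

#' Dense set of tf-quarnets induced by a network
#'
#' One unit-weight tf-quarnet per 4-subset of the taxa.  Uses the level-1
#' structure (cycle attachments, blobtree distances) rather than running the
#' reduction fixpoint per subset; equivalent to [induced_tf_quarnet()] on
#' every 4-subset.
#'
#' @param net an `sdnet`.
#' @return a `dense_quarnets` object.
#' @export
induced_quarnets <- function(net) {
  taxa <- sort(names(net$labels))
  n <- length(taxa)
  stopifnot(n >= 4L)
  sub <- combn(n, 4L)             # 4 x N taxon indices (ascending)
  N <- ncol(sub)
  TT <- matrix(taxa[sub], nrow = 4L)
  key <- paste(TT[1, ], TT[2, ], TT[3, ], TT[4, ], sep = "|")

  cyc <- net_cycles(net)
  atts <- lapply(cyc, function(cc) cycle_attachments(net, cc)[taxa])

  type <- rep(NA_character_, N)
  X <- matrix(NA_character_, N, 4L)
  ret <- rep(NA_character_, N)

  # (a) subsets separated into 4 parts around some cycle
  for (att in atts) {
    P <- matrix(att[sub], nrow = 4L)
    d4 <- P[1, ] != P[2, ] & P[1, ] != P[3, ] & P[1, ] != P[4, ] &
          P[2, ] != P[3, ] & P[2, ] != P[4, ] & P[3, ] != P[4, ]
    rows <- which(d4 & is.na(type))
    if (!length(rows)) next
    Pr <- P[, rows, drop = FALSE]; Tr <- TT[, rows, drop = FALSE]
    R <- matrix(0L, 4L, length(rows))
    for (i in 1:4) R[i, ] <- 1L + colSums(Pr < rep(Pr[i, ], each = 4L))
    ord <- matrix(NA_character_, length(rows), 4L)
    for (j in 1:4) ord[, j] <- Tr[R == j]
    has_ret <- colSums(Pr == 1L) > 0L   # reticulation is cycle position 1
    if (any(has_ret)) {
      rr <- rows[has_ret]
      X[rr, ] <- canon_cycle4_m(ord[has_ret, , drop = FALSE])
      ret[rr] <- Tr[Pr == 1L]
      type[rr] <- "cycle4"
    }
    if (any(!has_ret)) {
      # reticulation deleted: cycle opens between the wrap-around pair
      rr <- rows[!has_ret]
      m <- ord[!has_ret, , drop = FALSE]
      X[rr, ] <- canon_split_m(m) # split {y1,y2}|{y3,y4} in path order
      type[rr] <- "quartet"
    }
  }

  # (b) remaining subsets: quartet via four-point rule on blobtree distances
  todo <- which(is.na(type))
  if (length(todo)) {
    D <- tree_leaf_distances(blobtree(net))
    a <- TT[1, todo]; b <- TT[2, todo]; c_ <- TT[3, todo]; d <- TT[4, todo]
    s1 <- D[cbind(a, b)] + D[cbind(c_, d)]
    s2 <- D[cbind(a, c_)] + D[cbind(b, d)]
    s3 <- D[cbind(a, d)] + D[cbind(b, c_)]
    tie <- s1 == s2 & s2 == s3
    pick <- max.col(-cbind(s1, s2, s3), ties.method = "first")
    m <- matrix(NA_character_, length(todo), 4L)
    w1 <- pick == 1L & !tie; w2 <- pick == 2L & !tie; w3 <- pick == 3L & !tie
    m[w1, ] <- cbind(a, b, c_, d)[w1, ]
    m[w2, ] <- cbind(a, c_, b, d)[w2, ]
    m[w3, ] <- cbind(a, d, b, c_)[w3, ]
    if (any(tie)) {
      # four paths meet in a single blob with exactly 3 attachment points:
      # the two taxa sharing an attachment stay together
      for (att in atts) {
        rows <- which(tie & is.na(m[, 1L]))
        if (!length(rows)) break
        P <- matrix(att[sub[, todo[rows], drop = FALSE]], nrow = 4L)
        for (kk in seq_along(rows)) {
          p <- P[, kk]
          if (length(unique(p)) != 3L) next
          dupv <- as.integer(names(which(table(p) == 2L)))
          tog <- which(p == dupv); oth <- which(p != dupv)
          m[rows[kk], ] <- TT[c(tog, oth), todo[rows[kk]]]
        }
      }
      stopifnot(!anyNA(m[, 1L]))
    }
    X[todo, ] <- canon_split_m(m)
    type[todo] <- "quartet"
  }

  tab <- data.frame(key = key, type = type,
                    x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], x4 = X[, 4],
                    ret = ret, weight = 1, stringsAsFactors = FALSE)
  new_dense_quarnets(taxa, finish_tab(tab))
}
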