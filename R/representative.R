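# Step B1: dense representative tf-quarnet sets at high-degree blobtree
# vertices, and the quarnet distances (Step B2, eq. for tau) used for the
# TSP ordering.

#' Representative tf-quarnets of a high-degree vertex
#'
#' The vertex `v` of the tree induces a partition `Y1 | ... | Ys` of the taxa.
#' Every input quarnet with one leaf in each of four distinct parts is
#' relabeled by `f(x) = yi` for `x in Yi`; per 4-subset of parts the weights
#' of the six possible skeletons (3 quartet splits + 3 undirected 4-cycles)
#' are summed, the heaviest skeleton wins (ties resolved randomly) and gets
#' weight `w(t)/w(total)`; a winning 4-cycle's reticulation leaf is the one
#' with the largest summed weight below the reticulation among the 4-cycles
#' with that skeleton.
#'
#' Component `yi` is labeled by the smallest taxon of `Yi`.
#'
#' @param tree an `sdnet` tree.
#' @param v an internal vertex of degree >= 4.
#' @param Q a `dense_quarnets` object on the tree's taxa.
#' @return list with `set` (a `dense_quarnets` on the component labels) and
#'   `f` (named character: taxon -> component label).
#' @export
representative_quarnets <- function(tree, v, Q) {
  tc <- tree_components(tree, v)
  stopifnot(length(tc$nb) >= 4L)
  f <- character(length(Q$taxa)); names(f) <- Q$taxa
  for (cmp in tc$comps) f[cmp] <- cmp[1]
  list(set = representative_from_f(Q, f), f = f)
}

# f: named character vector taxon -> component label (surjective)
representative_from_f <- function(Q, f) {
  tab <- Q$tab
  lm <- qs_leaf_matrix(Q)
  C <- matrix(f[lm], ncol = 4L)
  keep <- C[, 1] != C[, 2] & C[, 1] != C[, 3] & C[, 1] != C[, 4] &
          C[, 2] != C[, 3] & C[, 2] != C[, 4] & C[, 3] != C[, 4]
  tab <- tab[keep, , drop = FALSE]
  X <- cbind(f[tab$x1], f[tab$x2], f[tab$x3], f[tab$x4])
  quart <- tab$type == "quartet"
  Xc <- X
  if (any(quart)) Xc[quart, ] <- canon_split_m(X[quart, , drop = FALSE])
  if (any(!quart)) Xc[!quart, ] <- canon_cycle4_m(X[!quart, , drop = FALSE])
  skel <- ifelse(quart,
                 quartet_canon_str(Xc[, 1], Xc[, 2], Xc[, 3], Xc[, 4]),
                 cycle_skel_str(Xc[, 1], Xc[, 2], Xc[, 3], Xc[, 4]))
  Xs <- sort_rows4(X)
  key <- paste(Xs[, 1], Xs[, 2], Xs[, 3], Xs[, 4], sep = "|")
  ret <- ifelse(quart, NA_character_, f[tab$ret])
  dt <- data.table::data.table(skey = key, skel = skel, ret = ret,
                               type = tab$type, w = tab$weight,
                               x1 = Xc[, 1], x2 = Xc[, 2], x3 = Xc[, 3], x4 = Xc[, 4])
  tot <- dt[, list(wtot = sum(w)), by = "skey"]
  sk <- dt[, list(wskel = sum(w)),
           by = c("skey", "skel", "type", "x1", "x2", "x3", "x4")]
  # winner skeleton per 4-subset; ties resolved randomly via a random
  # tie-break column (all randomness flows from the caller's RNG state)
  sk <- as.data.frame(sk)
  sk$u <- runif(nrow(sk))
  sk <- sk[order(sk$skey, -sk$wskel, sk$u), , drop = FALSE]
  win <- sk[!duplicated(sk$skey), , drop = FALSE]
  tot <- as.data.frame(tot)
  win$wq <- pmin(1, win$wskel / tot$wtot[match(win$skey, tot$skey)])
  # reticulation vote among the 4-cycles with the winning skeleton
  rt <- as.data.frame(dt[dt$type == "cycle4",
                         list(wret = sum(w)), by = c("skey", "skel", "ret")])
  win$retwin <- NA_character_
  if (nrow(rt)) {
    rt$u <- runif(nrow(rt))
    rt <- rt[order(rt$skey, rt$skel, -rt$wret, rt$u), , drop = FALSE]
    rt <- rt[!duplicated(paste(rt$skey, rt$skel)), , drop = FALSE]
    win$retwin <- rt$ret[match(paste(win$skey, win$skel),
                               paste(rt$skey, rt$skel))]
  }
  qs <- lapply(seq_len(nrow(win)), function(i) {
    r <- win[i, ]
    if (r$type == "quartet")
      tfq_quartet(c(r$x1, r$x2), c(r$x3, r$x4), r$wq)
    else
      tfq_cycle(c(r$x1, r$x2, r$x3, r$x4), r$retwin, r$wq)
  })
  dense_quarnets(qs)
}

# row-wise sort of an N x 4 character matrix (vectorised sorting network)
sort_rows4 <- function(m) {
  if (!nrow(m)) return(m)
  lo1 <- pmin(m[, 1], m[, 2]); hi1 <- pmax(m[, 1], m[, 2])
  lo2 <- pmin(m[, 3], m[, 4]); hi2 <- pmax(m[, 3], m[, 4])
  mn <- pmin(lo1, lo2); mx <- pmax(hi1, hi2)
  m1 <- pmax(lo1, lo2); m2 <- pmin(hi1, hi2)
  cbind(mn, pmin(m1, m2), pmax(m1, m2), mx, deparse.level = 0)
}

#' Quarnet distance matrix of a dense tf-quarnet set
#'
#' `D(a,b)` sums the tau contributions over all quarnets containing both `a`
#' and `b` (see [tau()]); symmetric with zero diagonal.
#'
#' @param Q a `dense_quarnets` object (typically a representative set).
#' @return numeric matrix over the taxa of `Q`.
#' @export
quarnet_distances <- function(Q) {
  taxa <- Q$taxa
  s <- length(taxa)
  D <- matrix(0, s, s, dimnames = list(taxa, taxa))
  tab <- Q$tab
  near_w <- (3 - tab$weight) / 2
  far_w  <- (3 + tab$weight) / 2
  quart <- tab$type == "quartet"
  # near pairs: same split side, or cycle neighbours; far pairs: the rest
  pair_add <- function(a, b, w) {
    i <- match(a, taxa); j <- match(b, taxa)
    li <- c((j - 1L) * s + i, (i - 1L) * s + j)
    agg <- rowsum(c(w, w), li)
    D[as.integer(rownames(agg))] <<- D[as.integer(rownames(agg))] + agg[, 1]
  }
  # quartet {x1,x2}|{x3,x4}: near (x1,x2),(x3,x4); cycle (x1,x2,x3,x4):
  # near consecutive pairs, far opposite pairs (x1,x3),(x2,x4)
  pair_add(tab$x1[quart], tab$x2[quart], near_w[quart])
  pair_add(tab$x3[quart], tab$x4[quart], near_w[quart])
  pair_add(tab$x1[quart], tab$x3[quart], far_w[quart])
  pair_add(tab$x1[quart], tab$x4[quart], far_w[quart])
  pair_add(tab$x2[quart], tab$x3[quart], far_w[quart])
  pair_add(tab$x2[quart], tab$x4[quart], far_w[quart])
  cy <- !quart
  pair_add(tab$x1[cy], tab$x2[cy], near_w[cy])
  pair_add(tab$x2[cy], tab$x3[cy], near_w[cy])
  pair_add(tab$x3[cy], tab$x4[cy], near_w[cy])
  pair_add(tab$x4[cy], tab$x1[cy], near_w[cy])
  pair_add(tab$x1[cy], tab$x3[cy], far_w[cy])
  pair_add(tab$x2[cy], tab$x4[cy], far_w[cy])
  D
}

#' Reticulation ranking of a representative quarnet set
#'
#' For `|Y| >= 5` the component leaves are ordered by the descending weighted
#' count of representative quarnets in which the leaf sits below the
#' reticulation (ties random).  For `|Y| = 4` the single quarnet decides: a
#' 4-cycle puts its reticulation leaf first and the other three in random
#' order; a quartet tree yields a fully random order.
#'
#' @param Q a `dense_quarnets` object (the representative set).
#' @param mode `"ret"` counts reticulation-leaf occurrences (default);
#'   `"member"` counts any membership in a 4-cycle.
#' @return character vector: the ranking `rho` (a permutation of the taxa).
#' @export
reticulation_ranking <- function(Q, mode = c("ret", "member")) {
  mode <- match.arg(mode)
  taxa <- Q$taxa
  tab <- Q$tab
  if (length(taxa) == 4L) {
    stopifnot(nrow(tab) == 1L)
    if (tab$type == "cycle4") {
      rest <- setdiff(taxa, tab$ret)
      return(c(tab$ret, rest[sample.int(3L)]))
    }
    return(taxa[sample.int(4L)])
  }
  cyc <- tab[tab$type == "cycle4", , drop = FALSE]
  score <- setNames(numeric(length(taxa)), taxa)
  if (nrow(cyc)) {
    if (mode == "ret") {
      agg <- rowsum(cyc$weight, cyc$ret)
      score[rownames(agg)] <- agg[, 1]
    } else {
      lm <- do.call(rbind, strsplit(cyc$key, "|", fixed = TRUE))
      agg <- rowsum(rep(cyc$weight, 4L), as.vector(lm))
      score[rownames(agg)] <- agg[, 1]
    }
  }
  taxa[order(-score, sample.int(length(taxa)))]
}
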