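#' @importFrom stats runif setNames
#' @importFrom utils combn head tail
#' @importFrom data.table data.table
NULL

# make data.table's [ semantics available inside this package
.datatable.aware <- TRUE

# ---- canonical forms ---------------------------------------------------------

#' Canonical form of a quartet split on four taxa
#'
#' Sides are sorted internally and ordered by their lexicographically smallest
#' member, so that the 8 equivalent writings of a split map to one vector.
#'
#' @param side1,side2 character vectors of length 2, the two sides of the split.
#' @return character vector of length 4: `c(x1,x2,x3,x4)` meaning split
#'   `{x1,x2} | {x3,x4}`.
#' @keywords internal
canon_split <- function(side1, side2) {
  s1 <- sort(side1); s2 <- sort(side2)
  if (s1[1] <= s2[1]) c(s1, s2) else c(s2, s1)
}

#' Canonical form of a cyclic order on four taxa
#'
#' Among the 8 rotations/reflections, returns the one starting at the smallest
#' label whose second element is smallest.
#'
#' @param ord character vector of length 4 (a cyclic order).
#' @return character vector of length 4, the canonical rotation/reflection.
#' @keywords internal
canon_cycle4 <- function(ord) {
  stopifnot(length(ord) == 4L, !anyDuplicated(ord))
  i <- which(ord == min(ord))[1L]
  nxt <- ord[c(2:4, 1)][i]
  prv <- ord[c(4, 1:3)][i]
  opp <- ord[c(3, 4, 1, 2)][i]
  if (nxt <= prv) c(ord[i], nxt, opp, prv) else c(ord[i], prv, opp, nxt)
}

# Vectorised canonicalisation; m is an N x 4 character matrix of splits
# ({m[,1],m[,2]} | {m[,3],m[,4]}) or cyclic orders. Returns N x 4 matrix.
canon_split_m <- function(m) {
  a <- pmin(m[, 1L], m[, 2L]); b <- pmax(m[, 1L], m[, 2L])
  c_ <- pmin(m[, 3L], m[, 4L]); d <- pmax(m[, 3L], m[, 4L])
  swap <- a > c_
  out <- cbind(ifelse(swap, c_, a), ifelse(swap, d, b),
               ifelse(swap, a, c_), ifelse(swap, b, d))
  out
}

canon_cycle4_m <- function(m) {
  # index of min per row
  i <- max.col(-matrix(rank_chr(m), ncol = 4L), ties.method = "first")
  n <- nrow(m)
  pick <- function(off) m[cbind(seq_len(n), ((i - 1L + off) %% 4L) + 1L)]
  x0 <- pick(0L); x1 <- pick(1L); x2 <- pick(2L); x3 <- pick(3L)
  fwd <- x1 <= x3
  cbind(x0, ifelse(fwd, x1, x3), x2, ifelse(fwd, x3, x1))
}

# rank character matrix entries globally (for vectorised min-finding)
rank_chr <- function(m) {
  u <- sort(unique(as.vector(m)))
  matrix(match(as.vector(m), u), nrow = nrow(m))
}

# canonical strings
quartet_canon_str <- function(x1, x2, x3, x4)
  paste0("Q:", x1, ",", x2, "|", x3, ",", x4)
cycle_canon_str <- function(x1, x2, x3, x4, ret)
  paste0("C:", x1, ",", x2, ",", x3, ",", x4, ";", ret)
cycle_skel_str <- function(x1, x2, x3, x4)
  paste0("C:", x1, ",", x2, ",", x3, ",", x4)

subset_key <- function(taxa4) paste(sort(taxa4), collapse = "|")

# ---- tf-quarnet --------------------------------------------------------------

#' Construct a quartet-tree tf-quarnet
#'
#' @param side1,side2 character vectors of length 2: the two sides of the
#'   nontrivial split.
#' @param weight quarnet weight in `[0, 1]`.
#' @return an object of class `tf_quarnet`.
#' @examples
#' q <- tfq_quartet(c("a", "b"), c("c", "d"), 0.8)
#' @export
tfq_quartet <- function(side1, side2, weight = 1) {
  leaves <- c(side1, side2)
  stopifnot(length(leaves) == 4L, !anyDuplicated(leaves),
            is.numeric(weight), weight >= 0, weight <= 1)
  x <- canon_split(side1, side2)
  structure(list(type = "quartet", leaves = sort(leaves), x = x,
                 ret = NA_character_, weight = as.numeric(weight)),
            class = "tf_quarnet")
}

#' Construct a 4-cycle tf-quarnet
#'
#' @param order character vector of length 4: the circular order of the leaves
#'   (up to rotation/reflection).
#' @param ret the leaf below the reticulation (must be in `order`).
#' @param weight quarnet weight in `[0, 1]`.
#' @return an object of class `tf_quarnet`.
#' @examples
#' q <- tfq_cycle(c("a", "b", "c", "d"), ret = "a")
#' @export
tfq_cycle <- function(order, ret, weight = 1) {
  stopifnot(length(order) == 4L, !anyDuplicated(order), ret %in% order,
            is.numeric(weight), weight >= 0, weight <= 1)
  x <- canon_cycle4(order)
  structure(list(type = "cycle4", leaves = sort(order), x = x,
                 ret = ret, weight = as.numeric(weight)),
            class = "tf_quarnet")
}

#' @export
print.tf_quarnet <- function(x, ...) {
  if (x$type == "quartet") {
    cat(sprintf("tf-quarnet (quartet tree) %s,%s|%s,%s  w=%g\n",
                x$x[1], x$x[2], x$x[3], x$x[4], x$weight))
  } else {
    cat(sprintf("tf-quarnet (4-cycle) (%s)  ret=%s  w=%g\n",
                paste(x$x, collapse = ","), x$ret, x$weight))
  }
  invisible(x)
}

#' Canonical identity string of a tf-quarnet
#'
#' Two tf-quarnets are equal as semi-directed networks iff their canonical
#' strings are equal (the reticulation leaf of a 4-cycle is part of the
#' identity; the weight is not).
#'
#' @param q a `tf_quarnet`.
#' @return length-1 character.
#' @export
quarnet_canon <- function(q) {
  if (q$type == "quartet") quartet_canon_str(q$x[1], q$x[2], q$x[3], q$x[4])
  else cycle_canon_str(q$x[1], q$x[2], q$x[3], q$x[4], q$ret)
}

# skeleton string: identity of the underlying undirected graph
quarnet_skeleton <- function(q) {
  if (q$type == "quartet") quartet_canon_str(q$x[1], q$x[2], q$x[3], q$x[4])
  else cycle_skel_str(q$x[1], q$x[2], q$x[3], q$x[4])
}

#' Pairwise tau distance contribution of a tf-quarnet
#'
#' For a quarnet of weight `w`, leaves on the same side of the split (quartet
#' tree) or neighbouring on the cycle contribute `(3 - w)/2`; leaves across the
#' split or opposite on the cycle contribute `(3 + w)/2`.  With unit weight
#' these reduce to 1 and 2.
#'
#' @param q a `tf_quarnet`.
#' @param a,b two distinct leaves of `q`.
#' @return a numeric scalar.
#' @examples
#' q <- tfq_cycle(c("a", "b", "c", "d"), "a")
#' tau(q, "a", "c") # opposite leaves: 2
#' @export
tau <- function(q, a, b) {
  stopifnot(inherits(q, "tf_quarnet"), a %in% q$leaves, b %in% q$leaves)
  if (a == b) stop("tau() requires two distinct leaves")
  near <- if (q$type == "quartet") {
    (a %in% q$x[1:2]) == (b %in% q$x[1:2])
  } else {
    # neighbours iff not opposite in the canonical cyclic order
    abs(match(a, q$x) - match(b, q$x)) != 2L
  }
  if (near) (3 - q$weight) / 2 else (3 + q$weight) / 2
}
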