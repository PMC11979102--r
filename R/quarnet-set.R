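# Dense tf-quarnet sets: exactly one tf-quarnet per 4-subset of the taxon set.
#
# Internally a data.frame `tab` with one row per 4-subset, sorted by `key`:
#   key   : "t1|t2|t3|t4" (sorted subset)
#   type  : "quartet" or "cycle4"
#   x1..x4: canonical arrangement (split sides {x1,x2}|{x3,x4}, or cyclic order)
#   ret   : reticulation leaf (NA for quartets)
#   weight: in [0,1]
#   canon : canonical identity string (includes ret)
#   skel  : canonical skeleton string (ignores ret)

new_dense_quarnets <- function(taxa, tab) {
  tab <- tab[order(tab$key), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(taxa = sort(taxa), tab = tab), class = "dense_quarnets")
}

finish_tab <- function(tab) {
  quart <- tab$type == "quartet"
  tab$canon <- ifelse(quart,
    quartet_canon_str(tab$x1, tab$x2, tab$x3, tab$x4),
    cycle_canon_str(tab$x1, tab$x2, tab$x3, tab$x4, tab$ret))
  tab$skel <- ifelse(quart,
    quartet_canon_str(tab$x1, tab$x2, tab$x3, tab$x4),
    cycle_skel_str(tab$x1, tab$x2, tab$x3, tab$x4))
  tab
}

#' Assemble a dense tf-quarnet set from individual quarnets
#'
#' @param quarnets a list of [tfq_quartet()] / [tfq_cycle()] objects, exactly
#'   one per 4-subset of the union of their leaf sets.
#' @return an object of class `dense_quarnets`.
#' @export
dense_quarnets <- function(quarnets) {
  stopifnot(length(quarnets) >= 1L,
            all(vapply(quarnets, inherits, TRUE, "tf_quarnet")))
  taxa <- sort(unique(unlist(lapply(quarnets, `[[`, "leaves"))))
  tab <- data.frame(
    key    = vapply(quarnets, function(q) subset_key(q$leaves), ""),
    type   = vapply(quarnets, `[[`, "", "type"),
    x1 = vapply(quarnets, function(q) q$x[1], ""),
    x2 = vapply(quarnets, function(q) q$x[2], ""),
    x3 = vapply(quarnets, function(q) q$x[3], ""),
    x4 = vapply(quarnets, function(q) q$x[4], ""),
    ret    = vapply(quarnets, `[[`, "", "ret"),
    weight = vapply(quarnets, `[[`, 0, "weight"),
    stringsAsFactors = FALSE)
  check_dense(taxa, tab$key)
  new_dense_quarnets(taxa, finish_tab(tab))
}

check_dense <- function(taxa, keys) {
  n <- length(taxa)
  if (n < 4L) stop("a dense quarnet set needs at least 4 taxa")
  want <- apply(combn(taxa, 4L), 2L, paste, collapse = "|")
  if (anyDuplicated(keys))
    stop("duplicate 4-subset in quarnet set: ", keys[duplicated(keys)][1])
  miss <- setdiff(want, keys)
  if (length(miss) || length(keys) != length(want))
    stop("quarnet set is not dense; e.g. missing subset ",
         if (length(miss)) miss[1] else keys[!keys %in% want][1])
  invisible(TRUE)
}

#' @export
print.dense_quarnets <- function(x, ...) {
  cat(sprintf("dense tf-quarnet set: %d taxa, %d quarnets (%d quartet trees, %d 4-cycles)\n",
              length(x$taxa), nrow(x$tab), sum(x$tab$type == "quartet"),
              sum(x$tab$type == "cycle4")))
  invisible(x)
}

#' Extract one tf-quarnet from a dense set
#'
#' @param Q a `dense_quarnets` object.
#' @param taxa4 character vector of 4 taxa.
#' @return a `tf_quarnet`.
#' @export
get_quarnet <- function(Q, taxa4) {
  i <- match(subset_key(taxa4), Q$tab$key)
  if (is.na(i)) stop("no quarnet on {", paste(taxa4, collapse = ","), "}")
  row_to_quarnet(Q$tab[i, ])
}

row_to_quarnet <- function(r) {
  if (r$type == "quartet")
    tfq_quartet(c(r$x1, r$x2), c(r$x3, r$x4), r$weight)
  else
    tfq_cycle(c(r$x1, r$x2, r$x3, r$x4), r$ret, r$weight)
}

align_tabs <- function(ref, cand) {
  if (!identical(ref$taxa, cand$taxa))
    stop("taxon sets differ between the two quarnet sets")
  # both tabs are sorted by key on construction
  stopifnot(identical(ref$tab$key, cand$tab$key))
  list(a = ref$tab, b = cand$tab)
}

#' tf-quarnet consistency score C
#'
#' Fraction of the tf-quarnets of the reference set that also occur in the
#' candidate set, `|Q(N) n Q(M)| / |Q(N)|`.  Weights are ignored; quarnets are
#' compared by canonical form (the reticulation leaf of a 4-cycle counts).
#'
#' @param reference,candidate two `dense_quarnets` objects on the same taxa.
#' @return numeric in `[0, 1]`.
#' @export
consistency_score <- function(reference, candidate) {
  z <- align_tabs(reference, candidate)
  mean(z$a$canon == z$b$canon)
}

#' Symmetric tf-quarnet consistency score S
#'
#' `|Q(N) n Q(M)| / |Q(N) u Q(M)|`.  For two dense sets on the same taxa every
#' disagreeing 4-subset is counted twice in the union, so with `k` of `m`
#' subsets disagreeing the score is `(m-k)/(m+k)`.
#'
#' @inheritParams consistency_score
#' @return numeric in `[0, 1]`.
#' @export
symmetric_consistency <- function(reference, candidate) {
  z <- align_tabs(reference, candidate)
  agree <- sum(z$a$canon == z$b$canon)
  m <- nrow(z$a)
  agree / (2 * m - agree)
}

#' Weighted tf-quarnet consistency score C'
#'
#' `w(Q n Q(N)) / w(Q)`: the summed weight of input quarnets induced by the
#' network, over the total input weight.
#'
#' @param Q a `dense_quarnets` object (the input data).
#' @param network a semi-directed network on the same taxa (see
#'   [semidirected_network()]), or a precomputed `dense_quarnets` of the
#'   network's induced set.
#' @return numeric in `[0, 1]`.
#' @export
weighted_consistency <- function(Q, network) {
  QN <- if (inherits(network, "dense_quarnets")) network
        else induced_quarnets(network)
  z <- align_tabs(Q, QN)
  wtot <- sum(z$a$weight)
  if (wtot <= 0) stop("degenerate weights: total input weight is zero")
  sum(z$a$weight[z$a$canon == z$b$canon]) / wtot
}

# ---- file I/O ---------------------------------------------------------------

#' Read a dense tf-quarnet set from a text file
#'
#' One record per line, whitespace separated.  Quartet trees:
#' `T t1 t2 t3 t4 a,b|c,d w`; 4-cycles: `C t1 t2 t3 t4 a,b,c,d ret w`.
#' The weight column may be omitted (defaults to 1).  `#` starts a comment; a
#' `taxa:` header line declares the taxon set.
#'
#' @param path file path.
#' @return a `dense_quarnets` object.
#' @export
read_quarnets <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  taxa <- NULL
  qs <- list()
  for (ln in lines) {
    if (startsWith(ln, "taxa:")) {
      taxa <- strsplit(trimws(sub("^taxa:", "", ln)), "\\s+")[[1]]
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (!f[1] %in% c("T", "C"))
      stop("unrecognised record type '", f[1], "' in line: ", ln)
    lv <- f[2:5]
    if (f[1] == "T") {
      # T t1 t2 t3 t4 a,b|c,d [w]
      if (!length(f) %in% c(6L, 7L)) stop("malformed quarnet line: ", ln)
      w <- if (length(f) == 7L) suppressWarnings(as.numeric(f[7])) else 1
      if (is.na(w) || w < 0 || w > 1)
        stop("weight outside [0,1] in line: ", ln)
      sides <- strsplit(f[6], "|", fixed = TRUE)[[1]]
      if (length(sides) != 2L) stop("malformed split in line: ", ln)
      s1 <- strsplit(sides[1], ",", fixed = TRUE)[[1]]
      s2 <- strsplit(sides[2], ",", fixed = TRUE)[[1]]
      if (length(s1) != 2L || length(s2) != 2L || !setequal(c(s1, s2), lv))
        stop("split does not match leaf set in line: ", ln)
      qs[[length(qs) + 1L]] <- tfq_quartet(s1, s2, w)
    } else {
      # C t1 t2 t3 t4 a,b,c,d ret [w]
      if (!length(f) %in% c(7L, 8L)) stop("malformed quarnet line: ", ln)
      w <- if (length(f) == 8L) suppressWarnings(as.numeric(f[8])) else 1
      if (is.na(w) || w < 0 || w > 1)
        stop("weight outside [0,1] in line: ", ln)
      ord <- strsplit(f[6], ",", fixed = TRUE)[[1]]
      if (length(ord) != 4L || !setequal(ord, lv))
        stop("cyclic order does not match leaf set in line: ", ln)
      ret <- f[7]
      if (!ret %in% ord)
        stop("reticulation leaf not in cyclic order in line: ", ln)
      qs[[length(qs) + 1L]] <- tfq_cycle(ord, ret, w)
    }
  }
  if (!is.null(taxa)) {
    seen <- sort(unique(unlist(lapply(qs, `[[`, "leaves"))))
    bad <- setdiff(seen, taxa)
    if (length(bad)) stop("unknown taxon in quarnet file: ", bad[1])
  }
  dense_quarnets(qs)
}

#' Write a dense tf-quarnet set to a text file
#'
#' @param Q a `dense_quarnets` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_quarnets <- function(Q, path) {
  tab <- Q$tab
  hdr <- paste("taxa:", paste(Q$taxa, collapse = " "))
  t4 <- do.call(rbind, strsplit(tab$key, "|", fixed = TRUE))
  body <- ifelse(tab$type == "quartet",
    sprintf("T %s %s %s %s %s,%s|%s,%s %s", t4[, 1], t4[, 2], t4[, 3], t4[, 4],
            tab$x1, tab$x2, tab$x3, tab$x4, format(tab$weight, digits = 12)),
    sprintf("C %s %s %s %s %s,%s,%s,%s %s %s", t4[, 1], t4[, 2], t4[, 3], t4[, 4],
            tab$x1, tab$x2, tab$x3, tab$x4, tab$ret,
            format(tab$weight, digits = 12)))
  writeLines(c(hdr, body), path)
  invisible(path)
}
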