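# delta-heuristic: dense weighted tf-quarnet sets from multiple sequence
# alignments via delta-values of 4-taxon subsets (Steps I-IV).

#' Read a multiple sequence alignment
#'
#' @param path file path (FASTA or NEXUS).
#' @param format `"auto"` guesses from the extension/first character.
#' @return an object of class `msa`: list with `labels` and `seqs`
#'   (uppercase character strings of equal length).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("nex", "nexus", "nxs")) "nexus" else "fasta"
  }
  x <- if (format == "fasta") {
    ape::read.FASTA(path)
  } else {
    d <- ape::read.nexus.data(path)
    lapply(d, function(v) paste(v, collapse = ""))
  }
  seqs <- if (format == "fasta")
    vapply(as.character(x), paste, "", collapse = "")
  else unlist(x)
  msa(toupper(seqs), names(seqs))
}

#' Construct an alignment object
#'
#' @param seqs character vector of equal-length sequences.
#' @param labels taxon labels (defaults to `names(seqs)`).
#' @return an `msa` object.
#' @export
msa <- function(seqs, labels = names(seqs)) {
  labels <- labels
  seqs <- toupper(unname(seqs))
  stopifnot(length(seqs) >= 4L, !is.null(labels),
            length(labels) == length(seqs), !anyDuplicated(labels))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment sequences must have equal length")
  structure(list(labels = as.character(labels), seqs = seqs), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("alignment: %d taxa, %d columns\n",
              length(x$labels), nchar(x$seqs[1])))
  invisible(x)
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$labels
  m
}

#' Pairwise normalized Hamming distances of an alignment
#'
#' For each pair of taxa, only the columns where both sequences are gap-free
#' are considered; the distance is the fraction of those columns where the
#' sequences differ.  Any non-gap symbol (including ambiguity codes) counts
#' as a mismatch unless identical.
#'
#' @param aln an `msa` object.
#' @return list of class `pairwise_hamming`: `h` (symmetric matrix) and
#'   `len` (matrix of per-pair gap-free column counts).
#' @export
pairwise_hamming <- function(aln) {
  m <- msa_matrix(aln)
  gap <- m == "-"
  n <- nrow(m)
  h <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  len <- matrix(0L, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    L <- sum(ok)
    if (L == 0L)
      stop("taxa '", aln$labels[i], "' and '", aln$labels[j],
           "' share no gap-free column")
    d <- sum(m[i, ok] != m[j, ok]) / L
    h[i, j] <- h[j, i] <- d
    len[i, j] <- len[j, i] <- L
  }
  structure(list(h = h, len = len), class = "pairwise_hamming")
}

#' delta-value of a 4-taxon subset
#'
#' With the three pair-sum distances relabeled so that
#' `h_ab|cd >= h_ac|bd >= h_ad|bc`, the delta-value is
#' `(h_ab|cd - h_ac|bd) / (h_ab|cd - h_ad|bc)`, and 0 when all three sums are
#' equal.  Values near 1 indicate strong support for a split (a quartet
#' tree); values near 0 indicate conflict (a 4-cycle).
#'
#' @param h a `pairwise_hamming` object (or plain symmetric matrix).
#' @param four character vector of 4 taxa.
#' @return numeric in `[0, 1]`.
#' @export
delta_value <- function(h, four) {
  if (inherits(h, "pairwise_hamming")) h <- h$h
  stopifnot(length(four) == 4L, all(four %in% rownames(h)))
  a <- four[1]; b <- four[2]; c_ <- four[3]; d <- four[4]
  sums <- c(h[a, b] + h[c_, d], h[a, c_] + h[b, d], h[a, d] + h[b, c_])
  s <- sort(sums, decreasing = TRUE)
  if (s[1] == s[3]) return(0)
  (s[1] - s[2]) / (s[1] - s[3])
}

#' Infer a dense weighted tf-quarnet set from an alignment (delta-heuristic)
#'
#' For every 4-subset the delta-value decides the shape: `delta >= lambda`
#' gives a quartet tree on the split with the highest pair-sum distance;
#' `delta < lambda` gives a 4-cycle arranged so that the two smaller-sum
#' splits are obtainable by deleting one reticulation edge (circular order
#' `(a,c,b,d)` under the labeling `h_ab|cd >= h_ac|bd >= h_ad|bc`).  Weights
#' are `|delta-lambda|/lambda` below the threshold and
#' `|delta-lambda|/(1-lambda)` above it.  The reticulation leaf of each
#' 4-cycle is its member with the highest mean delta-value `delta(x)` over
#' all 4-subsets containing `x` (ties broken via the seeded RNG).
#'
#' @param aln an `msa` object.
#' @param lambda treelikeness threshold in (0,1); default 0.3.
#' @param seed optional integer seed for tie-breaks.
#' @return a `dense_quarnets` object.
#' @export
infer_tf_quarnets <- function(aln, lambda = 0.3, seed = NULL) {
  stopifnot(lambda > 0, lambda < 1)
  if (!is.null(seed)) set.seed(seed)
  ph <- pairwise_hamming(aln)
  h <- ph$h
  taxa <- sort(aln$labels)
  n <- length(taxa)
  sub <- combn(n, 4L)
  N <- ncol(sub)
  TT <- matrix(taxa[sub], nrow = 4L)
  a <- TT[1, ]; b <- TT[2, ]; c_ <- TT[3, ]; d <- TT[4, ]
  s1 <- h[cbind(a, b)] + h[cbind(c_, d)]   # ab|cd
  s2 <- h[cbind(a, c_)] + h[cbind(b, d)]   # ac|bd
  s3 <- h[cbind(a, d)] + h[cbind(b, c_)]   # ad|bc
  S <- cbind(s1, s2, s3)
  # argmax split; exact ties broken by lexicographic split order
  # (ab|cd, ac|bd, ad|bc)
  o1 <- max.col(S, ties.method = "first")
  hi <- S[cbind(seq_len(N), o1)]
  rest <- matrix(0L, N, 2L)
  for (i in 1:3) rest[o1 == i, ] <- matrix(rep(setdiff(1:3, i), each = sum(o1 == i)),
                                           ncol = 2L)
  mid_v <- pmax(S[cbind(seq_len(N), rest[, 1])], S[cbind(seq_len(N), rest[, 2])])
  lo_v <- pmin(S[cbind(seq_len(N), rest[, 1])], S[cbind(seq_len(N), rest[, 2])])
  delta <- ifelse(hi == lo_v, 0, (hi - mid_v) / (hi - lo_v))
  w <- ifelse(delta <= lambda, abs(delta - lambda) / lambda,
              abs(delta - lambda) / (1 - lambda))
  # per-taxon mean delta over the subsets containing it
  dsum <- rowsum(rep(delta, 4L), as.vector(TT))
  dmean <- setNames(dsum[, 1] / choose(n - 1L, 3L), rownames(dsum))
  is_tree <- delta >= lambda
  # split sides per argmax index
  side_m <- function(k) switch(k,
    cbind(a, b, c_, d),   # ab|cd
    cbind(a, c_, b, d),   # ac|bd
    cbind(a, d, b, c_))   # ad|bc
  X <- matrix(NA_character_, N, 4L)
  for (k in 1:3) {
    rows <- is_tree & o1 == k
    if (any(rows)) X[rows, ] <- canon_split_m(side_m(k)[rows, , drop = FALSE])
  }
  ret <- rep(NA_character_, N)
  cyc <- !is_tree
  if (any(cyc)) {
    # circular order (a, c, b, d) under the relabeling with the top split
    # ab|cd: interleave the two pairs of the largest-sum split
    ord <- matrix(NA_character_, N, 4L)
    for (k in 1:3) {
      rows <- cyc & o1 == k
      if (!any(rows)) next
      sm <- side_m(k)[rows, , drop = FALSE]
      ord[rows, ] <- cbind(sm[, 1], sm[, 3], sm[, 2], sm[, 4])
    }
    X[cyc, ] <- canon_cycle4_m(ord[cyc, , drop = FALSE])
    # reticulation leaf: member with the highest delta(x); random tie-break
    dm <- matrix(dmean[TT], nrow = 4L)
    tie_eps <- matrix(stats::runif(4L * N, 0, 1e-9), nrow = 4L)
    pickr <- max.col(t(dm + tie_eps), ties.method = "first")
    ret[cyc] <- TT[cbind(pickr[cyc], which(cyc))]
  }
  tab <- data.frame(
    key = paste(TT[1, ], TT[2, ], TT[3, ], TT[4, ], sep = "|"),
    type = ifelse(is_tree, "quartet", "cycle4"),
    x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], x4 = X[, 4],
    ret = ret, weight = pmin(1, pmax(0, w)), stringsAsFactors = FALSE)
  new_dense_quarnets(taxa, finish_tab(tab))
}
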