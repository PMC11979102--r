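# Simulation machinery: random triangle-free level-1 networks, quarnet
# perturbation, displayed trees, and K2P sequence simulation along them.

#' Random binary triangle-free semi-directed level-1 network
#'
#' Grows a random rooted binary tree on `n` leaves by sequential leaf
#' insertion, adds `r ~ U{0..floor(n/3)}` reticulations by joining two random
#' edges (rejecting joins that would break acyclicity, level-1-ness or
#' triangle-freeness), and un-roots the result.
#'
#' @param n number of leaves (>= 4); taxa are `t01, t02, ...`.
#' @param seed optional integer seed.
#' @param r reticulation count; default drawn uniformly from
#'   `{0, ..., floor(n/3)}`.
#' @return an `sdnet`.
#' @export
random_network <- function(n, seed = NULL, r = NULL) {
  stopifnot(n >= 4L)
  if (!is.null(seed)) set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n))
  # draw r once so that rejection of hard placements does not bias the
  # marginal distribution of r away from uniform
  rr <- if (is.null(r)) sample.int(floor(n / 3) + 1L, 1L) - 1L else r
  for (attempt in seq_len(200L)) {
    rn <- random_rooted_tree(n, taxa)
    ok <- TRUE
    for (k in seq_len(rr)) {
      rn2 <- add_random_reticulation(rn)
      if (is.null(rn2)) { ok <- FALSE; break }
      rn <- rn2
    }
    if (!ok) next
    net <- as_semidirected(rn)
    good <- tryCatch({ validate_network(net); TRUE }, error = function(e) FALSE)
    if (good && length(valid_root_edges(net))) return(net)
  }
  stop("random_network: could not generate a valid network (n=", n, ")")
}

random_rooted_tree <- function(n, taxa) {
  # vertices: leaves 1..n; internals allocated upward
  nv <- n
  new_v <- function() { nv <<- nv + 1L; nv }
  root <- new_v()
  edges <- data.frame(parent = c(root, root), child = c(1L, 2L))
  for (k in 3:n) {
    j <- sample.int(nrow(edges), 1L)
    m <- new_v()
    p <- edges$parent[j]; c_ <- edges$child[j]
    edges <- rbind(edges[-j, , drop = FALSE],
                   data.frame(parent = c(p, m, m), child = c(m, c_, k)))
  }
  structure(list(edges = edges, root = root, labels = setNames(seq_len(n), taxa)),
            class = "rooted_net")
}

# one random reticulation: subdivide edges j1 (tail side) and j2 (head side),
# add an edge between the midpoints directed at j2's midpoint.  Valid partner
# edges become rare once earlier cycles occupy much of the tree, so after a
# few uniform draws the ordered pairs are enumerated in random order (one BFS
# per tail edge); NULL only if no valid join exists at all.
add_random_reticulation <- function(rn, tries = 20L) {
  ed <- rn$edges
  m <- nrow(ed)
  build <- function(j1, j2) {
    nv <- max(c(ed$parent, ed$child)) + 1:2
    u <- nv[1]; v <- nv[2]
    e2 <- rbind(ed[-c(j1, j2), , drop = FALSE],
                data.frame(parent = c(ed$parent[j1], u),
                           child = c(u, ed$child[j1])),
                data.frame(parent = c(ed$parent[j2], v),
                           child = c(v, ed$child[j2])),
                data.frame(parent = u, child = v))
    structure(list(edges = e2, root = rn$root, labels = rn$labels),
              class = "rooted_net")
  }
  # integer-indexed structures for the cheap pair test
  vs <- sort(unique(c(ed$parent, ed$child)))
  V <- length(vs)
  pa <- match(ed$parent, vs); ch <- match(ed$child, vs)
  rooti <- match(rn$root, vs)
  rets <- which(tabulate(ch, V) == 2L)
  sd <- structure(list(edges = data.frame(v1 = ed$parent, v2 = ed$child,
                                          directed = ed$child %in% vs[rets]),
                       labels = rn$labels), class = "sdnet")
  blocked <- rep(FALSE, V)
  blocked[match(unlist(lapply(net_cycles(sd), `[[`, "vs")), vs)] <- TRUE
  # ancestor test: anc[a, b] TRUE iff a is an ancestor of b (directed path)
  anc <- matrix(FALSE, V, V)
  for (j in seq_len(m)) anc[pa[j], ch[j]] <- TRUE
  repeat {
    nxt <- anc | (anc %*% anc > 0)
    if (identical(nxt, anc)) break
    anc <- nxt
  }
  adj_e <- split(c(seq_len(m), seq_len(m)), c(pa, ch))
  # one multi-source BFS from the endpoints of j1 (edge j1 removed); returns
  # dist and parent arrays over vertex indices
  bfs_from <- function(j1) {
    dist <- rep(NA_integer_, V); par <- rep(0L, V)
    src <- c(pa[j1], ch[j1])
    dist[src] <- 0L
    frontier <- src
    while (length(frontier)) {
      nxt <- integer()
      for (x in frontier) for (e_i in adj_e[[as.character(x)]]) {
        if (e_i == j1) next
        y <- if (pa[e_i] == x) ch[e_i] else pa[e_i]
        if (!is.na(dist[y])) next
        dist[y] <- dist[x] + 1L; par[y] <- x
        nxt <- c(nxt, y)
      }
      frontier <- nxt
    }
    list(dist = dist, par = par)
  }
  pair_ok <- function(j1, j2, b) {
    if (anc[ch[j2], pa[j1]] || ch[j2] == pa[j1]) return(FALSE) # directed cycle
    y2 <- c(pa[j2], ch[j2])
    y <- y2[which.min(b$dist[y2])]
    d <- b$dist[y]
    if (is.na(d) || d < 1L) return(FALSE)  # adjacent or unreachable
    path <- y
    while (b$par[path[1]] != 0L) path <- c(b$par[path[1]], path)
    if (any(blocked[path])) return(FALSE)  # cycles must stay vertex-disjoint
    if (rooti %in% path && d < 2L) return(FALSE) # unrooting would give triangle
    TRUE
  }
  bfs_cache <- vector("list", m)
  get_bfs <- function(j1) {
    if (is.null(bfs_cache[[j1]])) bfs_cache[[j1]] <<- bfs_from(j1)
    bfs_cache[[j1]]
  }
  for (t in seq_len(tries)) {
    j12 <- sample.int(m, 2L)
    if (!pair_ok(j12[1], j12[2], get_bfs(j12[1]))) next
    cand <- build(j12[1], j12[2])
    if (rooted_level1_ok(cand)) return(cand)
  }
  for (j1 in sample.int(m)) {
    b <- get_bfs(j1)
    for (j2 in sample(setdiff(seq_len(m), j1))) {
      if (!pair_ok(j1, j2, b)) next
      cand <- build(j1, j2)
      if (rooted_level1_ok(cand)) return(cand)
    }
  }
  NULL
}

# structural check on a rooted network candidate: acyclic, level-1 (cycles of
# the underlying graph are vertex-disjoint, one per reticulation) and all
# cycles of length >= 4 with the reticulation not adjacent to the root in a
# way that unrooting would create a triangle
rooted_level1_ok <- function(rn) {
  ed <- rn$edges
  if (!is_dag(ed, rn$root)) return(FALSE)
  rets <- as.integer(names(which(table(ed$child) == 2L)))
  sd <- structure(list(edges = data.frame(v1 = ed$parent, v2 = ed$child,
                                          directed = ed$child %in% rets),
                       labels = rn$labels), class = "sdnet")
  vs <- net_vertices(sd)
  if (length(rets) != nrow(ed) - length(vs) + 1L) return(FALSE)
  cyc <- tryCatch(net_cycles(sd), error = function(e) NULL)
  if (is.null(cyc)) return(FALSE)
  cv <- unlist(lapply(cyc, `[[`, "vs"))
  if (anyDuplicated(cv)) return(FALSE)
  for (cc in cyc) {
    len <- length(cc$vs)
    if (len < 4L) return(FALSE)
    # unrooting suppresses the root: a length-4 cycle through the root
    # becomes a triangle
    if (rn$root %in% cc$vs && len < 5L) return(FALSE)
  }
  TRUE
}

#' Randomly perturb the skeletons of a dense tf-quarnet set
#'
#' `round(epsilon * C(n,4))` quarnets, chosen without replacement, get a new
#' undirected skeleton drawn uniformly from the 5 alternatives (3 quartet
#' splits + 3 undirected 4-cycle orderings, minus the current one); a quarnet
#' that becomes a 4-cycle gets a uniform-random reticulation leaf.  Weights
#' are kept.
#'
#' @param Q a `dense_quarnets` object.
#' @param epsilon perturbation ratio in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a `dense_quarnets` object.
#' @export
perturb_quarnets <- function(Q, epsilon, seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- Q$tab
  N <- nrow(tab)
  mres <- round(epsilon * N)
  if (mres == 0L) return(Q)
  idx <- sample.int(N, mres)
  lm <- qs_leaf_matrix(Q)
  for (i in idx) {
    t4 <- lm[i, ] # sorted
    skels <- skeleton_universe(t4)
    cur <- match(tab$skel[i], vapply(skels, `[[`, "", "id"))
    stopifnot(!is.na(cur))
    new <- skels[[sample(setdiff(seq_len(6L), cur), 1L)]]
    tab$type[i] <- new$type
    tab$x1[i] <- new$x[1]; tab$x2[i] <- new$x[2]
    tab$x3[i] <- new$x[3]; tab$x4[i] <- new$x[4]
    tab$ret[i] <- if (new$type == "cycle4") t4[sample.int(4L, 1L)] else NA_character_
  }
  tab <- finish_tab(tab)
  new_dense_quarnets(Q$taxa, tab)
}

# the six undirected skeletons on a sorted 4-set
skeleton_universe <- function(t4) {
  s <- list(
    list(type = "quartet", x = c(t4[1], t4[2], t4[3], t4[4])),
    list(type = "quartet", x = c(t4[1], t4[3], t4[2], t4[4])),
    list(type = "quartet", x = c(t4[1], t4[4], t4[2], t4[3])),
    list(type = "cycle4", x = c(t4[1], t4[2], t4[3], t4[4])),
    list(type = "cycle4", x = c(t4[1], t4[2], t4[4], t4[3])),
    list(type = "cycle4", x = c(t4[1], t4[3], t4[2], t4[4])))
  lapply(s, function(z) {
    z$id <- if (z$type == "quartet")
      quartet_canon_str(z$x[1], z$x[2], z$x[3], z$x[4])
    else cycle_skel_str(z$x[1], z$x[2], z$x[3], z$x[4])
    z
  })
}

#' Displayed trees of a rooted network
#'
#' All `2^r` trees obtained by deleting one incoming edge per reticulation and
#' suppressing the resulting degree-2 vertices (duplicates retained).
#'
#' @param rooted a `rooted_net`; edge lengths may be supplied in a `len`
#'   column of `rooted$edges` and are summed when edges merge.
#' @return list of `rooted_net` trees.
#' @export
displayed_trees <- function(rooted) {
  ed <- rooted$edges
  if (is.null(ed$len)) ed$len <- 1
  rets <- as.integer(names(which(table(ed$child) == 2L)))
  if (!length(rets))
    return(list(structure(list(edges = ed, root = rooted$root,
                               labels = rooted$labels), class = "rooted_net")))
  in_edges <- lapply(rets, function(r) which(ed$child == r))
  combos <- expand.grid(lapply(in_edges, function(x) x),
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    drop <- as.integer(unlist(combos[i, ]))
    e <- ed[-drop, , drop = FALSE]
    suppress_rooted_deg2(e, rooted$root, rooted$labels)
  })
}

suppress_rooted_deg2 <- function(e, root, labels) {
  repeat {
    outd <- table(factor(e$parent, levels = unique(c(e$parent, e$child))))
    ind <- table(factor(e$child, levels = unique(c(e$parent, e$child))))
    vs <- unique(c(e$parent, e$child))
    changed <- FALSE
    for (v in vs) {
      iv <- ind[[as.character(v)]]; ov <- outd[[as.character(v)]]
      if (v == root && ov == 1L) {
        j <- which(e$parent == v)
        root <- e$child[j]
        e <- e[-j, , drop = FALSE]
        changed <- TRUE; break
      }
      if (v != root && iv == 1L && ov == 1L && !v %in% labels) {
        jin <- which(e$child == v); jout <- which(e$parent == v)
        newe <- data.frame(parent = e$parent[jin], child = e$child[jout],
                           len = e$len[jin] + e$len[jout])
        e <- rbind(e[-c(jin, jout), , drop = FALSE], newe)
        changed <- TRUE; break
      }
    }
    if (!changed) break
  }
  structure(list(edges = e, root = root, labels = labels), class = "rooted_net")
}

# branch lengths 0.3 / p(u,v): p is the mean edge-count of all root-to-leaf
# paths through (u,v)
assign_branch_lengths <- function(rooted, target = 0.3) {
  ed <- rooted$edges
  leaves <- unname(rooted$labels)
  paths <- list()
  walk <- function(v, eidx) {
    out <- which(ed$parent == v)
    if (!length(out)) { paths[[length(paths) + 1L]] <<- eidx; return(invisible()) }
    for (j in out) walk(ed$child[j], c(eidx, j))
  }
  walk(rooted$root, integer())
  m <- nrow(ed)
  plen <- lengths(paths)
  psum <- numeric(m); pcnt <- integer(m)
  for (k in seq_along(paths)) {
    idx <- paths[[k]]
    psum[idx] <- psum[idx] + plen[k]
    pcnt[idx] <- pcnt[idx] + 1L
  }
  stopifnot(all(pcnt > 0L))
  rooted$edges$len <- target / (psum / pcnt)
  rooted
}

# Kimura 2-parameter transition probabilities for branch length d (expected
# substitutions per site) and transition/transversion rate ratio kappa
k2p_probs <- function(d, kappa = 4) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt) # each of the two transversion targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

k2p_evolve <- function(seq_int, d, kappa = 4) {
  # bases coded 1=A, 2=G, 3=C, 4=T; transitions A<->G, C<->T
  p <- k2p_probs(d, kappa)
  L <- length(seq_int)
  u <- runif(L)
  out <- seq_int
  ts_partner <- c(2L, 1L, 4L, 3L)
  tv1 <- c(3L, 3L, 1L, 1L)
  tv2 <- c(4L, 4L, 2L, 2L)
  hit_ts <- u < p["ts"]
  hit_tv1 <- !hit_ts & u < p["ts"] + p["tv"]
  hit_tv2 <- !hit_ts & !hit_tv1 & u < p["ts"] + 2 * p["tv"]
  out[hit_ts] <- ts_partner[seq_int[hit_ts]]
  out[hit_tv1] <- tv1[seq_int[hit_tv1]]
  out[hit_tv2] <- tv2[seq_int[hit_tv2]]
  out
}

simulate_tree_msa <- function(tree, L, kappa = 4) {
  ed <- tree$edges
  seqs <- list()
  sim <- function(v, s) {
    out <- which(ed$parent == v)
    if (!length(out)) { seqs[[as.character(v)]] <<- s; return(invisible()) }
    for (j in out) sim(ed$child[j], k2p_evolve(s, ed$len[j], kappa))
  }
  sim(tree$root, sample.int(4L, L, replace = TRUE))
  bases <- c("A", "G", "C", "T")
  vapply(setNames(names(tree$labels), names(tree$labels)), function(t)
    paste(bases[seqs[[as.character(tree$labels[[t]])]]], collapse = ""), "")
}

#' Simulate a multiple sequence alignment along a network
#'
#' The network is rooted uniformly at random among its valid root edges,
#' branch lengths are assigned as `0.3/p(u,v)` (so root-to-leaf paths have
#' total length about 0.3), and sites are simulated under the Kimura
#' 2-parameter model with transition/transversion bias 4 along every
#' displayed tree (equal site shares, concatenated).
#'
#' @param net an `sdnet`.
#' @param k total number of sites.
#' @param seed optional integer seed.
#' @param kappa transition/transversion rate ratio (default 4).
#' @return an `msa` object.
#' @export
simulate_alignment <- function(net, k, seed = NULL, kappa = 4) {
  stopifnot(k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ok <- valid_root_edges(net)
  stopifnot(length(ok) > 0L)
  rooted <- root_network(net, edge = ok[sample.int(length(ok), 1L)])
  rooted <- assign_branch_lengths(rooted)
  trees <- displayed_trees(rooted)
  Tn <- length(trees)
  base <- k %/% Tn
  extra <- k - base * Tn
  shares <- rep(base, Tn) + c(rep(1L, extra), rep(0L, Tn - extra))
  taxa <- names(net$labels)
  parts <- lapply(seq_len(Tn), function(i) {
    if (shares[i] == 0L) return(setNames(rep("", length(taxa)), taxa))
    simulate_tree_msa(trees[[i]], shares[i], kappa)[taxa]
  })
  seqs <- vapply(taxa, function(t)
    paste(vapply(parts, `[[`, "", t), collapse = ""), "")
  msa(seqs, taxa)
}

#' Write an alignment to FASTA
#'
#' @param aln an `msa`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  writeLines(paste0(">", aln$labels, "\n", aln$seqs), path)
  invisible(path)
}

#' Quarnet-perturbation noise experiment
#'
#' For each combination of leaf count, perturbation ratio and replicate:
#' generate a random network, induce its dense tf-quarnet set, perturb the
#' requested fraction of skeletons, reconstruct with Squirrel, and record the
#' consistency scores and the reticulation-number difference.
#'
#' @param ns integer vector of leaf counts.
#' @param eps_list numeric vector of perturbation ratios.
#' @param reps replicates per combination.
#' @param seed integer seed (one stream drives the whole experiment).
#' @param tsp_mode passed to [squirrel()].
#' @return data.frame with columns `n`, `eps`, `rep`, `C`, `S`, `dr`
#'   (`r(N) - r(M)`), `r_true`, `r_est`.
#' @export
run_noise_experiment <- function(ns, eps_list, reps, seed = 1L,
                                 tsp_mode = "auto") {
  set.seed(seed)
  out <- list()
  for (n in ns) for (eps in eps_list) for (rep_i in seq_len(reps)) {
    net <- random_network(n)
    Q <- induced_quarnets(net)
    Qe <- perturb_quarnets(Q, eps)
    res <- squirrel(Qe, tsp_mode = tsp_mode)
    QM <- induced_quarnets(res$network)
    out[[length(out) + 1L]] <- data.frame(
      n = n, eps = eps, rep = rep_i,
      C = consistency_score(Q, QM),
      S = symmetric_consistency(Q, QM),
      dr = length(reticulations(net)) - length(reticulations(res$network)),
      r_true = length(reticulations(net)),
      r_est = length(reticulations(res$network)))
  }
  do.call(rbind, out)
}
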