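# Step B2: circular orderings via the travelling salesman problem.
#
# Exact solutions use Held-Karp dynamic programming (default for up to 13
# vertices, matching the published tool's threshold); larger instances use
# seeded simulated annealing with a 2-opt neighbourhood unless exact mode is
# forced.

#' Solve a TSP instance to obtain a circular ordering
#'
#' @param D symmetric distance matrix with zero diagonal (dimnames give the
#'   leaf labels).
#' @param mode `"auto"` (exact up to `exact_max`, annealing above),
#'   `"exact"` (always Held-Karp), or `"anneal"`.
#' @param exact_max Held-Karp threshold for `"auto"` (default 13).
#' @return character vector: a minimum-length (or heuristically short)
#'   Hamiltonian cycle over the labels, starting at the first label.
#' @export
solve_tsp <- function(D, mode = c("auto", "exact", "anneal"), exact_max = 13L) {
  mode <- match.arg(mode)
  s <- nrow(D)
  stopifnot(s >= 3L, isTRUE(all.equal(D, t(D))))
  labs <- rownames(D)
  if (s == 3L) return(labs)
  use_exact <- mode == "exact" || (mode == "auto" && s <= exact_max)
  tour <- if (use_exact) tsp_held_karp(D) else tsp_anneal(D)
  labs[tour]
}

tour_length <- function(D, tour) {
  s <- length(tour)
  sum(D[cbind(tour, tour[c(2:s, 1L)])])
}

# Held-Karp dynamic programming over subsets of {2..s}; city 1 fixed.
tsp_held_karp <- function(D) {
  s <- nrow(D)
  if (s > 20L) stop("exact TSP limited to 20 vertices (memory)")
  m <- s - 1L
  pow <- bitwShiftL(1L, 0:(m - 1L))
  full <- bitwShiftL(1L, m) - 1L
  dp <- matrix(Inf, nrow = full, ncol = m)
  par <- matrix(0L, nrow = full, ncol = m)
  for (j in seq_len(m)) dp[pow[j], j] <- D[1L, j + 1L]
  for (S in seq_len(full)) {
    js <- which(bitwAnd(S, pow) > 0L)
    if (length(js) < 2L) next
    for (j in js) {
      prev <- S - pow[j]
      ks <- js[js != j]
      vals <- dp[prev, ks] + D[ks + 1L, j + 1L]
      b <- which.min(vals)
      dp[S, j] <- vals[b]
      par[S, j] <- ks[b]
    }
  }
  ends <- dp[full, ] + D[2:s, 1L]
  j <- which.min(ends)
  tour <- integer(m)
  S <- full
  for (t in m:1) {
    tour[t] <- j + 1L
    pj <- par[S, j]
    S <- S - pow[j]
    j <- pj
  }
  c(1L, tour)
}

# seeded simulated annealing, 2-opt neighbourhood, geometric cooling
tsp_anneal <- function(D, restarts = 3L, cooling = 0.995) {
  s <- nrow(D)
  iters <- 20L * s^2
  best <- NULL; best_len <- Inf
  for (r in seq_len(restarts)) {
    tour <- c(1L, 1L + sample.int(s - 1L))
    len <- tour_length(D, tour)
    temp <- mean(D[upper.tri(D)])
    for (it in seq_len(iters)) {
      ij <- sort(sample.int(s, 2L))
      i <- ij[1]; j <- ij[2]
      if (i == 1L && j == s) { temp <- temp * cooling; next }
      # reverse tour[i..j]: edges (i-1,i) and (j,j+1) are replaced
      a <- tour[if (i == 1L) s else i - 1L]; b <- tour[i]
      c_ <- tour[j]; d <- tour[if (j == s) 1L else j + 1L]
      delta <- D[a, c_] + D[b, d] - D[a, b] - D[c_, d]
      if (delta < 0 || runif(1L) < exp(-delta / max(temp, 1e-12))) {
        tour[i:j] <- tour[j:i]
        len <- len + delta
      }
      temp <- temp * cooling
    }
    if (len < best_len) { best <- tour; best_len <- len }
  }
  # normalise: start at city 1
  k <- match(1L, best)
  best <- c(best[k:s], if (k > 1L) best[1:(k - 1L)])
  best
}
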