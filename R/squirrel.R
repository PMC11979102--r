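# Main driver: candidate blobtrees -> cycle expansion -> weighted consistency
# scoring -> best network.

#' Reconstruct a semi-directed level-1 network from a dense tf-quarnet set
#'
#' Builds the sequence of `n-3` candidate blobtrees, expands every candidate's
#' multifurcations into cycles and returns the candidate network with the
#' highest weighted tf-quarnet consistency score (ties: the first, i.e. most
#' resolved, candidate).
#'
#' @param Q a `dense_quarnets` object (see [read_quarnets()],
#'   [infer_tf_quarnets()], [induced_quarnets()]).
#' @param outgroup optional taxon label; every candidate is then rootable at
#'   the outgroup's pendant edge.
#' @param tsp_mode `"auto"` (exact TSP up to 13 cycle leaves, simulated
#'   annealing above), `"exact"`, or `"anneal"`.
#' @param seed integer seed governing all stochastic tie-breaks; identical
#'   inputs and seed give identical output.
#' @param rank_mode reticulation-ranking variant, see [reticulation_ranking()].
#' @return an object of class `squirrel_result`: list with `network` (the best
#'   `sdnet`), `score` (its weighted consistency), `candidates` (list of all
#'   `n-3` networks), `scores`, `trees` (the candidate blobtrees) and
#'   `support` (edge supports of T1).
#' @examples
#' net <- cycle_network(c("a", "b", "c", "d", "e"), ret = "a")
#' res <- squirrel(induced_quarnets(net), seed = 1)
#' res$score # 1: the network is reconstructed exactly
#' @export
squirrel <- function(Q, outgroup = NULL, tsp_mode = c("auto", "exact", "anneal"),
                     seed = NULL, rank_mode = "ret") {
  tsp_mode <- match.arg(tsp_mode)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(outgroup) && !outgroup %in% Q$taxa)
    stop("outgroup '", outgroup, "' is not among the taxa")
  cb <- candidate_blobtrees(Q)
  cache <- new.env(parent = emptyenv())
  candidates <- lapply(cb$trees, expand_tree, Q = Q, outgroup = outgroup,
                       tsp_mode = tsp_mode, rank_mode = rank_mode,
                       cache = cache)
  scores <- vapply(candidates, function(N) weighted_consistency(Q, N), 0)
  best <- which.max(scores) # first maximum: most resolved blobtree
  structure(list(network = candidates[[best]], score = scores[best],
                 best_index = best, candidates = candidates, scores = scores,
                 trees = cb$trees, support = cb$support),
            class = "squirrel_result")
}

#' @export
print.squirrel_result <- function(x, ...) {
  cat(sprintf("Squirrel result: %d candidate networks\n", length(x$candidates)))
  cat(sprintf("best candidate: #%d, weighted tf-quarnet consistency C' = %.4f\n",
              x$best_index, x$score))
  cat(sprintf("reticulations in best network: %d\n",
              length(reticulations(x$network))))
  invisible(x)
}
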