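# distances of every ranked edge to a reference edge, via one BFS distance
# matrix: d = 0 for the same edge, else 1 + min node distance between
# closest endpoints (1 = shares a metabolite)
edge_distances_to <- function(net, edge_ids, true_edge) {
  te <- net$edges[net$edges$edge_id == true_edge, ]
  if (nrow(te) != 1) rlang::abort("true_edge not in network")
  nd <- igraph::distances(net$graph, to = c(te$substrate, te$product))
  ids <- rownames(nd)
  m <- match(net$edges$edge_id, edge_ids)
  out <- rep(NA_real_, length(edge_ids))
  for (r in seq_len(nrow(net$edges))) {
    if (is.na(m[r])) next
    if (net$edges$edge_id[r] == true_edge) {
      out[m[r]] <- 0
    } else {
      a <- match(net$edges$substrate[r], ids)
      b <- match(net$edges$product[r], ids)
      out[m[r]] <- 1 + min(nd[a, ], nd[b, ])
    }
  }
  out
}

#' Classify a prediction against a known perturbed reaction
#'
#' Evaluation vocabulary of knockout benchmarks: a prediction is "exact" if
#' the top of the ranking (within `rank_threshold`) contains the perturbed
#' reaction itself (graph distance 0), "first_neighbor" if it contains a
#' directly adjacent reaction (distance 1), otherwise "not_identifiable".
#'
#' @param net An [mns_network()].
#' @param ranking A ranked tibble with `edge_id` and `rank` columns
#'   ([rank_reactions()] output, a baseline ranking, or a
#'   [rank_product_combine()] result with `combined_rank` renamed `rank`).
#' @param true_edge Edge id of the experimentally perturbed reaction.
#' @param rank_threshold Ranks <= this value count as "predicted" (default 1:
#'   only the top prediction).
#' @return A one-row tibble: `true_edge`, `predicted_rank_exact` (rank of
#'   the true edge), `best_first_neighbor_rank`, `class`.
#' @export
classify_prediction <- function(net, ranking, true_edge, rank_threshold = 1) {
  stopifnot(inherits(net, "mns_network"))
  d <- edge_distances_to(net, ranking$edge_id, true_edge)
  rank_exact <- min(ranking$rank[d == 0])
  fn <- ranking$rank[d == 1]
  rank_fn <- if (length(fn) > 0) min(fn) else Inf
  class <- if (rank_exact <= rank_threshold) {
    "exact"
  } else if (rank_fn <= rank_threshold) {
    "first_neighbor"
  } else {
    "not_identifiable"
  }
  tibble::tibble(true_edge = true_edge, predicted_rank_exact = rank_exact,
                 best_first_neighbor_rank = rank_fn, class = class)
}

#' Permutation significance of an identification
#'
#' Compares the observed rank of the perturbed reaction (and, separately,
#' the best rank among its first-neighbor reactions) against the rank
#' distribution obtained by permuting the reaction labels: which edge is
#' designated the truth is redrawn uniformly over the fixed ranking
#' geometry (the ranking itself is not recomputed — the p-value depends only
#' on rank distributions). `p = #permutations(rank <= observed) /
#' n_permutations`, one p-value each for the exact and the first-neighbor
#' identification; a reaction is significantly identified when either
#' p-value is below `alpha`.
#'
#' @inheritParams classify_prediction
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @param alpha Significance cutoff (default 0.05).
#' @return A one-row tibble: `p_exact`, `p_first_neighbor`, `significant`.
#' @export
rank_permutation_significance <- function(net, ranking, true_edge,
                                          n_permutations = 1000, seed = 1L,
                                          alpha = 0.05) {
  stopifnot(inherits(net, "mns_network"))
  ids <- ranking$edge_id
  # per candidate truth: its own rank and its best first-neighbor rank,
  # computed once from edge adjacency (shared metabolite)
  ends <- net$edges[match(ids, net$edges$edge_id), c("substrate", "product")]
  rank_of <- ranking$rank
  fn_rank <- vapply(seq_along(ids), function(r) {
    share <- (ends$substrate %in% c(ends$substrate[r], ends$product[r]) |
                ends$product %in% c(ends$substrate[r], ends$product[r]))
    share[r] <- FALSE
    if (any(share)) min(rank_of[share]) else Inf
  }, numeric(1))

  obs_i <- match(true_edge, ids)
  if (is.na(obs_i)) rlang::abort("true_edge not in ranking")
  draws <- withr::with_seed(as.integer(seed),
                            sample.int(length(ids), n_permutations,
                                       replace = TRUE))
  p_exact <- mean(rank_of[draws] <= rank_of[obs_i])
  p_fn <- mean(fn_rank[draws] <= fn_rank[obs_i])
  tibble::tibble(true_edge = true_edge, p_exact = p_exact,
                 p_first_neighbor = p_fn,
                 significant = p_exact < alpha | p_fn < alpha)
}

#' Hypergeometric overlap test between edge sets
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' overlap when `length(predicted)` edges are drawn from a universe
#' containing `length(known)` marked edges — the standard regulon-overlap
#' test.
#'
#' @param predicted,known Character vectors of edge ids (subsets of the
#'   universe).
#' @param universe Size of the edge universe.
#' @return A one-row tibble: `overlap_count`, `overlap_fraction`, `p`.
#' @export
overlap_test <- function(predicted, known, universe) {
  predicted <- unique(predicted)
  known <- unique(known)
  stopifnot(length(predicted) <= universe, length(known) <= universe)
  k <- length(intersect(predicted, known))
  p <- stats::phyper(k - 1, length(known), universe - length(known),
                     length(predicted), lower.tail = FALSE)
  tibble::tibble(overlap_count = k,
                 overlap_fraction = if (length(predicted) > 0) k / length(predicted) else 0,
                 p = p)
}
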