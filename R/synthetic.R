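#' Generate a synthetic metabolic network
#'
#' Topologies: `chain` (a linear pathway), `branched_tree` (a random tree
#' with node degree at most 4) and `random_sparse` (a connected graph with
#' about 1.3 * n edges: a random spanning tree plus random extra edges).
#' Reactions are labelled `R1`, `R2`, ... with the substrate the earlier
#' node on the construction path. Deterministic given the seed.
#'
#' @param n_metabolites Number of metabolites (>= 3).
#' @param topology `"chain"`, `"branched_tree"` or `"random_sparse"`.
#' @param seed Integer seed.
#' @return An [mns_network()].
#' @export
simulate_network <- function(n_metabolites = 30,
                             topology = c("chain", "branched_tree", "random_sparse"),
                             seed = 1L) {
  topology <- match.arg(topology)
  n <- as.integer(n_metabolites)
  if (n < 3) rlang::abort("need at least 3 metabolites")
  ids <- sprintf("M%02d", seq_len(n))

  edges <- withr::with_seed(as.integer(seed), {
    if (topology == "chain") {
      data.frame(substrate = ids[-n], product = ids[-1])
    } else if (topology == "branched_tree") {
      parent <- integer(n)
      deg <- integer(n)
      for (v in 2:n) {
        open <- which(deg[seq_len(v - 1)] < 4)
        p <- if (length(open) == 1) open else sample(open, 1)
        parent[v] <- p
        deg[p] <- deg[p] + 1
        deg[v] <- deg[v] + 1
      }
      data.frame(substrate = ids[parent[-1]], product = ids[-1])
    } else {
      parent <- c(0, vapply(2:n, function(v) sample(v - 1, 1), integer(1)))
      tree <- data.frame(substrate = ids[parent[-1]], product = ids[-1])
      target <- round(1.3 * n)
      extra <- max(0, target - (n - 1))
      have <- paste(pmin(tree$substrate, tree$product),
                    pmax(tree$substrate, tree$product))
      add <- list()
      guard <- 0
      while (length(add) < extra && guard < 50 * extra) {
        guard <- guard + 1
        uv <- sample(n, 2)
        key <- paste(min(ids[uv]), max(ids[uv]))
        if (key %in% have) next
        have <- c(have, key)
        add[[length(add) + 1]] <- data.frame(substrate = ids[min(uv)],
                                             product = ids[max(uv)])
      }
      rbind(tree, do.call(rbind, add))
    }
  })
  edges$reaction_id <- paste0("R", seq_len(nrow(edges)))
  mns_network(edges)
}

#' Simulate a planted metabolic perturbation
#'
#' Emulates the metabolome pattern of an enzyme knockout: removing the
#' perturbed reactant-pair edge splits the network locally; metabolites on
#' the substrate side accumulate (mean `+effect_size/2`) and metabolites on
#' the product side are depleted (mean `-effect_size/2`), with Gaussian
#' noise on top and a random subset masked unmeasured (partial metabolome
#' coverage). Sidedness on non-chain topologies is decided by BFS distance
#' to the perturbed edge's endpoints, ties to the substrate side. In
#' sequential mode each event (edge, boundary) applies its step from its
#' boundary frame onward; earlier frames carry baseline noise only.
#'
#' @param net An [mns_network()] (e.g. from [simulate_network()]).
#' @param perturbed_edges Character vector of edge ids (planted truth). One
#'   per event; default: the middle edge.
#' @param effect_size Step height delta in log2 units across the fracture.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param fraction_measured Fraction of metabolites retained as measured.
#' @param frames Number of frames S (1 = univariate).
#' @param event_boundaries Integer vector (within 2..S), one boundary per
#'   perturbed edge; required when `frames > 1`.
#' @param seed Integer seed.
#' @return A list (class `mns_synthetic`): `network`, `obs` (an `mns_obs`)
#'   and `truth` (the arguments, plus per-event side assignments).
#' @export
simulate_perturbation <- function(net, perturbed_edges = NULL, effect_size = 2,
                                  noise_sd = 0.5, fraction_measured = 0.8,
                                  frames = 1, event_boundaries = NULL,
                                  seed = 1L) {
  stopifnot(inherits(net, "mns_network"), effect_size >= 0, noise_sd >= 0,
            fraction_measured > 0, fraction_measured <= 1)
  S <- as.integer(frames)
  ids <- net$metabolites$id
  n <- length(ids)
  if (is.null(perturbed_edges)) {
    perturbed_edges <- net$edges$edge_id[ceiling(nrow(net$edges) / 2)]
  }
  if (!all(perturbed_edges %in% net$edges$edge_id)) {
    rlang::abort("perturbed edge not in network")
  }
  if (S > 1) {
    if (is.null(event_boundaries) ||
        length(event_boundaries) != length(perturbed_edges)) {
      rlang::abort("sequential mode needs one event boundary per perturbed edge")
    }
    if (any(event_boundaries < 2 | event_boundaries > S)) {
      rlang::abort("event boundaries must lie within 2..frames")
    }
  } else {
    event_boundaries <- rep(1L, length(perturbed_edges))
  }

  # substrate side = nodes at least as close to the substrate endpoint as to
  # the product endpoint once the perturbed edge is removed (ties: substrate)
  side_of <- function(edge_id) {
    e <- net$edges[net$edges$edge_id == edge_id, ]
    g2 <- igraph::delete_edges(
      net$graph, igraph::get_edge_ids(net$graph, c(e$substrate, e$product)))
    ds <- igraph::distances(g2, v = e$substrate)[1, ids]
    dp <- igraph::distances(g2, v = e$product)[1, ids]
    ifelse(ds <= dp, 1, -1)
  }
  sides <- vapply(perturbed_edges, side_of, numeric(n))

  mean_mat <- matrix(0, nrow = n, ncol = S)
  for (ev in seq_along(perturbed_edges)) {
    active <- if (S == 1) rep(TRUE, S) else seq_len(S) >= event_boundaries[ev]
    mean_mat[, active] <- mean_mat[, active] +
      sides[, ev] * effect_size / 2
  }

  obs_tbl <- withr::with_seed(as.integer(seed), {
    x <- mean_mat + matrix(stats::rnorm(n * S, sd = noise_sd), n, S)
    n_meas <- max(1L, round(fraction_measured * n))
    measured <- sort(sample(n, n_meas))
    x[setdiff(seq_len(n), measured), ] <- NA_real_
    tibble::tibble(metabolite = rep(ids, times = S),
                   frame = rep(seq_len(S), each = n),
                   value = as.vector(x))
  })

  structure(
    list(network = net, obs = as_mns_obs(obs_tbl),
         truth = list(perturbed_edges = perturbed_edges,
                      effect_size = effect_size, noise_sd = noise_sd,
                      fraction_measured = fraction_measured, frames = S,
                      event_boundaries = event_boundaries, sides = sides,
                      seed = as.integer(seed))),
    class = "mns_synthetic"
  )
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: [simulate_network()] then [simulate_perturbation()]
#' with a single planted event on the middle edge. The defaults (chain of
#' 30 metabolites, effect 2, noise 0.5, coverage 0.8, one frame) are the
#' benchmark conditions used throughout the package's tests.
#'
#' @inheritParams simulate_network
#' @inheritParams simulate_perturbation
#' @return An `mns_synthetic` list (`network`, `obs`, `truth`).
#' @export
simulate_dataset <- function(n_metabolites = 30, topology = "chain",
                             effect_size = 2, noise_sd = 0.5,
                             fraction_measured = 0.8, frames = 1,
                             perturbed_edges = NULL, event_boundaries = NULL,
                             seed = 1L) {
  net <- simulate_network(n_metabolites, topology, seed = seed)
  simulate_perturbation(net, perturbed_edges = perturbed_edges,
                        effect_size = effect_size, noise_sd = noise_sd,
                        fraction_measured = fraction_measured, frames = frames,
                        event_boundaries = event_boundaries, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Writes the network TSV, the observation TSV (wide: one column per frame)
#' and the planted truth as JSON.
#'
#' @param sim An `mns_synthetic` from [simulate_perturbation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "mns_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(sim$network, file.path(dir, "network.tsv"))
  wide <- tidyr::pivot_wider(sim$obs, names_from = "frame",
                             names_prefix = "f", values_from = "value")
  readr::write_tsv(wide, file.path(dir, "observations.tsv"))
  truth <- sim$truth
  truth$sides <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
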