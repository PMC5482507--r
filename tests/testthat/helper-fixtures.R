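# shared in-code fixtures and independent oracles

chain_network <- function(n = 4) {
  ids <- sprintf("M%02d", seq_len(n))
  mns_network(data.frame(reaction_id = paste0("R", seq_len(n - 1)),
                         substrate = ids[-n], product = ids[-1]))
}

triangle_network <- function() {
  mns_network(data.frame(reaction_id = c("R1", "R2", "R3"),
                         substrate = c("A", "B", "A"),
                         product = c("B", "C", "C")))
}

# a fully specified observation model without fitting
manual_model <- function(means, stds) {
  structure(list(n_states = length(means), means = means, stds = stds,
                 mean_type = "fixed", std_type = "fix", fit_seed = 0L),
            class = "mns_obs_model")
}

obs_from_values <- function(ids, values) {
  as_mns_obs(tibble::tibble(metabolite = ids, frame = 1L, value = values))
}

# Erdos-Renyi style random network (connected not required)
random_network <- function(n, p, seed) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- withr::with_seed(seed, stats::runif(nrow(pairs)) < p)
  if (!any(keep)) keep[1] <- TRUE
  mns_network(data.frame(reaction_id = paste0("R", seq_len(sum(keep))),
                         substrate = ids[pairs[keep, 1]],
                         product = ids[pairs[keep, 2]]))
}

# oracle: maximal cliques by exhaustive subset enumeration (n <= 12)
brute_force_cliques <- function(net) {
  ids <- net$metabolites$id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(net$edges))) {
    adj[net$edges$substrate[r], net$edges$product[r]] <- TRUE
    adj[net$edges$product[r], net$edges$substrate[r]] <- TRUE
  }
  is_clique <- function(s) all(adj[s, s][upper.tri(matrix(0, length(s), length(s)))])
  subsets <- unlist(lapply(2:n, function(k) utils::combn(n, k, simplify = FALSE)),
                    recursive = FALSE)
  cl <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cl, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, cl)
  out <- lapply(maximal, function(s) sort(ids[s]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# oracle: energy by direct summation over potential factors in R
energy_oracle <- function(net, x, model, lab, lambda1, lambda2 = 0) {
  ids <- net$metabolites$id
  S <- ncol(x)
  e <- 0
  for (s in seq_len(S)) {
    for (cl in net$cliques) {
      labs <- lab[match(cl, ids), s]
      e <- e + lambda1 * (length(unique(labs)) - 1) / length(labs)
    }
    for (i in seq_along(ids)) {
      if (!is.na(x[i, s])) {
        e <- e + (x[i, s] - model$means[lab[i, s]])^2 /
          (2 * model$stds[lab[i, s]]^2)
      }
    }
  }
  if (S > 1) {
    for (s in 2:S) {
      e <- e + sum(lambda2 * ifelse(lab[, s - 1] == lab[, s], -1, 1))
    }
  }
  e
}

# oracle: exhaustive MAP by enumerating all K^(M*S) labelings in R
map_oracle_energy <- function(net, x, model, lambda1, lambda2 = 0) {
  ids <- net$metabolites$id
  S <- ncol(x)
  K <- model$n_states
  nvar <- length(ids) * S
  grid <- do.call(expand.grid, rep(list(seq_len(K)), nvar))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- matrix(as.integer(grid[r, ]), nrow = length(ids), ncol = S)
    e <- energy_oracle(net, x, model, lab, lambda1, lambda2)
    if (e < best) best <- e
  }
  best
}
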