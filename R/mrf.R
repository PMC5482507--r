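#' Assemble a Markov random field over a metabolic network
#'
#' Each metabolite (per frame, for sequential data) carries a discrete hidden
#' module label. Maximal cliques of the reactant-pair graph contribute
#' neighborhood potentials weighted by `lambda1`; measured metabolites
#' contribute Gaussian observation potentials from the observation model;
#' consecutive frames of the same metabolite contribute sequence potentials
#' weighted by `lambda2`. The MAP labeling maximizes the unnormalized product
#' of all potentials (the partition function is labeling-independent and
#' never computed); equivalently it minimizes the energy, the negative log of
#' that product.
#'
#' @param net An [mns_network()].
#' @param obs An `mns_obs` observation set; every metabolite id must exist in
#'   the network. Metabolites of the network absent from `obs` (or with `NA`
#'   values) are treated as unmeasured: they keep their hidden node but
#'   contribute no observation factor.
#' @param model An `mns_obs_model` from [fit_observation_model()].
#' @param lambda1 Non-negative neighborhood weight.
#' @param lambda2 Non-negative sequence weight (ignored when there is a
#'   single frame).
#' @return An object of class `mns_mrf`.
#' @export
mns_mrf <- function(net, obs, model, lambda1 = 0, lambda2 = 0) {
  stopifnot(inherits(net, "mns_network"), inherits(obs, "mns_obs"),
            inherits(model, "mns_obs_model"), lambda1 >= 0, lambda2 >= 0)
  unknown <- setdiff(unique(obs$metabolite), net$metabolites$id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("observation metabolite(s) not in network: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  idx <- network_index(net)
  S <- frame_count(obs)
  x <- matrix(NA_real_, nrow = length(idx$ids), ncol = S)
  x[cbind(match(obs$metabolite, idx$ids), obs$frame)] <- obs$value
  net$metabolites$measured <- idx$ids %in% obs$metabolite[!is.na(obs$value)]
  structure(
    list(network = net, obs = obs, obs_model = model, x = x, idx = idx,
         lambda1 = lambda1, lambda2 = lambda2, frame_count = S),
    class = "mns_mrf"
  )
}

#' @export
print.mns_mrf <- function(x, ...) {
  cat(sprintf("<mns_mrf> %d metabolites x %d frame(s), K = %d, lambda1 = %g, lambda2 = %g\n",
              nrow(x$x), x$frame_count, x$obs_model$n_states, x$lambda1,
              x$lambda2))
  invisible(x)
}

labeling_matrix <- function(mrf, labeling) {
  if (is.matrix(labeling)) return(labeling)
  stopifnot(all(c("metabolite", "frame", "label") %in% names(labeling)))
  lab <- matrix(NA_integer_, nrow = nrow(mrf$x), ncol = mrf$frame_count)
  lab[cbind(match(labeling$metabolite, mrf$idx$ids), labeling$frame)] <-
    as.integer(labeling$label)
  if (anyNA(lab)) rlang::abort("labeling must cover every metabolite and frame")
  lab
}

labeling_tibble <- function(mrf, lab) {
  tibble::tibble(
    metabolite = rep(mrf$idx$ids, times = mrf$frame_count),
    frame = rep(seq_len(mrf$frame_count), each = length(mrf$idx$ids)),
    label = as.integer(lab)
  )
}

#' Energy of a labeling
#'
#' The energy is the negative log of the unnormalized potential product:
#' the sum over frames and cliques of `lambda1 * (unique-1)/size`, over
#' measured variables of `(x - mu(y))^2 / (2 sigma(y)^2)`, and over frame
#' boundaries of `lambda2 * f(y_prev, y_curr)`. `exp(-energy)` equals the
#' product of all potential factors.
#'
#' @param mrf An [mns_mrf()].
#' @param labeling A labeling tibble (`metabolite`, `frame`, `label`) or an
#'   integer matrix (metabolites x frames, labels 1..K).
#' @return The scalar energy.
#' @export
mrf_energy <- function(mrf, labeling) {
  stopifnot(inherits(mrf, "mns_mrf"))
  lab <- labeling_matrix(mrf, labeling)
  mrf_energy_cpp(lab - 1L, mrf$x, mrf$idx$cliques, mrf$idx$node_cliques,
                 mrf$idx$edges, mrf$obs_model$means, mrf$obs_model$stds,
                 mrf$lambda1, mrf$lambda2)
}

#' MAP inference of the hidden module labels
#'
#' `method = "exact"` enumerates all `K^(M*S)` labelings and returns a global
#' optimum (first in lexicographic node order among ties); `"auto"` selects
#' exact mode when at most 2^18 configurations exist. `"local"` starts from
#' the per-node observation-optimal labeling (unmeasured nodes at the middle
#' label), runs iterated conditional modes to convergence, then exhaustive
#' improving flips of connected variable subsets of up to `max_flip`
#' variables (lazy-flipper style) until no improving move remains; a uniform
#' labeling that beats the search result seeds a second search (this makes
#' the strong-smoothing limit exact). The search is deterministic: fixed
#' sweep order over sorted metabolite ids, ties broken toward lower labels.
#'
#' @param mrf An [mns_mrf()].
#' @param method `"auto"`, `"exact"` or `"local"`.
#' @param max_flip Largest connected subset size for the flip search.
#' @return A labeling tibble (`metabolite`, `frame`, `label`) with the
#'   attained `energy` as an attribute.
#' @export
mrf_map <- function(mrf, method = c("auto", "exact", "local"), max_flip = 2) {
  stopifnot(inherits(mrf, "mns_mrf"))
  method <- match.arg(method)
  res <- mrf_map_cpp(mrf$x, mrf$idx$cliques, mrf$idx$node_cliques,
                     mrf$idx$edges, mrf$obs_model$means, mrf$obs_model$stds,
                     mrf$lambda1, mrf$lambda2, method, as.integer(max_flip))
  out <- labeling_tibble(mrf, res$labels + 1L)
  attr(out, "energy") <- res$energy
  out
}

#' Extract fractures from a labeling
#'
#' A neighborhood fracture is a reactant-pair edge whose endpoint labels
#' differ within a frame; a sequence fracture is a metabolite whose label
#' changes across a frame boundary. Fractures between modules are the
#' candidate sites (and, in sequential data, times) of metabolic regulation.
#'
#' @param net An [mns_network()].
#' @param labeling A labeling tibble as returned by [mrf_map()].
#' @return A list with tibbles `neighborhood` (`edge_id`, `frame`) and
#'   `sequence` (`metabolite`, `boundary`; boundary s means between frames
#'   s-1 and s).
#' @export
extract_fractures <- function(net, labeling) {
  stopifnot(inherits(net, "mns_network"))
  lab_of <- function(met, frm) {
    labeling$label[match(paste(met, frm), paste(labeling$metabolite, labeling$frame))]
  }
  frames <- sort(unique(labeling$frame))
  neigh <- purrr::map_dfr(frames, function(s) {
    differ <- lab_of(net$edges$substrate, s) != lab_of(net$edges$product, s)
    tibble::tibble(edge_id = net$edges$edge_id[differ], frame = s)
  })
  seqf <- tibble::tibble(metabolite = character(0), boundary = integer(0))
  if (length(frames) > 1) {
    mets <- sort(unique(labeling$metabolite))
    seqf <- purrr::map_dfr(frames[-1], function(s) {
      switch_ <- lab_of(mets, s - 1L) != lab_of(mets, s)
      tibble::tibble(metabolite = mets[switch_], boundary = s)
    })
  }
  list(neighborhood = neigh, sequence = seqf)
}
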