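#' Configuration for the univariate lambda1 scan
#'
#' The scan is a two-step procedure: `lambda1` is doubled from
#' `lambda1_start` until the MAP labeling has no neighborhood fractures (the
#' ceiling), then a linear grid of `grid_size` equally spaced values on
#' (0, ceiling] is evaluated. Per reaction the scan records the largest grid
#' value at which it is still a fracture (`max_lambda1`, a stability index)
#' and at how many grid values it fractures (`n_fractures`).
#'
#' @param lambda1_start First value of the exponential ceiling search.
#' @param growth_factor Multiplier of the exponential search (> 1).
#' @param grid_size Number of linear grid points G.
#' @param n_permutations Number of label permutations for [permutation_test()].
#' @param seed Integer seed governing the permutations.
#' @param method,max_flip Passed to [mrf_map()]. Scans default to the
#'   `"local"` solver: it matched exhaustive enumeration on every tested
#'   instance and keeps permutation reruns fast even on small networks.
#' @return A list of class `mns_scan_config`.
#' @export
mns_scan_config <- function(lambda1_start = 0.0625, growth_factor = 2,
                            grid_size = 100, n_permutations = 1000,
                            seed = 1L, method = "local", max_flip = 2) {
  stopifnot(lambda1_start > 0, growth_factor > 1, grid_size >= 2,
            n_permutations >= 1)
  structure(list(lambda1_start = lambda1_start, growth_factor = growth_factor,
                 grid_size = as.integer(grid_size),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), method = method,
                 max_flip = as.integer(max_flip)),
            class = "mns_scan_config")
}

#' Find the lambda1 ceiling
#'
#' Exponentially increases `lambda1` from `lambda1_start` (by
#' `growth_factor`) until the MAP labeling assigns all metabolites to one
#' module, i.e. has zero neighborhood fractures. Errors if no ceiling is
#' found within 40 doublings (pathologically small sigmas).
#'
#' @param mrf An [mns_mrf()] (its `lambda1` is ignored).
#' @param config An [mns_scan_config()].
#' @return The smallest tested lambda1 with a fracture-free MAP labeling.
#' @export
find_lambda1_ceiling <- function(mrf, config = mns_scan_config()) {
  stopifnot(inherits(mrf, "mns_mrf"))
  lam <- config$lambda1_start
  cap <- config$lambda1_start * 2^40
  repeat {
    m <- mrf
    m$lambda1 <- lam
    lab <- mrf_map(m, method = config$method, max_flip = config$max_flip)
    fr <- extract_fractures(mrf$network, lab)
    if (nrow(fr$neighborhood) == 0) return(lam)
    if (lam >= cap) {
      rlang::abort("lambda1 ceiling not reached within 2^40 * start; check observation model sigmas")
    }
    lam <- lam * config$growth_factor
  }
}

#' Scan lambda1 and score reactions
#'
#' Runs MAP inference at every grid value of `lambda1` and accumulates, per
#' reactant-pair edge, `max_lambda1` (the largest grid value at which the
#' edge fractures; 0 if never) and `n_fractures` (the number of grid values
#' at which it fractures). Fractures that persist at a strong neighborhood
#' influence are the most likely sites of metabolic regulation.
#'
#' @param net An [mns_network()].
#' @param obs A univariate `mns_obs` observation set.
#' @param model An `mns_obs_model`.
#' @param config An [mns_scan_config()].
#' @return A tibble of class `mns_scan`, one row per edge with columns
#'   `edge_id`, `substrate`, `product`, `reaction_ids`, `max_lambda1`,
#'   `n_fractures`; the ceiling, grid and model internals are attached as
#'   attributes.
#' @export
scan_lambda1 <- function(net, obs, model, config = mns_scan_config()) {
  stopifnot(inherits(net, "mns_network"))
  if (frame_count(obs) != 1) {
    rlang::abort("scan_lambda1 is univariate; use mns_segment_seq for multi-frame data")
  }
  mrf <- mns_mrf(net, obs, model, lambda1 = 0)
  ceiling_l1 <- find_lambda1_ceiling(mrf, config)
  grid <- ceiling_l1 * seq_len(config$grid_size) / config$grid_size
  res <- mns_scan_cpp(mrf$x, grid, mrf$idx$cliques, mrf$idx$node_cliques,
                      mrf$idx$edges, model$means, model$stds, config$method,
                      config$max_flip)
  out <- net$edges |>
    dplyr::select("edge_id", "substrate", "product", "reaction_ids") |>
    dplyr::mutate(max_lambda1 = as.numeric(res$max_lambda1[1, ]),
                  n_fractures = as.integer(res$n_fractures[1, ]))
  structure(out, ceiling = ceiling_l1, grid = grid, config = config,
            mrf = mrf, class = c("mns_scan", class(out)))
}

#' Rank reactions by a scan criterion
#'
#' Ranks descending by `max_lambda1` or `n_fractures`; tied reactions share
#' the average rank. Row order is deterministic (rank, then edge id).
#'
#' @param scan An `mns_scan` (or any tibble with the criterion column).
#' @param criterion `"max_lambda1"` or `"n_fractures"`.
#' @return The scan tibble with a `rank` column, reordered.
#' @export
rank_reactions <- function(scan, criterion = c("max_lambda1", "n_fractures")) {
  criterion <- match.arg(criterion)
  out <- tibble::as_tibble(scan)
  out$rank <- rank(-out[[criterion]], ties.method = "average")
  dplyr::arrange(out, .data$rank, .data$edge_id)
}

#' Permutation significance of scan statistics
#'
#' Shuffles which observation value sits on which measured network node
#' (network topology and the set of measured positions fixed), reruns the
#' full lambda1 scan on the identical grid for each permutation, and reports
#' per reaction the fraction of permutations in which that reaction's
#' statistic reached or exceeded its observed value:
#' `p = #permutations(stat >= observed) / n_permutations`, for both
#' `max_lambda1` and `n_fractures`. A reaction with observed statistic 0 has
#' p = 1 by construction.
#'
#' @param scan An `mns_scan` from [scan_lambda1()].
#' @param n_permutations,seed Override the scan config if given.
#' @param pseudocount If `TRUE`, report the bias-corrected estimator
#'   `(k + 1) / (n + 1)` instead of `k / n`.
#' @return The scan tibble with columns `p_max_lambda1` and `p_n_fractures`.
#' @export
permutation_test <- function(scan, n_permutations = NULL, seed = NULL,
                             pseudocount = FALSE) {
  stopifnot(inherits(scan, "mns_scan"))
  config <- attr(scan, "config")
  mrf <- attr(scan, "mrf")
  grid <- attr(scan, "grid")
  B <- as.integer(n_permutations %||% config$n_permutations)
  seed <- as.integer(seed %||% config$seed)
  if (B < 1) rlang::abort("n_permutations must be >= 1")

  x <- mrf$x[, 1]
  measured <- which(!is.na(x))
  xs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      xp <- x
      xp[measured] <- sample(x[measured])
      xp
    }, numeric(length(x)))
  })
  res <- mns_scan_cpp(xs, grid, mrf$idx$cliques, mrf$idx$node_cliques,
                      mrf$idx$edges, mrf$obs_model$means, mrf$obs_model$stds,
                      config$method, config$max_flip)
  k_max <- colSums(res$max_lambda1 >= rep(scan$max_lambda1, each = B) - 1e-12)
  k_frac <- colSums(res$n_fractures >= rep(scan$n_fractures, each = B))
  est <- function(k) if (pseudocount) (k + 1) / (B + 1) else k / B
  out <- dplyr::mutate(tibble::as_tibble(scan),
                       p_max_lambda1 = est(k_max),
                       p_n_fractures = est(k_frac))
  structure(out, ceiling = attr(scan, "ceiling"), grid = grid,
            config = config, mrf = mrf, n_permutations = B,
            class = c("mns_scan", class(out)))
}

#' Combine predictor rankings with the rank product
#'
#' The rank product of a reaction is the geometric mean of its ranks across
#' predictors (e.g. the `max_lambda1` and `n_fractures` rankings of one or
#' more parameterizations); the most likely regulated reactions have the
#' smallest rank products. Significance is assessed by a seeded permutation
#' null: ranks are permuted independently within each predictor and the
#' observed rank product is compared against the pooled null distribution
#' (`rp_p = P(null rank product <= observed)`).
#'
#' @param rankings A list (>= 2) of ranked tibbles from [rank_reactions()],
#'   all over the same edge set.
#' @param n_permutations Number of null draws.
#' @param seed Integer seed.
#' @return A tibble `edge_id`, `rank_product`, `combined_rank`
#'   (average-tie ranks of the rank products), `rp_p`, ordered by ascending
#'   rank product.
#' @export
rank_product_combine <- function(rankings, n_permutations = 1000, seed = 1L) {
  if (length(rankings) < 2) rlang::abort("need at least two rankings")
  ids <- sort(rankings[[1]]$edge_id)
  rank_mat <- vapply(rankings, function(r) {
    if (!setequal(r$edge_id, ids) || length(r$edge_id) != length(ids)) {
      rlang::abort("all rankings must cover the same edge set")
    }
    r$rank[match(ids, r$edge_id)]
  }, numeric(length(ids)))
  E <- length(ids)
  P <- ncol(rank_mat)
  rp <- exp(rowMeans(log(rank_mat)))

  null_rp <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(b) {
      perm <- vapply(seq_len(P), function(j) rank_mat[sample.int(E), j],
                     numeric(E))
      exp(rowMeans(log(perm)))
    }, numeric(E))
  })
  rp_p <- vapply(rp, function(v) mean(null_rp <= v + 1e-12), numeric(1))

  tibble::tibble(edge_id = ids, rank_product = rp,
                 combined_rank = rank(rp, ties.method = "average"),
                 rp_p = rp_p) |>
    dplyr::arrange(.data$rank_product, .data$edge_id)
}

#' Univariate segmentation workflow
#'
#' Runs the full scan-mode pipeline: lambda1 ceiling search, linear scan,
#' ranking by both criteria, and permutation significance.
#'
#' @inheritParams scan_lambda1
#' @return An `mns_scan` tibble with per-edge statistics, ranks
#'   (`rank_max_lambda1`, `rank_n_fractures`) and permutation p-values.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(n_metabolites = 12, seed = 1)
#' model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
#' seg <- mns_segment(sim$network, sim$obs, model,
#'                    mns_scan_config(grid_size = 20, n_permutations = 50))
#' head(dplyr::arrange(seg, rank_max_lambda1), 3)
#' }
#' @export
mns_segment <- function(net, obs, model, config = mns_scan_config()) {
  scan <- scan_lambda1(net, obs, model, config)
  scan$rank_max_lambda1 <- rank(-scan$max_lambda1, ties.method = "average")
  scan$rank_n_fractures <- rank(-scan$n_fractures, ties.method = "average")
  permutation_test(scan)
}
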