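#' Configuration for the sequential (multi-frame) scan
#'
#' @param grid_size_l1,grid_size_l2 Linear grid sizes over the lambda1 and
#'   lambda2 ranges (the ranges come from [find_lambda_ranges()]).
#' @param weights Data frame with columns `w_s`, `w_n`: the sweep of sequence
#'   and neighborhood fracture-count weights in the score function. Default:
#'   equal weights from 0 to 0.3 in steps of 0.03.
#' @param lambda_start,growth_factor Exponential range-finder settings.
#' @param method,max_flip Passed to [mrf_map()].
#' @return A list of class `mns_seq_config`.
#' @export
mns_seq_config <- function(grid_size_l1 = 15, grid_size_l2 = 15,
                           weights = NULL, lambda_start = 0.0625,
                           growth_factor = 2, method = "local", max_flip = 2) {
  stopifnot(grid_size_l1 >= 2, grid_size_l2 >= 2)
  if (is.null(weights)) {
    w <- seq(0, 0.3, by = 0.03)
    weights <- tibble::tibble(w_s = w, w_n = w)
  }
  weights <- tibble::as_tibble(weights)
  stopifnot(all(c("w_s", "w_n") %in% names(weights)),
            all(weights$w_s >= 0), all(weights$w_n >= 0))
  structure(list(grid_size_l1 = as.integer(grid_size_l1),
                 grid_size_l2 = as.integer(grid_size_l2), weights = weights,
                 lambda_start = lambda_start, growth_factor = growth_factor,
                 method = method, max_flip = as.integer(max_flip)),
            class = "mns_seq_config")
}

#' Determine the lambda1 and lambda2 scan ranges
#'
#' The coarse-grained pre-scan of sequential mode: lambda1 is exponentially
#' increased with lambda2 = 0 until the MAP labeling has no neighborhood
#' fractures, and lambda2 is exponentially increased with lambda1 = 0 until
#' it has no sequence fractures. (With lambda1 = 0 the sequence weight
#' cannot remove neighborhood fractures, so the second search terminates on
#' the sequence-fracture count.)
#'
#' @param mrf A sequential [mns_mrf()] (S >= 2 frames).
#' @param config An [mns_seq_config()].
#' @return A list `lambda1_max`, `lambda2_max`.
#' @export
find_lambda_ranges <- function(mrf, config = mns_seq_config()) {
  stopifnot(inherits(mrf, "mns_mrf"))
  if (mrf$frame_count < 2) {
    rlang::abort("sequential mode needs at least 2 frames")
  }
  cap <- config$lambda_start * 2^40
  search <- function(which) {
    lam <- config$lambda_start
    repeat {
      m <- mrf
      m$lambda1 <- if (which == "l1") lam else 0
      m$lambda2 <- if (which == "l2") lam else 0
      fr <- extract_fractures(mrf$network,
                              mrf_map(m, method = config$method,
                                      max_flip = config$max_flip))
      n <- if (which == "l1") nrow(fr$neighborhood) else nrow(fr$sequence)
      if (n == 0) return(lam)
      if (lam >= cap) rlang::abort("lambda range search exceeded 2^40 * start")
      lam <- lam * config$growth_factor
    }
  }
  list(lambda1_max = search("l1"), lambda2_max = search("l2"))
}

#' Evaluate the sequential score at one (lambda1, lambda2) point
#'
#' Runs MAP inference at the given weights and evaluates
#' `score = mean(psi_O) - w_s * #seq / max(#seq) - w_n * #neigh / max(#neigh)`
#' where `mean(psi_O)` is the observation potential of the inferred labeling
#' averaged over measured variables (so all three score terms live on a
#' [0, 1] scale and the fracture weights can steer the optimum), the
#' fracture counts come from the inferred labeling, and the maxima are the
#' structure-determined totals `M * (S - 1)` (sequence) and `#edges * S`
#' (neighborhood). A point is excluded from score maximization when its
#' observation potential is zero or it has no fractures at all.
#'
#' @param mrf A sequential [mns_mrf()] (its lambdas are ignored).
#' @param lambda1,lambda2 Non-negative weights of the evaluated point.
#' @param w_s,w_n Fracture-count weights.
#' @param config An [mns_seq_config()].
#' @return A one-row tibble: `lambda1`, `lambda2`, `mean_obs_potential`,
#'   `n_seq_fractures`, `n_neigh_fractures`, `score`, `excluded`.
#' @export
evaluate_score <- function(mrf, lambda1, lambda2, w_s = 0, w_n = 0,
                           config = mns_seq_config()) {
  m <- mrf
  m$lambda1 <- lambda1
  m$lambda2 <- lambda2
  lab <- mrf_map(m, method = config$method, max_flip = config$max_flip)
  score_entry(mrf, lab, lambda1, lambda2, w_s, w_n)
}

score_entry <- function(mrf, lab, lambda1, lambda2, w_s, w_n) {
  fr <- extract_fractures(mrf$network, lab)
  lab_mat <- labeling_matrix(mrf, lab)
  measured <- !is.na(mrf$x)
  psi <- observation_potential(mrf$x[measured],
                               lab_mat[measured], mrf$obs_model)
  # mean over measured variables keeps the observation term on the same
  # [0, 1] scale as the normalized fracture penalties, so weights of a few
  # percent can actually steer the optimum and scores compare across datasets
  mean_obs <- if (any(measured)) mean(psi) else 0
  n_seq <- nrow(fr$sequence)
  n_neigh <- nrow(fr$neighborhood)
  max_seq <- nrow(mrf$x) * (mrf$frame_count - 1)
  max_neigh <- nrow(mrf$network$edges) * mrf$frame_count
  score <- mean_obs - w_s * n_seq / max_seq - w_n * n_neigh / max_neigh
  tibble::tibble(lambda1 = lambda1, lambda2 = lambda2,
                 mean_obs_potential = mean_obs, n_seq_fractures = n_seq,
                 n_neigh_fractures = n_neigh, score = score,
                 excluded = mean_obs == 0 || (n_seq + n_neigh) == 0)
}

#' Sequential segmentation: weight sweep over the score surface
#'
#' Lays a `grid_size_l1 x grid_size_l2` linear grid over (0, lambda1_max] x
#' (0, lambda2_max], runs MAP inference once per grid point, then for every
#' weight pair (w_s, w_n) scores all points, normalizes the scores of
#' non-excluded points to [0, 1], and selects the score-maximal point (ties:
#' smallest lambda1, then smallest lambda2). Each selected point's fracture
#' sets are recorded; per fracture the result reports the largest weight at
#' which it survives (its stability index) and, for neighborhood fractures,
#' the first frame at which the fracture appears — the read-out of the
#' sequential order of regulation events.
#'
#' @param net An [mns_network()].
#' @param obs A sequential `mns_obs` (S >= 2 frames).
#' @param model An `mns_obs_model` (e.g. fixed means c(-0.1, 0, 0.1) with
#'   all-data standard deviations for weak-effect time courses).
#' @param config An [mns_seq_config()].
#' @return An object of class `mns_seq_scan`: a list with
#'   `surface` (per-point tibble with per-weight scores), `selection` (one
#'   row per weight pair: selected lambdas, counts, normalized score,
#'   `all_excluded` flag), `labelings` (list of labeling tibbles per weight
#'   pair), `fractures` (list of fracture sets per weight pair), `ordering`
#'   (tibble: fracture, type, first frame/boundary, stability index) and
#'   `pseudo_steady_states` (weight intervals with constant fracture counts).
#' @export
mns_segment_seq <- function(net, obs, model, config = mns_seq_config()) {
  mrf <- mns_mrf(net, obs, model)
  ranges <- find_lambda_ranges(mrf, config)
  g1 <- ranges$lambda1_max * seq_len(config$grid_size_l1) / config$grid_size_l1
  g2 <- ranges$lambda2_max * seq_len(config$grid_size_l2) / config$grid_size_l2
  pts <- tidyr::expand_grid(lambda1 = g1, lambda2 = g2)

  labs <- purrr::pmap(pts, function(lambda1, lambda2) {
    m <- mrf
    m$lambda1 <- lambda1
    m$lambda2 <- lambda2
    mrf_map(m, method = config$method, max_flip = config$max_flip)
  })
  base <- purrr::pmap_dfr(
    list(labs, pts$lambda1, pts$lambda2),
    function(lab, l1, l2) score_entry(mrf, lab, l1, l2, 0, 0)
  )

  weights <- config$weights
  selection <- purrr::pmap_dfr(weights, function(w_s, w_n) {
    sc <- base$mean_obs_potential -
      w_s * base$n_seq_fractures / (nrow(mrf$x) * (mrf$frame_count - 1)) -
      w_n * base$n_neigh_fractures / (nrow(net$edges) * mrf$frame_count)
    ok <- !base$excluded
    if (!any(ok)) {
      return(tibble::tibble(w_s = w_s, w_n = w_n, lambda1 = NA_real_,
                            lambda2 = NA_real_, score = NA_real_,
                            score_norm = NA_real_, n_seq_fractures = NA_integer_,
                            n_neigh_fractures = NA_integer_,
                            all_excluded = TRUE))
    }
    rng <- range(sc[ok])
    norm <- if (diff(rng) > 0) (sc - rng[1]) / diff(rng) else rep(1, length(sc))
    best <- which(ok)[order(-sc[ok], base$lambda1[ok], base$lambda2[ok])][1]
    tibble::tibble(w_s = w_s, w_n = w_n, lambda1 = base$lambda1[best],
                   lambda2 = base$lambda2[best], score = sc[best],
                   score_norm = norm[best],
                   n_seq_fractures = base$n_seq_fractures[best],
                   n_neigh_fractures = base$n_neigh_fractures[best],
                   all_excluded = FALSE)
  })

  sel_idx <- match(paste(selection$lambda1, selection$lambda2),
                   paste(base$lambda1, base$lambda2))
  labelings <- purrr::map(sel_idx, function(i) if (is.na(i)) NULL else labs[[i]])
  fractures <- purrr::map(labelings, function(lab) {
    if (is.null(lab)) NULL else extract_fractures(net, lab)
  })

  ordering <- seq_ordering(weights, fractures)
  pss <- pseudo_steady_states(weights, selection)

  structure(list(surface = base, selection = selection, labelings = labelings,
                 fractures = fractures, ordering = ordering,
                 pseudo_steady_states = pss, ranges = ranges,
                 config = config, mrf = mrf),
            class = "mns_seq_scan")
}

# per fracture: first frame (neighborhood) or boundary (sequence) and the
# largest sweep weight at which it survives
seq_ordering <- function(weights, fractures) {
  rows <- purrr::imap_dfr(fractures, function(fr, w_idx) {
    if (is.null(fr)) return(tibble::tibble())
    dplyr::bind_rows(
      if (nrow(fr$neighborhood) > 0) {
        fr$neighborhood |>
          dplyr::group_by(.data$edge_id) |>
          dplyr::summarise(first_frame = min(.data$frame), .groups = "drop") |>
          dplyr::mutate(type = "neighborhood", fracture = .data$edge_id) |>
          dplyr::select("fracture", "type", "first_frame")
      },
      if (nrow(fr$sequence) > 0) {
        fr$sequence |>
          dplyr::group_by(.data$metabolite) |>
          dplyr::summarise(first_frame = min(.data$boundary), .groups = "drop") |>
          dplyr::mutate(type = "sequence", fracture = .data$metabolite) |>
          dplyr::select("fracture", "type", "first_frame")
      }
    ) |>
      dplyr::mutate(w_s = weights$w_s[w_idx], w_n = weights$w_n[w_idx])
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(fracture = character(0), type = character(0),
                          first_frame = integer(0), stability_w = numeric(0)))
  }
  rows |>
    dplyr::group_by(.data$fracture, .data$type) |>
    dplyr::summarise(first_frame = min(.data$first_frame),
                     stability_w = max(pmax(.data$w_s, .data$w_n)),
                     .groups = "drop") |>
    dplyr::arrange(.data$first_frame, .data$fracture)
}

# maximal runs of consecutive weight pairs with identical fracture counts
pseudo_steady_states <- function(weights, selection) {
  tot <- selection$n_seq_fractures + selection$n_neigh_fractures
  n <- length(tot)
  if (n == 0) return(tibble::tibble())
  change <- diff(tot) != 0
  change[is.na(change)] <- TRUE
  grp <- cumsum(c(TRUE, change))
  tibble::tibble(w_s = weights$w_s, w_n = weights$w_n, total = tot,
                 run = grp) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(w_from = min(pmax(.data$w_s, .data$w_n)),
                     w_to = max(pmax(.data$w_s, .data$w_n)),
                     total_fractures = dplyr::first(.data$total),
                     n_points = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"run")
}

#' @export
print.mns_seq_scan <- function(x, ...) {
  cat(sprintf("<mns_seq_scan> %d x %d lambda grid, %d weight pairs, %d ordered fractures\n",
              x$config$grid_size_l1, x$config$grid_size_l2,
              nrow(x$selection), nrow(x$ordering)))
  invisible(x)
}
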