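#' Impute unmeasured metabolites by random sampling
#'
#' The comparison baselines need a value on every network metabolite;
#' undetected metabolites receive values sampled with replacement from a
#' pool (typically the values of unannotated spectral features; by default
#' the observed value distribution itself, which permits benchmark runs on
#' synthetic data). Measured values are untouched; sampling is seeded.
#'
#' @param obs A univariate `mns_obs`.
#' @param net An [mns_network()].
#' @param pool Numeric vector to sample from; default: the observed values.
#' @param seed Integer seed.
#' @return An `mns_obs` covering every network metabolite.
#' @export
impute_unmeasured <- function(obs, net, pool = NULL, seed = 1L) {
  stopifnot(inherits(obs, "mns_obs"), inherits(net, "mns_network"))
  if (frame_count(obs) != 1) rlang::abort("baselines are univariate")
  vals <- stats::setNames(obs$value, obs$metabolite)
  missing <- setdiff(net$metabolites$id, names(vals)[!is.na(vals)])
  pool <- pool %||% obs$value[!is.na(obs$value)]
  if (length(missing) > 0 && length(pool) == 0) {
    rlang::abort("imputation pool is empty but unmeasured metabolites exist")
  }
  imputed <- if (length(missing) > 0) {
    withr::with_seed(as.integer(seed),
                     sample(pool, length(missing), replace = TRUE))
  } else {
    numeric(0)
  }
  out <- tibble::tibble(
    metabolite = c(names(vals)[!is.na(vals)], missing),
    frame = 1L,
    value = c(vals[!is.na(vals)], imputed)
  )
  as_mns_obs(out)
}

baseline_ranking <- function(net, scores, raw, method, seed) {
  out <- net$edges |>
    dplyr::select("edge_id", "substrate", "product", "reaction_ids") |>
    dplyr::mutate(score = scores, score_raw = raw,
                  rank = rank(-abs(scores), ties.method = "average")) |>
    dplyr::arrange(.data$rank, .data$edge_id)
  structure(out, method = method, imputation_seed = seed,
            class = c("mns_baseline", class(out)))
}

#' Reporter-reaction baseline
#'
#' Scores each reaction by the aggregated z-score of its direct substrate
#' and product: `z_raw = (z_s + z_p) / sqrt(2)`, then background-corrects by
#' subtracting the mean and dividing by the standard deviation of aggregates
#' from `n_background` same-size random metabolite draws (seeded). Reactions
#' are ranked by descending absolute corrected score. A symmetric change
#' (+2 on one side, -2 on the other) is invisible to this statistic.
#'
#' @param net An [mns_network()].
#' @param obs A fully valued univariate `mns_obs` (see [impute_unmeasured()]).
#' @param n_background Number of random draws for the background correction.
#' @param seed Integer seed.
#' @return A ranked `mns_baseline` tibble (`edge_id`, `score`, `score_raw`
#'   — the uncorrected aggregate — and `rank`).
#' @export
reporter_reaction_scores <- function(net, obs, n_background = 1000, seed = 1L) {
  stopifnot(inherits(net, "mns_network"), inherits(obs, "mns_obs"))
  vals <- stats::setNames(obs$value, obs$metabolite)
  need <- unique(c(net$edges$substrate, net$edges$product))
  if (any(is.na(vals[need]))) {
    rlang::abort("all reaction endpoints must be valued; run impute_unmeasured first")
  }
  raw <- (vals[net$edges$substrate] + vals[net$edges$product]) / sqrt(2)
  bg <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_background), function(b) {
      sum(sample(vals[need], 2, replace = FALSE)) / sqrt(2)
    }, numeric(1))
  })
  corrected <- (raw - mean(bg)) / stats::sd(bg)
  baseline_ranking(net, unname(corrected), unname(raw), "reporter", seed)
}

#' Mass-action-ratio baseline
#'
#' For log2 fold-change observations, the change of a reaction's
#' product-to-substrate mass-action ratio between conditions is
#' `|fc(product) - fc(substrate)|` on the log scale; reactions are ranked by
#' descending absolute score. Equal fold-changes on both sides leave the
#' ratio unbroken (score 0).
#'
#' @inheritParams reporter_reaction_scores
#' @return A ranked `mns_baseline` tibble.
#' @export
mass_action_scores <- function(net, obs, seed = 1L) {
  stopifnot(inherits(net, "mns_network"), inherits(obs, "mns_obs"))
  vals <- stats::setNames(obs$value, obs$metabolite)
  need <- unique(c(net$edges$substrate, net$edges$product))
  if (any(is.na(vals[need]))) {
    rlang::abort("all reaction endpoints must be valued; run impute_unmeasured first")
  }
  score <- abs(vals[net$edges$product] - vals[net$edges$substrate])
  baseline_ranking(net, unname(score), unname(score), "mass_action", seed)
}
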