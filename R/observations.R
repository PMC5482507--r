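#' Read per-metabolite differential observations
#'
#' Observations are unitless differential values per metabolite (log2
#' fold-changes between two conditions, or z-scores). Univariate data has one
#' value column; sequential data (time courses, dilution series) has one
#' column per frame. Empty or non-numeric cells mark a metabolite as
#' unmeasured in that frame.
#'
#' @param path TSV with header `metabolite<TAB>value` or
#'   `metabolite<TAB>f1<TAB>f2...`.
#' @return An `mns_obs` tibble in long form: `metabolite`, `frame`, `value`
#'   (NA = unmeasured), with attribute `frame_count`.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("observation file not found: ", path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 2) rlang::abort("observation table needs an id column and at least one value column")
  as_mns_obs(tab)
}

#' Coerce a data frame to an observation set
#'
#' @param x A data frame whose first column is the metabolite id and whose
#'   remaining columns are per-frame values, or an already-long data frame
#'   with columns `metabolite`, `frame`, `value`.
#' @return An `mns_obs` tibble (long form).
#' @export
as_mns_obs <- function(x) {
  x <- tibble::as_tibble(x)
  if (all(c("metabolite", "frame", "value") %in% names(x))) {
    long <- dplyr::mutate(x,
                          metabolite = as.character(.data$metabolite),
                          frame = as.integer(.data$frame),
                          value = suppressWarnings(as.numeric(.data$value)))
  } else {
    ids <- as.character(x[[1]])
    dup <- ids[duplicated(ids)]
    if (length(dup) > 0) {
      rlang::abort(paste0("duplicated metabolite row(s): ",
                          paste(unique(dup), collapse = ", ")))
    }
    vals <- x[, -1, drop = FALSE]
    long <- purrr::imap_dfr(seq_len(ncol(vals)), function(j, nm) {
      tibble::tibble(metabolite = ids, frame = j,
                     value = suppressWarnings(as.numeric(vals[[j]])))
    })
  }
  dup <- long |>
    dplyr::count(.data$metabolite, .data$frame) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0("duplicated metabolite row(s): ",
                        paste(unique(dup$metabolite), collapse = ", ")))
  }
  frames <- sort(unique(long$frame))
  if (!identical(frames, seq_along(frames))) {
    rlang::abort("frame indices must be contiguous from 1")
  }
  if (any(is.infinite(long$value), na.rm = TRUE)) {
    rlang::abort("observation values must be finite")
  }
  for (f in frames) {
    if (all(is.na(long$value[long$frame == f]))) {
      rlang::abort(paste0("frame ", f, " has no numeric values"))
    }
  }
  out <- dplyr::arrange(long, .data$frame, .data$metabolite)
  structure(out, frame_count = length(frames),
            class = c("mns_obs", class(out)))
}

#' Number of frames in an observation set
#' @param obs An `mns_obs` object.
#' @return Integer number of frames (1 for univariate data).
#' @export
frame_count <- function(obs) {
  attr(obs, "frame_count") %||% max(obs$frame)
}

#' The observation-model parameterization grid
#'
#' The observation model is tuned by three switches: the number of hidden
#' module labels (3, 4 or 5), how the state-dependent means are derived
#' (k-means cluster centers, or values equally spaced between the 0.001 and
#' 0.999 quantiles of the pooled data) and how the state-dependent standard
#' deviations are derived (fixed at 1, per-cluster k-means standard
#' deviations, or the standard deviation of the complete data). The full
#' Cartesian grid has 18 members, labelled `P1`..`P18` with `n_states` as the
#' major key, then `mean_type` (`kmeans` before `quantile`), then `std_type`
#' (`fix`, `kmeans`, `all_data`); under this ordering `P3` is
#' (3 states, k-means means, all-data standard deviations).
#'
#' @return A tibble with columns `id`, `n_states`, `mean_type`, `std_type`.
#' @export
mns_parameterizations <- function() {
  grid <- tidyr::expand_grid(
    n_states = c(3L, 4L, 5L),
    mean_type = c("kmeans", "quantile"),
    std_type = c("fix", "kmeans", "all_data")
  )
  dplyr::mutate(grid, id = paste0("P", dplyr::row_number()),
                .before = "n_states")
}

#' Fit the hidden-state Gaussian observation model
#'
#' Each hidden label k carries a Gaussian observation potential with mean
#' `mu(k)` and standard deviation `sigma(k)`. Means come from seeded 1-D
#' k-means (10 restarts, best within-cluster sum of squares), from equal
#' spacing on the 0.001--0.999 quantile range of the pooled data, or are
#' user-fixed (`fixed_means`, e.g. `c(-0.1, 0, 0.1)` for weak-effect
#' sequential data). Standard deviations are 1 for every state (`fix`), the
#' pooled-data standard deviation (`all_data`), or the per-cluster k-means
#' standard deviations matched to the sorted centers (`kmeans`;
#' `kmeans_std = "pooled"` instead assigns every state the average cluster
#' standard deviation). Labels are always ordered by ascending mean so that
#' "decreased / unchanged / increased" semantics are stable. Singleton or
#' zero-variance clusters get a floor of 1e-6 on sigma.
#'
#' @param obs An `mns_obs` object (all frames are pooled for fitting).
#' @param n_states Number of hidden labels K (>= 2).
#' @param mean_type `"kmeans"`, `"quantile"` or `"fixed"`.
#' @param std_type `"fix"`, `"kmeans"` or `"all_data"`.
#' @param seed Integer seed for the k-means restarts.
#' @param fixed_means Numeric vector of length `n_states`, required when
#'   `mean_type = "fixed"`.
#' @param fixed_stds Constant standard deviation used by `std_type = "fix"`
#'   (default 1; a single value recycled over states).
#' @param kmeans_std `"per_cluster"` (default) or `"pooled"`.
#' @return An object of class `mns_obs_model` with fields `n_states`,
#'   `means`, `stds`, `mean_type`, `std_type`, `fit_seed`.
#' @examples
#' obs <- as_mns_obs(data.frame(metabolite = letters[1:6],
#'                              value = c(-2, -2, 0, 0, 2, 2)))
#' fit_observation_model(obs, 3, "kmeans", "fix", seed = 1)
#' @export
fit_observation_model <- function(obs, n_states = 3, mean_type = c("kmeans", "quantile", "fixed"),
                                  std_type = c("all_data", "fix", "kmeans"),
                                  seed = 1L, fixed_means = NULL,
                                  fixed_stds = 1,
                                  kmeans_std = c("per_cluster", "pooled")) {
  mean_type <- match.arg(mean_type)
  std_type <- match.arg(std_type)
  kmeans_std <- match.arg(kmeans_std)
  n_states <- as.integer(n_states)
  if (n_states < 2) rlang::abort("n_states must be >= 2")

  x <- obs$value[!is.na(obs$value)]
  if (length(unique(x)) < n_states) {
    rlang::abort(paste0("need at least ", n_states,
                        " distinct observation values to fit ", n_states,
                        " states"))
  }

  km <- NULL
  if (mean_type == "kmeans" || std_type == "kmeans") {
    km <- withr::with_seed(seed, stats::kmeans(x, centers = n_states,
                                               nstart = 10, iter.max = 100))
  }

  means <- switch(mean_type,
    kmeans = sort(as.numeric(km$centers)),
    quantile = {
      q <- stats::quantile(x, c(0.001, 0.999), names = FALSE)
      seq(q[1], q[2], length.out = n_states)
    },
    fixed = {
      if (is.null(fixed_means) || length(fixed_means) != n_states) {
        rlang::abort("mean_type = 'fixed' requires fixed_means of length n_states")
      }
      sort(as.numeric(fixed_means))
    }
  )
  if (any(diff(means) <= 0)) {
    rlang::abort("state means must be strictly increasing after sorting")
  }

  stds <- switch(std_type,
    fix = rep(fixed_stds, length.out = n_states),
    all_data = rep(stats::sd(x), n_states),
    kmeans = {
      ord <- order(as.numeric(km$centers))
      per <- vapply(ord, function(cl) {
        v <- x[km$cluster == cl]
        if (length(v) < 2) 0 else stats::sd(v)
      }, numeric(1))
      if (kmeans_std == "pooled") per <- rep(mean(per), n_states)
      per
    }
  )
  if (any(stds < 1e-6)) {
    rlang::warn("degenerate cluster standard deviation floored at 1e-6")
    stds <- pmax(stds, 1e-6)
  }

  structure(
    list(n_states = n_states, means = means, stds = stds,
         mean_type = mean_type, std_type = std_type, fit_seed = seed),
    class = "mns_obs_model"
  )
}

#' @export
print.mns_obs_model <- function(x, ...) {
  cat(sprintf("<mns_obs_model> K = %d (means: %s; stds: %s)\n", x$n_states,
              paste(signif(x$means, 4), collapse = ", "),
              paste(signif(x$stds, 4), collapse = ", ")))
  invisible(x)
}

#' Gaussian observation potential
#'
#' `psi_O(x, k) = exp(-(x - mu(k))^2 / (2 sigma(k)^2))`, the unnormalized
#' Gaussian kernel tying an observed differential value to a hidden label.
#' Unmeasured metabolites contribute no observation factor (a factor of 1).
#'
#' @param x Observed value(s).
#' @param state Label index (1-based), recycled against `x`.
#' @param model An `mns_obs_model`.
#' @return Potential value(s) in (0, 1]; 1 for `NA` observations.
#' @export
observation_potential <- function(x, state, model) {
  stopifnot(inherits(model, "mns_obs_model"))
  mu <- model$means[state]
  sig <- model$stds[state]
  out <- exp(-(x - mu)^2 / (2 * sig^2))
  out[is.na(x)] <- 1
  out
}

#' Neighborhood potential of a clique labeling
#'
#' `psi_N = exp(-lambda1 * (unique - 1) / size)` where `unique` is the number
#' of distinct labels in the clique and `size` its number of members. Equals
#' 1 when the clique is label-homogeneous; decays with label diversity at a
#' rate set by the neighborhood weight `lambda1`.
#'
#' @param labels Integer vector of labels of the clique members (size >= 2).
#' @param lambda1 Non-negative neighborhood weight.
#' @return Potential value in (0, 1].
#' @export
neighborhood_potential <- function(labels, lambda1) {
  stopifnot(length(labels) >= 2, lambda1 >= 0)
  exp(-lambda1 * (length(unique(labels)) - 1) / length(labels))
}

#' Sequence potential between consecutive frames
#'
#' `psi_S = exp(-lambda2 * f)` with `f = -1` if the metabolite keeps its
#' label across the frame boundary and `+1` if it switches; `lambda2` sets
#' how strongly consecutive frames are pulled toward equal labels.
#'
#' @param label_prev,label_curr Labels at frames s-1 and s.
#' @param lambda2 Non-negative sequence weight.
#' @return A positive potential value.
#' @export
sequence_potential <- function(label_prev, label_curr, lambda2) {
  stopifnot(lambda2 >= 0)
  exp(-lambda2 * ifelse(label_prev == label_curr, -1, 1))
}

#' Log2 ratio helper
#'
#' Convenience for forming differential observations from two vectors of
#' (strictly positive) intensities.
#'
#' @param case,control Positive numeric vectors.
#' @return `log2(case / control)`.
#' @export
log2_ratio <- function(case, control) {
  stopifnot(all(case > 0, na.rm = TRUE), all(control > 0, na.rm = TRUE))
  log2(case / control)
}
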