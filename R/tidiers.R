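#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted observation model
#'
#' @param x An `mns_obs_model`.
#' @param ... Unused.
#' @return A tibble with one row per hidden state: `state`, `mean`, `sd`.
#' @export
tidy.mns_obs_model <- function(x, ...) {
  tibble::tibble(state = seq_len(x$n_states), mean = x$means, sd = x$stds)
}

#' @rdname tidy.mns_obs_model
#' @return For `glance`: a one-row tibble with `n_states`, `mean_type`,
#'   `std_type`, `fit_seed`.
#' @export
glance.mns_obs_model <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, mean_type = x$mean_type,
                 std_type = x$std_type, fit_seed = x$fit_seed)
}

#' Tidy a lambda1 scan
#'
#' @param x An `mns_scan`.
#' @param ... Unused.
#' @return The per-edge statistics as a plain tibble.
#' @export
tidy.mns_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$reaction_ids <- vapply(out$reaction_ids, paste, character(1),
                             collapse = ",")
  out
}

#' @rdname tidy.mns_scan
#' @return For `glance`: a one-row summary (`n_edges`, `lambda1_ceiling`,
#'   `grid_size`, `n_fractured_edges`).
#' @export
glance.mns_scan <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x),
                 lambda1_ceiling = attr(x, "ceiling"),
                 grid_size = length(attr(x, "grid")),
                 n_fractured_edges = sum(x$n_fractures > 0))
}

#' Tidy a sequential scan
#'
#' @param x An `mns_seq_scan`.
#' @param ... Unused.
#' @return The per-weight-pair selection tibble.
#' @export
tidy.mns_seq_scan <- function(x, ...) x$selection

#' @rdname tidy.mns_seq_scan
#' @export
glance.mns_seq_scan <- function(x, ...) {
  tibble::tibble(lambda1_max = x$ranges$lambda1_max,
                 lambda2_max = x$ranges$lambda2_max,
                 n_weight_pairs = nrow(x$selection),
                 n_ordered_fractures = nrow(x$ordering))
}

#' Plot per-reaction scan statistics
#'
#' Lollipop plot of `max_lambda1` (or `n_fractures`) per reactant-pair edge,
#' ordered by the statistic.
#'
#' @param object An `mns_scan`.
#' @param criterion `"max_lambda1"` or `"n_fractures"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mns_scan <- function(object, criterion = c("max_lambda1", "n_fractures"),
                              ...) {
  criterion <- match.arg(criterion)
  df <- tibble::as_tibble(object)
  df$edge_id <- stats::reorder(df$edge_id, df[[criterion]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[criterion]], y = .data$edge_id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$edge_id),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = criterion, y = "reaction (reactant pair)") +
    ggplot2::theme_minimal()
}

#' Plot a sequential score surface
#'
#' Tile plot of the score over the (lambda1, lambda2) grid at a given weight
#' pair; excluded points are blanked.
#'
#' @param object An `mns_seq_scan`.
#' @param w_s,w_n Fracture-count weights applied to the surface.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mns_seq_scan <- function(object, w_s = 0, w_n = 0, ...) {
  b <- object$surface
  sc <- b$mean_obs_potential -
    w_s * b$n_seq_fractures / (nrow(object$mrf$x) * (object$mrf$frame_count - 1)) -
    w_n * b$n_neigh_fractures /
      (nrow(object$mrf$network$edges) * object$mrf$frame_count)
  df <- dplyr::mutate(b, score = ifelse(b$excluded, NA_real_, sc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda1, y = .data$lambda2,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(lambda[1]), y = expression(lambda[2])) +
    ggplot2::theme_minimal()
}

#' Plot fractures on the network
#'
#' Draws the reactant-pair graph with metabolites coloured by module label
#' and fractured edges highlighted.
#'
#' @param net An [mns_network()].
#' @param labeling A labeling tibble from [mrf_map()] (one frame).
#' @param frame Frame to draw.
#' @return A ggplot object.
#' @export
plot_modules <- function(net, labeling, frame = 1) {
  lay <- igraph::layout_with_fr(net$graph)
  ids <- net$metabolites$id
  nodes <- tibble::tibble(id = ids, x = lay[, 1], y = lay[, 2])
  lab <- labeling[labeling$frame == frame, ]
  nodes$label <- factor(lab$label[match(ids, lab$metabolite)])
  ed <- net$edges
  ed$x <- nodes$x[match(ed$substrate, ids)]
  ed$y <- nodes$y[match(ed$substrate, ids)]
  ed$xend <- nodes$x[match(ed$product, ids)]
  ed$yend <- nodes$y[match(ed$product, ids)]
  ed$fractured <- lab$label[match(ed$substrate, lab$metabolite)] !=
    lab$label[match(ed$product, lab$metabolite)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$fractured)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "red3")) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$label),
                        shape = 21, size = 3) +
    ggplot2::theme_void()
}
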