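#' Build a metabolic reactant-pair network
#'
#' A metabolic network is represented as a simple undirected graph whose nodes
#' are metabolites and whose edges are main reactant pairs (the biochemically
#' principal substrate--product pair of a reaction, cofactors excluded).
#' Several reactions may share one reactant pair; they are merged into a
#' single edge carrying all their reaction ids. Maximal cliques of the graph
#' (the factor scopes of the neighborhood potentials) are enumerated at
#' construction time with exact Bron--Kerbosch pivoting via
#' [igraph::max_cliques()] and cached on the object.
#'
#' @param edges A data frame with columns `reaction_id`, `substrate`,
#'   `product` and optionally `enzyme`. One row per reaction; rows whose
#'   unordered substrate/product pair coincides are merged.
#' @param nodes Optional data frame with columns `metabolite_id` and `name`
#'   declaring metabolites (isolated nodes are allowed this way).
#' @return An object of class `mns_network`: a list with tibbles `metabolites`
#'   (`id`, `name`, `measured`) and `edges` (`edge_id`, `substrate`,
#'   `product`, `reaction_ids` list-column, `enzyme`), the underlying
#'   [igraph] graph, and the clique list.
#' @examples
#' net <- mns_network(data.frame(
#'   reaction_id = c("R1", "R2", "R3"),
#'   substrate   = c("A", "B", "A"),
#'   product     = c("B", "C", "B")
#' ))
#' net$edges
#' @export
mns_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("reaction_id", "substrate", "product")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("edge table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"enzyme" %in% names(edges)) edges$enzyme <- NA_character_
  bad <- which(edges$substrate == edges$product)
  if (length(bad) > 0) {
    rlang::abort(paste0("self-pair (substrate == product) in row(s) ",
                        paste(bad, collapse = ", "), ": '",
                        edges$substrate[bad[1]], "'"))
  }

  merged <- edges |>
    dplyr::mutate(
      .a = pmin(.data$substrate, .data$product),
      .b = pmax(.data$substrate, .data$product),
      edge_id = paste0(.data$.a, "~", .data$.b)
    ) |>
    dplyr::group_by(.data$edge_id) |>
    dplyr::summarise(
      substrate = dplyr::first(.data$substrate),
      product = dplyr::first(.data$product),
      reaction_ids = list(unique(.data$reaction_id)),
      enzyme = {
        v <- stats::na.omit(.data$enzyme)
        if (length(v) > 0) v[[1]] else NA_character_
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$edge_id)

  met_ids <- sort(unique(c(merged$substrate, merged$product,
                           if (!is.null(nodes)) as.character(nodes$metabolite_id))))
  names_map <- rep(NA_character_, length(met_ids))
  if (!is.null(nodes) && "name" %in% names(nodes)) {
    m <- match(met_ids, as.character(nodes$metabolite_id))
    names_map <- as.character(nodes$name)[m]
  }
  metabolites <- tibble::tibble(id = met_ids, name = names_map,
                                measured = FALSE)

  g <- igraph::graph_from_data_frame(
    merged[, c("substrate", "product")],
    directed = FALSE,
    vertices = data.frame(name = met_ids)
  )
  cliques <- enumerate_maximal_cliques_impl(g)

  structure(
    list(metabolites = metabolites, edges = merged, graph = g,
         cliques = cliques),
    class = "mns_network"
  )
}

#' @export
print.mns_network <- function(x, ...) {
  cat(sprintf("<mns_network> %d metabolites, %d reactant-pair edges, %d maximal cliques\n",
              nrow(x$metabolites), nrow(x$edges), length(x$cliques)))
  invisible(x)
}

enumerate_maximal_cliques_impl <- function(g) {
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  ord <- order(vapply(cl, paste, character(1), collapse = "\r"))
  cl[ord]
}

#' Enumerate maximal cliques of a network
#'
#' Maximal cliques are maximal sets of metabolites that are all pairwise
#' connected by reactant-pair edges; each clique contributes one neighborhood
#' potential per frame to the random field. In a triangle-free graph the
#' cliques are exactly the edges.
#'
#' @param net An [mns_network()].
#' @return A tibble with one row per maximal clique: `clique_id`, `members`
#'   (list-column of sorted metabolite ids), `size`. Rows are ordered
#'   lexicographically by sorted member ids.
#' @export
network_cliques <- function(net) {
  stopifnot(inherits(net, "mns_network"))
  tibble::tibble(
    clique_id = seq_along(net$cliques),
    members = net$cliques,
    size = lengths(net$cliques)
  )
}

#' Graph distance between two reactions
#'
#' Distance 0 means the same reactant pair ("exact" in the evaluation
#' vocabulary); distance 1 means the two edges share a metabolite ("first
#' neighbor"); otherwise the distance is 1 plus the shortest metabolite-path
#' distance between the closest endpoints. Edges in different connected
#' components are at distance `Inf`.
#'
#' @param net An [mns_network()].
#' @param edge_a,edge_b Edge ids (as in `net$edges$edge_id`).
#' @return A single non-negative number (possibly `Inf`).
#' @export
reaction_distance <- function(net, edge_a, edge_b) {
  stopifnot(inherits(net, "mns_network"))
  ea <- net$edges[net$edges$edge_id == edge_a, ]
  eb <- net$edges[net$edges$edge_id == edge_b, ]
  if (nrow(ea) != 1 || nrow(eb) != 1) {
    rlang::abort("edge id not found in network")
  }
  if (edge_a == edge_b) return(0)
  va <- c(ea$substrate, ea$product)
  vb <- c(eb$substrate, eb$product)
  d <- igraph::distances(net$graph, v = va, to = vb)
  1 + min(d)
}

#' Read a reactant-pair network from a file
#'
#' Two dialects are supported. `tsv`: tab-separated with header
#' `reaction_id substrate product [enzyme]`; lines starting with `#` are
#' ignored. `sif`: three columns `substrate rp product`, no header, with
#' reaction ids auto-generated (`E1`, `E2`, ...).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param nodes Optional path to a node table TSV
#'   (`metabolite_id name`).
#' @return An [mns_network()].
#' @export
read_network <- function(path, format = c("tsv", "sif"), nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("network file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  kept_idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) rlang::abort("network file is empty")

  if (format == "tsv") {
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (!all(c("reaction_id", "substrate", "product") %in% header)) {
      rlang::abort("TSV network header must contain reaction_id, substrate, product")
    }
    body <- lines[-1]
    idx <- kept_idx[-1]
    rows <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(rows) < 3)
    if (length(bad) > 0) {
      rlang::abort(paste0("malformed network row at line ", idx[bad[1]]))
    }
    pick <- function(col) {
      j <- match(col, header)
      vapply(rows, function(r) if (!is.na(j) && length(r) >= j) r[[j]] else NA_character_,
             character(1))
    }
    edges <- tibble::tibble(
      reaction_id = pick("reaction_id"),
      substrate = pick("substrate"),
      product = pick("product"),
      enzyme = if ("enzyme" %in% header) pick("enzyme") else NA_character_
    )
  } else {
    rows <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(rows) != 3)
    if (length(bad) > 0) {
      rlang::abort(paste0("malformed SIF row at line ", kept_idx[bad[1]]))
    }
    edges <- tibble::tibble(
      reaction_id = paste0("E", seq_along(rows)),
      substrate = vapply(rows, `[[`, character(1), 1),
      product = vapply(rows, `[[`, character(1), 3),
      enzyme = NA_character_
    )
  }

  node_tbl <- NULL
  if (!is.null(nodes)) {
    node_tbl <- readr::read_tsv(nodes, show_col_types = FALSE)
  }
  mns_network(edges, nodes = node_tbl)
}

#' Write a network to a TSV file
#'
#' Inverse of [read_network()] for the `tsv` dialect; merged reaction ids are
#' expanded back to one row per reaction.
#'
#' @param net An [mns_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "mns_network"))
  rows <- net$edges |>
    dplyr::mutate(reaction_ids = purrr::map(.data$reaction_ids, identity)) |>
    tidyr::unnest_longer(col = "reaction_ids", values_to = "reaction_id") |>
    dplyr::select("reaction_id", "substrate", "product", "enzyme") |>
    dplyr::arrange(.data$reaction_id)
  readr::write_tsv(rows, path)
  invisible(path)
}

# internal: index structures handed to the C++ solver (0-based)
network_index <- function(net) {
  ids <- net$metabolites$id
  cliques0 <- lapply(net$cliques, function(m) match(m, ids) - 1L)
  node_cliques0 <- vector("list", length(ids))
  for (i in seq_along(ids)) node_cliques0[[i]] <- integer(0)
  for (c in seq_along(cliques0)) {
    for (v in cliques0[[c]] + 1L) {
      node_cliques0[[v]] <- c(node_cliques0[[v]], c - 1L)
    }
  }
  edges0 <- cbind(match(net$edges$substrate, ids),
                  match(net$edges$product, ids)) - 1L
  storage.mode(edges0) <- "integer"
  list(ids = ids, cliques = cliques0, node_cliques = node_cliques0,
       edges = edges0)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
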