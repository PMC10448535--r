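# Score-filtered protein-protein interaction graph and degree-rule core
# selection.

#' Build a score-filtered interaction network
#'
#' Keeps edges whose combined score strictly exceeds `min_score` (the
#' high-confidence convention: a score of exactly 0.9 is excluded at the
#' default), optionally restricted to a gene set, with reciprocal
#' duplicate rows collapsed to one undirected edge (the maximum score is
#' kept) and self-loops ignored. Degree is the unweighted incident-edge
#' count; scores stay on the edges but do not enter the degree.
#'
#' @param pairs Tibble with `node1`, `node2`, `combined_score` on the
#'   0--1 scale (see [read_edge_list()]).
#' @param min_score Strict lower bound on the combined score. Default 0.9.
#' @param restrict_to Optional character vector; both endpoints must
#'   belong to it.
#' @return A `ppi_network`: list with `graph` (igraph) and `degree`
#'   (named integer vector).
#' @seealso [drop_isolated()], [select_core()]
#' @export
build_network <- function(pairs, min_score = 0.9, restrict_to = NULL) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("node1", "node2", "combined_score") %in% names(pairs)))
  if (any(pairs$combined_score < 0 | pairs$combined_score > 1)) {
    usage_error("combined scores must be on the 0-1 scale; see read_edge_list()")
  }
  keep <- pairs$combined_score > min_score & pairs$node1 != pairs$node2
  if (!is.null(restrict_to)) {
    keep <- keep & pairs$node1 %in% restrict_to & pairs$node2 %in% restrict_to
  }
  kept <- pairs[keep, , drop = FALSE]
  # canonical unordered orientation, then collapse duplicates (max score)
  a <- pmin(kept$node1, kept$node2)
  b <- pmax(kept$node1, kept$node2)
  edges <- tibble(a = a, b = b, combined_score = kept$combined_score)
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(combined_score = max(.data$combined_score),
                       .groups = "drop")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  deg <- igraph::degree(g)
  new_ppi_network(g, deg)
}

new_ppi_network <- function(graph, degree) {
  structure(list(graph = graph, degree = degree), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, mean degree ",
      signif(mean(x$degree), 4), "\n", sep = "")
  invisible(x)
}

#' Remove isolated nodes from an interaction network
#'
#' Drops degree-zero nodes; edges are untouched. This mirrors hiding
#' disconnected nodes before topology analysis, and [select_core()] takes
#' its mean degree over the remaining nodes.
#'
#' @param network A `ppi_network`.
#' @return A `ppi_network` without degree-zero nodes.
#' @export
drop_isolated <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  iso <- which(igraph::degree(network$graph) == 0)
  g <- if (length(iso)) igraph::delete_vertices(network$graph, iso)
       else network$graph
  new_ppi_network(g, igraph::degree(g))
}

#' Select core targets by the degree rule
#'
#' A gene is a core target when its degree strictly exceeds
#' `multiplier` times the mean degree, the mean being taken over the
#' network after isolated nodes are removed. At the default multiplier 2
#' the core can never be the whole network (degree > 2 x mean cannot hold
#' for every node).
#'
#' @param network A `ppi_network` with at least one edge.
#' @param multiplier Multiple of the mean degree a core target must
#'   strictly exceed. Default 2.
#' @return Tibble with columns `gene`, `degree`, sorted by degree
#'   descending then gene name; attribute `mean_degree` records the mean
#'   used.
#' @export
select_core <- function(network, multiplier = 2.0) {
  stopifnot(inherits(network, "ppi_network"))
  network <- drop_isolated(network)
  deg <- network$degree
  if (length(deg) == 0L || igraph::ecount(network$graph) == 0L) {
    usage_error("cannot select core targets from an empty network")
  }
  mu <- mean(deg)
  core <- deg[deg > multiplier * mu]
  out <- tibble(gene = names(core), degree = as.integer(core)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  structure(out, mean_degree = mu)
}

#' Full degree table of a network
#'
#' @param network A `ppi_network`.
#' @return Tibble `gene`, `degree`, sorted by degree descending then name.
#' @export
degree_table <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  tibble(gene = names(network$degree),
         degree = as.integer(network$degree)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
}
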