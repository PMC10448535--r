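# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an interaction network into its edge table
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble `node1`, `node2`, `combined_score`.
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  score <- igraph::edge_attr(x$graph, "combined_score")
  tibble(
    node1 = if (nrow(el)) el[, 1L] else character(),
    node2 = if (nrow(el)) el[, 2L] else character(),
    combined_score = score %||% rep(NA_real_, nrow(el))
  )
}

#' One-row network summary
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble with `nodes`, `edges`, `mean_degree`, `max_degree`.
#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(
    nodes = igraph::vcount(x$graph),
    edges = igraph::ecount(x$graph),
    mean_degree = if (length(x$degree)) mean(x$degree) else NA_real_,
    max_degree = if (length(x$degree)) max(x$degree) else NA_integer_
  )
}

#' Tidy a role graph into its node table
#'
#' @param x A `role_graph`.
#' @param ... Unused.
#' @return Tibble `node`, `role`, `degree`.
#' @method tidy role_graph
#' @export
tidy.role_graph <- function(x, ...) as_tibble(x$nodes)

#' @method glance role_graph
#' @export
glance.role_graph <- function(x, ...) {
  counts <- table(x$nodes$role)
  dplyr::bind_cols(
    tibble(nodes = nrow(x$nodes), edges = igraph::ecount(x$graph)),
    as_tibble(as.list(counts))
  )
}

#' Tidy a gene-organ catalog into (term, gene) pairs
#'
#' @param x An `organ_catalog`.
#' @param ... Unused.
#' @return Tibble `term`, `gene`.
#' @method tidy organ_catalog
#' @export
tidy.organ_catalog <- function(x, ...) {
  tibble(
    term = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(x$sets, use.names = FALSE)
  )
}

#' @method glance organ_catalog
#' @export
glance.organ_catalog <- function(x, ...) {
  tibble(
    terms = length(x$sets),
    universe = length(x$universe),
    associations = sum(lengths(x$sets)),
    mean_term_size = mean(lengths(x$sets))
  )
}

#' One-row summary of an enrichment run
#'
#' @param x An `organ_enrichment` tibble.
#' @param ... Unused.
#' @return Tibble with the method, family size, and significant counts by
#'   direction.
#' @method glance organ_enrichment
#' @export
glance.organ_enrichment <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    alpha = attr(x, "alpha"),
    terms = nrow(x),
    significant = sum(x$significant),
    enriched = sum(x$significant & x$direction == "enriched"),
    depleted = sum(x$significant & x$direction == "depleted")
  )
}

#' One-row summary of a pipeline run
#'
#' @param x An `organ_run`.
#' @param ... Unused.
#' @return Tibble of the headline counts of every stage.
#' @method glance organ_run
#' @export
glance.organ_run <- function(x, ...) {
  r <- x$report
  tibble(
    compounds_in = r$compounds$input,
    compounds_active = r$compounds$active,
    target_union = r$targets$union,
    core = r$network$core,
    significant_terms = r$enrichment$significant %||% NA_integer_,
    links = r$linking$links,
    top_tissue = r$linking$top_tissue
  )
}
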