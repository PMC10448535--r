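# Role-typed network assembly (compound-gene-organ) and the end-to-end
# pipeline: screen -> targets -> core -> enrich + link -> networks.

role_adjacency <- list(
  compound = "gene",
  gene = c("compound", "tissue", "organ-group"),
  tissue = "gene",
  `organ-group` = "gene"
)

#' Assemble a role-typed (bi-/tripartite) network
#'
#' Merges one or more typed edge lists -- each a tibble with columns
#' `node1`, `node2`, `role1`, `role2` -- into one undirected graph whose
#' nodes carry a `role` attribute (`compound`, `gene`, `tissue`,
#' `organ-group`) and a `degree` attribute. Edges are only allowed
#' between adjacent roles (compound--gene, gene--tissue,
#' gene--organ-group); an edge within one role, or a node claimed under
#' two roles, is a structure error naming the offender.
#'
#' @param ... Typed edge tibbles (e.g. from [compound_target_map()], or a
#'   `link_set` via [link_edges()]).
#' @param keep_isolated Keep nodes that end up with no edges? Default
#'   `FALSE`.
#' @return A `role_graph`: list with `graph` (igraph) and `nodes`
#'   (tibble `node`, `role`, `degree`).
#' @export
build_role_graph <- function(..., keep_isolated = FALSE) {
  edge_sets <- list(...)
  if (length(edge_sets) == 1L && is.list(edge_sets[[1L]]) &&
      !is.data.frame(edge_sets[[1L]])) {
    edge_sets <- edge_sets[[1L]]
  }
  edges <- dplyr::bind_rows(lapply(edge_sets, as_tibble))
  req <- c("node1", "node2", "role1", "role2")
  if (!all(req %in% names(edges))) {
    usage_error("typed edge lists need columns node1, node2, role1, role2")
  }
  roles_long <- tibble(
    node = c(edges$node1, edges$node2),
    role = c(edges$role1, edges$role2)
  ) |> dplyr::distinct()
  clash <- roles_long$node[duplicated(roles_long$node)]
  if (length(clash)) {
    abort(paste0("node `", clash[[1L]],
                 "` appears under more than one role"),
          class = "herborgan_structure_error")
  }
  bad_roles <- setdiff(roles_long$role, names(role_adjacency))
  if (length(bad_roles)) {
    abort(paste0("unknown node role `", bad_roles[[1L]], "`"),
          class = "herborgan_structure_error")
  }
  ok <- purrr::map2_lgl(edges$role1, edges$role2,
                        ~ .y %in% role_adjacency[[.x]])
  if (any(!ok)) {
    i <- which(!ok)[[1L]]
    abort(paste0("edge between non-adjacent roles: `", edges$node1[[i]],
                 "` (", edges$role1[[i]], ") -- `", edges$node2[[i]],
                 "` (", edges$role2[[i]], ")"),
          class = "herborgan_structure_error")
  }
  edges <- dplyr::distinct(edges[, req])
  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2")], directed = FALSE,
    vertices = roles_long
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  if (!keep_isolated && any(deg == 0)) {
    g <- igraph::delete_vertices(g, which(deg == 0))
    deg <- igraph::degree(g)
  }
  g <- igraph::set_vertex_attr(g, "degree", value = as.integer(deg))
  nodes <- tibble(
    node = igraph::V(g)$name,
    role = igraph::vertex_attr(g, "role"),
    degree = as.integer(deg)
  )
  structure(list(graph = g, nodes = nodes), class = "role_graph")
}

#' @export
print.role_graph <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat("<role_graph> ", nrow(x$nodes), " nodes (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Turn a link set into a typed edge list
#'
#' @param links A `link_set` (gene, tissue) or a gene-to-organ-group
#'   assignment table (`gene`, `organ_group` columns).
#' @param target_role Role of the second endpoint: `"tissue"` or
#'   `"organ-group"`.
#' @return Typed edge tibble for [build_role_graph()].
#' @export
link_edges <- function(links, target_role = c("tissue", "organ-group")) {
  target_role <- match.arg(target_role)
  links <- as_tibble(links)
  tibble(
    node1 = links$gene,
    node2 = links[[setdiff(names(links), c("gene", "value"))[1L]]],
    role1 = "gene",
    role2 = target_role
  )
}

# Run configuration ----------------------------------------------------------

#' Build a validated pipeline configuration
#'
#' All thresholds of the pipeline with their defaults: ADME bounds,
#' per-source confidence rules, interaction-score cutoff, core-degree
#' multiplier, enrichment method and level, linking rule and Z-score
#' ddof. Unknown names and out-of-domain values are rejected.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Recognized fields and defaults: `ob_min` 30, `dl_min` 0.18,
#'   `allowed_levels` A,B,C, `score_cutoff` 30, `min_score` 0.9,
#'   `multiplier` 2, `method` `"midp"`, `test_depletion` TRUE, `alpha`
#'   0.05, `rule` `"z"` (or `"mean"`), `ddof` 1, `enrich_on`
#'   `"union"` (or `"core"`), `link_on` `"core"` (or `"union"`),
#'   `run_enrichment` TRUE, `seed` 1, plus input paths `compounds`,
#'   `associations` (vector), `edges`, `catalog`, `atlas`, `atlas2`
#'   (optional), `grouping`, and `out_dir`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    compounds = NULL, associations = NULL, edges = NULL, catalog = NULL,
    atlas = NULL, atlas2 = NULL, grouping = NULL, out_dir = NULL,
    ob_min = 30, dl_min = 0.18,
    allowed_levels = c("A", "B", "C"), score_cutoff = 30,
    min_score = 0.9, multiplier = 2,
    method = "midp", test_depletion = TRUE, alpha = 0.05,
    rule = "z", ddof = 1,
    enrich_on = "union", link_on = "core",
    run_enrichment = TRUE, seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    usage_error(paste0("unknown config field(s): ",
                       paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(
    cfg$ob_min >= 0, cfg$dl_min >= 0, cfg$dl_min <= 1,
    cfg$score_cutoff >= 0, cfg$min_score >= 0, cfg$min_score <= 1,
    cfg$multiplier > 0, cfg$alpha > 0, cfg$alpha < 1,
    cfg$method %in% c("hypergeometric", "ease", "midp"),
    cfg$rule %in% c("z", "mean"), cfg$ddof %in% c(0, 1),
    cfg$enrich_on %in% c("union", "core"),
    cfg$link_on %in% c("union", "core")
  )
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration file
#'
#' Flat key-value YAML; unknown keys are rejected (fail-closed).
#'
#' @param path Config file path.
#' @return For `read_run_config()`, a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Pipeline -------------------------------------------------------------------

#' Run the full target-organ localization pipeline
#'
#' Executes, in order: compound screening (deduplication + ADME filter),
#' per-source association filtering restricted to the active compounds,
#' target union, PPI build and core selection, catalog enrichment on the
#' full target union, expression linking and organ-group assignment on
#' the core set, and assembly of the bipartite gene-organ and tripartite
#' compound-gene-organ networks. Every intermediate table is written
#' under `config$out_dir` along with a machine-readable JSON report of
#' all counts and the effective configuration. Given the same inputs and
#' configuration the outputs are byte-identical across reruns.
#'
#' @param config A [run_config()] whose input paths are all set.
#' @return An `organ_run` list: `report` (named list), `compounds`,
#'   `associations`, `targets`, `core`, `enrichment`, `links`,
#'   `assignment`, `ranking`, `network` (`role_graph`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (field in c("compounds", "associations", "edges", "atlas",
                  "grouping", "out_dir")) {
    if (is.null(config[[field]])) {
      usage_error(paste0("config field `", field, "` must be set"))
    }
  }
  if (isTRUE(config$run_enrichment) && is.null(config$catalog)) {
    usage_error("config field `catalog` must be set when enrichment runs")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  # -- screen
  raw_compounds <- read_compound_table(config$compounds)
  deduped <- dedup_compounds(raw_compounds)
  active <- adme_filter(deduped, ob_min = config$ob_min,
                        dl_min = config$dl_min)
  write_compound_table(active, out("active_compounds.tsv"))
  active_keys <- compound_keys(active)

  # -- targets
  assoc <- dplyr::bind_rows(lapply(config$associations, read_association_table))
  assoc <- assoc[assoc$compound_key %in% active_keys, , drop = FALSE]
  assoc <- filter_associations(assoc,
                               allowed_levels = config$allowed_levels,
                               score_cutoff = config$score_cutoff)
  targets <- union_targets(assoc)
  writeLines(targets, out("target_union.txt"))
  cg_edges <- compound_target_map(assoc)
  readr::write_tsv(cg_edges, out("compound_gene_edges.tsv"))

  # -- core
  ppi_pairs <- read_edge_list(config$edges)
  network <- build_network(ppi_pairs, min_score = config$min_score,
                           restrict_to = targets)
  network <- drop_isolated(network)
  core <- select_core(network, multiplier = config$multiplier)
  readr::write_tsv(degree_table(network), out("degree_table.tsv"))
  readr::write_tsv(core, out("core_targets.tsv"))
  write_graph(network, "graphml", out("ppi_network.graphml"))

  # -- enrich
  enrichment <- NULL
  n_significant <- NA_integer_
  if (isTRUE(config$run_enrichment)) {
    catalog <- read_catalog(config$catalog)
    enrich_genes <- if (config$enrich_on == "union") targets else core$gene
    enrichment <- enrich_catalog(enrich_genes, catalog,
                                 method = config$method,
                                 test_depletion = config$test_depletion,
                                 alpha = config$alpha)
    readr::write_tsv(as_tibble(enrichment), out("organ_enrichment.tsv"))
    n_significant <- sum(enrichment$significant)
  }

  # -- link
  atlas <- read_expression_matrix(config$atlas)
  if (!is.null(config$atlas2)) {
    atlas <- consensus_max(atlas, read_expression_matrix(config$atlas2))
  }
  link_genes <- if (config$link_on == "core") core$gene else targets
  atlas_sub <- atlas[atlas$gene %in% link_genes, , drop = FALSE]
  links <- if (config$rule == "z") {
    link_positive_z(zscore_rows(atlas_sub, ddof = config$ddof))
  } else {
    link_above_mean(atlas_sub)
  }
  grouping <- readr::read_tsv(config$grouping, col_types = "cc",
                              progress = FALSE)
  assignment <- assign_top_group(atlas_sub, grouping)
  ranking <- organ_degree_ranking(links)
  readr::write_tsv(as_tibble(links), out("gene_tissue_links.tsv"))
  readr::write_tsv(assignment, out("gene_group_assignment.tsv"))
  readr::write_tsv(as_tibble(ranking), out("organ_ranking.tsv"))

  # -- networks
  bipartite <- build_role_graph(link_edges(links, "tissue"))
  tri_assoc <- cg_edges[cg_edges$node2 %in% core$gene, , drop = FALSE]
  tripartite <- build_role_graph(
    list(tri_assoc, link_edges(assignment, "organ-group"))
  )
  write_graph(bipartite, "graphml", out("gene_tissue_network.graphml"))
  write_graph(tripartite, "graphml", out("compound_gene_organ.graphml"))

  report <- list(
    config = unclass(config),
    compounds = list(
      input = nrow(raw_compounds),
      deduplicated = nrow(deduped),
      active = nrow(active)
    ),
    targets = list(
      per_source = as.list(attr(targets, "per_source")),
      union = length(targets),
      compound_gene_edges = nrow(cg_edges)
    ),
    network = list(
      nodes = igraph::vcount(network$graph),
      edges = igraph::ecount(network$graph),
      mean_degree = mean(network$degree),
      core = nrow(core),
      core_genes = core$gene
    ),
    enrichment = if (isTRUE(config$run_enrichment)) {
      list(terms_tested = nrow(enrichment), significant = n_significant)
    } else {
      list(status = "skipped")
    },
    linking = list(
      genes = nrow(atlas_sub),
      links = nrow(links),
      assigned = nrow(assignment),
      top_tissue = if (nrow(ranking)) ranking$tissue[[1L]] else NA_character_
    ),
    networks = list(
      bipartite_nodes = nrow(bipartite$nodes),
      bipartite_edges = igraph::ecount(bipartite$graph),
      tripartite_nodes = nrow(tripartite$nodes),
      tripartite_edges = igraph::ecount(tripartite$graph)
    )
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(
    list(report = report, compounds = active, associations = assoc,
         targets = targets, core = core, enrichment = enrichment,
         links = links, assignment = assignment, ranking = ranking,
         network = tripartite),
    class = "organ_run"
  )
}

#' @export
print.organ_run <- function(x, ...) {
  r <- x$report
  cat("<organ_run>\n",
      "  compounds: ", r$compounds$input, " in -> ", r$compounds$active,
      " active\n",
      "  targets:   ", r$targets$union, " union -> ", r$network$core,
      " core\n",
      "  linking:   ", r$linking$links, " gene-tissue links; top tissue ",
      r$linking$top_tissue, "\n", sep = "")
  invisible(x)
}

# internal: stable per-record key used to join compounds and associations
compound_keys <- function(records) {
  ifelse(!is.na(records$cid), paste0("CID", records$cid),
         ifelse(!is.na(records$inchikey), records$inchikey,
                ifelse(!is.na(records$cas), records$cas,
                       normalize_name(records$name))))
}

#' Read a compound-target association table
#'
#' TSV with columns `compound_key`, `gene`, `source`, and optionally
#' `level` and `score`.
#'
#' @param path Path to the table.
#' @return Association tibble.
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) usage_error(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  req <- c("compound_key", "gene", "source")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    format_error(paste0("association table is missing column `",
                        missing[[1L]], "`: ", path))
  }
  tibble(
    compound_key = raw$compound_key,
    gene = raw$gene,
    source = raw$source,
    level = if ("level" %in% names(raw)) raw$level else NA_character_,
    score = if ("score" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$score))
    } else {
      NA_real_
    }
  )
}
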