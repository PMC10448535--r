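# Readers and writers for every external file the pipeline touches.
# All writers emit UTF-8 with LF line endings; all readers are total on the
# corresponding writer's output.

#' Describe a delimited-table dialect
#'
#' A small record of how a delimited text table is laid out. An empty cell is
#' always read as missing, independent of `na_tokens`.
#'
#' @param delimiter Single field-separator character. Default tab.
#' @param header Does the first non-comment line carry column names?
#' @param comment_prefix Lines starting with this character are skipped.
#' @param na_tokens Strings (other than the empty cell) read as missing.
#' @return An object of class `table_dialect`.
#' @examples
#' table_dialect(delimiter = ",", na_tokens = c("NA", "n/a"))
#' @export
table_dialect <- function(delimiter = "\t", header = TRUE,
                          comment_prefix = "#",
                          na_tokens = c("NA", "N/A")) {
  if (!is.character(delimiter) || length(delimiter) != 1L ||
      nchar(delimiter) != 1L) {
    usage_error("`delimiter` must be a single character.")
  }
  if (!is.character(comment_prefix) || nchar(comment_prefix) != 1L) {
    usage_error("`comment_prefix` must be a single character.")
  }
  na_tokens <- setdiff(as.character(na_tokens), "")
  structure(
    list(delimiter = delimiter, header = isTRUE(header),
         comment_prefix = comment_prefix, na_tokens = na_tokens),
    class = "table_dialect"
  )
}

# internal: match one of several accepted header spellings, case-insensitively
match_column <- function(nms, aliases) {
  hit <- which(tolower(nms) %in% tolower(aliases))
  if (length(hit) == 0L) NA_integer_ else hit[[1L]]
}

#' Read a compound table with ADME scores
#'
#' Reads a delimited table of herb compounds carrying at least a name column,
#' one identifier column (PubChem CID, CAS or InChIKey), oral bioavailability
#' (OB, percent), drug-likeness (DL, in \[0, 1\]) and a source label.
#' Alternative header spellings (`molecule_name`, `pubchem_cid`, ...) are
#' recognized. Missing identifiers are kept as `NA`, never as empty strings.
#'
#' @param path Path to the table.
#' @param dialect A [table_dialect()]; default tab-separated with header.
#' @return A tibble with columns `name`, `cid`, `cas`, `inchikey`, `ob`,
#'   `dl`, `sources` (a list-column of source-label character vectors, one
#'   label per raw row).
#' @seealso [dedup_compounds()], [adme_filter()]
#' @export
read_compound_table <- function(path, dialect = table_dialect()) {
  if (!file.exists(path)) usage_error(paste0("file not found: ", path))
  raw <- readr::read_delim(
    path, delim = dialect$delimiter,
    col_names = dialect$header, comment = dialect$comment_prefix,
    na = c("", dialect$na_tokens), col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  nms <- names(raw)
  idx <- list(
    name = match_column(nms, c("name", "molecule_name", "compound",
                               "compound_name", "molecule")),
    cid = match_column(nms, c("cid", "pubchem_id", "pubchem_cid")),
    cas = match_column(nms, c("cas", "cas_number", "casno")),
    inchikey = match_column(nms, c("inchikey", "inchi_key")),
    ob = match_column(nms, c("ob", "ob_percent", "ob(%)", "ob_%")),
    dl = match_column(nms, c("dl", "drug_likeness", "druglikeness")),
    source = match_column(nms, c("source", "database", "db", "source_db"))
  )
  for (col in c("name", "ob", "dl", "source")) {
    if (is.na(idx[[col]])) {
      format_error(paste0("compound table is missing mandatory column `",
                          col, "` (", path, ")"))
    }
  }
  if (is.na(idx$cid) && is.na(idx$cas) && is.na(idx$inchikey)) {
    format_error(paste0(
      "compound table needs at least one identifier column ",
      "(cid / cas / inchikey): ", path))
  }
  pull_col <- function(i) if (is.na(i)) rep(NA_character_, nrow(raw)) else raw[[i]]

  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      line <- bad[[1L]] + if (dialect$header) 1L else 0L
      format_error(paste0("non-numeric ", what, " value \"", x[bad[[1L]]],
                          "\" at line ", line, " of ", path))
    }
    out
  }
  parse_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out
  }
  tibble(
    name = pull_col(idx$name),
    cid = parse_int(pull_col(idx$cid)),
    cas = pull_col(idx$cas),
    inchikey = pull_col(idx$inchikey),
    ob = parse_num(pull_col(idx$ob), "OB"),
    dl = parse_num(pull_col(idx$dl), "DL"),
    sources = purrr::map(pull_col(idx$source),
                         ~ if (is.na(.x)) character() else .x)
  )
}

#' Write a compound table
#'
#' Inverse of [read_compound_table()]: emits a tab-separated table whose
#' `sources` list-column is collapsed with `";"`.
#'
#' @param compounds Tibble as returned by [read_compound_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  out <- compounds
  out$sources <- purrr::map_chr(out$sources, paste, collapse = ";")
  names(out)[names(out) == "sources"] <- "source"
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a scored interaction edge list
#'
#' Reads a whitespace- or tab-delimited edge list in the STRING export
#' dialect: `node1 node2 combined_score`, score on either the 0--1000
#' integer or the 0--1 decimal scale. Scores are normalized to 0--1
#' (any score above 1 marks the whole file as 0--1000). Self-loops are
#' dropped with a logged count (also in attribute `n_self_loops`).
#'
#' A file mixing the two scales -- integer-style scores above 1 alongside
#' fractional scores below 1 -- is rejected as malformed.
#'
#' @param path Path to the edge list. A header line (non-numeric third
#'   field) is detected and skipped.
#' @return Tibble with columns `node1`, `node2`, `combined_score` (0--1).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) usage_error(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) {
    return(structure(tibble(node1 = character(), node2 = character(),
                            combined_score = double()),
                     n_self_loops = 0L))
  }
  parts <- stringr::str_split(trimws(lines[keep]), "[ \t]+")
  nfield <- lengths(parts)
  bad <- which(nfield != 3L)
  if (length(bad)) {
    format_error(paste0("malformed edge-list row at line ", keep[bad[[1L]]],
                        " of ", path, " (expected 3 fields, got ",
                        nfield[bad[[1L]]], ")"))
  }
  m <- do.call(rbind, parts)
  score_chr <- m[, 3L]
  score <- suppressWarnings(as.numeric(score_chr))
  # header: first row's score field is non-numeric
  if (is.na(score[[1L]]) && !is.na(score_chr[[1L]])) {
    m <- m[-1L, , drop = FALSE]
    score <- score[-1L]
    keep <- keep[-1L]
  }
  bad <- which(is.na(score))
  if (length(bad)) {
    format_error(paste0("non-numeric combined_score at line ", keep[bad[[1L]]],
                        " of ", path))
  }
  if (any(score < 0)) {
    format_error(paste0("negative combined_score in ", path))
  }
  if (any(score > 1)) {
    if (any(score > 0 & score < 1)) {
      format_error(paste0(
        "mixed score scales in ", path,
        ": scores above 1 (0-1000 scale) alongside fractional scores"))
    }
    if (any(score > 1000)) {
      format_error(paste0("combined_score above 1000 in ", path))
    }
    score <- score / 1000
  }
  edges <- tibble(node1 = m[, 1L], node2 = m[, 2L], combined_score = score)
  loops <- edges$node1 == edges$node2
  n_loops <- sum(loops)
  if (n_loops > 0) {
    log_note("io", paste0("dropped ", n_loops, " self-loop(s) from ", path))
    edges <- edges[!loops, , drop = FALSE]
  }
  structure(edges, n_self_loops = n_loops)
}

#' Write a scored edge list in the STRING export dialect
#'
#' @param edges Tibble with `node1`, `node2`, `combined_score` on the
#'   0--1 scale.
#' @param path Output path.
#' @param scale `"0-1000"` (default; integer scores as STRING exports
#'   them) or `"0-1"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, scale = c("0-1000", "0-1")) {
  scale <- match.arg(scale)
  out <- tibble(
    node1 = edges$node1, node2 = edges$node2,
    combined_score = if (scale == "0-1000") {
      as.integer(round(edges$combined_score * 1000))
    } else {
      edges$combined_score
    }
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Construct a gene--organ catalog
#'
#' @param sets Named list; each element a character vector of gene symbols
#'   annotated to that term (organ / body part). Duplicates within a term
#'   are collapsed.
#' @param universe Optional character vector of background genes. Must be a
#'   superset of all term members; defaults to their union.
#' @return An object of class `organ_catalog` with elements `sets` and
#'   `universe`.
#' @examples
#' organ_catalog(list(liver = c("TP53", "EGFR"), kidney = "TP53"),
#'               universe = c("TP53", "EGFR", "MYC", "JUN"))
#' @export
organ_catalog <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    format_error("every catalog term needs a non-empty name")
  }
  if (anyDuplicated(names(sets))) {
    # merge duplicate term entries rather than erroring: GMT files sometimes
    # split one term over several lines
    sets <- tapply(sets, names(sets), function(x) unique(unlist(x)),
                   simplify = FALSE)
    sets <- lapply(sets, as.character)
  }
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(sets) == 0L)) {
    format_error("every catalog term must contain at least one gene")
  }
  member_union <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(member_union)
  } else {
    universe <- unique(trimws(as.character(universe)))
    missing <- setdiff(member_union, universe)
    if (length(missing)) {
      format_error(paste0(
        "catalog universe must contain every annotated gene; missing e.g. ",
        paste(head(missing, 3), collapse = ", ")))
    }
  }
  structure(list(sets = sets, universe = universe), class = "organ_catalog")
}

#' @export
print.organ_catalog <- function(x, ...) {
  cat("<organ_catalog> ", length(x$sets), " terms, ",
      length(x$universe), " genes in universe, ",
      sum(lengths(x$sets)), " associations\n", sep = "")
  invisible(x)
}

#' Read a gene--organ catalog
#'
#' Accepts either GMT (`term <TAB> description <TAB> gene ...`) or a
#' two-column `gene <TAB> term` table (an optional `gene`/`term` header row
#' is skipped). Duplicate (gene, term) pairs collapse to one association.
#' The background universe defaults to the union of all term members; a
#' gene belonging to no term can only enter the universe through
#' `universe_path`.
#'
#' @param path Path to the catalog file.
#' @param format `"auto"` (default; `.gmt` extension or a line with three
#'   or more fields selects GMT), `"gmt"`, or `"pairs"`.
#' @param universe_path Optional path to a one-gene-per-line universe file.
#' @return An [organ_catalog()].
#' @export
read_catalog <- function(path, format = c("auto", "gmt", "pairs"),
                         universe_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) usage_error(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split(lines, "\t")
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE) ||
                  any(lengths(parts) >= 3L)) "gmt" else "pairs"
  }
  if (format == "gmt") {
    terms <- purrr::map_chr(parts, 1L)
    if (any(!nzchar(trimws(terms)))) {
      format_error(paste0("empty term name in GMT file ", path))
    }
    if (any(lengths(parts) < 3L)) {
      format_error(paste0("GMT line with no genes in ", path))
    }
    sets <- purrr::map(parts, ~ .x[-(1:2)])
    names(sets) <- trimws(terms)
  } else {
    if (any(lengths(parts) != 2L)) {
      bad <- which(lengths(parts) != 2L)[[1L]]
      format_error(paste0("two-column catalog row with ",
                          lengths(parts)[bad], " fields at line ", bad,
                          " of ", path))
    }
    gene <- trimws(purrr::map_chr(parts, 1L))
    term <- trimws(purrr::map_chr(parts, 2L))
    if (tolower(gene[[1L]]) %in% c("gene", "symbol") &&
        tolower(term[[1L]]) %in% c("term", "organ", "organ_group", "tissue")) {
      gene <- gene[-1L]
      term <- term[-1L]
    }
    if (any(!nzchar(term))) {
      format_error(paste0("empty term name in ", path))
    }
    sets <- split(gene, term)
  }
  universe <- NULL
  if (!is.null(universe_path)) {
    universe <- trimws(readLines(universe_path, encoding = "UTF-8"))
    universe <- universe[nzchar(universe)]
  }
  organ_catalog(sets, universe = universe)
}

#' Write a catalog as GMT
#'
#' @param catalog An [organ_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "organ_catalog"))
  lines <- purrr::imap_chr(
    catalog$sets,
    ~ paste(c(.y, "na", .x), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-by-tissue expression matrix
#'
#' Tab-separated; first column gene symbols, remaining columns tissue
#' names, all values non-negative. Duplicate gene rows are collapsed by
#' per-tissue maximum (the same convention used for consensus normalized
#' expression across sources); duplicate tissue columns are rejected.
#'
#' @param path Path to the TSV.
#' @return An `expression_atlas`: a tibble whose first column is `gene`
#'   and whose remaining columns are tissues.
#' @seealso [link_above_mean()], [zscore_rows()], [consensus_max()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) usage_error(paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), "\t")[[1L]]
  tissues <- header[-1L]
  if (anyDuplicated(tissues)) {
    format_error(paste0("duplicate tissue column `",
                        tissues[duplicated(tissues)][[1L]], "` in ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  names(raw)[1L] <- "gene"
  vals <- suppressWarnings(
    vapply(raw[, -1L, drop = FALSE], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, tissues))
  bad <- which(is.na(vals) & !is.na(as.matrix(raw[, -1L])), arr.ind = TRUE)
  if (nrow(bad)) {
    format_error(paste0(
      "non-numeric expression value at gene `", raw$gene[bad[1L, 1L]],
      "`, tissue `", tissues[bad[1L, 2L]], "` in ", path))
  }
  raw <- dplyr::bind_cols(tibble(gene = raw$gene), as_tibble(vals))
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    format_error(paste0(
      "negative expression value at gene `", raw$gene[neg[1L, 1L]],
      "`, tissue `", tissues[neg[1L, 2L]], "` in ", path))
  }
  if (anyDuplicated(raw$gene)) {
    n_dup <- sum(duplicated(raw$gene))
    log_note("io", paste0("collapsed ", n_dup,
                          " duplicate gene row(s) by per-tissue maximum"))
    raw <- raw |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), max),
                       .groups = "drop")
  }
  as_expression_atlas(raw)
}

#' Coerce a gene-first tibble or matrix to an expression atlas
#'
#' @param x A data frame whose first column is the gene symbol (renamed to
#'   `gene`), or a numeric matrix with gene rownames.
#' @return An `expression_atlas` tibble.
#' @export
as_expression_atlas <- function(x) {
  if (is.matrix(x)) {
    x <- dplyr::bind_cols(tibble(gene = rownames(x)), as_tibble(x))
  }
  x <- as_tibble(x)
  names(x)[1L] <- "gene"
  if (anyDuplicated(x$gene)) usage_error("duplicate gene names in atlas")
  if (anyDuplicated(names(x))) usage_error("duplicate tissue names in atlas")
  if (ncol(x) < 2L) usage_error("atlas needs at least one tissue column")
  if (any(as.matrix(x[, -1L]) < 0, na.rm = TRUE)) {
    usage_error("atlas values must be non-negative")
  }
  class(x) <- c("expression_atlas", class(tibble()))
  x
}

# internal: atlas tibble -> numeric matrix with gene rownames
atlas_matrix <- function(atlas) {
  m <- as.matrix(atlas[, -1L, drop = FALSE])
  rownames(m) <- atlas$gene
  m
}

#' Write an expression atlas as TSV
#'
#' Values are written with a shortest round-trip representation, so
#' `read_expression_matrix(write_expression_matrix(a))` reproduces `a`
#' exactly.
#'
#' @param atlas An `expression_atlas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(atlas, path) {
  readr::write_tsv(as_tibble(atlas), path)
  invisible(path)
}

#' Export a network to GraphML, SIF or edge TSV
#'
#' Nodes carry `role` and `degree` attributes. GraphML (via igraph)
#' preserves both as node attributes; SIF uses the interaction word
#' `links` (isolated nodes become single-field lines); edge TSV has
#' header `node1 node2 role1 role2`.
#'
#' @param graph An igraph object with vertex attributes `role` and
#'   `degree`, or a [build_network()] / [build_role_graph()] result.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, format = c("graphml", "sif", "tsv"), path) {
  format <- match.arg(format)
  g <- if (inherits(graph, c("ppi_network", "role_graph"))) graph$graph
       else graph
  if (!inherits(g, "igraph")) usage_error("`graph` is not a graph object")
  if (!"role" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "role", value = "gene")
  }
  if (!"degree" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  roles <- setNames(igraph::vertex_attr(g, "role"),
                    igraph::V(g)$name)
  if (format == "sif") {
    edge_lines <- if (nrow(el)) paste(el[, 1L], "links", el[, 2L]) else character()
    isolated <- setdiff(igraph::V(g)$name, unique(c(el[, 1L], el[, 2L])))
    writeLines(c(edge_lines, isolated), path, useBytes = TRUE)
  } else {
    out <- tibble(
      node1 = el[, 1L], node2 = el[, 2L],
      role1 = unname(roles[el[, 1L]]), role2 = unname(roles[el[, 2L]])
    )
    readr::write_tsv(out, path)
  }
  invisible(path)
}
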