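# ADME screening: deduplicate multi-source compound records and keep the
# active ones (OB >= 30 %, DL >= 0.18 by default, both inclusive).

# internal: canonical identifier priority used for merging
id_priority <- c("cid", "inchikey", "cas", "name_key")

# internal: add the normalized-name key column
with_name_key <- function(records) {
  records$name_key <- normalize_name(records$name)
  records
}

#' Deduplicate compound records across sources
#'
#' Records sharing an identifier are merged, with identifier priority
#' PubChem CID, then InChIKey, then CAS, then the normalized compound name
#' (case-folded, whitespace-collapsed, Greek letters spelled out). A merged
#' record keeps the union of source labels, the first non-missing value of
#' each identifier, and the maximum OB/DL where sources disagree. Records
#' carrying no identifier at all are dropped with a logged count.
#'
#' Merging is transitive: if A shares a CID with B and B shares a CAS with
#' C, all three collapse into one record (union-find over shared keys).
#'
#' @param records Compound tibble as from [read_compound_table()].
#' @return Deduplicated compound tibble; attribute `n_dropped` counts
#'   identifier-less records removed.
#' @examples
#' x <- tibble::tibble(
#'   name = c("Beta-sitosterol", "beta sitosterol"),
#'   cid = c(222284L, 222284L), cas = NA, inchikey = NA,
#'   ob = c(36.91, 36.0), dl = c(0.75, 0.75),
#'   sources = list("TCMSP", "HIT2.0")
#' )
#' dedup_compounds(x)
#' @export
dedup_compounds <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    return(structure(records, n_dropped = 0L))
  }
  if (!is.list(records$sources)) {
    records$sources <- purrr::map(records$sources,
                                  ~ if (is.na(.x)) character() else .x)
  }
  records <- with_name_key(records)
  has_id <- Reduce(`|`, lapply(id_priority, function(k) !is.na(records[[k]])))
  n_dropped <- sum(!has_id)
  if (n_dropped > 0) {
    log_note("screen", paste0("dropped ", n_dropped,
                              " record(s) with no usable identifier"))
    records <- records[has_id, , drop = FALSE]
  }
  n <- nrow(records)
  if (n == 0L) {
    records$name_key <- NULL
    return(structure(records, n_dropped = n_dropped))
  }
  # union-find over records connected by any shared identifier value
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (key in id_priority) {
    vals <- as.character(records[[key]])
    groups <- split(which(!is.na(vals)), vals[!is.na(vals)])
    for (g in groups) {
      if (length(g) > 1L) for (j in g[-1L]) unite(g[[1L]], j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  first_non_na <- function(x) {
    hit <- which(!is.na(x))
    if (length(hit)) x[[hit[[1L]]]] else x[[1L]]
  }
  max_or_na <- function(x) if (all(is.na(x))) x[[1L]] else max(x, na.rm = TRUE)
  merged <- lapply(split(seq_len(n), root), function(rows) {
    r <- records[rows, , drop = FALSE]
    tibble(
      name = first_non_na(r$name),
      cid = first_non_na(r$cid),
      cas = first_non_na(r$cas),
      inchikey = first_non_na(r$inchikey),
      ob = max_or_na(r$ob),
      dl = max_or_na(r$dl),
      sources = list(sort(unique(unlist(r$sources))))
    )
  })
  out <- dplyr::bind_rows(merged)
  structure(out, n_dropped = n_dropped)
}

#' Filter compounds by oral bioavailability and drug-likeness
#'
#' Keeps records with OB and DL present, `ob >= ob_min` and
#' `dl >= dl_min`, both bounds inclusive. Input order is preserved.
#' Records missing either score cannot demonstrate activity and are
#' excluded (counted in attribute `n_missing_scores`).
#'
#' @param records Compound tibble.
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness, unitless in \[0, 1\]. Default 0.18.
#' @return Filtered compound tibble.
#' @export
adme_filter <- function(records, ob_min = 30, dl_min = 0.18) {
  records <- as_tibble(records)
  missing_scores <- is.na(records$ob) | is.na(records$dl)
  if (any(missing_scores)) {
    log_note("screen", paste0(sum(missing_scores),
                              " record(s) lacked OB or DL and were excluded"))
  }
  keep <- !missing_scores & records$ob >= ob_min & records$dl >= dl_min
  structure(records[keep, , drop = FALSE],
            n_missing_scores = sum(missing_scores))
}

#' Compounds present in two or more sources
#'
#' After deduplication, returns the records whose source-label set has at
#' least two members, sorted by compound name.
#'
#' @param records Deduplicated compound tibble (see [dedup_compounds()]).
#' @return Compound tibble, possibly empty.
#' @export
cross_source_overlap <- function(records) {
  records <- as_tibble(records)
  keep <- lengths(records$sources) >= 2L
  out <- records[keep, , drop = FALSE]
  out[order(out$name), , drop = FALSE]
}

#' The printed 17-compound screening table
#'
#' Loads the package's copy of the published active-compound table for
#' Radix Achyranthis Bidentatae (name, PubChem CID, OB, DL, and the two
#' source-database accessions).
#'
#' @param long If `TRUE` (default), expand to one record per
#'   compound-source pair (OB/DL are the screening database's scores and
#'   travel with every row), ready for [dedup_compounds()]. If `FALSE`,
#'   return the table as printed, one row per compound.
#' @return A tibble.
#' @examples
#' nrow(adme_filter(dedup_compounds(rab_compounds())))
#' @export
rab_compounds <- function(long = TRUE) {
  path <- system.file("extdata", "rab_active_compounds.tsv",
                      package = "herborgan", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    molecule_name = "c", cid = "i", ob = "d", dl = "d",
    tcmsp_id = "c", hit2_id = "c"
  ), progress = FALSE)
  if (!long) return(raw)
  per_source <- dplyr::bind_rows(
    raw |> dplyr::filter(!is.na(.data$tcmsp_id)) |>
      dplyr::mutate(source = "TCMSP"),
    raw |> dplyr::filter(!is.na(.data$hit2_id)) |>
      dplyr::mutate(source = "HIT2.0")
  )
  tibble(
    name = per_source$molecule_name,
    cid = per_source$cid,
    cas = NA_character_,
    inchikey = NA_character_,
    ob = per_source$ob,
    dl = per_source$dl,
    sources = purrr::map(per_source$source, identity)
  )
}

#' The printed 44-gene core-target table with organ groups
#'
#' Loads the package's copy of the published core-target list, each gene
#' labelled with the organ group where its expression was highest
#' (bone marrow, lymphoid tissue, whole blood, smooth muscle, prostate,
#' lung, cardiac myocytes, thyroid).
#'
#' @return Tibble with columns `gene`, `organ_group`.
#' @export
rab_core_genes <- function() {
  path <- system.file("extdata", "rab_core_gene_groups.tsv",
                      package = "herborgan", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' The 15-tissue to 8-organ-group regrouping map
#'
#' Maps hematopoietic cell-type tissues (CD33+, CD34+, B lymphoblasts,
#' CD14+, CD56+, BDCA4+, Raji, CD19+, CD4+) and whole tissues to the eight
#' organ groups used for highest-expression assignment.
#'
#' @return Tibble with columns `tissue`, `organ_group`; usable as the
#'   `grouping` argument of [assign_top_group()].
#' @export
organ_grouping <- function() {
  path <- system.file("extdata", "organ_grouping.tsv",
                      package = "herborgan", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
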