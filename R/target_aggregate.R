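# Per-source confidence filtering of compound-target associations and the
# deduplicated target union.

#' Apply per-source confidence rules to compound-target associations
#'
#' Each association row names a `source`. Rows from `HIT2` are kept iff
#' their letter `level` is in `allowed_levels` (default A, B, C); rows from
#' `BATMAN` are kept iff `score >= score_cutoff` (default 30, inclusive);
#' rows from any other source (e.g. TCMSP) carry no stated rule and pass
#' unchanged. A HIT2 row without a level, or a BATMAN row without a score,
#' is excluded and counted.
#'
#' @param assocs Tibble with columns `compound_key`, `gene`, `source`, and
#'   optionally `level` (letter grade) and `score` (non-negative number).
#' @param allowed_levels Character vector of acceptable letter grades.
#' @param score_cutoff Minimum similarity score for BATMAN rows; the
#'   comparison is inclusive (`>=`).
#' @return Filtered association tibble; attribute `n_unscored` counts rows
#'   excluded for a missing level/score.
#' @examples
#' a <- tibble::tibble(
#'   compound_key = "c1", gene = c("TP53", "EGFR", "JUN"),
#'   source = c("HIT2", "HIT2", "BATMAN"),
#'   level = c("A", "D", NA), score = c(NA, NA, 42)
#' )
#' filter_associations(a)
#' @export
filter_associations <- function(assocs, allowed_levels = c("A", "B", "C"),
                                score_cutoff = 30) {
  assocs <- as_tibble(assocs)
  if (!all(c("compound_key", "gene", "source") %in% names(assocs))) {
    usage_error(
      "associations need columns compound_key, gene, source")
  }
  if (!"level" %in% names(assocs)) assocs$level <- NA_character_
  if (!"score" %in% names(assocs)) assocs$score <- NA_real_
  if (any(!is.na(assocs$score) & assocs$score < 0)) {
    usage_error("association scores must be non-negative")
  }
  src <- toupper(assocs$source)
  is_hit <- src %in% c("HIT2", "HIT2.0", "HIT")
  is_batman <- src %in% c("BATMAN", "BATMAN-TCM")
  unscored <- (is_hit & is.na(assocs$level)) |
    (is_batman & is.na(assocs$score))
  if (any(unscored)) {
    log_note("targets", paste0(
      sum(unscored), " association(s) lacked the confidence field ",
      "their source requires and were excluded"))
  }
  keep <- !unscored & (
    (!is_hit & !is_batman) |
      (is_hit & toupper(assocs$level) %in% toupper(allowed_levels)) |
      (is_batman & assocs$score >= score_cutoff)
  )
  structure(assocs[keep, , drop = FALSE], n_unscored = sum(unscored))
}

#' Deduplicated union of target genes
#'
#' Distinct gene symbols across all (already confidence-filtered)
#' associations, sorted lexicographically (C collation, so results do not
#' depend on the session locale). Per-source distinct-gene counts and all
#' pairwise overlap counts are attached for the run report.
#'
#' @param assocs Filtered association tibble (see [filter_associations()]).
#' @param mapping Optional two-column data frame (`from`, `to`) applied to
#'   gene symbols before the union (e.g. alias to official symbol).
#' @return Character vector of gene symbols; attributes `per_source`
#'   (named integer vector) and `overlaps` (tibble `source_a`, `source_b`,
#'   `n_shared`).
#' @export
union_targets <- function(assocs, mapping = NULL) {
  assocs <- as_tibble(assocs)
  gene <- trimws(assocs$gene)
  if (any(!nzchar(gene))) usage_error("empty gene symbol in associations")
  if (!is.null(mapping)) {
    mp <- setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
    hit <- gene %in% names(mp)
    gene[hit] <- unname(mp[gene[hit]])
  }
  frac_lower <- mean(grepl("[a-z]", gene))
  if (length(gene) && frac_lower > 0.10) {
    warn(paste0(
      round(100 * frac_lower), "% of gene symbols contain lowercase ",
      "letters; non-human symbols may not have been mapped upstream"))
  }
  by_source <- split(gene, assocs$source)
  per_source <- vapply(by_source, function(g) length(unique(g)), integer(1))
  srcs <- names(by_source)
  overlaps <- tidyr::expand_grid(source_a = srcs, source_b = srcs) |>
    dplyr::filter(.data$source_a < .data$source_b) |>
    dplyr::mutate(n_shared = purrr::map2_int(
      .data$source_a, .data$source_b,
      ~ length(intersect(by_source[[.x]], by_source[[.y]]))
    ))
  out <- sort(unique(gene), method = "radix")
  structure(out, per_source = per_source, overlaps = overlaps)
}

#' Distinct compound-gene edges for network building
#'
#' Collapses associations asserted by several sources to one edge per
#' (compound, gene) pair and labels endpoints with their roles.
#'
#' @param assocs Filtered association tibble.
#' @return Tibble with columns `node1` (compound key), `node2` (gene),
#'   `role1` (`"compound"`), `role2` (`"gene"`).
#' @export
compound_target_map <- function(assocs) {
  assocs <- as_tibble(assocs)
  edges <- dplyr::distinct(
    tibble(node1 = as.character(assocs$compound_key),
           node2 = trimws(assocs$gene))
  )
  edges$role1 <- "compound"
  edges$role2 <- "gene"
  edges
}
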