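# Linking genes to tissues from expression atlases: above-mean rule,
# row Z-scores with the positive-Z rule, dual-source consensus maxima, and
# highest-expression organ-group assignment.

#' Consensus of two expression atlases by per-cell maximum
#'
#' Mirrors the consensus normalized expression (nTPM) convention: for each
#' gene and tissue, the highest value across the two sources is used.
#' Consensus is only defined for genes present in both sources, so genes
#' are intersected; tissues are unioned, a tissue present in one source
#' carrying that source's value.
#'
#' @param atlas_a,atlas_b Two `expression_atlas` objects
#'   (see [as_expression_atlas()]). A shared tissue name means the same
#'   tissue.
#' @return An `expression_atlas` over the common genes and the union of
#'   tissues.
#' @export
consensus_max <- function(atlas_a, atlas_b) {
  ma <- atlas_matrix(atlas_a)
  mb <- atlas_matrix(atlas_b)
  genes <- intersect(rownames(ma), rownames(mb))
  tissues <- union(colnames(ma), colnames(mb))
  out <- matrix(NA_real_, length(genes), length(tissues),
                dimnames = list(genes, tissues))
  shared <- intersect(colnames(ma), colnames(mb))
  only_a <- setdiff(colnames(ma), shared)
  only_b <- setdiff(colnames(mb), shared)
  if (length(shared)) {
    out[, shared] <- pmax(ma[genes, shared, drop = FALSE],
                          mb[genes, shared, drop = FALSE])
  }
  if (length(only_a)) out[, only_a] <- ma[genes, only_a, drop = FALSE]
  if (length(only_b)) out[, only_b] <- mb[genes, only_b, drop = FALSE]
  as_expression_atlas(out)
}

# internal: construct a link set tibble
new_link_set <- function(gene, tissue, rule) {
  structure(
    dplyr::distinct(tibble(gene = gene, tissue = tissue)),
    class = c("link_set", class(tibble())), rule = rule
  )
}

#' Link genes to tissues where expression exceeds the gene's mean
#'
#' A gene is linked to every tissue where its expression is strictly
#' higher than its own average across all tissues of the atlas. A
#' constant row has no tissue above its mean and produces no links; any
#' non-constant row links at least its maximum and never its minimum.
#'
#' @param atlas An `expression_atlas`.
#' @return A `link_set` tibble (`gene`, `tissue`) with attribute
#'   `rule = "above_mean"`.
#' @export
link_above_mean <- function(atlas) {
  m <- atlas_matrix(atlas)
  hit <- m > rowMeans(m)
  idx <- which(hit, arr.ind = TRUE)
  new_link_set(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]], "above_mean")
}

#' Row-standardize an expression atlas
#'
#' Converts each gene's expression profile to standard scores
#' `z = (x - mean) / sd` across tissues, so expression becomes comparable
#' between tissues within a gene. Rows with zero standard deviation
#' (constant expression) cannot be standardized; they are flagged, not
#' divided.
#'
#' @param atlas An `expression_atlas` with at least two tissues.
#' @param ddof Delta degrees of freedom for the standard deviation:
#'   1 (default) for the sample sd, 0 for the population sd.
#' @return A `zscore_atlas` tibble of the same shape (constant rows carry
#'   `NA`), with attribute `constant_genes`.
#' @export
zscore_rows <- function(atlas, ddof = 1) {
  if (!ddof %in% c(0, 1)) usage_error("`ddof` must be 0 or 1")
  m <- atlas_matrix(atlas)
  if (ncol(m) < 2L) {
    usage_error("Z-scores need at least two tissues")
  }
  mu <- rowMeans(m)
  centered <- m - mu
  denom <- if (ddof == 1) ncol(m) - 1L else ncol(m)
  s <- sqrt(rowSums(centered^2) / denom)
  constant <- s == 0
  z <- centered / ifelse(constant, NA_real_, s)
  out <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(z))
  structure(out, class = c("zscore_atlas", class(tibble())),
            constant_genes = rownames(m)[constant], ddof = ddof)
}

#' Link genes to tissues with positive Z-score
#'
#' A gene is linked to every tissue where its standardized expression is
#' strictly positive (overexpression relative to the gene's own mean).
#' Flagged constant rows yield no links. On non-constant rows this rule
#' coincides exactly with [link_above_mean()], since `z > 0` iff
#' `x > mean`.
#'
#' @param z A `zscore_atlas` from [zscore_rows()].
#' @return A `link_set` tibble with attribute `rule = "z_positive"`.
#' @export
link_positive_z <- function(z) {
  stopifnot(inherits(z, "zscore_atlas"))
  m <- as.matrix(z[, -1L, drop = FALSE])
  rownames(m) <- z$gene
  hit <- !is.na(m) & m > 0
  idx <- which(hit, arr.ind = TRUE)
  new_link_set(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]], "z_positive")
}

#' Assign each gene to its highest-expression organ group
#'
#' Tissues are first regrouped into organ groups (e.g. CD33+ myeloid
#' cells, CD34+ cells and B lymphoblasts into bone marrow); each group's
#' value for a gene is the maximum over its member tissues, and the gene
#' is assigned to the group with the highest value. Ties go to the
#' lexicographically smallest group name and are counted. Tissues absent
#' from the grouping are ignored; a gene with all-zero expression across
#' grouped tissues is left unassigned and counted.
#'
#' @param atlas An `expression_atlas`.
#' @param grouping Data frame with columns `tissue`, `organ_group` (see
#'   [organ_grouping()] for the shipped 15-tissue map).
#' @return Tibble `gene`, `organ_group`, `value` (the winning group
#'   maximum); attributes `n_ties` and `unassigned` (character vector).
#' @export
assign_top_group <- function(atlas, grouping) {
  grouping <- as_tibble(grouping)
  stopifnot(all(c("tissue", "organ_group") %in% names(grouping)))
  m <- atlas_matrix(atlas)
  grouping <- grouping[grouping$tissue %in% colnames(m), , drop = FALSE]
  if (nrow(grouping) == 0L) {
    usage_error("no atlas tissue appears in the grouping map")
  }
  groups <- split(grouping$tissue, grouping$organ_group)
  group_max <- vapply(
    groups,
    function(tis) apply(m[, tis, drop = FALSE], 1L, max),
    numeric(nrow(m))
  )
  group_max <- matrix(group_max, nrow = nrow(m),
                      dimnames = list(rownames(m), names(groups)))
  # columns are sorted group names, so which.max's first-hit rule is the
  # lexicographic tie-break
  group_max <- group_max[, order(colnames(group_max)), drop = FALSE]
  best <- apply(group_max, 1L, which.max)
  best_val <- group_max[cbind(seq_len(nrow(m)), best)]
  n_ties <- sum(rowSums(group_max == best_val) > 1L)
  assigned <- best_val > 0
  if (n_ties > 0) {
    log_note("link", paste0(n_ties, " gene(s) had tied top groups; ",
                            "lexicographically first group kept"))
  }
  if (any(!assigned)) {
    log_note("link", paste0(sum(!assigned), " gene(s) had zero expression ",
                            "across all grouped tissues; left unassigned"))
  }
  out <- tibble(
    gene = rownames(m)[assigned],
    organ_group = colnames(group_max)[best[assigned]],
    value = best_val[assigned]
  )
  structure(out, n_ties = n_ties, unassigned = rownames(m)[!assigned])
}

#' Rank tissues or organ groups by linked-gene count
#'
#' The degree of a tissue in the bipartite gene-tissue network is the
#' number of distinct genes linked to it. Returns the full ranking,
#' sorted by degree descending then name; the degrees sum to the number
#' of edges.
#'
#' @param links A `link_set` (or any tibble with `gene` plus a tissue /
#'   group column as its second column).
#' @return Tibble of class `organ_ranking` with columns `tissue`,
#'   `degree`.
#' @export
organ_degree_ranking <- function(links) {
  links <- as_tibble(links)
  if (nrow(links) == 0L) {
    return(structure(tibble(tissue = character(), degree = integer()),
                     class = c("organ_ranking", class(tibble()))))
  }
  key <- names(links)[2L]
  out <- links |>
    dplyr::distinct() |>
    dplyr::count(.data[[key]], name = "degree") |>
    dplyr::rename(tissue = dplyr::all_of(key)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$tissue)
  out$degree <- as.integer(out$degree)
  structure(out, class = c("organ_ranking", class(tibble())))
}
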