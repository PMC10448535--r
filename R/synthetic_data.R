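# Synthetic input generators with planted ground truth. Every generator is a
# pure function of its arguments (including the seed): the same call writes
# byte-identical files. The defaults mirror the magnitudes of a single-herb
# study (a ~170-compound table screening down to 17 actives, three target
# sources of roughly 200/300/80 genes with a 448-gene union, 44 hub targets,
# a 150-term organ catalog over a 7,000-gene universe, and 84-/54-tissue
# atlases regrouped into 8 organ groups).

# internal: zero-padded synthetic symbols
symbol_pool <- function(n, prefix = "G") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate a compound table with a known active subset
#'
#' Active compounds draw OB ~ Uniform(30, 70) and DL ~ Uniform(0.18, 0.9)
#' (inside both screening bounds); inactive compounds fail at least one
#' bound. A stated fraction of compounds is duplicated under a second
#' source label, so deduplication and cross-source overlap can be
#' exercised against known truth.
#'
#' @param n Number of distinct compounds. Default 170.
#' @param frac_active Fraction passing the ADME filter (exact count
#'   `round(n * frac_active)`). Default 0.1.
#' @param frac_dual Fraction of compounds also listed under the second
#'   source. Default 0.15.
#' @param seed Integer seed; fully determines the output.
#' @param path Optional path; when given, the per-source table is written
#'   there as TSV.
#' @return List with `table` (per-source rows: name, cid, ob, dl, source),
#'   `truth` (list: `active` compound keys, `dual_source` keys, `seed`),
#'   and `path`.
#' @export
gen_compounds <- function(n = 170, frac_active = 0.1, frac_dual = 0.15,
                          seed = 1, path = NULL) {
  stopifnot(frac_active >= 0, frac_active <= 1)
  withr::with_seed(seed, {
    n_active <- round(n * frac_active)
    name <- sprintf("compound_%03d", seq_len(n))
    cid <- 100000L + seq_len(n)
    active <- seq_len(n) <= n_active
    ob <- dl <- numeric(n)
    ob[active] <- runif(n_active, 30, 70)
    dl[active] <- runif(n_active, 0.18, 0.9)
    # inactives fail OB, DL, or both
    mode <- sample(c("ob", "dl", "both"), n - n_active, replace = TRUE)
    ob[!active] <- ifelse(mode == "dl", runif(sum(!active), 30, 70),
                          runif(sum(!active), 0, 29.9))
    dl[!active] <- ifelse(mode == "ob", runif(sum(!active), 0.18, 0.9),
                          runif(sum(!active), 0, 0.17))
    tab <- tibble(name = name, cid = cid,
                  ob = round(ob, 2), dl = round(dl, 2), source = "TCMSP")
    dual <- sort(sample.int(n, round(n * frac_dual)))
    tab <- dplyr::bind_rows(
      tab,
      dplyr::mutate(tab[dual, , drop = FALSE], source = "HIT2.0")
    )
    if (!is.null(path)) readr::write_tsv(tab, path)
    list(
      table = tab,
      truth = list(active = paste0("CID", cid[active]),
                   dual_source = paste0("CID", cid[dual]),
                   seed = seed),
      path = path
    )
  })
}

#' Generate a hub-planted interaction edge list
#'
#' Hub genes are wired to every other gene with probability `hub_p` and
#' ordinary genes to each other with the much smaller `spoke_p`, so the
#' planted hubs are exactly the nodes whose degree exceeds twice the mean.
#' Planted edges get combined scores strictly above 0.9 (901--1000 on the
#' STRING integer scale); additional decoy edges get scores at or below
#' 0.9 and must disappear under the high-confidence filter.
#'
#' @param n_genes Number of genes. Default 200.
#' @param n_hubs Number of planted hubs. Default 3.
#' @param spoke_p Spoke--spoke edge probability. Default 0.01.
#' @param hub_p Hub--anything edge probability. Default 0.8. Must exceed
#'   `spoke_p` unless `force = TRUE`.
#' @param decoy_p Probability of a low-score decoy edge on unused pairs.
#'   Default 0.01.
#' @param seed Integer seed.
#' @param genes Optional character vector of gene names (length
#'   `n_genes`); default synthetic symbols.
#' @param hubs Optional hub names drawn from `genes`; default the first
#'   `n_hubs`.
#' @param path Optional output TSV (STRING dialect, 0--1000 scores).
#' @param force Allow the degenerate `hub_p <= spoke_p` setting, under
#'   which hub recovery is not guaranteed.
#' @return List with `edges` (tibble node1/node2/combined_score, 0--1
#'   scale), `truth` (list: `hubs`, `seed`), `path`.
#' @export
gen_ppi <- function(n_genes = 200, n_hubs = 3, spoke_p = 0.01, hub_p = 0.8,
                    decoy_p = 0.01, seed = 1, genes = NULL, hubs = NULL,
                    path = NULL, force = FALSE) {
  stopifnot(n_hubs < n_genes)
  if (hub_p <= spoke_p && !force) {
    usage_error(paste0(
      "hub_p (", hub_p, ") must exceed spoke_p (", spoke_p,
      ") for planted hubs to be recoverable; use force = TRUE to override"))
  }
  genes <- genes %||% symbol_pool(n_genes)
  stopifnot(length(genes) == n_genes)
  hubs <- hubs %||% genes[seq_len(n_hubs)]
  stopifnot(all(hubs %in% genes), length(hubs) == n_hubs)
  withr::with_seed(seed, {
    pairs <- t(utils::combn(genes, 2L))
    is_hub_pair <- pairs[, 1L] %in% hubs | pairs[, 2L] %in% hubs
    p <- ifelse(is_hub_pair, hub_p, spoke_p)
    on <- runif(nrow(pairs)) < p
    planted <- tibble(
      node1 = pairs[on, 1L], node2 = pairs[on, 2L],
      combined_score = sample(901:1000, sum(on), replace = TRUE) / 1000
    )
    off_idx <- which(!on)
    decoy_on <- off_idx[runif(length(off_idx)) < decoy_p]
    decoys <- tibble(
      node1 = pairs[decoy_on, 1L], node2 = pairs[decoy_on, 2L],
      combined_score = sample(150:900, length(decoy_on), replace = TRUE) / 1000
    )
    edges <- dplyr::bind_rows(planted, decoys)
    if (!is.null(path)) write_edge_list(edges, path)
    list(edges = edges, truth = list(hubs = hubs, seed = seed), path = path)
  })
}

#' Generate an organ catalog with planted enriched and depleted terms
#'
#' Builds a catalog of `n_terms` gene sets over a synthetic universe and a
#' query gene list with known structure: term `"planted_enriched"`
#' receives the list genes at rate `signal_fraction` (each list gene is
#' drawn from that term with this probability, otherwise uniformly from
#' the rest of the universe), and term `"planted_depleted"` avoids the
#' list entirely. The remaining decoy terms are uniform draws whose sizes
#' follow a truncated normal around `term_size_mean` -- the scale of a
#' phenotype catalog linking ~7,000 genes to ~150 body parts through
#' ~150,000 associations.
#'
#' @param n_terms Number of terms. Default 150.
#' @param universe_size Genes in the universe. Default 7000.
#' @param planted_term_size Size of the enriched term. Default 100.
#' @param list_size Query-list size. Default 50.
#' @param signal_fraction Probability a list gene comes from the planted
#'   term. Default 0.6. Use `K/N` for a null list.
#' @param depleted_term_size Size of the planted depleted term. Default
#'   1000 (at the catalog's mean term size, where a zero overlap is
#'   detectably depleted).
#' @param term_size_mean,term_size_sd Decoy term-size distribution
#'   (normal, rounded, truncated to \[50, 3000\]). Defaults 1000 / 250.
#' @param plant Plant the two signal terms at all? `FALSE` gives a fully
#'   null catalog/list pair for calibration.
#' @param seed Integer seed.
#' @param gene_list Optional externally supplied query list (character);
#'   the planted term is then built around it instead of drawing a list.
#' @param dir Optional directory; when given, writes `catalog.gmt` and
#'   `gene_list.txt` there.
#' @return List with `catalog` (an [organ_catalog()]), `gene_list`,
#'   `truth` (list: `enriched_term`, `depleted_term`, `signal_fraction`,
#'   `seed`), `paths`.
#' @export
gen_catalog_and_list <- function(n_terms = 150, universe_size = 7000,
                                 planted_term_size = 100, list_size = 50,
                                 signal_fraction = 0.6,
                                 depleted_term_size = 1000,
                                 term_size_mean = 1000, term_size_sd = 250,
                                 plant = TRUE, seed = 1, gene_list = NULL,
                                 dir = NULL) {
  stopifnot(planted_term_size <= universe_size,
            signal_fraction >= 0, signal_fraction <= 1)
  withr::with_seed(seed, {
    universe <- symbol_pool(universe_size)
    sets <- list()
    truth <- list(enriched_term = NA_character_,
                  depleted_term = NA_character_,
                  signal_fraction = signal_fraction, seed = seed)
    if (plant) {
      if (is.null(gene_list)) {
        # draw the list gene by gene: from the planted term w.p.
        # signal_fraction, else uniformly from the remainder
        planted <- sample(universe, planted_term_size)
        rest <- setdiff(universe, planted)
        from_term <- runif(list_size) < signal_fraction
        n_term <- min(sum(from_term), planted_term_size)
        gene_list <- c(sample(planted, n_term),
                       sample(rest, list_size - n_term))
      } else {
        stopifnot(all(gene_list %in% universe))
        in_term <- gene_list[runif(length(gene_list)) < signal_fraction]
        filler <- sample(setdiff(universe, gene_list),
                         max(planted_term_size - length(in_term), 0L))
        planted <- c(in_term, filler)
      }
      avoid <- unique(c(gene_list, planted))
      depleted <- sample(setdiff(universe, avoid), depleted_term_size)
      sets[["planted_enriched"]] <- planted
      sets[["planted_depleted"]] <- depleted
      truth$enriched_term <- "planted_enriched"
      truth$depleted_term <- "planted_depleted"
    } else if (is.null(gene_list)) {
      gene_list <- sample(universe, list_size)
    }
    n_decoys <- n_terms - length(sets)
    sizes <- pmin(pmax(round(rnorm(n_decoys, term_size_mean, term_size_sd)),
                       50), 3000)
    decoys <- lapply(sizes, function(s) sample(universe, s))
    names(decoys) <- sprintf("term_%03d", seq_len(n_decoys))
    sets <- c(sets, decoys)
    catalog <- organ_catalog(sets, universe = universe)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(catalog = file.path(dir, "catalog.gmt"),
                    gene_list = file.path(dir, "gene_list.txt"))
      write_catalog(catalog, paths$catalog)
      writeLines(gene_list, paths$gene_list)
    }
    list(catalog = catalog, gene_list = gene_list, truth = truth,
         paths = paths)
  })
}

#' Generate expression atlases with planted organ-group overexpression
#'
#' Each gene gets a lognormal baseline level; its cell values are that
#' baseline under multiplicative lognormal noise of coefficient of
#' variation `cv`, and the tissues of the gene's planted organ group are
#' multiplied by `fold`. A second, independently re-noised atlas sharing
#' the same baselines and planted groups is returned for consensus tests.
#'
#' @param n_genes Number of genes (ignored when `genes` is given).
#' @param tissues Character vector of tissue names; must cover every
#'   tissue named in `grouping`.
#' @param grouping Data frame `tissue`, `organ_group` defining the groups
#'   whose member tissues are boosted (see [organ_grouping()]).
#' @param fold Multiplicative boost of the planted group. Default 4; must
#'   exceed 1 (use 1 for a no-signal atlas).
#' @param cv Coefficient of variation of the multiplicative noise.
#'   Default 0.3.
#' @param seed Integer seed.
#' @param genes Optional gene names.
#' @param tissues2 Optional tissue subset for the second atlas (default:
#'   same tissues).
#' @param paths Optional character vector of length 2; when given the two
#'   atlases are written there as TSV.
#' @return List with `atlas`, `atlas2` (both `expression_atlas`), `truth`
#'   (list: `gene_groups` named character vector, `fold`, `cv`, `seed`),
#'   `paths`.
#' @export
gen_atlas <- function(n_genes = 200, tissues, grouping, fold = 4, cv = 0.3,
                      seed = 1, genes = NULL, tissues2 = NULL, paths = NULL) {
  stopifnot(fold >= 1)
  grouping <- as_tibble(grouping)
  stopifnot(all(grouping$tissue %in% tissues))
  genes <- genes %||% symbol_pool(n_genes)
  tissues2 <- tissues2 %||% tissues
  stopifnot(all(tissues2 %in% tissues))
  withr::with_seed(seed, {
    n <- length(genes)
    groups <- sort(unique(grouping$organ_group))
    planted <- sample(groups, n, replace = TRUE)
    names(planted) <- genes
    baseline <- rlnorm(n, meanlog = log(50), sdlog = 1)
    sdlog <- sqrt(log(1 + cv^2))
    make_atlas <- function(tis) {
      boost <- matrix(1, n, length(tis), dimnames = list(genes, tis))
      for (g in groups) {
        members <- intersect(grouping$tissue[grouping$organ_group == g], tis)
        if (length(members)) boost[planted == g, members] <- fold
      }
      noise <- matrix(rlnorm(n * length(tis), -sdlog^2 / 2, sdlog),
                      n, length(tis))
      vals <- baseline * boost * noise
      m <- matrix(round(vals, 3), n, length(tis),
                  dimnames = list(genes, tis))
      as_expression_atlas(m)
    }
    atlas <- make_atlas(tissues)
    atlas2 <- make_atlas(tissues2)
    if (!is.null(paths)) {
      write_expression_matrix(atlas, paths[[1L]])
      write_expression_matrix(atlas2, paths[[2L]])
    }
    list(atlas = atlas, atlas2 = atlas2,
         truth = list(gene_groups = planted, fold = fold, cv = cv,
                      seed = seed),
         paths = paths)
  })
}

#' Generate a complete study bundle with planted truth
#'
#' Writes every input the pipeline consumes -- compound table, three
#' per-source association tables, a PPI edge list, an organ catalog with
#' query structure, two expression atlases and the tissue-grouping map --
#' into `dir`, together with `truth.json`, and returns a ready
#' [run_config()]. The planted truth determines what every pipeline stage
#' must recover: 17 active compounds, per-source target lists of 207, 312
#' and 78 genes with a 448-gene union, 44 hub genes that become the core
#' set, one enriched and one depleted catalog term, and each gene's
#' overexpressed organ group.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; determines everything.
#' @return List with `config` (a `run_config`), `truth` (list), `dir`.
#' @export
gen_study <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  universe <- symbol_pool(7000)
  grouping_path <- file.path(dir, "grouping.tsv")
  grouping <- organ_grouping()
  readr::write_tsv(grouping, grouping_path)

  comp <- gen_compounds(n = 170, frac_active = 0.1, seed = seed + 11,
                        path = file.path(dir, "compounds.tsv"))
  active_keys <- comp$truth$active

  per_source <- NULL
  union_genes <- NULL
  withr::with_seed(seed + 23, {
    union_genes <- sort(sample(universe, 448))
    s_tcmsp <- sample(union_genes, 207)
    s_batman <- sample(union_genes, 78)
    uncovered <- setdiff(union_genes, c(s_tcmsp, s_batman))
    stopifnot(length(uncovered) <= 312)
    s_hit <- c(uncovered,
               sample(setdiff(union_genes, uncovered),
                      312 - length(uncovered)))
    assoc_of <- function(genes, source) {
      tibble(
        compound_key = sample(active_keys, length(genes), replace = TRUE),
        gene = genes, source = source,
        level = NA_character_, score = NA_real_
      )
    }
    a_tcmsp <- assoc_of(s_tcmsp, "TCMSP")
    a_hit <- assoc_of(s_hit, "HIT2") |>
      dplyr::mutate(level = sample(c("A", "B", "C"), dplyr::n(),
                                   replace = TRUE))
    a_batman <- assoc_of(s_batman, "BATMAN") |>
      dplyr::mutate(score = round(runif(dplyr::n(), 30, 100), 1))
    # planted failures: wrong level / sub-threshold score / inactive compound
    fail_hit <- tibble(
      compound_key = sample(active_keys, 30, replace = TRUE),
      gene = sample(universe, 30), source = "HIT2",
      level = sample(c("D", "E"), 30, replace = TRUE), score = NA_real_
    )
    fail_batman <- tibble(
      compound_key = sample(active_keys, 20, replace = TRUE),
      gene = sample(universe, 20), source = "BATMAN",
      level = NA_character_, score = round(runif(20, 0, 29.9), 1)
    )
    inactive_rows <- tibble(
      compound_key = paste0("CID", 100000L + 150:169),
      gene = sample(universe, 20), source = "TCMSP",
      level = NA_character_, score = NA_real_
    )
    paths_assoc <- file.path(dir, c("assoc_tcmsp.tsv", "assoc_hit2.tsv",
                                    "assoc_batman.tsv"))
    readr::write_tsv(dplyr::bind_rows(a_tcmsp, inactive_rows),
                     paths_assoc[[1L]])
    readr::write_tsv(dplyr::bind_rows(a_hit, fail_hit), paths_assoc[[2L]])
    readr::write_tsv(dplyr::bind_rows(a_batman, fail_batman),
                     paths_assoc[[3L]])
    per_source <- c(BATMAN = length(unique(s_batman)),
                    HIT2 = length(unique(s_hit)),
                    TCMSP = length(unique(s_tcmsp)))
  })

  hubs <- withr::with_seed(seed + 41, sort(sample(union_genes, 44)))
  ppi <- gen_ppi(n_genes = 448, n_hubs = 44, spoke_p = 0.01, hub_p = 0.8,
                 seed = seed + 37, genes = union_genes, hubs = hubs,
                 path = file.path(dir, "ppi_edges.tsv"))

  cat_bundle <- gen_catalog_and_list(
    n_terms = 150, universe_size = 7000, planted_term_size = 1000,
    signal_fraction = 0.6, depleted_term_size = 1000,
    seed = seed + 53, gene_list = union_genes, dir = dir
  )

  tissues84 <- c(grouping$tissue, sprintf("tissue_%02d", 1:69))
  tissues54 <- c(grouping$tissue, sprintf("tissue_%02d", 1:39))
  atl <- gen_atlas(
    tissues = tissues84, grouping = grouping, fold = 4, cv = 0.3,
    seed = seed + 71, genes = union_genes, tissues2 = tissues54,
    paths = file.path(dir, c("atlas_biogps.tsv", "atlas_hpa.tsv"))
  )

  truth <- list(
    seed = seed,
    active_compounds = comp$truth$active,
    dual_source_compounds = comp$truth$dual_source,
    per_source_targets = as.list(per_source),
    union_targets = union_genes,
    hubs = ppi$truth$hubs,
    enriched_term = cat_bundle$truth$enriched_term,
    depleted_term = cat_bundle$truth$depleted_term,
    gene_groups = as.list(atl$truth$gene_groups)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  config <- run_config(
    compounds = file.path(dir, "compounds.tsv"),
    associations = file.path(dir, c("assoc_tcmsp.tsv", "assoc_hit2.tsv",
                                    "assoc_batman.tsv")),
    edges = file.path(dir, "ppi_edges.tsv"),
    catalog = file.path(dir, "catalog.gmt"),
    atlas = file.path(dir, "atlas_biogps.tsv"),
    atlas2 = file.path(dir, "atlas_hpa.tsv"),
    grouping = grouping_path,
    out_dir = file.path(dir, "out"),
    seed = seed
  )
  list(config = config, truth = truth, dir = dir)
}
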