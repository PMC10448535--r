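# Gene-set enrichment and depletion against a gene-organ catalog.
#
# All tests condition on the 2x2 margins: with a universe of N genes, a term
# annotating K of them, and a query list of n genes, the overlap X is
# hypergeometric. Three p-value constructions are offered:
#   classical   P(X >= k)                      (upper tail)
#   EASE        P(X >= k - 1)                  (one overlap gene discounted;
#                                              conservative, k = 0 -> 1)
#   mid-p       P(X > k) + P(X = k) / 2        (half weight on the observed
#                                              table; less conservative)
# Depletion mirrors the lower tail. Multiple testing uses Benjamini-Hochberg
# over the whole family of tested hypotheses.

#' Validate hypergeometric contingency counts
#'
#' @param k Overlap between the query list and the term.
#' @param K Term size within the universe.
#' @param n Query-list size within the universe.
#' @param N Universe size.
#' @return A list `(k, K, n, N)`, invisibly, after validation.
#' @export
contingency_counts <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    abort("contingency counts must be non-negative integers",
          class = "herborgan_domain_error")
  }
  if (K > N || n > N || k > min(K, n)) {
    abort(sprintf(
      "invalid contingency counts: need k <= min(K, n) and K, n <= N (got k=%d K=%d n=%d N=%d)",
      k, K, n, N), class = "herborgan_domain_error")
  }
  invisible(list(k = k, K = K, n = n, N = N))
}

#' Classical hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @inheritParams contingency_counts
#' @return A probability.
#' @export
hyper_p <- function(k, K, n, N) {
  contingency_counts(k, K, n, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-adjusted Fisher enrichment p-value
#'
#' The EASE score is the one-sided Fisher (hypergeometric upper-tail)
#' p-value computed after removing one gene from the overlap:
#' `P(X >= k - 1)`. A single-gene overlap is fully discounted
#' (`k = 1` gives 1), making the score robust against one-hit terms.
#'
#' @inheritParams contingency_counts
#' @return A probability; `k = 0` returns 1.
#' @export
ease_p <- function(k, K, n, N) {
  contingency_counts(k, K, n, N)
  if (k == 0) return(1)
  phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Mid-p hypergeometric tail probability
#'
#' Gives the observed table half weight:
#' enriched `P(X > k) + P(X = k)/2`, depleted `P(X < k) + P(X = k)/2`.
#' The two directions are exactly complementary
#' (`midp(enr) + midp(dep) = 1`), and the mid-p always lies between the
#' two classical tails.
#'
#' @inheritParams contingency_counts
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower).
#' @return A probability.
#' @export
midp <- function(k, K, n, N, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  contingency_counts(k, K, n, N)
  half <- dhyper(k, K, N - K, n) / 2
  if (direction == "enriched") {
    phyper(k, K, N - K, n, lower.tail = FALSE) + half
  } else {
    phyper(k - 1, K, N - K, n, lower.tail = TRUE) + half
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: values are clipped to 1,
#' monotone non-decreasing in rank, and returned in the original order.
#' Delegates to [stats::p.adjust()] after validating the domain.
#'
#' @param pvals Numeric vector of probabilities in \[0, 1\].
#' @return Adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]", class = "herborgan_domain_error")
  }
  p.adjust(pvals, method = "BH")
}

#' Score a gene list against a gene-organ catalog
#'
#' For every catalog term, the overlap with the query list is tested for
#' enrichment (and, optionally, depletion) under the chosen p-value
#' construction, and the whole family of tested hypotheses is
#' Benjamini-Hochberg adjusted together. Query genes outside the catalog
#' universe are dropped from `n` with a logged count.
#'
#' Each term is reported once, in its fold-change direction (`enriched`
#' when `fold > 1` or the overlap is exactly the expectation, `depleted`
#' otherwise); the reported `p_raw`/`p_adj` belong to the test of that
#' direction. When `test_depletion = FALSE`, only the enrichment tail is
#' ever tested, so under-represented terms simply come out non-significant.
#'
#' @param gene_list Character vector of query gene symbols.
#' @param catalog An [organ_catalog()].
#' @param method `"hypergeometric"` (classical tail), `"ease"` (the
#'   DAVID-style discounted Fisher test) or `"midp"` (the mid-p tail used
#'   for phenotype-catalog enrichment). Depletion tests use the matching
#'   lower-tail construction (classical lower tail under `"ease"`, which
#'   has no depleted analogue).
#' @param test_depletion Also test every term's lower tail? Default `TRUE`
#'   for `"midp"`, `FALSE` otherwise.
#' @param alpha Significance level on the adjusted p-value. Default 0.05.
#' @return Tibble of class `organ_enrichment` with columns `term`, `k`,
#'   `K`, `n`, `N`, `fold`, `direction`, `p_raw`, `p_adj`, `significant`,
#'   sorted by `p_adj` ascending then fold descending; attribute
#'   `n_outside_universe` counts dropped query genes.
#' @examples
#' cat <- organ_catalog(list(liver = c("TP53", "EGFR", "JUN"),
#'                           kidney = c("MYC", "FOS")),
#'                      universe = c("TP53", "EGFR", "JUN", "MYC", "FOS",
#'                                   paste0("G", 1:45)))
#' enrich_catalog(c("TP53", "EGFR"), cat, method = "hypergeometric")
#' @export
enrich_catalog <- function(gene_list, catalog,
                           method = c("hypergeometric", "ease", "midp"),
                           test_depletion = NULL, alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(catalog, "organ_catalog"))
  if (is.null(test_depletion)) test_depletion <- method == "midp"
  gene_list <- unique(trimws(gene_list))
  inside <- gene_list %in% catalog$universe
  n_out <- sum(!inside)
  if (n_out > 0) {
    log_note("enrich", paste0(n_out, " query gene(s) outside the catalog ",
                              "universe were dropped"))
  }
  genes <- gene_list[inside]
  if (length(genes) == 0L) {
    usage_error("no query genes remain inside the catalog universe")
  }
  N <- length(catalog$universe)
  n <- length(genes)
  terms <- names(catalog$sets)
  K <- unname(lengths(catalog$sets))
  k <- unname(vapply(catalog$sets, function(s) sum(genes %in% s),
                     integer(1)))

  p_enr <- switch(method,
    hypergeometric = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    ease = ifelse(k == 0, 1, phyper(k - 2, K, N - K, n, lower.tail = FALSE)),
    midp = phyper(k, K, N - K, n, lower.tail = FALSE) +
      dhyper(k, K, N - K, n) / 2
  )
  p_dep <- switch(method,
    hypergeometric = ,
    ease = phyper(k, K, N - K, n, lower.tail = TRUE),
    midp = phyper(k - 1, K, N - K, n, lower.tail = TRUE) +
      dhyper(k, K, N - K, n) / 2
  )

  expected <- n * K / N
  fold <- ifelse(expected > 0, k / expected, 0)
  direction <- ifelse(fold >= 1, "enriched", "depleted")

  if (test_depletion) {
    family <- c(p_enr, p_dep)
    adj <- bh_adjust(pmin(family, 1))
    adj_enr <- adj[seq_along(p_enr)]
    adj_dep <- adj[seq_along(p_dep) + length(p_enr)]
    p_raw <- ifelse(direction == "enriched", p_enr, p_dep)
    p_adj <- ifelse(direction == "enriched", adj_enr, adj_dep)
  } else {
    p_raw <- p_enr
    p_adj <- bh_adjust(pmin(p_raw, 1))
  }

  out <- tibble(
    term = terms, k = k, K = as.integer(K), n = n, N = N,
    fold = fold, direction = direction,
    p_raw = p_raw, p_adj = pmax(p_adj, p_raw),
    significant = p_adj < alpha
  ) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(.data$fold), .data$term)
  structure(out,
            class = c("organ_enrichment", class(tibble())),
            method = method, alpha = alpha, test_depletion = test_depletion,
            n_outside_universe = n_out)
}
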