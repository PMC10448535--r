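# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (enumeration, pairwise scans) so they never share code
# with the implementation they check.

options(herborgan.quiet = TRUE)

# O(n^2) pairwise-merge oracle for compound deduplication: repeatedly merge
# any two records sharing an identifier until a fixed point.
oracle_dedup <- function(records) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    r$sources <- records$sources[[i]]
    r$name_key <- herborgan::normalize_name(r$name)
    r
  })
  shares_id <- function(a, b) {
    for (k in c("cid", "inchikey", "cas", "name_key")) {
      if (!is.na(a[[k]]) && !is.na(b[[k]]) &&
          identical(as.character(a[[k]]), as.character(b[[k]]))) {
        return(TRUE)
      }
    }
    FALSE
  }
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    for (i in seq_along(recs)) {
      if (merged) break
      for (j in seq_along(recs)) {
        if (j <= i) next
        if (shares_id(recs[[i]], recs[[j]])) {
          a <- recs[[i]]; b <- recs[[j]]
          for (k in c("name", "cid", "cas", "inchikey", "name_key")) {
            if (is.na(a[[k]])) a[[k]] <- b[[k]]
          }
          for (k in c("ob", "dl")) {
            a[[k]] <- if (all(is.na(c(a[[k]], b[[k]])))) NA_real_
                      else max(c(a[[k]], b[[k]]), na.rm = TRUE)
          }
          a$sources <- sort(unique(c(a$sources, b$sources)))
          recs[[i]] <- a
          recs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
  }
  recs
}

# exhaustive hypergeometric tail by summation of the pmf
oracle_tail_sum <- function(from, K, n, N) {
  ks <- from:min(K, n)
  if (from > min(K, n)) return(0)
  sum(vapply(ks, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# enumeration oracle: fraction of all C(N, n) gene lists with overlap >= k
# against the fixed term {1, ..., K}
oracle_enumeration <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# hand-rolled Benjamini-Hochberg step-up (independent of stats::p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# random small atlas as a plain tibble
random_atlas <- function(n_genes, n_tissues, seed) {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n_genes * n_tissues, 0, 100), 3),
                n_genes, n_tissues,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("t", sprintf("%02d", seq_len(n_tissues)))))
    herborgan::as_expression_atlas(m)
  })
}

# link-set tibble sorted for comparison, attributes stripped
sorted_links <- function(links) {
  out <- tibble::as_tibble(links)[, c("gene", "tissue")]
  out <- out[order(out$gene, out$tissue), ]
  attr(out, "rule") <- NULL
  tibble::remove_rownames(out)
}
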