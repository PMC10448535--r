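test_that("EASE discounts one overlap gene and matches the tail-sum oracle", {
  expect_equal(ease_p(0, 10, 20, 100), 1)
  expect_equal(ease_p(1, 10, 20, 100), 1)  # single hit fully discounted
  expect_equal(ease_p(5, 10, 20, 100), oracle_tail_sum(4, 10, 20, 100),
               tolerance = 1e-12)
  # EASE is never smaller than the classical tail of the same table
  for (k in 0:8) {
    expect_gte(ease_p(k, 10, 20, 100), hyper_p(k, 10, 20, 100))
  }
  expect_error(ease_p(5, 4, 20, 100), class = "herborgan_domain_error")
})

test_that("mid-p tails are complementary and bracketed by the classical tails", {
  grid <- expand.grid(K = 1:8, n = 1:8)
  for (i in seq_len(nrow(grid))) {
    K <- grid$K[i]; n <- grid$n[i]; N <- 10
    for (k in 0:min(K, n)) {
      enr <- midp(k, K, n, N, "enriched")
      dep <- midp(k, K, n, N, "depleted")
      expect_equal(enr + dep, 1, tolerance = 1e-12)
      # mid-p lies between P(X > k) and P(X >= k)
      expect_lte(enr, hyper_p(k, K, n, N) + 1e-15)
      expect_gte(enr, hyper_p(k, K, n, N) - dhyper(k, K, N - K, n) - 1e-15)
      if (dhyper(k, K, N - K, n) > 0) {
        expect_lt(enr, hyper_p(k, K, n, N))
      }
    }
  }
  # maximal overlap: enriched mid-p collapses to half the point mass
  expect_equal(midp(4, 5, 4, 10, "enriched"),
               dhyper(4, 5, 5, 4) / 2, tolerance = 1e-15)
  # frozen enumeration value for k=2, K=5, n=4, N=10:
  # all C(10,4) draws, fraction with overlap > 2 plus half of == 2
  subsets <- utils::combn(10, 4)
  ov <- colSums(subsets <= 5)
  expect_equal(midp(2, 5, 4, 10, "enriched"),
               mean(ov > 2) + mean(ov == 2) / 2, tolerance = 1e-12)
})

test_that("hypergeometric tail p equals exhaustive enumeration for small universes", {
  for (N in c(6, 9, 11)) {
    for (n in 1:(N - 1)) {
      subsets <- utils::combn(N, n)
      for (K in 1:(N - 1)) {
        ov <- colSums(subsets <= K)
        for (k in 0:min(K, n)) {
          expect_equal(hyper_p(k, K, n, N), mean(ov >= k),
                       tolerance = 1e-12,
                       label = sprintf("P(X>=%d) for K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(2, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), adj[perm])
      # BH never rejects more than unadjusted testing
      expect_lte(sum(adj < 0.05), sum(p < 0.05))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "herborgan_domain_error")
})

test_that("a perfect-overlap term ranks first with maximal fold under any method", {
  withr::with_seed(3, {
    universe <- paste0("G", 1:200)
    sets <- c(list(target = universe[1:10]),
              lapply(1:20, function(i) sample(universe, 10)))
    names(sets) <- c("target", paste0("decoy", 1:20))
  })
  cat <- organ_catalog(sets, universe = universe)
  for (m in c("hypergeometric", "ease", "midp")) {
    res <- enrich_catalog(universe[1:10], cat, method = m)
    expect_equal(res$term[[1]], "target")
    expect_equal(res$fold[[1]], 200 / 10)  # k/(nK/N) = N/K at full overlap
    expect_equal(res$direction[[1]], "enriched")
  }
})

test_that("genes outside the universe are dropped and an empty list errors", {
  cat <- organ_catalog(list(liver = c("A", "B")), universe = c("A", "B", "C"))
  res <- enrich_catalog(c("A", "ZZZ"), cat)
  expect_equal(attr(res, "n_outside_universe"), 1L)
  expect_equal(res$n[[1]], 1L)
  expect_error(enrich_catalog("ZZZ", cat), class = "herborgan_usage_error")
})

test_that("depletion of empty overlaps is tested and flagged", {
  withr::with_seed(4, {
    universe <- paste0("G", 1:2000)
    avoided <- universe[1:600]
    sets <- c(list(avoided = avoided),
              lapply(1:30, function(i) sample(universe, 100)))
    names(sets) <- c("avoided", paste0("t", 1:30))
    gene_list <- sample(setdiff(universe, avoided), 60)
  })
  cat <- organ_catalog(sets, universe = universe)
  res <- enrich_catalog(gene_list, cat, method = "midp",
                        test_depletion = TRUE)
  row <- res[res$term == "avoided", ]
  expect_equal(row$k, 0L)
  expect_equal(row$direction, "depleted")
  expect_lt(row$p_adj, 0.05)
  # p_adj never falls below p_raw
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("the planted enriched term dominates a generated catalog", {
  g <- gen_catalog_and_list(seed = 10)
  res <- enrich_catalog(g$gene_list, g$catalog, method = "midp")
  expect_equal(res$term[[1]], "planted_enriched")
  expect_lt(res$p_adj[[1]], 0.05)
  dep <- res[res$term == "planted_depleted", ]
  expect_equal(dep$direction, "depleted")
})
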