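tiny_atlas <- function(values, tissues = paste0("t", seq_len(ncol(values))),
                       genes = paste0("g", seq_len(nrow(values)))) {
  dimnames(values) <- list(genes, tissues)
  as_expression_atlas(values)
}

test_that("consensus takes the per-cell maximum over intersected genes", {
  a <- tiny_atlas(matrix(c(5, 1), 1), tissues = c("t1", "t2"), genes = "g")
  b <- tiny_atlas(matrix(c(7, 0, 3), 1), tissues = c("t1", "t2", "t3"),
                  genes = "g")
  cons <- consensus_max(a, b)
  expect_equal(unlist(cons[1, c("t1", "t2", "t3")]),
               c(t1 = 7, t2 = 1, t3 = 3))  # max, max, carried from b

  # a gene missing from one source has no consensus value
  a2 <- tiny_atlas(matrix(1:4, 2), genes = c("g1", "g2"))
  b2 <- tiny_atlas(matrix(5:6, 1), genes = "g2")
  expect_equal(consensus_max(a2, b2)$gene, "g2")

  # elementwise oracle on a random pair
  ra <- random_atlas(50, 10, seed = 12)
  rb <- random_atlas(50, 10, seed = 13)
  cons <- consensus_max(ra, rb)
  ma <- as.matrix(ra[, -1]); mb <- as.matrix(rb[, -1])
  expect_equal(as.matrix(cons[, -1]), pmax(ma, mb), ignore_attr = TRUE)
})

test_that("above-mean linking is strict and skips constant rows", {
  atlas <- tiny_atlas(rbind(c(1, 2, 3), c(5, 5, 5)))
  links <- link_above_mean(atlas)
  expect_equal(nrow(links), 1L)
  expect_equal(links$tissue, "t3")   # 2 is not > mean 2; 3 is

  # row-scan oracle on a larger atlas
  big <- random_atlas(200, 84, seed = 14)
  links <- link_above_mean(big)
  m <- as.matrix(big[, -1]); rownames(m) <- big$gene
  expected <- sum(m > rowMeans(m))
  expect_equal(nrow(links), expected)
  # each non-constant row links >= 1 and <= T-1 tissues
  per_gene <- table(factor(links$gene, levels = big$gene))
  expect_true(all(per_gene >= 1 & per_gene <= ncol(m) - 1))
})

test_that("row Z-scores have mean 0 and the stated sd, with constants flagged", {
  atlas <- tiny_atlas(rbind(c(1, 2, 3), c(4, 4, 4)))
  z <- zscore_rows(atlas)
  expect_equal(unlist(z[1, -1]), c(t1 = -1, t2 = 0, t3 = 1))
  expect_equal(attr(z, "constant_genes"), "g2")
  expect_true(all(is.na(z[2, -1])))

  big <- random_atlas(100, 20, seed = 15)
  for (dd in c(0, 1)) {
    z <- zscore_rows(big, ddof = dd)
    m <- as.matrix(z[, -1])
    expect_true(all(abs(rowMeans(m)) < 1e-9))
    denom <- ncol(m) - dd
    sds <- sqrt(rowSums((m - rowMeans(m))^2) / denom)
    expect_true(all(abs(sds - 1) < 1e-9))
  }
  expect_error(zscore_rows(tiny_atlas(matrix(1, 1))),
               class = "herborgan_usage_error")
})

test_that("positive-Z linking equals above-mean linking on non-constant rows", {
  atlas <- tiny_atlas(rbind(c(1, 2, 3)))
  expect_equal(sorted_links(link_positive_z(zscore_rows(atlas))),
               tibble::tibble(gene = "g1", tissue = "t3"))
  for (seed in 1:5) {
    big <- random_atlas(100, 54, seed = seed)
    expect_equal(sorted_links(link_positive_z(zscore_rows(big))),
                 sorted_links(link_above_mean(big)))
  }
})

test_that("highest-expression assignment uses group maxima and breaks ties low", {
  grouping <- organ_grouping()
  atlas <- tiny_atlas(
    matrix(c(900, 400, 100), 1),
    tissues = c("CD33+ myeloid cells", "whole blood", "prostate"),
    genes = "TNF"
  )
  out <- assign_top_group(atlas, grouping)
  expect_equal(out$organ_group, "bone marrow")

  # exact tie across two groups goes to the alphabetically first
  tie <- tiny_atlas(matrix(c(5, 5), 1),
                    tissues = c("prostate", "lung"), genes = "g")
  out <- assign_top_group(tie, grouping)
  expect_equal(out$organ_group, "lung")
  expect_equal(attr(out, "n_ties"), 1L)

  # all-zero rows stay unassigned
  zero <- tiny_atlas(matrix(c(0, 0), 1),
                     tissues = c("prostate", "lung"), genes = "g")
  out <- assign_top_group(zero, grouping)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "unassigned"), "g")

  # the winning group always contains an above-mean-linked tissue
  g <- gen_atlas(n_genes = 60, tissues = grouping$tissue,
                 grouping = grouping, seed = 22)
  asg <- assign_top_group(g$atlas, grouping)
  links <- link_above_mean(g$atlas)
  for (i in seq_len(nrow(asg))) {
    linked <- links$tissue[links$gene == asg$gene[i]]
    members <- grouping$tissue[grouping$organ_group == asg$organ_group[i]]
    expect_true(length(intersect(linked, members)) >= 1)
  }
})

test_that("planted organ groups are recovered at strong signal", {
  grouping <- organ_grouping()
  hits <- 0; total <- 0
  for (seed in 1:5) {
    g <- gen_atlas(n_genes = 200, tissues = grouping$tissue,
                   grouping = grouping, fold = 4, cv = 0.3, seed = seed)
    asg <- assign_top_group(g$atlas, grouping)
    truth <- g$truth$gene_groups
    hits <- hits + sum(asg$organ_group == truth[asg$gene])
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.95)
})

test_that("organ degree ranking tallies distinct genes per tissue", {
  links <- tibble::tibble(gene = c("g1", "g2", "g1"),
                          tissue = c("t1", "t1", "t2"))
  rk <- organ_degree_ranking(links)
  expect_equal(rk$tissue, c("t1", "t2"))
  expect_equal(rk$degree, c(2L, 1L))

  expect_equal(nrow(organ_degree_ranking(links[0, ])), 0L)

  withr::with_seed(16, {
    big <- tibble::tibble(gene = sample(paste0("g", 1:40), 300, TRUE),
                          tissue = sample(paste0("t", 1:12), 300, TRUE))
  })
  big <- dplyr::distinct(big)
  rk <- organ_degree_ranking(big)
  tally <- sort(table(big$tissue), decreasing = TRUE)
  expect_equal(sum(rk$degree), nrow(big))
  expect_equal(sort(rk$degree, decreasing = TRUE),
               as.integer(sort(tally, decreasing = TRUE)))
})
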