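assoc_row <- function(gene, source, level = NA_character_, score = NA_real_,
                      compound = "c1") {
  tibble::tibble(compound_key = compound, gene = gene, source = source,
                 level = level, score = score)
}

test_that("per-source confidence rules apply only to their source", {
  a <- dplyr::bind_rows(
    assoc_row("TP53", "HIT2", level = "A"),
    assoc_row("EGFR", "HIT2", level = "C"),
    assoc_row("JUN", "HIT2", level = "D"),
    assoc_row("MYC", "BATMAN", score = 30),
    assoc_row("FOS", "BATMAN", score = 29.99),
    assoc_row("SRC", "TCMSP")          # no rule for TCMSP: passes
  )
  out <- filter_associations(a)
  expect_setequal(out$gene, c("TP53", "EGFR", "MYC", "SRC"))
})

test_that("rows missing their required confidence field are excluded, not erred", {
  a <- dplyr::bind_rows(
    assoc_row("TP53", "HIT2"),                 # no level
    assoc_row("MYC", "BATMAN"),                # no score
    assoc_row("SRC", "TCMSP")
  )
  out <- filter_associations(a)
  expect_equal(out$gene, "SRC")
  expect_equal(attr(out, "n_unscored"), 2L)
})

test_that("confidence filtering is idempotent and recovers a planted subset", {
  withr::with_seed(31, {
    n <- 200
    src <- sample(c("TCMSP", "HIT2", "BATMAN"), n, replace = TRUE)
    pass <- logical(n)
    level <- rep(NA_character_, n)
    score <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (src[i] == "HIT2") {
        pass[i] <- runif(1) < 0.5
        level[i] <- if (pass[i]) sample(c("A", "B", "C"), 1)
                    else sample(c("D", "E"), 1)
      } else if (src[i] == "BATMAN") {
        pass[i] <- runif(1) < 0.5
        score[i] <- if (pass[i]) runif(1, 30, 100) else runif(1, 0, 29.9)
      } else {
        pass[i] <- TRUE
      }
    }
    a <- tibble::tibble(compound_key = "c1",
                        gene = paste0("G", seq_len(n)),
                        source = src, level = level, score = score)
  })
  out <- filter_associations(a)
  expect_setequal(out$gene, a$gene[pass])
  expect_equal(tibble::as_tibble(filter_associations(out)),
               tibble::as_tibble(out))
})

test_that("the target union is a sorted deduplicated set with source counts", {
  a <- dplyr::bind_rows(
    assoc_row("TP53", "TCMSP", compound = "c1"),
    assoc_row("TP53", "HIT2", level = "A", compound = "c2"),
    assoc_row("EGFR", "TCMSP", compound = "c1")
  )
  u <- union_targets(filter_associations(a))
  expect_identical(as.character(u), c("EGFR", "TP53"))
  expect_equal(attr(u, "per_source")[["TCMSP"]], 2L)
  expect_length(union_targets(a[0, ]), 0L)
})

test_that("union size obeys inclusion-exclusion on planted source overlaps", {
  withr::with_seed(41, {
    pool <- paste0("G", 1:800)
    s1 <- sample(pool, 207)
    s2 <- sample(pool, 312)
    s3 <- sample(pool, 78)
    a <- dplyr::bind_rows(
      tibble::tibble(compound_key = "c1", gene = s1, source = "TCMSP",
                     level = NA_character_, score = NA_real_),
      tibble::tibble(compound_key = "c1", gene = s2, source = "HIT2",
                     level = "A", score = NA_real_),
      tibble::tibble(compound_key = "c1", gene = s3, source = "BATMAN",
                     level = NA_character_, score = 50)
    )
  })
  u <- union_targets(a)
  ie <- length(s1) + length(s2) + length(s3) -
    length(intersect(s1, s2)) - length(intersect(s1, s3)) -
    length(intersect(s2, s3)) + length(intersect(intersect(s1, s2), s3))
  expect_equal(length(u), ie)
  expect_lte(length(u), sum(attr(u, "per_source")))
  ov <- attr(u, "overlaps")
  look <- function(a, b) ov$n_shared[ov$source_a == a & ov$source_b == b]
  expect_equal(look("HIT2", "TCMSP"), length(intersect(s1, s2)))
  expect_equal(look("BATMAN", "TCMSP"), length(intersect(s1, s3)))
  expect_equal(look("BATMAN", "HIT2"), length(intersect(s2, s3)))
})

test_that("an optional symbol mapping is honored before the union", {
  a <- assoc_row("Tp53_alias", "TCMSP")
  u <- union_targets(a, mapping = data.frame(from = "Tp53_alias",
                                             to = "TP53"))
  expect_identical(as.character(u), "TP53")
})

test_that("compound-gene edges are distinct pairs with role labels", {
  a <- dplyr::bind_rows(
    assoc_row("TP53", "TCMSP", compound = "c1"),
    assoc_row("TP53", "HIT2", level = "A", compound = "c1"),
    assoc_row("EGFR", "TCMSP", compound = "c2")
  )
  edges <- compound_target_map(a)
  expect_equal(nrow(edges), 2L)
  expect_true(all(edges$role1 == "compound" & edges$role2 == "gene"))

  # brute-force distinct-pair oracle on a larger random table
  withr::with_seed(17, {
    big <- tibble::tibble(
      compound_key = sample(paste0("c", 1:17), 500, TRUE),
      gene = sample(paste0("G", 1:60), 500, TRUE),
      source = "TCMSP", level = NA_character_, score = NA_real_
    )
  })
  expect_equal(nrow(compound_target_map(big)),
               nrow(unique(big[, c("compound_key", "gene")])))
})
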