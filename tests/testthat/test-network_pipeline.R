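test_that("role graphs merge typed edges and compute degrees", {
  cg <- tibble::tibble(node1 = "c1", node2 = "g1",
                       role1 = "compound", role2 = "gene")
  gg <- tibble::tibble(node1 = "g1", node2 = "bone marrow",
                       role1 = "gene", role2 = "organ-group")
  rg <- build_role_graph(cg, gg)
  expect_equal(nrow(rg$nodes), 3L)
  expect_equal(igraph::ecount(rg$graph), 2L)
  deg <- setNames(rg$nodes$degree, rg$nodes$node)
  expect_equal(deg[["g1"]], 2L)
  expect_equal(deg[["c1"]], 1L)
  expect_equal(sum(rg$nodes$degree), 2L * igraph::ecount(rg$graph))
})

test_that("role conflicts and same-role edges are structure errors", {
  cg <- tibble::tibble(node1 = "c1", node2 = "X",
                       role1 = "compound", role2 = "gene")
  tg <- tibble::tibble(node1 = "X", node2 = "g2",
                       role1 = "tissue", role2 = "gene")
  expect_error(build_role_graph(cg, tg), "more than one role",
               class = "herborgan_structure_error")

  same <- tibble::tibble(node1 = "g1", node2 = "g2",
                         role1 = "gene", role2 = "gene")
  expect_error(build_role_graph(same), "non-adjacent",
               class = "herborgan_structure_error")
})

test_that("tripartite degree attributes match a tally oracle", {
  withr::with_seed(25, {
    cg <- dplyr::distinct(tibble::tibble(
      node1 = sample(paste0("c", 1:10), 80, TRUE),
      node2 = sample(paste0("g", 1:25), 80, TRUE),
      role1 = "compound", role2 = "gene"
    ))
    gg <- dplyr::distinct(tibble::tibble(
      node1 = sample(paste0("g", 1:25), 60, TRUE),
      node2 = sample(paste0("o", 1:6), 60, TRUE),
      role1 = "gene", role2 = "organ-group"
    ))
  })
  rg <- build_role_graph(cg, gg)
  all_edges <- dplyr::bind_rows(cg, gg)
  tally <- table(c(all_edges$node1, all_edges$node2))
  for (i in seq_len(nrow(rg$nodes))) {
    expect_equal(rg$nodes$degree[i],
                 as.integer(tally[[rg$nodes$node[i]]]))
  }
})

test_that("run configurations validate fields and round-trip through YAML", {
  expect_error(run_config(nonsense = 1), class = "herborgan_usage_error")
  expect_error(run_config(alpha = 2))
  cfg <- run_config(ob_min = 25, method = "ease", seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$ob_min, 25)
  expect_equal(back$method, "ease")
  # unknown keys in a config file fail closed
  writeLines("bogus_key: 1", path)
  expect_error(read_run_config(path), class = "herborgan_usage_error")
})

test_that("the pipeline recovers every planted stage of a study bundle", {
  dir <- withr::local_tempdir()
  st <- gen_study(dir, seed = 4)
  run <- run_pipeline(st$config)
  r <- run$report
  expect_equal(r$compounds$active, length(st$truth$active_compounds))
  expect_equal(unlist(r$targets$per_source),
               unlist(st$truth$per_source_targets))
  expect_equal(r$targets$union, length(st$truth$union_targets))
  expect_setequal(r$network$core_genes, st$truth$hubs)
  expect_equal(run$enrichment$term[[1]], st$truth$enriched_term)
  expect_true(run$enrichment$significant[[1]])
  # gene nodes of the tripartite network are exactly the core set
  gene_nodes <- run$network$nodes$node[run$network$nodes$role == "gene"]
  expect_true(all(gene_nodes %in% run$core$gene))
  expect_equal(sum(run$network$nodes$degree),
               2L * igraph::ecount(run$network$graph))
  # every expected artifact landed on disk
  outs <- list.files(st$config$out_dir)
  expect_true(all(c("report.json", "active_compounds.tsv",
                    "core_targets.tsv", "organ_enrichment.tsv",
                    "organ_ranking.tsv", "compound_gene_organ.graphml")
                  %in% outs))
})

test_that("disabling enrichment skips that stage but still links", {
  dir <- withr::local_tempdir()
  st <- gen_study(dir, seed = 6)
  cfg <- st$config
  cfg$run_enrichment <- FALSE
  run <- run_pipeline(cfg)
  expect_equal(run$report$enrichment$status, "skipped")
  expect_null(run$enrichment)
  expect_gt(nrow(run$links), 0L)
  expect_false("organ_enrichment.tsv" %in% list.files(cfg$out_dir))
})

test_that("reruns at a fixed seed are byte-identical", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  st1 <- gen_study(dir1, seed = 8)
  st2 <- gen_study(dir2, seed = 8)
  for (f in c("compounds.tsv", "ppi_edges.tsv", "catalog.gmt",
              "atlas_biogps.tsv", "truth.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  run1 <- run_pipeline(st1$config)
  # second run in a fresh out dir over the same inputs
  cfg2 <- st1$config
  cfg2$out_dir <- file.path(dir1, "out2")
  run2 <- run_pipeline(cfg2)
  r1 <- readLines(file.path(st1$config$out_dir, "report.json"))
  r2 <- readLines(file.path(cfg2$out_dir, "report.json"))
  expect_identical(gsub("out2", "out", r2), r1)
})
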