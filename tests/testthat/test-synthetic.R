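test_that("network generation is reproducible with the requested scale", {
  tiny <- generate_network(2, 1, 1)
  e <- network_edges(tiny)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$protein1, e$protein2), c("gene_0", "gene_1"))

  a <- network_edges(generate_network(200, 8, 5))
  b <- network_edges(generate_network(200, 8, 5))
  expect_identical(a, b)
  expect_false(identical(a, network_edges(generate_network(200, 8, 6))))

  g <- generate_network(500, 10, 7)
  md <- mean(igraph::degree(g$graph))
  expect_gte(md, 8); expect_lte(md, 12)
  expect_true(all(network_edges(g)$combined_score %in% 150:999))
  expect_error(generate_network(10, 10, 1), "below n_genes")
})

test_that("annotation terms honor size bounds and the locality dial", {
  net <- generate_network(300, 6, 2)
  fixed <- generate_annotations(net, 30, c(5, 5), 0.9, 4)
  expect_true(all(lengths(fixed$gene_sets) == 5))
  expect_identical(generate_annotations(net, 30, c(5, 5), 0.9, 4)$gene_sets,
                   fixed$gene_sets)

  # locality 0: membership is uniform across genes
  rand <- generate_annotations(net, 250, c(10, 10), 0, 8)
  counts <- table(factor(unlist(rand$gene_sets),
                         levels = network_nodes(net)))
  rate <- counts / 250
  expect_equal(mean(rate), 10 / 300, tolerance = 0.002)
  # no gene should be wildly over-represented under uniform growth
  expect_lt(max(rate), 0.25)

  # locality 1: terms are connected subgraphs
  local <- generate_annotations(net, 20, c(6, 6), 1, 9)
  for (s in local$gene_sets[1:5]) {
    sub <- igraph::induced_subgraph(net$graph, s)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("planted positives meet their quotas and respond to signal strength", {
  net <- generate_network(300, 5, 3)
  cat <- generate_annotations(net, 60, c(5, 10), 0.9, 3)
  cfg <- synthetic_config(n_genes = 300, mean_degree = 5, n_terms = 60,
                          term_size_range = c(5, 10),
                          diseases = c("d1", "d2"),
                          n_positives_per_disease = c(40, 25),
                          n_driver_terms_per_disease = 2,
                          signal_strength = 0.9, seed = 3)
  pl <- plant_disease_signal(net, cat, cfg)
  expect_equal(unname(colSums(pl$matrix)), c(40, 25))
  expect_length(pl$ground_truth$driver_terms$d1, 2)
  expect_true(all(unlist(pl$ground_truth$driver_terms) %in% cat$term_ids))
  # recorded overlaps are flagged in both diseases
  ov <- pl$ground_truth$overlap_genes[["d1 & d2"]]
  if (length(ov)) {
    expect_true(all(pl$matrix[ov, "d1"] == 1 & pl$matrix[ov, "d2"] == 1))
  }

  # positives' driver-score median exceeds negatives' under strong signal
  enc <- encode_profiles(net, cat, rownames(pl$matrix))
  drv <- pl$ground_truth$driver_terms$d1
  y <- pl$matrix[, "d1"]
  pos_med <- median(rowMeans(enc[y == 1, drv, drop = FALSE]))
  neg_med <- median(rowMeans(enc[y == 0, drv, drop = FALSE]))
  expect_gt(pos_med, neg_med)
})

test_that("zero signal plants uniform positives", {
  net <- generate_network(250, 5, 13)
  cat <- generate_annotations(net, 40, c(5, 10), 0.9, 13)
  # across seeds, compare driver-score distributions of positives vs negatives
  pvals <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_genes = 250, mean_degree = 5, n_terms = 40,
                            term_size_range = c(5, 10), diseases = "d",
                            n_positives_per_disease = 60,
                            n_driver_terms_per_disease = 2,
                            signal_strength = 0, seed = s)
    pl <- plant_disease_signal(net, cat, cfg)
    y <- pl$matrix[, "d"]
    deg <- igraph::degree(net$graph)
    suppressWarnings(
      wilcox.test(deg[y == 1], deg[y == 0])$p.value)
  }, 0.0)
  # uniform sampling: location test should almost never fire at alpha 0.01
  expect_lte(sum(pvals < 0.01), 2)
})

test_that("the benchmark bundle round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 250, mean_degree = 6, n_terms = 40,
                          term_size_range = c(5, 10),
                          diseases = c("d1", "d2", "d3"),
                          n_positives_per_disease = c(20, 30, 10), seed = 5)
  manifest <- generate_benchmark_bundle(cfg, dir)
  expect_identical(manifest$seed, 5L)
  m <- read_disease_gene_matrix(file.path(dir, "disease_gene_matrix.tsv"))
  expect_equal(unname(colSums(m)), c(20, 30, 10))
  net <- read_network_edges(file.path(dir, "network.txt"))
  expect_identical(length(network_nodes(net)), 250L)
  cat <- read_gmt(file.path(dir, "annotations.gmt"))
  expect_length(cat, 40)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_named(gt, c("driver_terms", "overlap_genes"))
  ycfg <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(ycfg$seed, 5L)

  # regeneration is byte-identical; a different seed is not
  dir2 <- withr::local_tempdir()
  generate_benchmark_bundle(cfg, dir2)
  for (f in c("network.txt", "annotations.gmt", "disease_gene_matrix.tsv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
  cfg2 <- cfg; cfg2$seed <- 6L
  dir3 <- withr::local_tempdir()
  generate_benchmark_bundle(cfg2, dir3)
  expect_false(identical(
    readLines(file.path(dir, "disease_gene_matrix.tsv")),
    readLines(file.path(dir3, "disease_gene_matrix.tsv"))))
})
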