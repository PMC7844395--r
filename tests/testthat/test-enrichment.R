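make_net <- function(edges) {
  functional_network(data.frame(protein1 = edges[, 1], protein2 = edges[, 2],
                                combined_score = 500L,
                                stringsAsFactors = FALSE))
}

test_that("neighbor sets are direct neighbors, excluding the gene itself", {
  tri <- make_net(cbind(c("a", "b", "a"), c("b", "c", "c")))
  expect_setequal(neighbor_set(tri, "a"), c("b", "c"))
  expect_identical(neighbor_set(tri, "zzz"), character())
  star <- make_net(cbind("hub", paste0("leaf", 1:5)))
  expect_setequal(neighbor_set(star, "hub"), paste0("leaf", 1:5))
})

test_that("hypergeometric upper tail matches hand-enumerated cases", {
  expect_identical(hypergeom_upper_tail(10, 5, 4, 0), 1.0)
  expect_identical(hypergeom_upper_tail(10, 10, 3, 3), 1.0)
  expect_equal(hypergeom_upper_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-14)
  expect_equal(enrichment_score(10, 5, 4, 4), -log10(5 / 210),
               tolerance = 1e-12)
  expect_identical(enrichment_score(10, 5, 4, 0), 0.0)
  expect_equal(enrichment_score(10, 5, 4, 3),
               -log10(hypergeom_upper_tail(10, 5, 4, 3)), tolerance = 1e-12)
})

test_that("tail probabilities agree with exhaustive enumeration and phyper", {
  set.seed(7)
  for (i in 1:60) {
    N <- sample(4:12, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n + M - N)
    m <- pick1(lo:min(M, n))
    p <- hypergeom_upper_tail(N, M, n, m)
    expect_equal(p, oracle_hyper_tail(N, M, n, m), tolerance = 1e-12,
                 label = sprintf("N=%d M=%d n=%d m=%d", N, M, n, m))
    expect_equal(p, phyper(m - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("tail is monotone in the overlap, normalized, and M/n symmetric", {
  for (N in c(8, 15, 40)) {
    M <- floor(N / 3) + 1
    n <- floor(N / 2)
    lo <- max(0, n + M - N)
    tails <- hypergeom_upper_tail(N, M, n, lo:min(M, n))
    expect_true(all(diff(tails) <= 1e-15))
    pmf_sum <- sum(dhyper(0:min(M, n), M, N - M, n))
    expect_equal(pmf_sum, 1, tolerance = 1e-12)
    for (m in lo:min(M, n)) {
      expect_equal(hypergeom_upper_tail(N, M, n, m),
                   hypergeom_upper_tail(N, n, M, m), tolerance = 1e-12)
    }
  }
})

test_that("invalid counts are rejected", {
  expect_error(hypergeom_upper_tail(10, 11, 3, 1), "exceed N")
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "min\\(M, n\\)")
  expect_error(hypergeom_upper_tail(10, 8, 8, 2), "feasible")
})

test_that("encoding matches a direct tail computation on a toy universe", {
  # 6-gene universe; g0 has neighbors g1, g2, g3, all annotated to T1
  edges <- cbind(rep("g0", 3), c("g1", "g2", "g3"))
  net <- functional_network(
    data.frame(protein1 = edges[, 1], protein2 = edges[, 2],
               combined_score = 900L, stringsAsFactors = FALSE),
    nodes = paste0("g", 0:5))
  cat <- annotation_catalog("T1", "toy", list(c("g1", "g2", "g3")))
  enc <- encode_profiles(net, cat, paste0("g", 0:5))
  expect_equal(enc["g0", "T1"], -log10(1 / 20), tolerance = 1e-12)
  # g5 is isolated: all-zero row
  expect_identical(unname(enc["g5", ]), 0)
  # empty catalog: zero feature columns
  empty <- annotation_catalog(character(), character(), list())
  enc0 <- encode_profiles(net, empty, paste0("g", 0:5))
  expect_identical(dim(enc0), c(6L, 0L))
})

test_that("encoding is invariant to gene order and catalog line order", {
  net <- generate_network(60, 4, 3)
  cat1 <- generate_annotations(net, 12, c(4, 8), 0.5, 5)
  genes <- network_nodes(net)
  enc1 <- encode_profiles(net, cat1, genes)
  enc2 <- encode_profiles(net, cat1, rev(genes))
  expect_equal(enc1, enc2[genes, ], tolerance = 1e-14)
  perm <- c(5:12, 1:4)
  cat2 <- annotation_catalog(cat1$term_ids[perm], cat1$descriptions[perm],
                             cat1$gene_sets[perm])
  enc3 <- encode_profiles(net, cat2, genes)
  expect_equal(enc1, enc3[, colnames(enc1)], tolerance = 1e-14)
})

test_that("terms outside the universe give zero columns with a warning", {
  net <- make_net(cbind("a", "b"))
  cat <- annotation_catalog(c("T1", "T2"), c("d1", "d2"),
                            list(c("a", "b"), c("x", "y")))
  expect_warning(enc <- encode_profiles(net, cat, c("a", "b")),
                 "no gene in the universe")
  expect_identical(unname(enc[, "T2"]), c(0, 0))
})
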