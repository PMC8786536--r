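test_that("edge-list loading symmetrizes, deduplicates and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA"), f)
  net <- load_network(f)
  expect_equal(igraph::vcount(net), 2)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(net$n_self_loops_removed, 1)
  expect_equal(net$n_duplicate_edges_removed, 1)
  # handshake lemma on a fresh 3-edge file
  writeLines(c("A\tB", "B\tC", "C\tD"), f)
  net3 <- load_network(f)
  expect_equal(sum(igraph::degree(net3)), 2 * igraph::ecount(net3))
  # extra columns (scored edge lists) are tolerated
  writeLines(c("A\tB\t0.9", "B\tC\t0.3"), f)
  expect_equal(igraph::ecount(load_network(f)), 2)
  # empty file warns and returns an empty network
  writeLines(character(0), f)
  expect_warning(net0 <- load_network(f), "empty")
  expect_equal(igraph::vcount(net0), 0)
})

test_that("induced subnetwork keeps only internal edges and summarizes degree", {
  net <- load_network(data.frame(from = c("A", "B", "C"),
                                 to = c("B", "C", "A")))  # triangle
  sub <- induced_subnetwork(net, c("A", "B"))
  expect_equal(sub$n_nodes, 2)
  expect_equal(sub$n_edges, 1)
  expect_equal(sub$mean_degree, 1)
  # path A-B-C restricted to its endpoints has no edges
  path <- load_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  ends <- induced_subnetwork(path, c("A", "C"))
  expect_equal(c(ends$n_nodes, ends$n_edges, ends$mean_degree), c(2, 0, 0))
  # the full node set reproduces the network
  full <- induced_subnetwork(net, c("A", "B", "C", "missing"))
  expect_equal(full$n_edges, igraph::ecount(net))
})

test_that("Fisher enrichment tail is exact against enumeration and phyper", {
  # published driver-table configurations at 3 significant figures
  expect_equal(signif(fisher_enrichment_tail(4, 12, 205, 17381), 3), 3.06e-5)
  expect_equal(signif(fisher_enrichment_tail(5, 31, 205, 17381), 3), 6.09e-5)
  expect_equal(signif(fisher_enrichment_tail(5, 26, 205, 17381), 3), 2.88e-5)
  expect_equal(signif(fisher_enrichment_tail(4, 20, 205, 17381), 3), 1.66e-4)
  # a = 0 is the whole distribution
  expect_equal(fisher_enrichment_tail(0, 5, 10, 100), 1)
  # small case against direct enumeration
  expect_equal(fisher_enrichment_tail(2, 1, 3, 6),
               hyper_tail_oracle(2, 1, 3, 6), tolerance = 1e-12)
  # exhaustive grid over all consistent tables with N <= 60
  for (N in c(7, 19, 38, 60)) {
    for (K in c(1, floor(N / 3), N - 1)) {
      for (n in c(1, floor(N / 2), N)) {
        for (a in 0:min(K, n)) {
          b <- n - a
          if (b > N - K) next
          expect_equal(fisher_enrichment_tail(a, b, K, N),
                       hyper_tail_oracle(a, b, K, N), tolerance = 1e-12)
          expect_equal(fisher_enrichment_tail(a, b, K, N),
                       stats::phyper(a - 1, K, N - K, n,
                                     lower.tail = FALSE),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # monotone decreasing in a at fixed degree
  ps <- vapply(0:10, function(a) fisher_enrichment_tail(a, 10 - a, 50, 500),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_enrichment_tail(5, 1, 4, 100), "margins")
})

test_that("neighborhood enrichment counts neighbors against the full network", {
  # star: center S with 4 leaves, 3 of them marked, plus unrelated edges
  edges <- data.frame(
    from = c("S", "S", "S", "S", "U1", "U2"),
    to = c("L1", "L2", "L3", "L4", "U2", "U3"))
  net <- load_network(edges)
  res <- neighborhood_enrichment(net, c("L1", "L2", "L3", "S"),
                                 test_genes = "S")
  expect_equal(res$ei_neighbors, 3)
  expect_equal(res$other_neighbors, 1)
  expect_equal(res$proportion, 0.75)
  expect_equal(res$network_size, 8)
  expect_equal(res$background_set_size, 4)
  expect_equal(res$p_value, hyper_tail_oracle(3, 1, 4, 8),
               tolerance = 1e-12)
  # star center with every leaf marked
  all_marked <- neighborhood_enrichment(net, c("L1", "L2", "L3", "L4", "S"),
                                        test_genes = "S")
  expect_equal(all_marked$proportion, 1)
  # saturated background: every gene's neighbors are all marked, p = 1
  sat <- neighborhood_enrichment(net, igraph::V(net)$name)
  expect_true(all(sat$p_value == 1))
  expect_true(all(sat$ei_neighbors == igraph::degree(net)[sat$gene_id]))
  # a + b equals the gene's degree
  expect_equal(res$ei_neighbors + res$other_neighbors,
               unname(igraph::degree(net)["S"]))
  # isolated test gene is flagged with p = 1
  net_iso <- igraph::add_vertices(net, 1, name = "alone")
  iso <- neighborhood_enrichment(net_iso, c("alone", "L1"),
                                 test_genes = "alone")
  expect_true(iso$degree_zero)
  expect_equal(iso$p_value, 1)
  expect_equal(iso$proportion, 0)
})

test_that("enrichment is invariant to edge order and duplicated edges", {
  set.seed(9)
  base <- data.frame(from = sample(LETTERS[1:12], 30, TRUE),
                     to = sample(LETTERS[1:12], 30, TRUE))
  base <- base[base$from != base$to, ]
  bg <- c("A", "B", "C")
  r1 <- neighborhood_enrichment(load_network(base), bg)
  r2 <- neighborhood_enrichment(
    load_network(rbind(base[rev(seq_len(nrow(base))), ], base[1:5, ])), bg)
  expect_equal(r1, r2)
})

test_that("driver selection applies strict FDR and proportion criteria", {
  res <- data.frame(
    gene_id = c("sel", "prop_edge", "fdr_edge", "weak"),
    ei_neighbors = c(4, 2, 8, 1), other_neighbors = c(12, 18, 12, 19),
    background_set_size = 205, network_size = 17381,
    proportion = c(0.250, 0.10, 0.4, 0.05),
    p_value = c(3.06e-5, 1e-4, 2e-4, 0.2),
    q_value = c(0.006, 0.01, 0.05, 0.6),
    degree_zero = FALSE)
  out <- select_drivers(res)
  expect_equal(out$gene_id, "sel")        # q = 0.006 and proportion 0.250
  # proportion exactly 0.10 and q exactly 0.05 are both rejected
  expect_false(any(c("prop_edge", "fdr_edge") %in% out$gene_id))
  # tightening either threshold can only shrink the set
  for (fdr in c(0.04, 0.01)) {
    expect_lte(nrow(select_drivers(res, fdr_threshold = fdr)), nrow(out))
  }
  expect_equal(nrow(select_drivers(res, proportion_threshold = 0.9)), 0)
})

test_that("degree distribution is an exact histogram", {
  tri <- load_network(data.frame(from = c("A", "B", "C"),
                                 to = c("B", "C", "A")))
  dd <- degree_distribution(tri)
  expect_equal(dd, data.frame(degree = 2L, count = 3L))
  expect_equal(sum(dd$count), igraph::vcount(tri))
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(degree_distribution(empty)), 0)
})
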