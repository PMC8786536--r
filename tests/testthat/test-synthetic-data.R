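test_that("simulation configs validate their invariants", {
  expect_error(sim_config(n_pairs = 0), "positive")
  expect_error(sim_config(n_ei = 150, n_es = 100, n_genes = 200),
               "exceed")
  expect_error(sim_config(expr_effect = -1), "non-negative")
  expect_error(sim_config(meth_effect = 0.6), "outside")
  expect_error(sim_config(driver_wiring = 1.5), "driver_wiring")
  expect_error(sim_config(cohort_n = 1), "cohort_n")
  expect_error(sim_config(follow_up_horizon = -2), "horizon")
})

test_that("omics simulation is deterministic and respects value ranges", {
  cfg <- fast_config(seed = 5)
  a <- simulate_omics(cfg)
  b <- simulate_omics(cfg)
  expect_identical(a, b)
  expect_true(all(unclass(a$expr) > 0))
  expect_true(all(is.finite(unclass(a$expr))))
  expect_true(all(unclass(a$beta) >= 0 & unclass(a$beta) <= 1))
  # a different seed changes the draw
  expect_false(identical(unclass(a$expr),
                         unclass(simulate_omics(fast_config(seed = 6))$expr)))
  # every planted gene appears in the matrices, labels disjoint
  expect_true(all(a$truth$gene_id %in% rownames(a$expr)))
  expect_equal(sum(a$truth$class == "EI"), cfg$n_ei)
  expect_equal(sum(a$truth$class == "ES"), cfg$n_es)
  expect_true(all(a$truth$class[a$truth$driver] != "null"))
  # probes lie inside their gene's promoter window
  map <- map_probes_to_promoters(a$probe_annotation, a$gene_models)
  expect_setequal(map$probe_id, a$probe_annotation$probe_id)
  expect_equal(length(attr(map, "unmapped_genes")), 0)
})

test_that("planted effects shift group means by about the configured amounts", {
  cfg <- fast_config(n_pairs = 40, seed = 12)
  sim <- simulate_omics(cfg)
  s <- split(seq_len(ncol(sim$expr)), groups_of(sim$expr))
  lfc <- log2(rowMeans(unclass(sim$expr)[, s$tumor]) /
                rowMeans(unclass(sim$expr)[, s$normal]))
  ei <- sim$truth$class == "EI"; es <- sim$truth$class == "ES"
  null <- sim$truth$class == "null"
  expect_equal(mean(lfc[ei]), cfg$expr_effect, tolerance = 0.25)
  expect_equal(mean(lfc[es]), -cfg$expr_effect, tolerance = 0.25)
  expect_lt(abs(mean(lfc[null])), 0.15)
  meth <- aggregate_promoter_methylation(
    sim$beta, map_probes_to_promoters(sim$probe_annotation,
                                      sim$gene_models))
  db <- rowMeans(unclass(meth)[, s$tumor]) -
    rowMeans(unclass(meth)[, s$normal])
  db <- db[sim$truth$gene_id]
  expect_lt(abs(mean(db[ei]) + cfg$meth_effect), 0.04)
  expect_lt(abs(mean(db[es]) - cfg$meth_effect), 0.04)
  expect_lt(abs(mean(db[null])), 0.05)
})

test_that("zero-effect simulations produce no systematic differential calls", {
  n_false <- 0; n_total <- 0
  for (seed in 1:3) {
    cfg <- fast_config(expr_effect = 0, meth_effect = 0, coupling = 0,
                       n_pairs = 20, seed = seed)
    sim <- simulate_omics(cfg)
    meth <- aggregate_promoter_methylation(
      sim$beta, map_probes_to_promoters(sim$probe_annotation,
                                        sim$gene_models))
    calls <- classify_ei_es(call_differential_expression(sim$expr),
                            call_differential_methylation(meth))
    n_false <- n_false + sum(calls$epigenetic_class != "none")
    n_total <- n_total + nrow(calls)
  }
  # EI/ES requires jointly passing the FDR-controlled expression call and
  # the methylation call; the false rate is far below either level alone
  p0 <- 0.05 * 0.05
  expect_lte(n_false / n_total, p0 + 3 * sqrt(p0 * (1 - p0) / n_total))
})

test_that("EI/ES recall grows with effect size", {
  recall <- vapply(c(0.5, 1.25, 2.5), function(eff) {
    cfg <- fast_config(expr_effect = eff, meth_effect = min(eff / 8, 0.3),
                       n_pairs = 20, seed = 77)
    sim <- simulate_omics(cfg)
    meth <- aggregate_promoter_methylation(
      sim$beta, map_probes_to_promoters(sim$probe_annotation,
                                        sim$gene_models))
    calls <- classify_ei_es(call_differential_expression(sim$expr),
                            call_differential_methylation(meth))
    truth <- sim$truth
    planted <- truth$class != "null"
    mean(calls$epigenetic_class[match(truth$gene_id[planted],
                                      calls$gene_id)] ==
           truth$class[planted])
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], recall[1])
})

test_that("network simulation is simple, heavy-tailed and plants driver wiring", {
  cfg <- fast_config(seed = 19)
  sim <- simulate_omics(cfg)
  net <- simulate_network(cfg, sim$truth)
  expect_identical(edge_fingerprint(net),
                   edge_fingerprint(simulate_network(cfg, sim$truth)))
  expect_false(any(igraph::which_loop(net)))
  expect_false(any(igraph::which_multiple(net)))
  expect_equal(sum(igraph::degree(net)), 2 * igraph::ecount(net))
  dd <- degree_distribution(net)
  expect_gte(max(dd$degree), mean(igraph::degree(net)))
  # planted drivers' neighborhoods hold about driver_wiring marked genes
  marked <- sim$truth$gene_id[sim$truth$class != "null"]
  drivers <- sim$truth$gene_id[sim$truth$driver]
  prop <- vapply(drivers, function(d) {
    nb <- igraph::neighbors(net, d)$name
    mean(nb %in% marked)
  }, numeric(1))
  expect_true(all(prop > 0.3))
  # with null wiring the driver neighborhoods match the global fraction
  cfg0 <- fast_config(driver_wiring = 0, seed = 19)
  net0 <- simulate_network(cfg0, sim$truth)
  prop0 <- vapply(drivers, function(d)
    mean(igraph::neighbors(net0, d)$name %in% marked), numeric(1))
  expect_lt(mean(prop0), 0.25)
})

test_that("cohort simulation encodes the marker in scores, stage and hazard", {
  cfg <- fast_config(cohort_n = 300, seed = 31)
  cohort <- simulate_cohort(cfg)
  expect_identical(cohort, simulate_cohort(cfg))
  expect_true(all(cohort$staining_score %in% 1:4))
  expect_true(all(cohort$follow_up >= 0))
  expect_true(all(cohort$event %in% 0:1))
  # IHC dichotomization recovers the latent state
  expect_equal(as.character(cohort$marker_level), cohort$marker_state)
  # stage is associated with the marker
  tab <- table(cohort$tnm_stage, cohort$marker_level)
  expect_gt(tab["III-IV", "high"] / sum(tab[, "high"]),
            tab["III-IV", "low"] / sum(tab[, "low"]))
  # marker-high patients die faster
  lr <- logrank_test(cohort$follow_up, cohort$event, cohort$marker_level)
  expect_lt(lr$p_value, 0.01)
  # a one-group cohort leaves association and comparison ops degenerate
  one <- cohort
  one$marker_level <- factor("low", levels = c("low", "high"))
  expect_error(logrank_test(one$follow_up, one$event, one$marker_level),
               "two")
})

test_that("written simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- fast_config(seed = 2)
  files <- write_simulation(cfg, dir)
  expect_true(all(file.exists(files)))
  samples <- read.delim(file.path(dir, "samples.tsv"))
  expr <- read_omics_matrix(file.path(dir, "expression.tsv"), samples)
  sim <- simulate_omics(cfg)
  expect_equal(unclass(expr), unclass(sim$expr), tolerance = 1e-12)
  expect_equal(groups_of(expr), groups_of(sim$expr))
  net <- load_network(file.path(dir, "network.tsv"))
  ref <- simulate_network(cfg, sim$truth)
  expect_equal(igraph::vcount(net), sum(igraph::degree(ref) > 0))
  expect_equal(igraph::ecount(net), igraph::ecount(ref))
})
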