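test_that("generators are pure functions of their seed", {
  cfg <- sim_expression_config(n_genes = 50, planted_genes = "g1",
                               effect_size = 2, rng_seed = 11)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))

  ncfg <- sim_network_config(n_nodes = 40, planted_module_size = 6,
                             rng_seed = 5)
  g1 <- simulate_interactome(ncfg)
  g2 <- simulate_interactome(ncfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  td <- stats::setNames(c(2, -3, 1.5), c("a", "b", "c"))
  v1 <- simulate_validation_stats(c("a", "b", "c"), td, 0.5, rng_seed = 9)
  expect_identical(v1, simulate_validation_stats(c("a", "b", "c"), td, 0.5,
                                                 rng_seed = 9))
})

test_that("null expression is calibrated at the ordinary t-test level", {
  em <- simulate_expression(sim_expression_config(n_genes = 1000,
                                                  effect_size = 0,
                                                  rng_seed = 21))
  p <- row_t_oracle(em$values, em$groups)$p
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("planted effects of 5 sigma dominate the |t| ranking", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_expression_config(n_genes = 1000, n_case = 10,
                                 n_control = 10,
                                 planted_genes = paste0("g", 1:20),
                                 effect_size = 5, noise_sd = 1,
                                 rng_seed = 1000 + s)
    em <- simulate_expression(cfg)
    t <- row_t_oracle(em$values, em$groups)$t
    top30 <- names(sort(abs(t), decreasing = TRUE))[1:30]
    sum(paste0("g", 1:20) %in% top30)
  }, 0)
  expect_gte(mean(hits >= 18), 0.95)
})

test_that("planted interactome modules meet their density contract", {
  g <- simulate_interactome(sim_network_config(n_nodes = 30,
                                               planted_module_size = 6,
                                               planted_internal_density = 1,
                                               rng_seed = 3))
  planted <- igraph::graph_attr(g, "planted")
  sub <- igraph::induced_subgraph(g, planted)
  expect_equal(igraph::ecount(sub), 15)  # density 1 forces a clique

  g50 <- simulate_interactome(sim_network_config(n_nodes = 50,
                                                 planted_module_size = 0,
                                                 rng_seed = 1))
  expect_equal(igraph::vcount(g50), 50)
  expect_true(igraph::is_simple(g50))

  gd <- simulate_interactome(sim_network_config(
    n_nodes = 100, topology = "gnp", density = 0.05,
    planted_module_size = 10, planted_internal_density = 0.9,
    rng_seed = 7))
  expect_true(igraph::is_simple(gd))
  pl <- igraph::graph_attr(gd, "planted")
  internal_deg <- igraph::degree(igraph::induced_subgraph(gd, pl))
  bg <- setdiff(igraph::V(gd)$name, pl)
  expect_gt(mean(internal_deg), mean(igraph::degree(gd, bg)))
  dens <- igraph::ecount(igraph::induced_subgraph(gd, pl)) / choose(10, 2)
  expect_gte(dens, 0.9)
})

test_that("validation statistics honour the concordant fraction", {
  td <- stats::setNames(c(3, -2, 4, -1, 2, -5), paste0("g", 1:6))
  v <- simulate_validation_stats(names(td), td, concordant_frac = 1,
                                 rng_seed = 2)
  expect_true(all(sign(v$t) == sign(td[v$gene_id])))
  expect_true(all(v$p < 0.05))

  v0 <- simulate_validation_stats(names(td), td, concordant_frac = 0,
                                  rng_seed = 2)
  expect_equal(nrow(v0), 6)
})

test_that("concordance strength drives the Fisher p down", {
  set.seed(77)
  td <- stats::setNames(c(rnorm(15, 3), rnorm(15, -3)), paste0("g", 1:30))
  med_p <- vapply(c(0.2, 0.5, 0.8, 1.0), function(frac) {
    ps <- vapply(1:50, function(s) {
      v <- simulate_validation_stats(names(td), td, frac, rng_seed = s)
      directional_concordance(names(td), data.frame(gene_id = names(td),
                                                    t = td), v)$fisher_p
    }, 0)
    stats::median(ps)
  }, 0)
  expect_true(all(diff(med_p) <= 1e-12))
})

test_that("simulation configs reject invalid designs", {
  expect_error(sim_expression_config(n_case = 1), "2 samples")
  expect_error(sim_expression_config(noise_sd = 0), "noise_sd")
  expect_error(sim_expression_config(n_genes = 10, planted_genes = "g99"),
               "universe")
  expect_error(sim_network_config(n_nodes = 5, planted_module_size = 6),
               "exceeds")
  expect_error(simulate_validation_stats(character(), c(a = 1), 0.5),
               "empty")
})

test_that("raw probe generator feeds the preprocessing chain", {
  pm <- simulate_raw_probes(n_genes = 20, n_samples = 12, rng_seed = 4)
  expect_s3_class(pm, "probe_matrix")
  expect_identical(dim(pm$values), dim(pm$detection_p))
  expect_true(any(pm$values < 0))           # background-corrected negatives
  expect_true(anyNA(pm$probe2gene))          # some unannotated probes
  gm <- preprocess_chain(pm)
  expect_true(all(is.finite(gm)))
  expect_lte(nrow(gm), 20)
})
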