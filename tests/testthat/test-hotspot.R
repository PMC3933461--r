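test_that("seed selection ranks by absolute statistic with lexical ties", {
  t <- c(A = 3, B = -5, C = 1)
  expect_identical(select_seeds(t, names(t), 2), c("B", "A"))
  expect_identical(select_seeds(t, names(t), 10),
                   c("B", "A", "C"))  # truncation keeps the full sort
  expect_warning(select_seeds(t, names(t), 10), "truncating")

  set.seed(30)
  t2 <- stats::setNames(stats::rnorm(20), paste0("g", 1:20))
  got <- select_seeds(t2, names(t2), 20)
  brute <- names(t2)[order(-abs(t2), names(t2))]
  expect_identical(got, brute)

  # ties break lexicographically by gene id
  t3 <- c(zz = 2, aa = -2, mm = 2)
  expect_identical(select_seeds(t3, names(t3), 3), c("aa", "mm", "zz"))
  expect_error(select_seeds(t3, "absent", 1), "no network node")
})

test_that("module modularity is the total internal edge weight", {
  tri <- make_wnet(cbind(c("a", "b", "c"), c("b", "c", "a")),
                   c(0.5, 0.25, 0.25))
  m <- module_modularity(tri, c("a", "b", "c"))
  expect_equal(as.numeric(m), 1.0)
  expect_equal(attr(m, "avg_weight_density"), 1 / 3)
  expect_equal(as.numeric(module_modularity(tri, c("a", "b"))), 0.5)
  expect_equal(as.numeric(module_modularity(tri, "a")), 0)  # empty sum

  # additivity: one more internal edge of weight 0.2 adds exactly 0.2
  sq <- make_wnet(cbind(c("a", "b", "c"), c("b", "c", "d")),
                  c(0.3, 0.4, 0.2))
  sq2 <- make_wnet(cbind(c("a", "b", "c", "a"), c("b", "c", "d", "c")),
                   c(0.3, 0.4, 0.2, 0.2))
  expect_equal(as.numeric(module_modularity(sq2, c("a", "b", "c"))),
               as.numeric(module_modularity(sq, c("a", "b", "c"))) + 0.2)
})

test_that("the annealer reproduces the exhaustive Hamiltonian optimum", {
  # heavy clique vs light clique joined by a bridge: the seed's clique wins
  w <- two_clique_wnet(0.9, 0.1, 0.1)
  cfg <- hotspot_config(gamma = 0.5, min_module_size = 2, rng_seed = 1)
  mod <- spinglass_module(w, "n1", cfg)
  expect_identical(sort(mod$members), paste0("n", 1:6))
  oracle <- exhaustive_best_module(w, "n1", 0.5)
  expect_identical(sort(mod$members), oracle$members)
  expect_equal(mod$hamiltonian, oracle$H, tolerance = 1e-10)

  # gamma -> 0: the module grows to the seed's whole connected component
  cfg0 <- hotspot_config(gamma = 1e-6, min_module_size = 2, rng_seed = 2)
  mod0 <- spinglass_module(w, "n1", cfg0)
  expect_identical(sort(mod0$members), sort(paste0("n", 1:12)))
  expect_identical(sort(mod0$members),
                   exhaustive_best_module(w, "n1", 1e-6)$members)

  # random <=12-node graphs, three resolutions: consensus equals oracle
  for (s in 1:6) {
    wr <- random_wnet(sample(6:12, 1), 0.35, seed = 400 + s)
    seedv <- igraph::V(wr)$name[which.max(igraph::degree(wr))]
    for (gam in c(0.25, 0.5, 1.0)) {
      cfg_r <- hotspot_config(gamma = gam, min_module_size = 1,
                              rng_seed = s * 10 + round(gam * 4))
      got <- spinglass_module(wr, seedv, cfg_r)
      expect_identical(sort(got$members),
                       exhaustive_best_module(wr, seedv, gam)$members)
    }
  }
})

test_that("single annealing restarts almost always find the optimum", {
  wr <- random_wnet(10, 0.4, seed = 99)
  seedv <- igraph::V(wr)$name[which.max(igraph::degree(wr))]
  oracle <- exhaustive_best_module(wr, seedv, 0.5)
  hit <- vapply(1:40, function(r) {
    m <- spinglass_module(wr, seedv, hotspot_config(
      gamma = 0.5, min_module_size = 1, n_restarts = 1, rng_seed = r))
    identical(sort(m$members), oracle$members)
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("isolated or undersized seeds yield no module", {
  w <- make_wnet(cbind("a", "b"), 0.8)
  w <- igraph::add_vertices(w, 1, name = "lone")
  class(w) <- c("weighted_interactome", class(w))
  cfg <- hotspot_config(min_module_size = 2, rng_seed = 1)
  expect_null(spinglass_module(w, "lone", cfg))
  expect_error(spinglass_module(w, "ghost", cfg), "not a network node")
  # community smaller than the floor -> none
  cfg10 <- hotspot_config(min_module_size = 10, rng_seed = 1)
  expect_null(spinglass_module(w, "a", cfg10))
})

test_that("permutation p is exact under exchangeable statistics", {
  w <- two_clique_wnet()
  t_eq <- stats::setNames(rep(2, 12), paste0("n", 1:12))
  igraph::V(w)$t <- t_eq[igraph::V(w)$name]
  w <- igraph::set_graph_attr(w, "t_max", 2)
  class(w) <- c("weighted_interactome", class(w))
  p <- permutation_pvalue(w, paste0("n", 1:6), n_perm = 300, rng_seed = 5)
  expect_equal(as.numeric(p), 1)
})

test_that("Monte-Carlo permutation p approaches the exhaustive value", {
  edges <- cbind(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  t <- c(a = 5, b = 4, c = 1, d = 0.5, e = 3)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "e")
  wn <- weight_edges(g, t)
  members <- c("a", "b", "c")

  # exact p over all 120 permutations of the node statistics
  abs_t <- abs(t[igraph::V(wn)$name])
  sub <- igraph::induced_subgraph(wn, members)
  deg_int <- igraph::degree(sub)[members]
  tmax <- igraph::graph_attr(wn, "t_max")
  m_obs <- as.numeric(module_modularity(wn, members))
  perms <- NULL
  idx <- seq_along(abs_t)
  for (p1 in idx) for (p2 in setdiff(idx, p1)) for (p3 in setdiff(idx, c(p1, p2)))
    perms <- rbind(perms, c(p1, p2, p3))
  m_all <- apply(perms, 1, function(pp) sum(deg_int * abs_t[pp]) / (2 * tmax))
  p_exact <- mean(m_all >= m_obs - 1e-12)

  p_mc <- permutation_pvalue(wn, members, n_perm = 5000, rng_seed = 8)
  expect_lt(abs(as.numeric(p_mc) - p_exact), 0.02)
  expect_equal(attr(p_mc, "m_obs"), m_obs, tolerance = 1e-12)
  expect_error(permutation_pvalue(wn, members, n_perm = 0), "n_perm")
})

test_that("permutation p-values are super-uniform for unoptimized modules", {
  set.seed(55)
  net <- simulate_interactome(sim_network_config(n_nodes = 80,
                                                 planted_module_size = 0,
                                                 rng_seed = 3))
  nodes <- igraph::V(net)$name
  ps <- vapply(1:100, function(i) {
    t <- stats::setNames(stats::rnorm(80), nodes)
    wn <- weight_edges(net, t)
    start <- sample(nodes, 1)
    members <- unique(c(start, nodes[unlist(igraph::ego(net, 1, start))]))
    as.numeric(permutation_pvalue(wn, members, n_perm = 199,
                                  rng_seed = i))
  }, 0)
  for (alpha in c(0.05, 0.1))
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 100))
})

test_that("detect_hotspots is deterministic given its seed", {
  net <- simulate_interactome(sim_network_config(
    n_nodes = 80, planted_module_size = 8,
    planted_internal_density = 1, rng_seed = 12))
  planted <- igraph::graph_attr(net, "planted")
  t <- stats::setNames(abs(stats::rnorm(80)) + 0.1,
                       igraph::V(net)$name)
  t[planted] <- 8
  wn <- weight_edges(net, t)
  cfg <- hotspot_config(n_seeds = 5, min_module_size = 5, n_perm = 99,
                        rng_seed = 42)
  r1 <- detect_hotspots(wn, cfg = cfg)
  r2 <- detect_hotspots(wn, cfg = cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(lapply(r1$modules, `[[`, "members"),
                   lapply(r2$modules, `[[`, "members"))
  # the planted clique is recovered as the top module
  expect_gte(length(r1$modules), 1)
  top <- r1$modules[[1]]
  jac <- length(intersect(top$members, planted)) /
    length(union(top$members, planted))
  expect_gte(jac, 0.7)
  expect_lte(top$p_adj, 0.05)
})
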