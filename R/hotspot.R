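#' Configuration for the hotspot (expression-module) search
#'
#' @param n_seeds number of seed genes (top-ranked by absolute statistic).
#' @param gamma spin-glass resolution parameter \eqn{\gamma > 0}; 0.5
#'   balances internal weight against half the configuration-model
#'   expectation and yields modules of useful size on interactome-scale
#'   networks.
#' @param min_module_size communities smaller than this do not count as
#'   modules.
#' @param n_perm permutations for the modularity null.
#' @param alpha significance level on the adjusted permutation p.
#' @param start_temp,stop_temp,cool_fact simulated-annealing schedule
#'   (geometric cooling, `stop_temp < start_temp`, `0 < cool_fact < 1`).
#' @param sweeps membership-flip proposals per temperature step, as a
#'   multiple of the candidate-node count.
#' @param hops basin-hopping cycles after each anneal: the local minimum
#'   is kicked (random membership flips) and greedily re-descended,
#'   keeping the best configuration; crosses barriers that single flips
#'   cannot.
#' @param hop_frac fraction of candidate nodes flipped by a kick.
#' @param n_restarts annealing restarts per seed; the lowest-Hamiltonian
#'   community wins.
#' @param adjust `"bonferroni"` (conservative, default) or `"none"`:
#'   adjustment of the permutation p across tested modules.
#' @param dedup_jaccard among significant modules, drop the sparser
#'   (lower average-weight-density) module of any pair with Jaccard
#'   overlap above this threshold (`NULL` disables de-duplication);
#'   applied after permutation testing, so the multiplicity adjustment
#'   spans every module examined.
#' @param seed_rank `"abs_t"` (default) ranks seeds by absolute statistic;
#'   `"avg_weight"` by the mean weight of their incident edges.
#' @param rng_seed integer seed driving both the annealing and the
#'   permutation streams.
#' @return a validated list of class `hotspot_config`.
#' @export
hotspot_config <- function(n_seeds = 100, gamma = 0.5, min_module_size = 10,
                           n_perm = 1000, alpha = 0.05, start_temp = 1,
                           stop_temp = 0.01, cool_fact = 0.99, sweeps = 5,
                           hops = 20, hop_frac = 0.25, n_restarts = 3,
                           adjust = c("bonferroni", "none"),
                           dedup_jaccard = 0.5,
                           seed_rank = c("abs_t", "avg_weight"),
                           rng_seed = 1) {
  if (gamma <= 0) stopf("gamma must be > 0")
  if (cool_fact <= 0 || cool_fact >= 1) stopf("cool_fact must lie in (0,1)")
  if (stop_temp >= start_temp) stopf("stop_temp must be < start_temp")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (n_seeds < 1) stopf("n_seeds must be >= 1")
  structure(list(n_seeds = as.integer(n_seeds), gamma = gamma,
                 min_module_size = as.integer(min_module_size),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 start_temp = start_temp, stop_temp = stop_temp,
                 cool_fact = cool_fact, sweeps = as.integer(sweeps),
                 hops = as.integer(hops), hop_frac = hop_frac,
                 n_restarts = as.integer(n_restarts),
                 adjust = match.arg(adjust),
                 dedup_jaccard = dedup_jaccard,
                 seed_rank = match.arg(seed_rank),
                 rng_seed = as.integer(rng_seed)),
            class = "hotspot_config")
}

#' Select seed genes by absolute statistic
#'
#' The `k` network nodes with the largest absolute t-statistics, ordered
#' decreasing; ties are broken lexicographically by gene id.
#'
#' @param stats named t-statistic vector or a `gene_id`/`t` data.frame.
#' @param network_nodes character vector of network node ids.
#' @param k number of seeds (>= 1); values beyond the node count truncate
#'   with a warning.
#' @return character vector of seed gene ids.
#' @export
select_seeds <- function(stats, network_nodes, k = 100) {
  if (k < 1) stopf("k must be >= 1")
  tvec <- as_stat_vector(stats)
  tvec <- tvec[names(tvec) %in% network_nodes]
  if (!length(tvec)) stopf("no network node carries a statistic")
  if (k > length(tvec)) {
    warnf("k = %d exceeds the %d scored network nodes; truncating", k,
          length(tvec))
    k <- length(tvec)
  }
  ord <- order(-abs(tvec), names(tvec))
  names(tvec)[ord[seq_len(k)]]
}

# Seeds ranked by average incident edge weight (alternative mode).
seeds_by_avg_weight <- function(wnet, k) {
  nodes <- igraph::V(wnet)$name
  avg <- igraph::strength(wnet, weights = igraph::E(wnet)$weight) /
    pmax(igraph::degree(wnet), 1)
  ord <- order(-avg, nodes)
  k <- min(k, length(nodes))
  nodes[ord[seq_len(k)]]
}

#' Modularity of a node set: total internal edge weight
#'
#' The modularity M of a community is the sum of the weights of all edges
#' with both endpoints inside it. The average weight per internal edge
#' ("average weight density") and the internal edge count are attached as
#' attributes.
#'
#' @param wnet a `weighted_interactome`.
#' @param members character vector of member gene ids (subset of nodes).
#' @return numeric M with attributes `n_edges` and `avg_weight_density`.
#' @export
module_modularity <- function(wnet, members) {
  stopifnot(all(members %in% igraph::V(wnet)$name))
  sub <- igraph::induced_subgraph(wnet, members)
  w <- igraph::E(sub)$weight
  m <- sum(w)
  structure(m, n_edges = length(w),
            avg_weight_density = if (length(w)) m / length(w) else NA_real_)
}

# Compressed adjacency of a weighted interactome for the C++ annealer.
wnet_csr <- function(wnet) {
  n <- igraph::vcount(wnet)
  ends <- igraph::ends(wnet, igraph::E(wnet), names = FALSE)
  w <- igraph::E(wnet)$weight
  from <- c(ends[, 1], ends[, 2])
  to <- c(ends[, 2], ends[, 1])
  ww <- c(w, w)
  o <- order(from)
  deg <- tabulate(from, nbins = n)
  list(ptr = c(0L, cumsum(deg)), idx = as.integer(to[o] - 1L),
       w = ww[o],
       strength = as.numeric(igraph::strength(wnet,
                                              weights = igraph::E(wnet)$weight)),
       twoW = 2 * sum(w))
}

#' Seeded spin-glass search for the module around one seed
#'
#' Finds the community containing `seed` by minimizing the weighted
#' spin-glass (Potts model) Hamiltonian
#' \deqn{H = -\sum_{i<j} (w_{ij} - \gamma\, s_i s_j / 2W)\,
#'   \delta(\sigma_i, \sigma_j)}
#' over two-state spin assignments (in / out of the seed's community) of
#' the seed's connected component, with the seed pinned "in". Here
#' \eqn{w_{ij}} is the edge weight (0 for non-edges), \eqn{s_i} the
#' strength (weighted degree) and \eqn{2W} the total strength, so
#' \eqn{\gamma\, s_i s_j/2W} is the configuration-model expected weight of
#' the pair; both in-group and out-group pairs contribute. Optimization is
#' simulated annealing with geometric cooling followed by basin hopping
#' (greedy descent, then kick/re-descend cycles keeping the best
#' configuration), best of `cfg$n_restarts` restarts.
#'
#' @param wnet a `weighted_interactome`.
#' @param seed a network gene id.
#' @param cfg a [hotspot_config()]; `cfg$rng_seed = NULL` leaves the RNG
#'   state untouched.
#' @return a `hotspot_module` (list: `seed`, `members`, `modularity`,
#'   `avg_weight_density`, `size`, `hamiltonian`, `p_perm` / `p_adj`
#'   placeholders), or `NULL` when the seed is isolated or its community
#'   is smaller than `cfg$min_module_size`.
#' @export
spinglass_module <- function(wnet, seed, cfg = hotspot_config()) {
  nodes <- igraph::V(wnet)$name
  if (!seed %in% nodes) stopf("seed '%s' is not a network node", seed)
  seed_idx <- match(seed, nodes)
  inc <- igraph::incident(wnet, seed_idx)
  if (length(inc) == 0 || all(igraph::E(wnet)$weight[as.integer(inc)] <= 0))
    return(NULL)  # isolated node of association
  comp <- igraph::components(wnet)
  cand <- which(comp$membership == comp$membership[seed_idx])
  if (length(cand) < cfg$min_module_size) return(NULL)
  csr <- wnet_csr(wnet)
  seed_if(cfg$rng_seed)
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    res <- .spinglass_anneal_cpp(csr$ptr, csr$idx, csr$w, csr$strength,
                                 csr$twoW, seed_idx - 1L,
                                 as.integer(cand - 1L), cfg$gamma,
                                 cfg$start_temp, cfg$stop_temp,
                                 cfg$cool_fact, cfg$sweeps, cfg$hops,
                                 cfg$hop_frac)
    if (is.null(best) || res$H < best$H - 1e-12) best <- res
  }
  members <- nodes[best$members + 1L]
  if (length(members) < cfg$min_module_size) return(NULL)
  new_hotspot_module(wnet, seed, members, best$H)
}

new_hotspot_module <- function(wnet, seed, members, hamiltonian = NA_real_) {
  m <- module_modularity(wnet, members)
  structure(list(seed = seed, members = members,
                 modularity = as.numeric(m),
                 avg_weight_density = attr(m, "avg_weight_density"),
                 n_edges = attr(m, "n_edges"),
                 size = length(members), hamiltonian = hamiltonian,
                 p_perm = NA_real_, p_adj = NA_real_),
            class = "hotspot_module")
}

#' @export
print.hotspot_module <- function(x, ...) {
  cat(sprintf("hotspot_module '%s': %d genes, M = %.4f, p_perm = %s\n",
              x$seed, x$size, x$modularity,
              ifelse(is.na(x$p_perm), "(untested)",
                     format(x$p_perm, digits = 3))))
  invisible(x)
}

#' Permutation p-value for a module's modularity
#'
#' Node statistics (absolute t) are shuffled over all network nodes with
#' the topology fixed, edge weights are recomputed with the same formula
#' and the same \eqn{t_{max}}, and the modularity of the fixed member set
#' is recomputed. The empirical p-value uses the add-one correction
#' \eqn{p = (1 + \#\{M_{perm} \ge M_{obs}\}) / (1 + n_{perm})}, so ties
#' count against the module and p is never 0.
#'
#' @param wnet a `weighted_interactome`.
#' @param module a `hotspot_module` or a character vector of members.
#' @param n_perm number of permutations (>= 1).
#' @param rng_seed integer seed (`NULL`: current RNG state).
#' @return numeric p in (0, 1\]; attributes `m_obs` and `n_perm`.
#' @export
permutation_pvalue <- function(wnet, module, n_perm = 1000,
                               rng_seed = NULL) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  members <- if (inherits(module, "hotspot_module")) module$members
             else as.character(module)
  nodes <- igraph::V(wnet)$name
  stopifnot(all(members %in% nodes))
  abs_t <- abs(node_stats(wnet))
  t_max <- igraph::graph_attr(wnet, "t_max")
  sub <- igraph::induced_subgraph(wnet, members)
  deg_int <- igraph::degree(sub)[members]  # internal degree per member
  nm <- length(members)
  # observed modularity via the same inner product as the permutations,
  # so exchangeable statistics give exact ties
  m_obs <- sum(deg_int * abs_t[members]) / (2 * t_max)
  seed_if(rng_seed)
  m_perm <- vapply(seq_len(n_perm), function(i)
    sum(deg_int * abs_t[sample.int(length(abs_t), nm)]), 0) / (2 * t_max)
  p <- (1 + sum(m_perm >= m_obs - 1e-12)) / (1 + n_perm)
  structure(p, m_obs = m_obs, n_perm = n_perm)
}

module_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Detect expression-module hotspots in a weighted interactome
#'
#' The full seeded search: rank seeds by absolute statistic, grow a
#' spin-glass community around each, drop communities below the size
#' floor, de-duplicate heavily overlapping ones, assess each surviving
#' module by permutation, adjust across tested modules, and return the
#' significant modules ranked by average weight density (the size-free
#' reading of modularity; the permutation test uses the total internal
#' weight).
#'
#' @param wnet a `weighted_interactome`.
#' @param stats optional statistic vector/data.frame for seed selection;
#'   defaults to the node statistics stored in `wnet`.
#' @param cfg a [hotspot_config()].
#' @return an object of class `expmod_set`: list with `modules` (the
#'   significant [spinglass_module()] results, ranked by modularity),
#'   `table` (data.frame over all tested modules: seed, size, modularity,
#'   avg_weight_density, p_perm, p_adj, significant), `jaccard` (pairwise
#'   overlap matrix of the significant modules), `n_seeds_tried`,
#'   `n_modules_grown`, and `config`.
#' @examples
#' net <- simulate_interactome(sim_network_config(n_nodes = 60,
#'   planted_module_size = 8, planted_internal_density = 1))
#' t <- setNames(rnorm(60), paste0("g", 1:60))
#' t[igraph::graph_attr(net, "planted")] <- 8
#' wnet <- weight_edges(net, t)
#' res <- detect_hotspots(wnet, cfg = hotspot_config(n_seeds = 5,
#'   min_module_size = 5, n_perm = 99, rng_seed = 1))
#' res$table
#' @export
detect_hotspots <- function(wnet, stats = NULL, cfg = hotspot_config()) {
  stopifnot(inherits(cfg, "hotspot_config"))
  if (!length(cfg$rng_seed))  # un-seeded config: draw a logged seed once
    cfg$rng_seed <- sample.int(2147483646L, 1)
  tvec <- if (is.null(stats)) node_stats(wnet) else as_stat_vector(stats)
  seeds <- if (cfg$seed_rank == "avg_weight")
    seeds_by_avg_weight(wnet, cfg$n_seeds)
  else select_seeds(tvec, igraph::V(wnet)$name, cfg$n_seeds)

  grown <- list()
  for (i in seq_along(seeds)) {
    sub_cfg <- cfg
    sub_cfg$rng_seed <- derive_seed(cfg$rng_seed, 1L, i)
    mod <- spinglass_module(wnet, seeds[i], sub_cfg)
    if (!is.null(mod)) grown[[length(grown) + 1L]] <- mod
  }
  n_grown <- length(grown)

  # drop exact duplicates (the same community grown from several seeds);
  # every remaining module is permutation-tested and enters the
  # multiplicity adjustment
  if (n_grown > 1) {
    keys <- vapply(grown, function(m) paste(sort(m$members), collapse = "|"),
                   "")
    grown <- grown[!duplicated(keys)]
  }

  n_tested <- length(grown)
  for (j in seq_along(grown)) {
    p <- permutation_pvalue(wnet, grown[[j]], n_perm = cfg$n_perm,
                            rng_seed = derive_seed(cfg$rng_seed, 2L, j))
    grown[[j]]$p_perm <- as.numeric(p)
    grown[[j]]$p_adj <- if (cfg$adjust == "bonferroni")
      min(1, as.numeric(p) * n_tested) else as.numeric(p)
  }

  tab <- if (n_tested) data.frame(
    seed = vapply(grown, `[[`, "", "seed"),
    size = vapply(grown, `[[`, 0L, "size"),
    modularity = vapply(grown, `[[`, 0, "modularity"),
    avg_weight_density = vapply(grown, `[[`, 0, "avg_weight_density"),
    p_perm = vapply(grown, `[[`, 0, "p_perm"),
    p_adj = vapply(grown, `[[`, 0, "p_adj"),
    stringsAsFactors = FALSE)
  else data.frame(seed = character(), size = integer(),
                  modularity = numeric(), avg_weight_density = numeric(),
                  p_perm = numeric(), p_adj = numeric())
  tab$significant <- tab$p_adj <= cfg$alpha

  sig <- grown[tab$significant]
  if (length(sig)) {
    ord <- order(-vapply(sig, `[[`, 0, "avg_weight_density"))
    sig <- sig[ord]
    # report largely non-overlapping modules: greedy de-duplication by
    # Jaccard overlap, keeping the denser module of each redundant pair
    if (!is.null(cfg$dedup_jaccard) && length(sig) > 1) {
      kept <- list()
      for (m in sig) {
        over <- vapply(kept, function(k)
          module_jaccard(k$members, m$members), 0)
        if (!length(over) || max(over) <= cfg$dedup_jaccard)
          kept[[length(kept) + 1L]] <- m
      }
      sig <- kept
    }
  } else {
    message(sprintf(
      "detect_hotspots: no significant module (%d seeds tried, %d modules grown, %d tested)",
      length(seeds), n_grown, n_tested))
  }
  tab <- tab[order(-tab$avg_weight_density), , drop = FALSE]
  rownames(tab) <- NULL

  jac <- matrix(numeric(0), 0, 0)
  if (length(sig)) {
    jac <- outer(seq_along(sig), seq_along(sig), Vectorize(function(i, j)
      module_jaccard(sig[[i]]$members, sig[[j]]$members)))
    dimnames(jac) <- list(vapply(sig, `[[`, "", "seed"),
                          vapply(sig, `[[`, "", "seed"))
  }

  structure(list(modules = sig, table = tab, jaccard = jac,
                 n_seeds_tried = length(seeds), n_modules_grown = n_grown,
                 config = cfg),
            class = "expmod_set")
}

#' @export
print.expmod_set <- function(x, ...) {
  cat(sprintf(
    "expmod_set: %d significant module(s) (of %d tested, %d grown from %d seeds)\n",
    length(x$modules), nrow(x$table), x$n_modules_grown, x$n_seeds_tried))
  if (nrow(x$table)) print(head(x$table, 10))
  invisible(x)
}

#' Write the per-run hotspot outputs
#'
#' Module table, one weighted edge list per significant module, and a
#' key-value run manifest.
#'
#' @param res an `expmod_set`.
#' @param wnet the `weighted_interactome` it was computed on.
#' @param dir output directory (created if needed).
#' @export
write_hotspot_outputs <- function(res, wnet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- res$table
  tab$members <- vapply(seq_len(nrow(tab)), function(i) {
    mod <- Filter(function(m) m$seed == tab$seed[i], res$modules)
    if (length(mod)) paste(sort(mod[[1]]$members), collapse = ",") else ""
  }, "")
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, 6)
  write.table(tab, file.path(dir, "modules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (m in res$modules) {
    sub <- igraph::induced_subgraph(wnet, m$members)
    class(sub) <- class(wnet)
    write_weighted_edgelist(sub, file.path(dir, paste0("module_", m$seed,
                                                       ".tsv")))
  }
  cfg <- res$config
  manifest <- c(sprintf("package_version=%s",
                        as.character(utils::packageVersion("expmods"))),
                vapply(names(cfg), function(k)
                  sprintf("%s=%s", k, paste(format(cfg[[k]]), collapse = ",")),
                  ""),
                sprintf("n_seeds_tried=%d", res$n_seeds_tried),
                sprintf("n_modules_grown=%d", res$n_modules_grown),
                sprintf("n_modules_tested=%d", nrow(res$table)),
                sprintf("n_significant=%d", length(res$modules)))
  writeLines(manifest, file.path(dir, "run_manifest.txt"))
  invisible(dir)
}
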