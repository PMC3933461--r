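# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force enumeration, textbook formulas, and
# direct counting only.

# Exhaustive minimizer of the two-state spin-glass Hamiltonian
#   H = -sum_{i<j} (w_ij - gamma s_i s_j/2W) delta(spin_i, spin_j)
# over all in/out assignments of the seed's connected component with the
# seed pinned "in"; both the in-group and the out-group pairs count.
# Only feasible for ~12-node graphs.
exhaustive_best_module <- function(wnet, seed, gamma) {
  nodes <- igraph::V(wnet)$name
  ends <- igraph::ends(wnet, igraph::E(wnet))
  w <- igraph::E(wnet)$weight
  s <- stats::setNames(igraph::strength(wnet, weights = w), nodes)
  twoW <- 2 * sum(w)
  comp <- igraph::components(wnet)
  cand <- nodes[comp$membership == comp$membership[match(seed, nodes)]]
  others <- setdiff(cand, seed)
  stopifnot(length(others) <= 15)
  group_score <- function(mem) {
    if (length(mem) < 2) return(0)
    inC <- ends[, 1] %in% mem & ends[, 2] %in% mem
    ss <- s[mem]
    sum(w[inC]) - gamma * ((sum(ss)^2 - sum(ss^2)) / 2) / twoW
  }
  best <- NULL
  bestH <- Inf
  for (k in 0:(2^length(others) - 1)) {
    mem <- c(seed, others[as.logical(bitwAnd(k, 2^(seq_along(others) - 1)))])
    H <- -group_score(mem) - group_score(setdiff(cand, mem))
    if (H < bestH - 1e-12) {
      bestH <- H
      best <- sort(mem)
    }
  }
  list(members = best, H = bestH)
}

# Textbook pooled two-sample t-statistic (equal-variance).
pooled_t_oracle <- function(x_case, x_control) {
  n1 <- length(x_case)
  n0 <- length(x_control)
  sp2 <- (sum((x_case - mean(x_case))^2) +
            sum((x_control - mean(x_control))^2)) / (n1 + n0 - 2)
  (mean(x_case) - mean(x_control)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# Row-wise ordinary two-sample t-test p-values (oracle for calibration and
# power checks on simulated matrices).
row_t_oracle <- function(values, groups) {
  xc <- values[, groups == "case", drop = FALSE]
  x0 <- values[, groups == "control", drop = FALSE]
  n1 <- ncol(xc)
  n0 <- ncol(x0)
  sp2 <- (rowSums((xc - rowMeans(xc))^2) +
            rowSums((x0 - rowMeans(x0))^2)) / (n1 + n0 - 2)
  t <- (rowMeans(xc) - rowMeans(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n1 + n0 - 2))
}

# Benjamini-Hochberg step-up by direct definition:
# q_i = min over j with p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / rank(p, ties.method = "first")[p >= p[i]]))
  }, 0)
}

# Two-sided Fisher exact p by enumerating every table with the observed
# margins and summing hypergeometric point probabilities <= observed.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  if (n == 0) return(1)
  amin <- max(0, c1 - (n - r1))
  amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Build a weighted interactome directly from an edge table with explicit
# weights (and optional node statistics), bypassing weight_edges().
make_wnet <- function(edges, weights, t = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  igraph::E(g)$weight <- weights
  if (!is.null(t)) {
    igraph::V(g)$t <- t[igraph::V(g)$name]
    g <- igraph::set_graph_attr(g, "t_max", max(abs(t)))
  }
  class(g) <- c("weighted_interactome", class(g))
  g
}

# Two 6-cliques joined by one bridge; heavy weights inside the first.
two_clique_wnet <- function(w_in = 0.9, w_out = 0.1, w_bridge = 0.1) {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- paste0("n", 1:12)
  ends <- igraph::ends(g, igraph::E(g))
  id <- function(x) as.integer(sub("n", "", x))
  w <- ifelse(id(ends[, 1]) <= 6 & id(ends[, 2]) <= 6, w_in,
              ifelse(id(ends[, 1]) > 6 & id(ends[, 2]) > 6, w_out,
                     w_bridge))
  igraph::E(g)$weight <- w
  class(g) <- c("weighted_interactome", class(g))
  g
}

# Deterministic random weighted graph for oracle sweeps.
random_wnet <- function(n, p_edge, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) >= 3) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.05, 1)
  class(g) <- c("weighted_interactome", class(g))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
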