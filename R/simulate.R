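#' Configuration for a synthetic two-group expression matrix
#'
#' Defines a case/control microarray-style experiment simulated directly on
#' the log2 scale: every gene draws i.i.d. normal intensities around a
#' common baseline, and a chosen set of "planted" genes receives an additive
#' mean shift in the case group. Defaults mirror a small clinical design of
#' 7 cases versus 5 controls.
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per group (each must be >= 2).
#' @param planted_genes character vector of gene ids (subset of the
#'   simulated universe `g1..gN`) carrying the differential-expression
#'   effect.
#' @param effect_size mean case-minus-control shift, log2 units.
#' @param noise_sd per-gene standard deviation, log2 units (> 0).
#' @param baseline_mean baseline log2 intensity.
#' @param heteroscedastic if `TRUE`, per-gene standard deviations are drawn
#'   from a scaled inverse-chi-square law (df 4) around `noise_sd` instead
#'   of being shared.
#' @param rng_seed integer seed; generation is a pure function of it.
#' @return a validated list of class `sim_expression_config`.
#' @export
sim_expression_config <- function(n_genes = 1000, n_case = 7, n_control = 5,
                                  planted_genes = character(),
                                  effect_size = 0, noise_sd = 1,
                                  baseline_mean = 8,
                                  heteroscedastic = FALSE, rng_seed = 1) {
  if (n_case < 2 || n_control < 2)
    stopf("need at least 2 samples per group (got %d cases, %d controls)",
          n_case, n_control)
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  universe <- paste0("g", seq_len(n_genes))
  if (!all(planted_genes %in% universe))
    stopf("planted_genes outside the simulated gene universe g1..g%d",
          n_genes)
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 planted_genes = planted_genes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 heteroscedastic = isTRUE(heteroscedastic),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_expression_config")
}

#' Simulate a gene-level log2 expression matrix with group labels
#'
#' @param cfg a [sim_expression_config()].
#' @return an object of class `expr_matrix`: a list with `values` (genes x
#'   samples numeric matrix, rownames gene ids) and `groups` (factor with
#'   levels `control`, `case`, one per column).
#' @examples
#' em <- simulate_expression(sim_expression_config(n_genes = 50))
#' dim(em$values)
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_expression_config"))
  seed_if(cfg$rng_seed)
  n <- cfg$n_genes
  m <- cfg$n_case + cfg$n_control
  sds <- if (cfg$heteroscedastic) {
    cfg$noise_sd * sqrt(4 / rchisq(n, df = 4))
  } else rep(cfg$noise_sd, n)
  vals <- matrix(rnorm(n * m, mean = cfg$baseline_mean, sd = rep(sds, m)),
                 nrow = n, ncol = m)
  rownames(vals) <- paste0("g", seq_len(n))
  groups <- factor(rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
                   levels = c("control", "case"))
  colnames(vals) <- paste0(ifelse(groups == "case", "case_", "ctrl_"),
                           c(seq_len(cfg$n_case), seq_len(cfg$n_control)))
  if (length(cfg$planted_genes) && cfg$effect_size != 0)
    vals[cfg$planted_genes, groups == "case"] <-
      vals[cfg$planted_genes, groups == "case"] + cfg$effect_size
  expr_matrix(vals, groups)
}

#' Construct an expression matrix with group labels
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param groups factor/character of length `ncol(values)` with exactly the
#'   labels `case` and `control`.
#' @export
expr_matrix <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(as.character(groups), levels = c("control", "case"))
  if (anyNA(groups))
    stopf("groups must be labelled 'case' or 'control'")
  if (length(groups) != ncol(values))
    stopf("one group label per sample column required")
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values), sum(x$groups == "case"),
              sum(x$groups == "control")))
  invisible(x)
}

#' Configuration for a synthetic interactome with a planted dense module
#'
#' The background graph is scale-free-like (preferential attachment) by
#' default, since real protein-interaction networks are heavy-tailed;
#' a uniform-random (Erdos-Renyi) background is available. A subset of
#' nodes is then densified so that its internal edge density is at least
#' `planted_internal_density`.
#'
#' @param n_nodes number of nodes (genes `g1..gN`).
#' @param topology `"pa"` (preferential attachment, default) or `"gnp"`.
#' @param attachment edges added per step for `"pa"`.
#' @param density background edge probability for `"gnp"`.
#' @param planted_module_size size of the planted module (<= n_nodes);
#'   0 disables planting.
#' @param planted_internal_density minimum internal edge density of the
#'   planted module, in \[0, 1\].
#' @param planted_bridges number of bridge edges tying the planted module
#'   to the background. The planted members keep no other background
#'   edges, making the module a weakly-coupled dense subnetwork -- the
#'   regime in which a small hotspot is identifiable as a distinct
#'   community; strongly-embedded modules dissolve into their
#'   neighborhood at moderate resolution.
#' @param rng_seed integer seed.
#' @export
sim_network_config <- function(n_nodes = 300, topology = c("pa", "gnp"),
                               attachment = 2, density = 0.05,
                               planted_module_size = 10,
                               planted_internal_density = 0.8,
                               planted_bridges = 3,
                               rng_seed = 1) {
  topology <- match.arg(topology)
  if (planted_module_size > n_nodes)
    stopf("planted_module_size (%d) exceeds n_nodes (%d)",
          planted_module_size, n_nodes)
  if (planted_internal_density < 0 || planted_internal_density > 1)
    stopf("planted_internal_density must lie in [0,1]")
  structure(list(n_nodes = as.integer(n_nodes), topology = topology,
                 attachment = attachment, density = density,
                 planted_module_size = as.integer(planted_module_size),
                 planted_internal_density = planted_internal_density,
                 planted_bridges = as.integer(planted_bridges),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_network_config")
}

#' Simulate an interactome with a planted dense subnetwork
#'
#' @param cfg a [sim_network_config()].
#' @return a simple undirected [igraph::graph] whose vertex names are gene
#'   ids; the planted members are stored in the graph attribute `planted`.
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_network_config"))
  seed_if(cfg$rng_seed)
  g <- if (cfg$topology == "pa") {
    igraph::sample_pa(cfg$n_nodes, m = cfg$attachment, directed = FALSE)
  } else {
    igraph::sample_gnp(cfg$n_nodes, p = cfg$density)
  }
  igraph::V(g)$name <- paste0("g", seq_len(cfg$n_nodes))
  planted <- character()
  k <- cfg$planted_module_size
  if (k >= 2) {
    planted <- paste0("g", sort(sample.int(cfg$n_nodes, k)))
    # detach the members from the background, then densify internally and
    # re-attach through a fixed number of bridges
    drop <- unique(unlist(igraph::incident_edges(g, planted)))
    if (length(drop)) g <- igraph::delete_edges(g, drop)
    pairs <- t(utils::combn(planted, 2))
    need <- ceiling(cfg$planted_internal_density * nrow(pairs))
    take <- sample.int(nrow(pairs), need)
    g <- igraph::add_edges(g, t(pairs[take, , drop = FALSE]))
    background <- setdiff(igraph::V(g)$name, planted)
    nb <- min(cfg$planted_bridges, length(background))
    if (nb > 0) {
      # anchor the bridges at background hubs, as disease modules attach
      # to the well-connected core of real interactomes
      deg_bg <- igraph::degree(g, background)
      hubs <- background[order(-deg_bg)][seq_len(min(3 * nb,
                                                     length(background)))]
      bridges <- rbind(sample(planted, nb, replace = TRUE),
                       sample(hubs, nb))
      g <- igraph::add_edges(g, bridges)
    }
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "planted", planted)
  g
}

#' Simulate validation-cohort statistics for a module
#'
#' Emulates testing a discovered module in an independent case/control
#' dataset: a fixed fraction of the module genes replicate (same sign as
#' the discovery statistic, magnitude beyond the nominal two-sided
#' significance threshold of a t law with `df` degrees of freedom), the
#' remainder sit near zero.
#'
#' @param module_genes character vector of module gene ids (non-empty).
#' @param discovery_t named numeric vector of discovery t-statistics
#'   covering `module_genes`.
#' @param concordant_frac fraction in \[0,1\] of module genes that
#'   replicate; `floor(concordant_frac * length(module_genes))` genes do.
#' @param rng_seed integer seed.
#' @param df residual degrees of freedom of the emulated validation design
#'   (default 6, i.e. 4 cases vs 4 controls).
#' @param alpha nominal two-sided level defining "significant" magnitude.
#' @return data.frame with columns `gene_id`, `t`, `p`.
#' @export
simulate_validation_stats <- function(module_genes, discovery_t,
                                      concordant_frac, rng_seed = 1,
                                      df = 6, alpha = 0.05) {
  if (!length(module_genes)) stopf("empty module")
  if (concordant_frac < 0 || concordant_frac > 1)
    stopf("concordant_frac must lie in [0,1]")
  if (!all(module_genes %in% names(discovery_t)))
    stopf("discovery_t missing for some module genes")
  seed_if(rng_seed)
  n <- length(module_genes)
  k <- floor(concordant_frac * n)
  tcrit <- stats::qt(1 - alpha / 2, df = df)
  sgn <- ifelse(discovery_t[module_genes] >= 0, 1, -1)
  tv <- rnorm(n, mean = 0, sd = 0.5)          # non-replicating: near zero
  if (k > 0) {
    conc <- sample.int(n, k)
    tv[conc] <- sgn[conc] * (tcrit + abs(rnorm(k, mean = 1, sd = 0.5)))
  }
  data.frame(gene_id = module_genes, t = as.numeric(tv),
             p = 2 * pt(-abs(tv), df = df), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate raw-scale probe-level data for the preprocessing stage
#'
#' Generates background-corrected raw intensities (lognormal for expressed
#' probes, noise around zero -- including negative values -- for
#' unexpressed ones), matching detection p-values, and a probe-to-gene
#' annotation in which some probes are unannotated and some genes carry
#' several probes.
#'
#' @param n_genes number of annotated genes.
#' @param probes_per_gene integer vector sampled from for the number of
#'   probes per gene.
#' @param n_samples number of arrays.
#' @param frac_unexpressed fraction of probes that are unexpressed
#'   (uniform detection p-values, near-zero intensities).
#' @param n_unannotated number of extra probes with no gene mapping.
#' @param mean_log2,sd_log2 location/scale of expressed log2 intensities.
#' @param rng_seed integer seed.
#' @return a [probe_matrix()] with `detection_p` and `probe2gene` set.
#' @export
simulate_raw_probes <- function(n_genes = 40, probes_per_gene = 1:3,
                                n_samples = 12, frac_unexpressed = 0.3,
                                n_unannotated = 5, mean_log2 = 7,
                                sd_log2 = 1, rng_seed = 1) {
  seed_if(rng_seed)
  per_gene <- sample(probes_per_gene, n_genes, replace = TRUE)
  gene_of <- rep(paste0("g", seq_len(n_genes)), per_gene)
  gene_of <- c(gene_of, rep(NA_character_, n_unannotated))
  np <- length(gene_of)
  probes <- paste0("p", seq_len(np))
  expressed <- runif(np) >= frac_unexpressed
  vals <- matrix(0, np, n_samples,
                 dimnames = list(probes, paste0("s", seq_len(n_samples))))
  detp <- vals
  for (i in seq_len(np)) {
    if (expressed[i]) {
      vals[i, ] <- 2^rnorm(n_samples, mean_log2, sd_log2)
      detp[i, ] <- runif(n_samples, 0, 0.01)
    } else {
      vals[i, ] <- rnorm(n_samples, mean = 5, sd = 15)  # some go negative
      detp[i, ] <- runif(n_samples, 0, 1)
    }
  }
  probe_matrix(vals, detection_p = detp,
               probe2gene = setNames(gene_of, probes))
}
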