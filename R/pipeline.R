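#' Default pipeline configuration
#'
#' Stage parameters mirror the reference analysis: detection p < 0.05,
#' 100 seeds, gamma 0.5, minimum module size 10, 1000 permutations,
#' significance level 0.05.
#'
#' @return nested named list (YAML-serializable).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "expmods_out",
    synthetic = list(enabled = TRUE, n_genes = 300, n_case = 7,
                     n_control = 5, effect_size = 4, noise_sd = 1,
                     baseline_mean = 8, n_nodes = 300, topology = "pa",
                     attachment = 2, planted_module_size = 10,
                     planted_internal_density = 0.9,
                     concordant_frac = 0.8),
    input = list(expression = NULL, detection = NULL, annotation = NULL,
                 groups = NULL, interactome = NULL, gene_sets = NULL,
                 validation = NULL),
    preprocess = list(enabled = FALSE, p_thresh = 0.05,
                      min_samples = NULL),
    diffexp = list(prior_df = NULL, pi0 = NULL),
    hotspot = list(n_seeds = 100L, gamma = 0.5, min_module_size = 10L,
                   n_perm = 1000L, alpha = 0.05, adjust = "bonferroni",
                   dedup_jaccard = 0.5),
    downstream = list(alpha = 0.05)
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  merge_config(default_config(), cfg)
}

#' @rdname read_config
#' @param config nested named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  h <- cfg$hotspot
  if (is.null(h$n_perm) || h$n_perm < 1)
    stopf("config error: hotspot.n_perm must be >= 1")
  if (h$gamma <= 0) stopf("config error: hotspot.gamma must be > 0")
  if (h$alpha <= 0 || h$alpha > 1)
    stopf("config error: hotspot.alpha must lie in (0,1]")
  if (!isTRUE(cfg$synthetic$enabled)) {
    for (f in c("expression", "groups", "interactome")) {
      p <- cfg$input[[f]]
      if (is.null(p)) stopf("config error: input.%s required %s", f,
                            "when synthetic data is disabled")
      if (!file.exists(p))
        stopf("input stage: missing file for input.%s: %s", f, p)
    }
  }
  invisible(cfg)
}

#' Run the full expression-module pipeline
#'
#' (optional synthetic generation) -> preprocessing -> moderated t /
#' q-values -> interactome integration and edge weighting -> seeded
#' spin-glass hotspot detection with permutation significance ->
#' validation concordance and gene-set enrichment. Every stage writes a
#' tab-separated table into the output directory together with a run
#' manifest; reruns with the same configuration reproduce byte-identical
#' tables.
#'
#' @param config a config list, or the path to a YAML config file (see
#'   [default_config()]).
#' @param outdir optional override of the configured output directory.
#' @param seed optional override of the configured global seed.
#' @return (invisibly) list with `de` (statistics table), `wnet`,
#'   `hotspots` (`expmod_set`), `concordance` (or NULL), `enrichment`
#'   (or NULL), `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  planted <- character()
  gene_sets <- NULL
  stats_v <- NULL

  if (isTRUE(cfg$synthetic$enabled)) {
    s <- cfg$synthetic
    net <- simulate_interactome(sim_network_config(
      n_nodes = s$n_nodes, topology = s$topology,
      attachment = s$attachment,
      planted_module_size = s$planted_module_size,
      planted_internal_density = s$planted_internal_density,
      rng_seed = derive_seed(cfg$seed, 10L)))
    planted <- igraph::graph_attr(net, "planted")
    em <- simulate_expression(sim_expression_config(
      n_genes = s$n_genes, n_case = s$n_case, n_control = s$n_control,
      planted_genes = planted, effect_size = s$effect_size,
      noise_sd = s$noise_sd, baseline_mean = s$baseline_mean,
      rng_seed = derive_seed(cfg$seed, 11L)))
    expr <- em$values
    groups <- em$groups
    write_matrix_tsv(expr, file.path(cfg$outdir, "expression.tsv"),
                     id_name = "gene_id", digits = NA)
    write.table(data.frame(sample_id = colnames(expr),
                           group = as.character(groups)),
                file.path(cfg$outdir, "groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    el <- igraph::as_edgelist(net)
    write.table(el, file.path(cfg$outdir, "interactome.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    expr <- read_matrix_tsv(cfg$input$expression)
    groups <- read_sample_groups(cfg$input$groups)[colnames(expr)]
    net <- read_interactome(cfg$input$interactome)
    if (isTRUE(cfg$preprocess$enabled)) {
      pm <- probe_matrix(
        expr,
        detection_p = if (!is.null(cfg$input$detection))
          read_matrix_tsv(cfg$input$detection),
        probe2gene = if (!is.null(cfg$input$annotation))
          read_probe_annotation(cfg$input$annotation))
      expr <- preprocess_chain(pm, p_thresh = cfg$preprocess$p_thresh,
                               min_samples = cfg$preprocess$min_samples,
                               filter = !is.null(pm$detection_p),
                               collapse = !is.null(pm$probe2gene))
    }
    if (!is.null(cfg$input$gene_sets))
      gene_sets <- read_gmt(cfg$input$gene_sets)
  }

  de <- moderated_t_test(expr, groups, prior_df = cfg$diffexp$prior_df)
  de$q <- as.numeric(estimate_qvalues(de$p, pi0 = cfg$diffexp$pi0))
  de <- de[order(de$p, de$gene_id), ]
  write_de_table(de, file.path(cfg$outdir, "diffexp.tsv"), digits = NA)

  inet <- integrate_interactome(net, de$gene_id)
  wnet <- weight_edges(inet, de)
  write_weighted_edgelist(wnet, file.path(cfg$outdir,
                                          "weighted_edges.tsv"))

  h <- cfg$hotspot
  hcfg <- hotspot_config(n_seeds = h$n_seeds, gamma = h$gamma,
                         min_module_size = h$min_module_size,
                         n_perm = h$n_perm, alpha = h$alpha,
                         adjust = h$adjust,
                         dedup_jaccard = h$dedup_jaccard,
                         rng_seed = derive_seed(cfg$seed, 12L))
  hot <- detect_hotspots(wnet, cfg = hcfg)
  write_hotspot_outputs(hot, wnet, cfg$outdir)

  conc <- NULL
  enr <- NULL
  if (length(hot$modules)) {
    top <- hot$modules[[1]]
    stats_v <- if (isTRUE(cfg$synthetic$enabled)) {
      simulate_validation_stats(top$members, setNames(de$t, de$gene_id),
                                cfg$synthetic$concordant_frac,
                                rng_seed = derive_seed(cfg$seed, 13L))
    } else if (!is.null(cfg$input$validation)) {
      read.delim(cfg$input$validation, stringsAsFactors = FALSE)
    }
    if (!is.null(stats_v)) {
      conc <- directional_concordance(top$members, de, stats_v,
                                      alpha = cfg$downstream$alpha)
      write_concordance(conc, file.path(cfg$outdir, "concordance.tsv"))
    }
    if (!is.null(gene_sets)) {
      enr <- hypergeometric_enrichment(
        intersect(top$members, de$gene_id), gene_sets, de$gene_id)
      write.table(enr, file.path(cfg$outdir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- c(sprintf("seed=%d", cfg$seed),
                sprintf("n_genes=%d", nrow(expr)),
                sprintf("n_network_nodes=%d", igraph::vcount(wnet)),
                sprintf("n_network_edges=%d", igraph::ecount(wnet)),
                sprintf("n_significant_modules=%d", length(hot$modules)),
                if (length(planted))
                  sprintf("planted=%s", paste(planted, collapse = ",")))
  writeLines(manifest, file.path(cfg$outdir, "pipeline_manifest.txt"))
  write_config(cfg, file.path(cfg$outdir, "config_used.yaml"))

  invisible(list(de = de, wnet = wnet, hotspots = hot, concordance = conc,
                 enrichment = enr, planted = planted, outdir = cfg$outdir))
}
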