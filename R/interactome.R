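#' Read an interactome from an edge list or SIF file
#'
#' Edge-list files have two whitespace/tab-separated node columns per line;
#' SIF lines are `source<TAB>interaction-type<TAB>target[<TAB>target...]`
#' (the interaction type is ignored). Duplicate edges -- including reversed
#' duplicates -- are collapsed and self-loops dropped with a message.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.sif` -> SIF), `"edgelist"` or
#'   `"sif"`.
#' @return a simple undirected [igraph::graph] with named vertices.
#' @export
read_interactome <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
              else "edgelist"
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(lines), "[ \t]+")
  edges <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (format == "edgelist") {
      if (length(f) != 2)
        stopf("malformed edge-list line %d: expected 2 fields, got %d",
              lineno[i], length(f))
      edges[[i]] <- cbind(f[1], f[2])
    } else {
      if (length(f) == 1)
        stopf("malformed SIF line %d: lone node", lineno[i])
      if (length(f) < 3)
        stopf("malformed SIF line %d: expected source, type, target(s)",
              lineno[i])
      edges[[i]] <- cbind(f[1], f[-(1:2)])
    }
  }
  em <- do.call(rbind, edges)
  if (is.null(em) || !nrow(em)) stopf("no edges in %s", path)
  loops <- em[, 1] == em[, 2]
  if (any(loops))
    message(sprintf("read_interactome: dropped %d self-loop(s)",
                    sum(loops)))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Restrict an interactome to the measured genes
#'
#' Induced subgraph on the intersection of the graph's nodes with the
#' genes measured on the array. Nodes left without any edge are retained
#' but flagged in the vertex attribute `isolated`.
#'
#' @param graph an [igraph::graph] with named vertices.
#' @param measured_genes character vector of measured gene ids.
#' @return the induced subgraph; a message logs node and edge counts.
#' @export
integrate_interactome <- function(graph, measured_genes) {
  shared <- intersect(igraph::V(graph)$name, measured_genes)
  if (!length(shared))
    stopf("no overlap between interactome nodes and measured genes")
  g <- igraph::induced_subgraph(graph, shared)
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  message(sprintf(
    "integrate_interactome: %d nodes, %d edges after integration (%d isolated)",
    igraph::vcount(g), igraph::ecount(g), sum(igraph::V(g)$isolated)))
  g
}

#' Attach differential-expression edge weights to an interactome
#'
#' Each edge g--h receives the combined strength of its endpoints'
#' statistics,
#' \deqn{w_{gh} = (|t_g| + |t_h|) / (2\, t_{max}),}
#' the average of the absolute statistics normalized by the maximum
#' absolute statistic \eqn{t_{max}}, so that all weights lie in \[0, 1\]
#' and an edge attains weight 1 exactly when both endpoints carry the
#' maximal statistic. Non-interacting pairs carry no weight.
#'
#' @param graph an [igraph::graph] with named vertices (e.g. from
#'   [integrate_interactome()]).
#' @param stats named numeric vector of per-gene t-statistics, or a
#'   data.frame with `gene_id` and `t` columns; every node must be
#'   covered.
#' @param t_max_scope `"network"` (default): normalize by the maximum
#'   |t| over network nodes; `"all"`: over every gene in `stats`.
#' @param normalize optional replacement for the default normalization:
#'   a function `(abs_t_g, abs_t_h, t_max) -> weight`.
#' @return a `weighted_interactome`: the igraph with edge attribute
#'   `weight`, vertex attribute `t`, and graph attribute `t_max`.
#' @export
weight_edges <- function(graph, stats, t_max_scope = c("network", "all"),
                         normalize = NULL) {
  t_max_scope <- match.arg(t_max_scope)
  tvec <- as_stat_vector(stats)
  nodes <- igraph::V(graph)$name
  missing <- setdiff(nodes, names(tvec))
  if (length(missing))
    stopf("no statistic for %d node(s), e.g. %s", length(missing),
          paste(head(missing, 3), collapse = ", "))
  tn <- tvec[nodes]
  t_max <- if (t_max_scope == "network") max(abs(tn)) else max(abs(tvec))
  if (t_max <= 0) stopf("all statistics are zero: degenerate normalization")
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  fun <- normalize %||% function(a, b, tm) (a + b) / (2 * tm)
  w <- fun(abs(tn[ends[, 1]]), abs(tn[ends[, 2]]), t_max)
  g <- igraph::set_edge_attr(graph, "weight", value = as.numeric(w))
  g <- igraph::set_vertex_attr(g, "t", value = as.numeric(tn))
  g <- igraph::set_graph_attr(g, "t_max", t_max)
  class(g) <- unique(c("weighted_interactome", class(g)))
  g
}

as_stat_vector <- function(stats) {
  if (is.data.frame(stats)) {
    if (!all(c("gene_id", "t") %in% names(stats)))
      stopf("stats data.frame needs gene_id and t columns")
    return(setNames(stats$t, stats$gene_id))
  }
  if (is.null(names(stats))) stopf("stats vector must be named by gene id")
  stats
}

#' Node statistics of a weighted interactome
#' @param wnet a `weighted_interactome`.
#' @return named numeric vector of t-statistics.
#' @export
node_stats <- function(wnet) {
  setNames(igraph::V(wnet)$t, igraph::V(wnet)$name)
}

#' Write a weighted edge list (`g<TAB>h<TAB>w`, 6 decimals)
#' @param wnet a `weighted_interactome`.
#' @param path output path.
#' @export
write_weighted_edgelist <- function(wnet, path) {
  ends <- igraph::ends(wnet, igraph::E(wnet), names = TRUE)
  df <- data.frame(ends[, 1], ends[, 2],
                   sprintf("%.6f", igraph::E(wnet)$weight))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export a weighted interactome as GraphML for visualization tools
#' @param wnet a `weighted_interactome` (or any igraph).
#' @param path output path.
#' @export
write_graphml <- function(wnet, path) {
  g <- wnet
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
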