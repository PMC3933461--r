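#' Directional concordance of a module between two datasets
#'
#' Module genes scored in both a discovery and a validation dataset are
#' cross-classified by the sign of their statistics. Two readings are
#' reported: (i) the 2x2 sign table `sign(t_discovery) x sign(t_validation)`
#' over all shared module genes, with a two-sided Fisher exact test; and
#' (ii) the nominal-significance filter -- `n_same` counts module genes
#' with validation p < `alpha` and matching sign, `n_opposite` those with
#' validation p < `alpha` and opposite sign.
#'
#' @param module character vector of module gene ids.
#' @param stats_d,stats_v discovery / validation statistics: data.frames
#'   with `gene_id`, `t` and (for `stats_v`) `p` columns, or named `t`
#'   vectors (then the nominal filter needs `p` inside a data.frame).
#' @param alpha nominal two-sided significance level for the filter.
#' @return an object of class `concordance_result`: list with `table`
#'   (2x2 counts), `n_same`, `n_opposite`, `fisher_p`, and `per_gene`
#'   (data.frame: gene_id, t_discovery, t_validation, p_validation,
#'   class in same/opposite/nonsignificant).
#' @export
directional_concordance <- function(module, stats_d, stats_v,
                                    alpha = 0.05) {
  d <- as_stat_frame(stats_d)
  v <- as_stat_frame(stats_v)
  shared <- intersect(module, intersect(d$gene_id, v$gene_id))
  if (!length(shared))
    stopf("no module gene is scored in both datasets")
  td <- setNames(d$t, d$gene_id)[shared]
  tv <- setNames(v$t, v$gene_id)[shared]
  pv <- if ("p" %in% names(v)) setNames(v$p, v$gene_id)[shared]
        else rep(NA_real_, length(shared))

  sgn <- function(x) ifelse(x > 0, "+", "-")
  tab <- table(factor(sgn(td), levels = c("+", "-")),
               factor(sgn(tv), levels = c("+", "-")),
               dnn = c("discovery", "validation"))
  cls <- rep("nonsignificant", length(shared))
  sig <- !is.na(pv) & pv < alpha
  cls[sig & sgn(td) == sgn(tv)] <- "same"
  cls[sig & sgn(td) != sgn(tv)] <- "opposite"

  structure(list(table = unclass(tab),
                 n_same = sum(cls == "same"),
                 n_opposite = sum(cls == "opposite"),
                 fisher_p = fisher_exact_2x2(unclass(tab)),
                 per_gene = data.frame(gene_id = shared, t_discovery = td,
                                       t_validation = tv, p_validation = pv,
                                       class = cls, row.names = NULL,
                                       stringsAsFactors = FALSE)),
            class = "concordance_result")
}

as_stat_frame <- function(stats) {
  if (is.data.frame(stats)) {
    if (!all(c("gene_id", "t") %in% names(stats)))
      stopf("stats data.frame needs gene_id and t columns")
    return(stats)
  }
  if (is.null(names(stats))) stopf("stats vector must be named by gene id")
  data.frame(gene_id = names(stats), t = as.numeric(stats),
             stringsAsFactors = FALSE)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance_result: %d same / %d opposite (nominal filter), Fisher p = %.3g\n",
    x$n_same, x$n_opposite, x$fisher_p))
  print(x$table)
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric point probabilities of all tables (at the
#' observed margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stopf("need a 2x2 table")
  if (any(tab < 0)) stopf("counts must be nonnegative")
  if (any(tab != round(tab))) stopf("counts must be integers")
  if (sum(tab) == 0) return(1)
  fisher.test(tab)$p.value
}

#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test of the overlap between the module and
#' each gene set, within a fixed gene universe; Benjamini-Hochberg FDR
#' across sets.
#'
#' @param module character vector of module gene ids (subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]); sets are intersected with the universe.
#' @param universe character vector of all scorable gene ids.
#' @return data.frame: `set`, `set_size` (within universe), `overlap`,
#'   `p` (\eqn{P(X \ge k)}), `fdr`, `genes` (comma-joined overlap).
#' @export
hypergeometric_enrichment <- function(module, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  if (!all(module %in% universe)) stopf("module must be within the universe")
  module <- unique(module)
  n <- length(module)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    hit <- intersect(set, module)
    k <- length(hit)
    p <- if (k == 0) 1 else
      phyper(k - 1, length(set), N - length(set), n, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[order(out$p), c("set", "set_size", "overlap", "p", "fdr", "genes")]
}

#' Write a concordance result as plain tables
#'
#' Per-gene table plus a summary block of counts and the Fisher p.
#'
#' @param res a `concordance_result`.
#' @param path output path for the per-gene table; the summary goes to
#'   `<path>.summary.txt`.
#' @export
write_concordance <- function(res, path) {
  write.table(res$per_gene, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(sprintf("n_same=%d", res$n_same),
               sprintf("n_opposite=%d", res$n_opposite),
               sprintf("fisher_p=%.6g", res$fisher_p),
               sprintf("table=%s", paste(res$table, collapse = ","))),
             paste0(path, ".summary.txt"))
  invisible(path)
}
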