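#' Probe-level intensity matrix
#'
#' Container for raw (or normalized) probe-level data: an intensity matrix,
#' an optional identically-shaped detection p-value matrix, and an optional
#' probe-to-gene annotation.
#'
#' @param values numeric matrix, probes in rows (unique rownames), samples
#'   in columns (unique colnames).
#' @param detection_p optional numeric matrix of per-probe per-sample
#'   detection p-values, same shape and dimnames as `values`.
#' @param probe2gene optional named character vector mapping probe id to
#'   gene id (`NA` = unannotated probe).
#' @export
probe_matrix <- function(values, detection_p = NULL, probe2gene = NULL) {
  values <- as.matrix(values)
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stopf("probe ids (rownames) must be present and unique")
  if (ncol(values) > 0 &&
      (is.null(colnames(values)) || anyDuplicated(colnames(values))))
    stopf("sample ids (colnames) must be present and unique")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stopf("detection_p must have the same shape as values")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p,
                 probe2gene = probe2gene), class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples%s%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "" else ", detection p present",
              if (is.null(x$probe2gene)) "" else ", annotation present"))
  invisible(x)
}

#' Filter probes by detection p-value
#'
#' Retains exactly the probes whose detection p-value is strictly below
#' `p_thresh` in at least `min_samples` samples; probe order is preserved.
#' The default `min_samples` generalizes the "5 of 12 samples" rule as
#' `ceiling(5/12 * n_samples)`.
#'
#' @param m a [probe_matrix()] with `detection_p` present.
#' @param p_thresh detection p-value threshold (strict), in (0, 1\].
#' @param min_samples minimum number of samples below threshold.
#' @return the filtered `probe_matrix`; attributes `n_input` and `n_kept`
#'   record the probe counts, and [retention_percent()] reads them back.
#' @export
detection_filter <- function(m, p_thresh = 0.05, min_samples = NULL) {
  stopifnot(inherits(m, "probe_matrix"))
  if (is.null(m$detection_p))
    stopf("no detection p-values available; skip the detection-filter stage")
  ns <- ncol(m$values)
  min_samples <- min_samples %||% ceiling(5 / 12 * ns)
  if (p_thresh <= 0 || p_thresh > 1) stopf("p_thresh must lie in (0,1]")
  if (min_samples < 1 || min_samples > ns)
    stopf("min_samples must lie in [1, %d]", ns)
  keep <- rowSums(m$detection_p < p_thresh) >= min_samples
  out <- probe_matrix(m$values[keep, , drop = FALSE],
                      m$detection_p[keep, , drop = FALSE], m$probe2gene)
  attr(out, "n_input") <- nrow(m$values)
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Percentage of probes retained by a filter
#'
#' @param n_kept,n_total probe counts; `n_kept` may also be a filtered
#'   [probe_matrix()] carrying its own counts.
#' @return percentage (0--100), unrounded.
#' @export
retention_percent <- function(n_kept, n_total = NULL) {
  if (inherits(n_kept, "probe_matrix")) {
    n_total <- attr(n_kept, "n_input")
    n_kept <- attr(n_kept, "n_kept")
    if (is.null(n_total)) stopf("matrix carries no filter counts")
  }
  100 * n_kept / n_total
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to the same empirical distribution: the
#' across-column mean of sorted values. Ties within a column receive the
#' mean of the reference quantiles they span.
#'
#' @param m a [probe_matrix()] (no missing values).
#' @return the normalized `probe_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  if (nrow(m$values) == 0 || ncol(m$values) == 0) stopf("empty matrix")
  if (anyNA(m$values)) stopf("missing values not supported")
  norm <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(norm) <- dimnames(m$values)
  probe_matrix(norm, m$detection_p, m$probe2gene)
}

#' Floor non-positive values and log2-transform
#'
#' Replaces every value below zero by the global minimum strictly-positive
#' value of the matrix, then takes log2. Zeros are floored the same way,
#' since the point of flooring is to make log2 well defined.
#'
#' @param m a [probe_matrix()] containing at least one positive value.
#' @return the transformed `probe_matrix`.
#' @export
floor_log2 <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  v <- m$values
  pos <- v[v > 0]
  if (!length(pos)) stopf("matrix contains no positive value")
  v[v <= 0] <- min(pos)
  probe_matrix(log2(v), m$detection_p, m$probe2gene)
}

#' Collapse probes to genes by averaging
#'
#' Drops probes without a gene annotation and averages the expression
#' profiles of probes mapping to the same gene (arithmetic mean per
#' sample, on whatever scale the matrix is on -- the standard chain calls
#' this after the log2 transform).
#'
#' @param m a [probe_matrix()] with `probe2gene` present.
#' @return numeric matrix, genes x samples, unique gene rownames.
#' @export
collapse_probes <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  if (is.null(m$probe2gene) || !length(m$probe2gene))
    stopf("no probe-to-gene annotation available")
  genes <- m$probe2gene[rownames(m$values)]
  keep <- !is.na(genes)
  if (!any(keep)) stopf("no annotated probes left")
  v <- m$values[keep, , drop = FALSE]
  genes <- genes[keep]
  out <- rowsum(v, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  as.matrix(out)
}

#' Run the full preprocessing chain
#'
#' detection filter -> quantile normalization -> flooring + log2 ->
#' probe-to-gene collapsing. Stages without their required inputs
#' (detection p-values, annotation) can be skipped explicitly.
#'
#' @param m a [probe_matrix()].
#' @param p_thresh,min_samples see [detection_filter()].
#' @param filter,collapse logical switches for the optional stages.
#' @return gene x sample log2 matrix (or probe-level if `collapse = FALSE`).
#' @export
preprocess_chain <- function(m, p_thresh = 0.05, min_samples = NULL,
                             filter = TRUE, collapse = TRUE) {
  if (filter) m <- detection_filter(m, p_thresh, min_samples)
  m <- floor_log2(quantile_normalize(m))
  if (collapse) collapse_probes(m) else m$values
}
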