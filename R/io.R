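#' Read a tab-separated matrix (first column ids, header of sample ids)
#'
#' @param path file path.
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as tab-separated text
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_name header for the id column.
#' @param digits significant digits (`NA` = full precision).
#' @export
write_matrix_tsv <- function(m, path, id_name = "id", digits = 6) {
  vals <- if (is.na(digits)) m else signif(m, digits)
  df <- data.frame(rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-level dataset from tab-separated files
#'
#' @param values_path intensity matrix file.
#' @param detection_path optional detection p-value matrix file (same
#'   shape).
#' @param annotation_path optional two-column file (probe_id, gene_id).
#' @return a [probe_matrix()].
#' @export
read_probe_matrix <- function(values_path, detection_path = NULL,
                              annotation_path = NULL) {
  vals <- read_matrix_tsv(values_path)
  detp <- if (!is.null(detection_path)) read_matrix_tsv(detection_path)
  p2g <- if (!is.null(annotation_path)) read_probe_annotation(annotation_path)
  probe_matrix(vals, detection_p = detp, probe2gene = p2g)
}

#' Read a two-column probe-to-gene annotation
#'
#' @param path tab-separated file with columns probe id, gene id (header
#'   optional but recommended); empty gene ids become `NA`.
#' @return named character vector probe id -> gene id.
#' @export
read_probe_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (ncol(df) < 2) stopf("annotation needs two columns (probe, gene)")
  gene <- as.character(df[[2]])
  gene[!nzchar(gene) | gene == "NA"] <- NA_character_
  setNames(gene, as.character(df[[1]]))
}

#' Read case/control sample annotation
#'
#' @param path tab-separated file with columns sample id and group label
#'   (`case`/`control`).
#' @return factor of groups named by sample id.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  grp <- factor(tolower(df[[2]]), levels = c("control", "case"))
  if (anyNA(grp)) stopf("group labels must be 'case' or 'control'")
  setNames(grp, as.character(df[[1]]))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stopf("malformed GMT line %d: need name, description, >=1 gene", bad[1])
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, "", 1))
}

#' Write a differential-expression table
#'
#' Tab-separated with columns gene_id, AvExp(control), AvExp(case), logFC,
#' t, P-value, q-value.
#'
#' @param stats data.frame as returned by [moderated_t_test()] (with a `q`
#'   column added by [estimate_qvalues()], optional).
#' @param path output path.
#' @param digits significant digits (`NA` = full precision).
#' @export
write_de_table <- function(stats, path, digits = 6) {
  df <- stats
  num <- vapply(df, is.numeric, TRUE)
  if (!is.na(digits)) df[num] <- lapply(df[num], signif, digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-25 discovery statistics from a 7-case/5-control aortic-dissection
#' expression study
#'
#' The bundled summary table (Entrez id, symbol, group mean log2
#' expression, logFC, moderated t, p, q) for the 25 most significant genes
#' of the discovery cohort; useful as a worked example for the
#' differential-expression container invariants.
#'
#' @return data.frame with one row per gene.
#' @export
aad_top25 <- function() {
  path <- system.file("extdata", "aad_top25_de_stats.tsv",
                      package = "expmods")
  read.delim(path, stringsAsFactors = FALSE)
}
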