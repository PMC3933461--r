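# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used to match the variance of log sample variances to the
# theoretical log-F moments when estimating the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (!is.finite(x)) return(if (x > 0) 1e-10 else Inf)
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated two-group t-statistics (empirical Bayes)
#'
#' For each gene, the case-minus-control log fold-change is tested with a
#' regularized t-statistic: the pooled residual variance \eqn{s_g^2} (with
#' \eqn{d_g = n_1+n_2-2} degrees of freedom) is shrunk toward a prior
#' \eqn{s_0^2} with \eqn{d_0} prior degrees of freedom,
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and \eqn{t_g = \mathrm{logFC}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})} is
#' referred to a t law with \eqn{d_0 + d_g} degrees of freedom. The
#' hyperparameters \eqn{(d_0, s_0^2)} are fitted by matching the observed
#' mean and variance of \eqn{\log s_g^2} to the moments of a scaled
#' F/chi-square model. With `prior_df = 0` this is the ordinary pooled
#' two-sample t-test; with `prior_df = Inf` all genes share the common
#' variance \eqn{s_0^2}.
#'
#' Genes with zero sample variance keep \eqn{s_g^2 = 0}; the prior keeps
#' their t finite (a degenerate, non-finite \eqn{d_0} estimate is treated
#' as an infinite prior with a warning).
#'
#' @param expr an [expr_matrix()], or a numeric genes x samples matrix (then
#'   `groups` is required).
#' @param groups factor/character of `case`/`control` labels per column;
#'   ignored when `expr` is an `expr_matrix`.
#' @param prior_df optional fixed prior degrees of freedom (`0`, finite, or
#'   `Inf`); `NULL` (default) estimates it from the data.
#' @return data.frame with one row per gene: `gene_id`, `avexp_control`,
#'   `avexp_case`, `logfc`, `t`, `p`; attributes `df_prior`, `s2_prior`,
#'   `df_residual`.
#' @examples
#' em <- simulate_expression(sim_expression_config(n_genes = 100))
#' head(moderated_t_test(em))
#' @export
moderated_t_test <- function(expr, groups = NULL, prior_df = NULL) {
  if (inherits(expr, "expr_matrix")) {
    groups <- expr$groups
    expr <- expr$values
  }
  expr <- as.matrix(expr)
  if (is.null(groups)) stopf("groups required")
  groups <- factor(as.character(groups), levels = c("control", "case"))
  if (anyNA(groups)) stopf("groups must be labelled 'case' or 'control'")
  if (!all(is.finite(expr))) stopf("expression values must be finite")
  n1 <- sum(groups == "case")
  n0 <- sum(groups == "control")
  if (n1 < 2 || n0 < 2) stopf("need >= 2 samples per group")

  xc <- expr[, groups == "case", drop = FALSE]
  x0 <- expr[, groups == "control", drop = FALSE]
  m1 <- rowMeans(xc)
  m0 <- rowMeans(x0)
  logfc <- m1 - m0
  df_res <- n1 + n0 - 2
  s2 <- (rowSums((xc - m1)^2) + rowSums((x0 - m0)^2)) / df_res

  fit <- fit_variance_prior(s2, df_res)
  d0 <- prior_df %||% fit$df_prior
  if (is.null(prior_df) && !is.finite(d0)) {
    warnf("prior degrees of freedom estimate is not finite; %s",
          "using an infinite prior (full shrinkage)")
  }
  s02 <- fit$s2_prior
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df_res * s2) / (d0 + df_res)

  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  df_total <- d0 + df_res
  p <- 2 * pt(-abs(t), df = df_total)

  out <- data.frame(gene_id = rownames(expr) %||%
                      paste0("g", seq_along(logfc)),
                    avexp_control = m0, avexp_case = m1, logfc = logfc,
                    t = t, p = p, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  attr(out, "df_residual") <- df_res
  out
}

# Moment-matching fit of the scaled chi-square prior for gene variances:
# z = log s^2 has mean digamma(d/2) - log(d/2) + log s0^2 and excess
# variance trigamma(d0/2) beyond trigamma(d/2) under the hierarchical
# model. Zero variances carry no log information and are excluded here.
fit_variance_prior <- function(s2, df_res) {
  pos <- s2 > 0
  if (!any(pos)) return(list(df_prior = Inf, s2_prior = mean(s2)))
  z <- log(s2[pos])
  e <- z - digamma(df_res / 2) + log(df_res / 2)
  emean <- mean(e)
  evar <- if (sum(pos) > 1) var(e) - trigamma(df_res / 2) else -1
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df_prior = d0, s2_prior = s02)
}

#' Assemble and validate a per-gene differential-expression record
#'
#' The log fold-change is derived from the group means (case minus
#' control); supplied statistics are checked against the container's
#' invariants (`p`, `q` in \[0,1\]; `sign(t) = sign(logfc)` when the fold
#' change is nonzero).
#'
#' @param gene_id character ids.
#' @param avexp_control,avexp_case group mean log2 expression.
#' @param t,p,q optional statistic columns.
#' @return data.frame of class `de_stats`.
#' @export
de_stats <- function(gene_id, avexp_control, avexp_case, t = NULL,
                     p = NULL, q = NULL) {
  logfc <- avexp_case - avexp_control
  out <- data.frame(gene_id = as.character(gene_id),
                    avexp_control = avexp_control,
                    avexp_case = avexp_case, logfc = logfc,
                    stringsAsFactors = FALSE)
  if (!is.null(t)) {
    if (any(logfc != 0 & sign(t) != sign(logfc)))
      stopf("sign(t) must match sign(logfc)")
    out$t <- t
  }
  for (col in c("p", "q")) {
    v <- get(col)
    if (!is.null(v)) {
      if (any(v < 0 | v > 1)) stopf("%s-values must lie in [0,1]", col)
      out[[col]] <- v
    }
  }
  class(out) <- c("de_stats", "data.frame")
  out
}

#' Storey q-values from a vector of p-values
#'
#' Estimates the null proportion \eqn{\pi_0} from the flat right tail of
#' the p-value distribution -- \eqn{\hat\pi_0(\lambda) =
#' \#\{p > \lambda\}/(m(1-\lambda))} smoothed by a running mean over the
#' \eqn{\lambda} grid and read off at the largest \eqn{\lambda}; if the
#' smoother degenerates the most conservative (largest) grid estimate is
#' used -- then applies the step-up rule
#' \eqn{q_i = \min_{j: p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)},
#' capped at 1. With `pi0 = 1` this is exactly Benjamini-Hochberg.
#'
#' @param p numeric p-values in \[0,1\] (non-empty).
#' @param lambda grid of tail cutoffs in \[0,1).
#' @param pi0 optional fixed null proportion (e.g. `1` for plain BH).
#' @return numeric q-values, same order as `p`; attribute `pi0`.
#' @export
estimate_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05),
                             pi0 = NULL) {
  if (!length(p)) stopf("empty p-value vector")
  if (any(p < 0 | p > 1 | !is.finite(p))) stopf("p-values must lie in [0,1]")
  m <- length(p)
  if (is.null(pi0)) {
    raw <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    k <- length(raw)
    smooth <- vapply(seq_len(k), function(i)
      mean(raw[max(1, i - 1):min(k, i + 1)]), 0)
    pi0 <- smooth[k]
    if (!is.finite(pi0) || pi0 <= 0)
      pi0 <- max(raw[is.finite(raw)], na.rm = TRUE)
    pi0 <- min(pi0, 1)
    pi0 <- max(pi0, 1 / m)
  }
  o <- order(p)
  q_sorted <- pmin(pi0 * m * p[o] / seq_len(m), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}
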