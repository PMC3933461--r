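toy_expr <- function(values, groups) {
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expr_matrix(values, groups)
}

test_that("a gene with identical values in both groups carries no signal", {
  set.seed(3)
  vals <- rbind(rep(5, 6), matrix(stats::rnorm(5 * 6), 5, 6))
  em <- toy_expr(vals, rep(c("case", "control"), each = 3))
  de <- moderated_t_test(em)
  expect_equal(de$logfc[1], 0)
  expect_equal(de$t[1], 0)
  expect_equal(de$p[1], 1)
})

test_that("prior df 0 reproduces the ordinary pooled t-test exactly", {
  set.seed(8)
  vals <- matrix(stats::rnorm(12 * 6), 12, 6)
  groups <- rep(c("case", "control"), each = 3)
  de <- moderated_t_test(toy_expr(vals, groups), prior_df = 0)
  for (i in 1:12) {
    expect_equal(de$t[i], pooled_t_oracle(vals[i, 1:3], vals[i, 4:6]),
                 tolerance = 1e-10)
  }
  expect_equal(de$p, 2 * stats::pt(-abs(de$t), df = 4), tolerance = 1e-12)
})

test_that("estimated shrinkage agrees with the reference empirical-Bayes fit", {
  em <- simulate_expression(sim_expression_config(
    n_genes = 300, planted_genes = paste0("g", 1:15), effect_size = 2,
    heteroscedastic = TRUE, rng_seed = 14))
  de <- moderated_t_test(em)
  design <- stats::model.matrix(~em$groups)
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(attr(de, "df_prior"), fit$df.prior, tolerance = 1e-6)
})

test_that("the prior-df limits bracket the moderated statistic", {
  set.seed(5)
  vals <- matrix(stats::rnorm(50 * 8, sd = rep(stats::runif(50, 0.5, 2), 8)),
                 50, 8)
  groups <- rep(c("case", "control"), each = 4)
  em <- toy_expr(vals, groups)
  de0 <- moderated_t_test(em, prior_df = 0)
  deInf <- moderated_t_test(em, prior_df = Inf)
  s0 <- sqrt(attr(deInf, "s2_prior"))
  expect_equal(deInf$t, deInf$logfc / (s0 * sqrt(1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  # large finite prior df converges to the shared-variance limit
  de_big <- moderated_t_test(em, prior_df = 1e9)
  expect_equal(de_big$t, deInf$t, tolerance = 1e-5)
  # small prior df converges to the pooled t
  de_small <- moderated_t_test(em, prior_df = 1e-9)
  expect_equal(de_small$t, de0$t, tolerance = 1e-5)
})

test_that("null p-values are uniform", {
  em <- simulate_expression(sim_expression_config(n_genes = 5000,
                                                  effect_size = 0,
                                                  rng_seed = 33))
  de <- moderated_t_test(em)
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("q-values follow Storey's rule and its BH limit", {
  expect_equal(as.numeric(estimate_qvalues(rep(1, 7))), rep(1, 7))

  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  q <- estimate_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), bh_oracle(p), tolerance = 1e-12)
  expect_equal(as.numeric(q), stats::p.adjust(p, "BH"), tolerance = 1e-12)

  set.seed(6)
  p2 <- stats::runif(500)^1.6
  q2 <- estimate_qvalues(p2)
  pi0 <- attr(q2, "pi0")
  expect_true(pi0 > 0 && pi0 <= 1)
  o <- order(p2)
  expect_true(all(diff(q2[o]) >= -1e-12))       # q monotone in p
  expect_true(all(q2 >= p2 * pi0 - 1e-12))      # q >= pi0 * p
  expect_true(all(q2 <= 1))
  expect_error(estimate_qvalues(numeric()), "empty")
  expect_error(estimate_qvalues(c(0.5, 2)), "0,1")
})

test_that("published worked rows satisfy the record invariants", {
  tab <- aad_top25()
  ds <- de_stats(tab$Symbol, tab$AvExp_Control, tab$AvExp_Case,
                 t = tab$t, p = tab$P_value, q = tab$q_value)
  # recomputed logFC agrees with the printed column at printed precision
  expect_equal(signif(ds$logfc[ds$gene_id == "JAK2"], 6), -1.77674)
  expect_equal(signif(ds$logfc[ds$gene_id == "TIMP1"], 7), 1.189827)
  expect_equal(signif(ds$logfc[ds$gene_id == "CDC45L"], 6), 17.4935)
  # q nondecreasing when sorted by p
  o <- order(ds$p)
  expect_true(all(diff(ds$q[o]) >= 0))
  expect_true(all(ds$logfc == 0 | sign(ds$t) == sign(ds$logfc)))
})

test_that("degenerate inputs are rejected or shrunk gracefully", {
  vals <- matrix(stats::rnorm(20), 4, 5)
  expect_error(moderated_t_test(toy_expr(vals,
                                         c("case", rep("control", 4)))),
               ">= 2")
  # zero-variance genes stay finite thanks to the prior
  set.seed(2)
  vals2 <- rbind(c(1, 1, 1, 0, 0, 0), matrix(stats::rnorm(30), 5, 6))
  de <- moderated_t_test(toy_expr(vals2, rep(c("case", "control"), each = 3)))
  expect_true(all(is.finite(de$t)))
  expect_gt(abs(de$t[1]), 0)
})
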