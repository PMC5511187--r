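test_that("a noiseless PMI gene is fit exactly", {
  smp <- toy_samples(30, pmi = seq(60, 1620, length.out = 30))
  y <- 5 + 2 * smp$pmi_min
  fit <- fit_pmi_model(y, smp)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
})

test_that("null genes give uniform p-values and covered alpha", {
  set.seed(51)
  n <- 60
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  smp$age <- sample(21:70, n, TRUE)
  ps <- numeric(1000)
  covered <- logical(1000)
  Y <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("g%04d", 1:1000), smp$sample_id))
  Y <- Y + outer(rep(3, 1000), smp$age)   # age effect only, no PMI effect
  X <- pmidecay:::build_design(smp, NULL, include_pmi = TRUE)
  fit <- pmidecay:::ols_term_test(Y, X, "pmi")
  expect_gt(ks.test(fit$p, "punif")$p.value, 0.01)
  covered <- abs(fit$estimate) <= 2 * fit$se
  expect_gt(mean(covered), 0.9)
})

test_that("zero-variance genes report alpha 0, p 1", {
  smp <- toy_samples(20)
  fit <- fit_pmi_model(rep(4, 20), smp)
  expect_equal(fit$alpha, 0)
  expect_equal(fit$p_value, 1)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the permutation gate passes perfect fits and is vacuous at cutoff n_perm", {
  smp <- toy_samples(25, pmi = seq(100, 1500, length.out = 25))
  y <- 1 + 2 * smp$pmi_min
  g <- permutation_gate(y, smp, n_perm = 1000, pass_cutoff = 500, seed = 3)
  expect_equal(g$perm_count, 0)
  expect_true(g$perm_pass)
  set.seed(4)
  ynull <- rnorm(25)
  g2 <- permutation_gate(ynull, smp, n_perm = 200, pass_cutoff = 200, seed = 3)
  expect_true(g2$perm_pass)
  expect_error(permutation_gate(ynull, smp, n_perm = 0), "n_perm")
})

test_that("null-gene permutation pass rate matches cutoff/n_perm", {
  ds <- make_dataset(n_genes = 400, n_samples = 80, frac_pmi_genes = 0,
                     n_hidden_factors = 0, seed = 23)
  ex <- log2_expr(ds)
  cnt <- pmidecay:::permutation_counts(unclass(ex), ds$samples, NULL,
                                       n_perm = 1000, seed = 7)
  pass_rate <- mean(cnt < 50)
  expect_gt(pass_rate, 0.02)
  expect_lt(pass_rate, 0.10)
})

test_that("association recovers planted effects with faithful directions", {
  ds <- make_dataset(n_genes = 1000, n_samples = 200, frac_pmi_genes = 0.1,
                     effect_size_sd = 1, seed = 29)
  ex <- log2_expr(ds)
  f <- fit_factors(ex, ds$samples, k = 10)
  a <- run_association(ex, ds$samples, f, n_perm = 500)
  truth <- ds$truth$true_alpha[a$table$gene_id]
  n_true <- sum(truth != 0)
  detected <- a$table$direction != "null"
  expect_gt(sum(detected & truth != 0), 0.7 * n_true)
  # false discoveries bounded near the nominal FDR
  expect_lt(sum(detected & truth == 0), 0.075 * sum(detected) + 3)
  # direction labels match the planted sign
  dirsign <- ifelse(a$table$direction == "up", 1,
                    ifelse(a$table$direction == "down", -1, 0))
  ok <- dirsign[detected & truth != 0] == sign(truth[detected & truth != 0])
  expect_gte(mean(ok), 0.95)
  # gated counts never exceed raw counts
  expect_true(all(a$counts$total_gated <= a$counts$total))
})

test_that("the bootstrap curve degenerates to the full-data count", {
  ds <- make_dataset(n_genes = 200, n_samples = 60, frac_pmi_genes = 0.2,
                     n_hidden_factors = 0, seed = 37)
  ex <- log2_expr(ds)
  a <- run_association(ex, ds$samples, NULL)
  full_count <- sum(a$table$q_value <= 0.05)
  bc <- sample_size_bootstrap(ex, ds$samples, NULL, sizes = 60, n_boot = 3,
                              fixed_n = 60, seed = 5)
  expect_equal(bc$mean_counts, full_count)
  expect_equal(bc$fixed_n_mean_count, full_count)
  expect_error(sample_size_bootstrap(ex, ds$samples, NULL, sizes = c(20, 80)),
               "exceeds")
  expect_error(sample_size_bootstrap(ex, ds$samples, NULL, sizes = 40,
                                     fixed_n = 80), "fixed_n")
})

test_that("all-null data give a flat bootstrap curve near zero", {
  ds <- make_dataset(n_genes = 300, n_samples = 100, frac_pmi_genes = 0,
                     n_hidden_factors = 0, seed = 41)
  ex <- log2_expr(ds)
  bc <- sample_size_bootstrap(ex, ds$samples, NULL, sizes = c(20, 60, 100),
                              n_boot = 5, fixed_n = 20, seed = 6)
  expect_true(all(bc$mean_counts <= 2))
})

test_that("cross-tissue summary counts hits and direction consistency", {
  mk <- function(genes, dirs) data.frame(gene_id = genes, direction = dirs,
                                         stringsAsFactors = FALSE)
  res <- list(t1 = mk(c("gA", "gB", "gC"), c("up", "down", "null")),
              t2 = mk(c("gA", "gB", "gC"), c("up", "up", "null")),
              t3 = mk(c("gA", "gB", "gC"), c("up", "null", "null")))
  out <- summarize_cross_tissue(res)
  expect_equal(out$n_tissues[out$gene_id == "gA"], 3)
  expect_true(out$direction_consistent[out$gene_id == "gA"])
  expect_false(out$direction_consistent[out$gene_id == "gB"])
  expect_false("gC" %in% out$gene_id)
  none <- summarize_cross_tissue(list(mk("gA", "up"), mk("gB", "down")))
  expect_equal(nrow(none), 0)
  expect_error(summarize_cross_tissue(res[1]), ">= 2")
})
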