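manual_factors <- function(values) {
  structure(list(values = values,
                 loadings = matrix(numeric(0), 0, 0),
                 var_explained = rep(NA_real_, nrow(values)),
                 retained = rep(TRUE, nrow(values)),
                 pearson_p = rep(NA_real_, nrow(values)),
                 spearman_p = rep(NA_real_, nrow(values))),
            class = "pmi_factors")
}

test_that("a planted rank-1 confounder is recovered as factor 1", {
  set.seed(21)
  n <- 120; G <- 300
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  conf <- rnorm(n)
  load <- rnorm(G, 0, 1)
  Y <- outer(load, conf) + matrix(rnorm(G * n, 0, 0.5), G, n)
  dimnames(Y) <- list(sprintf("g%03d", 1:G), smp$sample_id)
  f <- infer_hidden_factors(toy_expr(Y), smp, k = 5)
  expect_gt(abs(cor(f$values[1, ], conf)), 0.95)
  expect_true(all(diff(f$var_explained) <= 1e-12))
  # sign convention: largest-magnitude loading is positive
  expect_gt(f$loadings[1, which.max(abs(f$loadings[1, ]))], 0)
})

test_that("factor count edge cases behave", {
  smp <- toy_samples(20)
  Y <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), smp$sample_id))
  f0 <- infer_hidden_factors(toy_expr(Y), smp, k = 0)
  expect_equal(nrow(f0$values), 0)
  expect_error(infer_hidden_factors(toy_expr(Y), smp, k = 20), "smaller")
})

test_that("PMI screening drops linear, rank-only and keeps null factors", {
  n <- 8
  pmi <- seq(100, 1500, length.out = n)
  vals <- rbind(pmi,                      # identical to PMI -> Pearson kills
                (pmi / 100)^12,           # rank-perfect, linearly weak
                c(0.3, -1, 2, 0.1, -0.7, 1.2, -0.2, 0.5))  # unrelated
  rownames(vals) <- c("f_lin", "f_rank", "f_null")
  f <- filter_factors_by_pmi(manual_factors(vals), pmi)
  expect_false(f$retained[1])
  expect_lt(f$pearson_p[1], 1e-10)
  # the rank-perfect factor is excluded via Spearman even though Pearson
  # alone would let it through
  expect_gte(f$pearson_p[2], 0.05)
  expect_lt(f$spearman_p[2], 0.05)
  expect_false(f$retained[2])
  expect_true(f$retained[3])
  expect_error(filter_factors_by_pmi(manual_factors(vals), pmi[-1]),
               "length|match")
})

test_that("an unrelated factor is retained at roughly (0.95)^2 frequency", {
  set.seed(31)
  n <- 150
  pmi <- runif(n, 60, 1620)
  kept <- vapply(1:300, function(i) {
    v <- matrix(rnorm(n), 1, dimnames = list("f1", NULL))
    filter_factors_by_pmi(manual_factors(v), pmi)$retained[1]
  }, logical(1))
  expect_gt(mean(kept), 0.85)
  expect_lt(mean(kept), 0.975)
})

test_that("residualisation removes covariates but preserves the PMI slope", {
  set.seed(41)
  n <- 100
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  smp$age <- sample(21:70, n, replace = TRUE)
  Y <- rbind(age_gene = 3 * smp$age + rnorm(n, 0, 0.5),
             pmi_gene = 2 * smp$pmi_min + rnorm(n, 0, 0.5),
             flat_gene = rep(7, n))
  colnames(Y) <- smp$sample_id
  r <- residualize(toy_expr(Y), smp)
  expect_identical(expr_stage(r), "residual")
  expect_lt(abs(cor(unclass(r)["age_gene", ], smp$age)), 1e-8)
  slope <- coef(lm(unclass(r)["pmi_gene", ] ~ smp$pmi_min))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
  expect_equal(unclass(r)["flat_gene", ], setNames(rep(0, n), smp$sample_id))
})

test_that("residuals are orthogonal to every retained regressor", {
  ds <- make_dataset(n_genes = 80, n_samples = 90, seed = 17)
  ex <- log2_expr(ds)
  f <- fit_factors(ex, ds$samples, k = 6)
  r <- residualize(ex, ds$samples, f)
  regs <- cbind(age = ds$samples$age, gender = ds$samples$gender,
                bmi = ds$samples$bmi,
                t(f$values[f$retained, , drop = FALSE]))
  expect_lt(max(abs(cor(t(unclass(r)), regs))), 1e-6)
})

test_that("excluding a PMI-tilted confounder inflates the null PMI test", {
  # documents the cost of the two-step screen: a real confounder whose
  # chance in-sample PMI correlation triggers exclusion leaves its
  # PMI-aligned component uncorrected in every gene
  set.seed(47)
  n <- 150; G <- 800
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  conf <- scale(smp$pmi_min)[, 1] * 0.25 + rnorm(n) # tilted towards PMI
  Y <- outer(rnorm(G, 0, 0.5), conf) + matrix(rnorm(G * n), G, n)
  dimnames(Y) <- list(sprintf("g%03d", 1:G), smp$sample_id)
  ex <- toy_expr(Y)
  f <- fit_factors(ex, smp, k = 5)
  expect_false(f$retained[1])           # the screen drops the confounder
  a_without <- run_association(ex, smp, f)
  expect_gt(mean(a_without$table$p_value < 0.05), 0.06)
  # keeping the factor in the design restores calibration
  f$retained[1] <- TRUE
  a_with <- run_association(ex, smp, f)
  expect_lt(abs(mean(a_with$table$p_value < 0.05) - 0.05), 0.02)
})

test_that("alpha estimates agree between residual-based and full fits", {
  ds <- make_dataset(n_genes = 150, n_samples = 150, frac_pmi_genes = 0.2,
                     seed = 19)
  ex <- log2_expr(ds)
  f <- fit_factors(ex, ds$samples, k = 8)
  full <- run_association(ex, ds$samples, f)
  r <- residualize(ex, ds$samples, f)
  resid_fit <- run_association(r, ds$samples, NULL)
  within2se <- abs(full$table$alpha - resid_fit$table$alpha) <=
    2 * full$table$alpha_se
  expect_gte(mean(within2se), 0.95)
})
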