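toy_geno <- function(codes, donors = sprintf("d%02d", seq_len(ncol(codes)))) {
  dimnames(codes) <- list(sprintf("rs%d", seq_len(nrow(codes))), donors)
  geno_matrix(codes)
}

test_that("MAF is computed by allele counting and filters correctly", {
  g <- toy_geno(matrix(c(0, 0, 1, 2, 1,   # f = 4/10 = 0.4
                         0, 0, 0, 0, 0,   # monomorphic
                         1, 1, 1, 1, 1),  # all het, f = 0.5
                       nrow = 3, byrow = TRUE))
  maf <- snp_maf(g)
  expect_equal(unname(maf), c(0.4, 0, 0.5))
  kept <- filter_snps_by_maf(g, 0.15)
  expect_equal(rownames(kept), c("rs1", "rs3"))
  expect_error(filter_snps_by_maf(toy_geno(matrix(numeric(0), 0, 5)), 0.15),
               "empty")
})

test_that("MAF is invariant under allele-label swap", {
  set.seed(61)
  for (i in 1:50) {
    codes <- matrix(sample(0:2, 40, TRUE), 4, 10)
    g1 <- toy_geno(codes)
    g2 <- toy_geno(2 - codes)
    expect_equal(snp_maf(g1), snp_maf(g2))
  }
})

test_that("the Bonferroni-scale threshold reproduces the printed cutoff", {
  expect_equal(signif(interaction_threshold(0.05, 1051649), 3), 4.75e-8)
  expect_equal(interaction_threshold(0.05, 1), 0.05)
  expect_equal(interaction_threshold(0.05, 1000), 5e-5)
  expect_error(interaction_threshold(0.05, 0), "positive")
})

test_that("a strong genotype-dependent slope crossover is detected", {
  set.seed(71)
  n <- 180
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  codes <- sample(0:2, n, TRUE, prob = c(0.36, 0.48, 0.16))
  # code 0: +0.01/min, code 2: -0.01/min
  y <- 8 + (0.01 - 0.01 * codes) * (smp$pmi_min - 840) + rnorm(n, 0, 0.5)
  fit <- fit_interaction_model(y, codes, smp)
  expect_lt(fit$p_value, 4.75e-8)
  expect_equal(fit$interaction_beta, -0.01, tolerance = 0.15)
  # monomorphic SNP is skipped
  expect_message(out <- fit_interaction_model(y, rep(1, n), smp),
                 "monomorphic")
  expect_null(out)
})

test_that("the product-term test is calibrated under a genotype-main-effect null", {
  set.seed(73)
  n <- 150
  smp <- toy_samples(n, pmi = runif(n, 60, 1620))
  codes <- sample(0:2, n, TRUE, prob = c(0.49, 0.42, 0.09))
  G <- 2000
  Y <- outer(rnorm(G, 0, 0.5), codes) + matrix(rnorm(G * n), G, n)
  dimnames(Y) <- list(sprintf("g%04d", 1:G), smp$sample_id)
  X <- pmidecay:::build_design(smp, NULL, include_pmi = TRUE)
  X <- cbind(X, snp = codes, `pmi:snp` = smp$pmi_min * codes)
  fit <- pmidecay:::ols_term_test(Y, X, "pmi:snp")
  expect_gte(mean(fit$p < 0.05), 0.04)
  expect_lte(mean(fit$p < 0.05), 0.06)
})

test_that("the scan flags planted pairs and respects the seed", {
  ds <- make_dataset(n_genes = 80, n_samples = 180, frac_pmi_genes = 0,
                     n_snps = 40, n_interaction_pairs = 8,
                     interaction_slope_sd = 1.5, noise_sd = 0.5, seed = 33)
  ex <- log2_expr(ds)
  sc <- scan_interactions(ex, ds$samples, NULL, ds$genotypes,
                          n_genes_subsample = 80, seed = 5)
  tkey <- with(ds$truth$true_interactions, paste(gene_id, snp_id))
  planted <- sc[paste(sc$gene_id, sc$snp_id) %in% tkey, ]
  expect_gte(sum(planted$significant), 0.8 * length(tkey))
  # estimated interaction sign matches the planted sign for detected pairs
  det <- planted[planted$significant, ]
  tr <- ds$truth$true_interactions
  tsign <- sign(tr$interaction_beta[match(paste(det$gene_id, det$snp_id),
                                          paste(tr$gene_id, tr$snp_id))])
  expect_gte(mean(sign(det$interaction_beta) == tsign), 0.95)
  # pairs on genes with no planted interaction flag at about the expected
  # Bonferroni-scale rate (planted genes are excluded: their omitted true
  # interaction inflates product-term tests against other SNPs); allow
  # generous Poisson slack since tests share genes and SNPs
  clean <- !(sc$gene_id %in% tr$gene_id)
  expected <- sum(clean) * attr(sc, "threshold")
  expect_lte(sum(sc$significant[clean]), expected + 4 * sqrt(expected + 1) + 2)
  sc2 <- scan_interactions(ex, ds$samples, NULL, ds$genotypes,
                           n_genes_subsample = 20, seed = 9)
  sc3 <- scan_interactions(ex, ds$samples, NULL, ds$genotypes,
                           n_genes_subsample = 20, seed = 9)
  expect_identical(unique(sc2$gene_id), unique(sc3$gene_id))
})

test_that("validation requires replication plus the permutation check", {
  cfg <- sim_config(n_genes = 40, n_samples = 150, frac_pmi_genes = 0,
                    n_snps = 20, n_interaction_pairs = 3,
                    interaction_slope_sd = 2, noise_sd = 0.5, seed = 81)
  ds1 <- simulate_dataset(cfg)
  # second tissue: same donors/genotypes, same planted interactions
  cfg2 <- cfg; cfg2$seed <- 82L; cfg2$tissue <- "tissue2"
  ds2 <- simulate_dataset(cfg2, genotypes = ds1$genotypes,
                          interactions = ds1$truth$true_interactions)
  # third tissue: same genotypes, interactions NOT planted
  cfg3 <- cfg; cfg3$seed <- 83L; cfg3$n_interaction_pairs <- 0L
  ds3 <- simulate_dataset(cfg3, genotypes = ds1$genotypes)

  ex1 <- log2_expr(ds1)
  sc <- scan_interactions(ex1, ds1$samples, NULL, ds1$genotypes,
                          n_genes_subsample = 40, seed = 5)
  hits <- sc[sc$significant, ]
  tkey <- with(ds1$truth$true_interactions, paste(gene_id, snp_id))
  hits <- hits[paste(hits$gene_id, hits$snp_id) %in% tkey, ]
  expect_gt(nrow(hits), 0)
  disc <- list(expression = ex1, samples = ds1$samples, factors = NULL,
               genotypes = ds1$genotypes)
  oth_planted <- list(list(expression = log2_expr(ds2),
                           samples = ds2$samples, factors = NULL,
                           genotypes = ds2$genotypes))
  oth_null <- list(list(expression = log2_expr(ds3), samples = ds3$samples,
                        factors = NULL, genotypes = ds3$genotypes))
  v1 <- validate_interactions(hits, disc, oth_planted, n_perm = 200,
                              pass_cutoff = 10, seed = 3)
  expect_true(all(v1$validated))
  v2 <- validate_interactions(hits, disc, oth_null, n_perm = 200,
                              pass_cutoff = 10, seed = 3)
  expect_false(any(v2$validated))
  # a zero pass cutoff can never validate
  v3 <- validate_interactions(hits, disc, oth_planted, n_perm = 200,
                              pass_cutoff = 0, seed = 3)
  expect_false(any(v3$validated))
  expect_error(validate_interactions(hits, disc, list()), "other tissue")
})
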