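#' Minor-allele-frequency filter
#'
#' Retains SNPs whose MAF (computed as `min(f, 1 - f)` with
#' `f = sum(codes) / (2 * n_donors)`) is at least `min_maf`.
#'
#' @param genotypes a [geno_matrix()].
#' @param min_maf MAF threshold (default 0.15).
#' @return the filtered genotype matrix.
#' @export
filter_snps_by_maf <- function(genotypes, min_maf = 0.15) {
  if (nrow(genotypes) == 0) stop("empty genotype matrix")
  maf <- snp_maf(genotypes)
  geno_matrix(unclass(genotypes)[maf >= min_maf, , drop = FALSE])
}

#' Bonferroni-scale interaction significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of retained SNPs tested.
#' @return `alpha / n_tests`.
#' @export
interaction_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  alpha / n_tests
}

# map donor-level genotype codes onto samples via donor_id; NA for samples
# whose donor is absent from the genotype table
snp_codes_for_samples <- function(genotypes, samples, snp_id) {
  unclass(genotypes)[snp_id, match(samples$donor_id, colnames(genotypes))]
}

#' Fit the genotype-by-PMI interaction model for one gene/SNP pair
#'
#' Extends the PMI regression with an additive genotype main effect and a
#' PMI-by-genotype product term; the product-term coefficient (slope change
#' per alternative allele per minute) is tested with a two-sided t-test.
#'
#' @param expr_gene per-sample expression vector.
#' @param snp_codes per-sample genotype codes in \{0, 1, 2\}.
#' @param samples aligned sample table.
#' @param factors factor set or `NULL`.
#' @return one-row data.frame `interaction_beta`, `se`, `t_stat`, `p_value`;
#'   `NULL` (with a message) if the SNP is monomorphic in these samples.
#' @export
fit_interaction_model <- function(expr_gene, snp_codes, samples,
                                  factors = NULL) {
  if (length(unique(snp_codes)) < 2) {
    message("SNP is monomorphic in the analysed samples; skipped")
    return(NULL)
  }
  X <- build_design(samples, factors, include_pmi = TRUE)
  X <- cbind(X, snp = snp_codes, `pmi:snp` = samples$pmi_min * snp_codes)
  Y <- matrix(expr_gene, nrow = 1,
              dimnames = list("gene", samples$sample_id))
  fit <- ols_term_test(Y, X, "pmi:snp")
  data.frame(interaction_beta = unname(fit$estimate), se = unname(fit$se),
             t_stat = unname(fit$t), p_value = unname(fit$p))
}

#' Scan genes x SNPs for genotype-by-PMI interactions
#'
#' Tests every MAF-retained SNP against a seeded random subsample of genes;
#' pairs with product-term p below `interaction_threshold(alpha, n_snps)`
#' are flagged significant.
#'
#' @param expr normalized-stage expression matrix.
#' @param samples aligned sample table.
#' @param factors factor set or `NULL`.
#' @param genotypes [geno_matrix()] (donor-level); samples from donors
#'   absent here are dropped with a message.
#' @param n_genes_subsample genes to test (default 2000; capped at the
#'   matrix size).
#' @param min_maf MAF filter threshold (default 0.15).
#' @param alpha family-wise level for the threshold (default 0.05).
#' @param seed seed for the gene subsample.
#' @return data.frame `gene_id`, `snp_id`, `interaction_beta`, `p_value`,
#'   `maf`, `significant`, plus attributes `threshold` and `n_snps_retained`.
#' @export
scan_interactions <- function(expr, samples, factors = NULL, genotypes,
                              n_genes_subsample = 2000, min_maf = 0.15,
                              alpha = 0.05, seed = 1L) {
  if (expr_stage(expr) == "raw")
    stop("interaction scan expects normalized-stage expression")
  geno <- filter_snps_by_maf(genotypes, min_maf)
  maf <- snp_maf(geno)
  have_geno <- samples$donor_id %in% colnames(geno)
  if (!all(have_geno)) {
    message(sum(!have_geno), " sample(s) lack genotypes and are dropped")
    samples <- samples[have_geno, , drop = FALSE]
    expr <- expr_matrix(unclass(expr)[, samples$sample_id, drop = FALSE],
                        expr_stage(expr))
    factors <- subset_factors(factors, which(have_geno))
  }
  genes <- rownames(expr)
  if (n_genes_subsample < length(genes))
    genes <- with_seed(seed, sort(sample(genes, n_genes_subsample)))
  Y <- unclass(expr)[genes, , drop = FALSE]
  thr <- interaction_threshold(alpha, nrow(geno))
  base <- build_design(samples, factors, include_pmi = TRUE)
  out <- vector("list", nrow(geno))
  for (s in seq_len(nrow(geno))) {
    codes <- snp_codes_for_samples(geno, samples, rownames(geno)[s])
    if (length(unique(codes)) < 2) next
    X <- cbind(base, snp = codes, `pmi:snp` = samples$pmi_min * codes)
    fit <- ols_term_test(Y, X, "pmi:snp")
    out[[s]] <- data.frame(gene_id = genes, snp_id = rownames(geno)[s],
                           interaction_beta = unname(fit$estimate),
                           p_value = unname(fit$p),
                           maf = unname(maf[s]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), snp_id = character(0),
                      interaction_beta = numeric(0), p_value = numeric(0),
                      maf = numeric(0))
  res$significant <- res$p_value < thr
  attr(res, "threshold") <- thr
  attr(res, "n_snps_retained") <- nrow(geno)
  res
}

#' Cross-tissue validation of interaction hits
#'
#' A discovery-tissue interaction is `validated` when (a) its product term
#' is nominally significant (p < `alpha_other`) in at least one other
#' tissue, and (b) it survives a PMI-permutation check in the discovery
#' tissue (fewer than `pass_cutoff` of `n_perm` permutations beat the
#' original p-value).
#'
#' @param records rows of [scan_interactions()] output to validate
#'   (typically the significant ones).
#' @param discovery list with `expression`, `samples`, `factors`,
#'   `genotypes` for the discovery tissue.
#' @param others list of such lists for the other tissues.
#' @param alpha_other nominal level in other tissues (default 0.05).
#' @param n_perm permutations (default 10000).
#' @param pass_cutoff maximum admissible permutation count (default 500).
#' @param seed permutation seed.
#' @return `records` with `perm_count`, `replicated`, `validated` columns.
#' @export
validate_interactions <- function(records, discovery, others,
                                  alpha_other = 0.05, n_perm = 10000,
                                  pass_cutoff = 500, seed = 1L) {
  if (length(others) < 1) stop("need at least one other tissue dataset")
  if (nrow(records) == 0) {
    records$perm_count <- integer(0)
    records$replicated <- logical(0)
    records$validated <- logical(0)
    return(records)
  }
  records$replicated <- FALSE
  for (oth in others) {
    for (r in seq_len(nrow(records))) {
      if (records$replicated[r]) next
      g <- records$gene_id[r]
      if (!(g %in% rownames(oth$expression)) ||
          !(records$snp_id[r] %in% rownames(oth$genotypes))) next
      codes <- snp_codes_for_samples(oth$genotypes, oth$samples,
                                     records$snp_id[r])
      if (anyNA(codes)) next
      fit <- fit_interaction_model(unclass(oth$expression)[g, ], codes,
                                   oth$samples, oth$factors)
      if (!is.null(fit) && fit$p_value < alpha_other)
        records$replicated[r] <- TRUE
    }
  }
  records$perm_count <- vapply(seq_len(nrow(records)), function(r) {
    interaction_perm_count(records$gene_id[r], records$snp_id[r], discovery,
                           n_perm, seed)
  }, integer(1))
  records$validated <- records$replicated & records$perm_count < pass_cutoff
  records
}

# permutation count for one (gene, SNP) product term in the discovery tissue:
# permute PMI (main effect and product both move), refit, compare |t|
interaction_perm_count <- function(gene_id, snp_id, discovery, n_perm, seed) {
  smp <- discovery$samples
  codes <- snp_codes_for_samples(discovery$genotypes, smp, snp_id)
  y <- matrix(unclass(discovery$expression)[gene_id, ], nrow = 1,
              dimnames = list(gene_id, smp$sample_id))
  base <- build_design(smp, discovery$factors, include_pmi = FALSE)
  tstat_for <- function(pmi) {
    X <- cbind(base, pmi = pmi, snp = codes, `pmi:snp` = pmi * codes)
    abs(ols_term_test(y, X, "pmi:snp")$t)
  }
  t_obs <- tstat_for(smp$pmi_min)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(smp$pmi_min),
           numeric(nrow(smp)))
  })
  sum(vapply(seq_len(n_perm), function(i) tstat_for(perms[, i]),
             numeric(1)) > t_obs + 1e-12)
}
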