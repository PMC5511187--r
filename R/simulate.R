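#' Simulation configuration
#'
#' Defines a GTEx-like single-tissue simulation with known ground truth.
#' Expression is simulated on the log2 scale as
#' baseline + alpha * PMI + covariate effects + hidden-factor effects +
#' genotype-by-PMI terms + Gaussian noise, then emitted as `2^x - 1`
#' (clipped at 0) so that the preprocessing `log2(x + 1)` recovers the
#' simulated scale.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples (one donor per sample).
#' @param pmi_range `(min, max)` postmortem interval in minutes; the default
#'   60--1620 spans 1--27 hours. PMI is drawn uniformly over the range.
#' @param n_hidden_factors number of hidden confounding factors (<= 15).
#' @param frac_pmi_genes fraction of genes with a true nonzero PMI slope.
#' @param effect_size_sd scale of true PMI slopes, in residual-SD units per
#'   hour: slopes are drawn `N(0, (effect_size_sd * noise_sd / 60)^2)` per
#'   minute.
#' @param frac_dv_genes fraction of genes that are differentially variable
#'   between the short- and long-PMI halves.
#' @param dv_variance_ratio ratio of long-PMI to short-PMI residual variance
#'   for "increase" DV genes (inverted for "decrease" genes).
#' @param frac_dv_increase fraction of DV genes whose variance increases with
#'   PMI; the remainder decrease.
#' @param n_snps number of simulated SNPs; per-SNP alternative-allele
#'   frequencies are uniform on (0.15, 0.5) and genotypes are Hardy-Weinberg
#'   draws, so every SNP clears a 15% MAF filter by construction.
#' @param n_interaction_pairs number of planted (gene, SNP) genotype-by-PMI
#'   interaction pairs.
#' @param interaction_slope_sd scale of the per-allele PMI-slope change, in
#'   residual-SD units per hour per alternative allele.
#' @param noise_sd residual (log2-scale) noise standard deviation.
#' @param tissue tissue label written into the sample table.
#' @param seed integer seed; fully determines the generated dataset.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, n_samples = 150,
                       pmi_range = c(60, 1620), n_hidden_factors = 5,
                       frac_pmi_genes = 0.1, effect_size_sd = 1,
                       frac_dv_genes = 0.05, dv_variance_ratio = 4,
                       frac_dv_increase = 0.5,
                       n_snps = 100, n_interaction_pairs = 0,
                       interaction_slope_sd = 1, noise_sd = 1,
                       tissue = "tissue1", seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples, pmi_range = pmi_range,
              n_hidden_factors = n_hidden_factors,
              frac_pmi_genes = frac_pmi_genes, effect_size_sd = effect_size_sd,
              frac_dv_genes = frac_dv_genes,
              dv_variance_ratio = dv_variance_ratio,
              frac_dv_increase = frac_dv_increase,
              n_snps = n_snps, n_interaction_pairs = n_interaction_pairs,
              interaction_slope_sd = interaction_slope_sd, noise_sd = noise_sd,
              tissue = tissue, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
      stop(sprintf("invalid configuration field '%s': must be a count >= 0", nm))
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid configuration field '%s': must be in [0, 1]", nm))
  }
  chk_pos <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x <= 0)
      stop(sprintf("invalid configuration field '%s': must be positive", nm))
  }
  for (nm in c("n_genes", "n_samples", "n_hidden_factors", "n_snps",
               "n_interaction_pairs"))
    chk_count(cfg[[nm]], nm)
  for (nm in c("frac_pmi_genes", "frac_dv_genes", "frac_dv_increase"))
    chk_frac(cfg[[nm]], nm)
  for (nm in c("effect_size_sd", "dv_variance_ratio", "interaction_slope_sd",
               "noise_sd"))
    chk_pos(cfg[[nm]], nm)
  if (length(cfg$pmi_range) != 2 || cfg$pmi_range[1] >= cfg$pmi_range[2] ||
      cfg$pmi_range[1] < 0)
    stop("invalid configuration field 'pmi_range': need 0 <= min < max")
  if (cfg$n_interaction_pairs > 0 &&
      (cfg$n_snps < 1 || cfg$n_genes < 1))
    stop("invalid configuration field 'n_interaction_pairs': needs genes and SNPs")
  invisible(cfg)
}

#' Generate a synthetic PMI-expression dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @param genotypes optional pre-existing genotype matrix (SNP x donor) to
#'   reuse, e.g. when simulating a second tissue on the same donors.
#' @param interactions optional data.frame `(gene_id, snp_id,
#'   interaction_beta)` to re-plant the same interaction triples in another
#'   tissue.
#' @return a list with elements `expression` (raw-stage [expr_matrix()],
#'   RPKM-like), `samples` (covariate data.frame), `genotypes`
#'   ([geno_matrix()]) and `truth` (list with `true_alpha` per-minute slopes,
#'   `true_dv_flag` in \{none, increase, decrease\}, `true_interactions`,
#'   `hidden_factor_loadings`, `factor_values`).
#' @export
simulate_dataset <- function(config, genotypes = NULL, interactions = NULL) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config, genotypes, interactions))
}

simulate_dataset_impl <- function(cfg, genotypes, interactions) {
  G <- cfg$n_genes; n <- cfg$n_samples
  gene_ids <- sprintf("gene_%04d", seq_len(G))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  donor_ids <- sprintf("donor_%03d", seq_len(n))

  pmi <- stats::runif(n, cfg$pmi_range[1], cfg$pmi_range[2])
  age <- sample(21:70, n, replace = TRUE)
  gender <- stats::rbinom(n, 1, 0.5)
  bmi <- pmin(pmax(stats::rnorm(n, 27, 4), 15), 45)
  rin <- stats::runif(n, 6.5, 10)
  samples <- data.frame(sample_id = sample_ids, donor_id = donor_ids,
                        tissue = cfg$tissue, pmi_min = pmi, age = age,
                        gender = gender, bmi = bmi, rin = rin,
                        stringsAsFactors = FALSE)

  if (is.null(genotypes)) {
    if (cfg$n_snps > 0) {
      f <- stats::runif(cfg$n_snps, 0.15, 0.5)
      codes <- matrix(as.double(stats::rbinom(cfg$n_snps * n, 2, rep(f, n))),
                      nrow = cfg$n_snps, ncol = n,
                      dimnames = list(sprintf("snp_%04d", seq_len(cfg$n_snps)),
                                      donor_ids))
      genotypes <- geno_matrix(codes)
    } else {
      genotypes <- geno_matrix(matrix(numeric(0), 0, n,
                                      dimnames = list(NULL, donor_ids)))
    }
  }

  # per-gene true PMI slopes (per minute); effect_size_sd is per hour
  n_pmi <- round(cfg$frac_pmi_genes * G)
  true_alpha <- numeric(G)
  if (n_pmi > 0) {
    idx <- sample.int(G, n_pmi)
    true_alpha[idx] <- stats::rnorm(n_pmi, 0,
                                    cfg$effect_size_sd * cfg$noise_sd / 60)
  }

  # covariate effects (modest, of both signs)
  beta_age <- stats::rnorm(G, 0, 0.005)
  gamma_bmi <- stats::rnorm(G, 0, 0.01)
  delta_gender <- stats::rnorm(G, 0, 0.2)

  # hidden confounders: factor values per sample, loadings per gene
  K <- cfg$n_hidden_factors
  fac_vals <- matrix(stats::rnorm(K * n), nrow = K, ncol = n,
                     dimnames = list(if (K > 0) sprintf("hidden_%02d", 1:K),
                                     sample_ids))
  loadings <- matrix(stats::rnorm(K * G, 0, 0.5), nrow = K, ncol = G,
                     dimnames = list(rownames(fac_vals), gene_ids))

  # differential-variability genes: noise SD scaled by sqrt(ratio) in one half
  n_dv <- round(cfg$frac_dv_genes * G)
  dv_flag <- rep("none", G)
  if (n_dv > 0) {
    pool <- setdiff(seq_len(G), which(true_alpha != 0))
    if (length(pool) < n_dv) pool <- seq_len(G)
    dv_idx <- sample(pool, n_dv)
    n_inc <- round(cfg$frac_dv_increase * n_dv)
    dv_flag[dv_idx] <- rep(c("increase", "decrease"),
                           c(n_inc, n_dv - n_inc))[sample.int(n_dv)]
  }
  long_half <- pmi > stats::median(pmi)

  # planted genotype-by-PMI interactions (per allele per minute)
  if (is.null(interactions)) {
    if (cfg$n_interaction_pairs > 0) {
      gi <- sample(gene_ids, cfg$n_interaction_pairs,
                   replace = cfg$n_interaction_pairs > G)
      # draw interaction SNPs only from those whose realised MAF clears the
      # downstream 15% filter, so planted pairs are always testable
      cand <- rownames(genotypes)[snp_maf(genotypes) >= 0.15]
      if (length(cand) == 0) cand <- rownames(genotypes)
      si <- sample(cand, cfg$n_interaction_pairs,
                   replace = cfg$n_interaction_pairs > length(cand))
      interactions <- data.frame(
        gene_id = gi, snp_id = si,
        interaction_beta = stats::rnorm(cfg$n_interaction_pairs, 0,
                                        cfg$interaction_slope_sd * cfg$noise_sd / 60),
        stringsAsFactors = FALSE)
    } else {
      interactions <- data.frame(gene_id = character(0), snp_id = character(0),
                                 interaction_beta = numeric(0))
    }
  }

  # baseline = log2 expression at the PMI-range midpoint, so that genes with
  # strong slopes stay on a realistic abundance scale across the whole range
  # (the intercept absorbs the reparameterisation; true_alpha is unchanged)
  pmi_mid <- mean(cfg$pmi_range)
  mu <- stats::rnorm(G, 8, 2)
  Y <- matrix(mu, G, n) +
    outer(true_alpha, pmi - pmi_mid) +
    outer(beta_age, age) +
    outer(gamma_bmi, bmi) +
    outer(delta_gender, gender) +
    (if (K > 0) crossprod(loadings, fac_vals) else 0)

  if (nrow(interactions) > 0) {
    for (r in seq_len(nrow(interactions))) {
      g <- match(interactions$gene_id[r], gene_ids)
      codes <- genotypes[interactions$snp_id[r], donor_ids]
      Y[g, ] <- Y[g, ] +
        interactions$interaction_beta[r] * codes * (pmi - pmi_mid) +
        stats::rnorm(1, 0, 0.3) * codes   # small genotype main effect
    }
  }

  sd_mat <- matrix(cfg$noise_sd, G, n)
  inc <- dv_flag == "increase"; dec <- dv_flag == "decrease"
  if (any(inc)) sd_mat[inc, long_half] <- cfg$noise_sd * sqrt(cfg$dv_variance_ratio)
  if (any(dec)) sd_mat[dec, !long_half] <- cfg$noise_sd * sqrt(cfg$dv_variance_ratio)
  Y <- Y + matrix(stats::rnorm(G * n), G, n) * sd_mat
  dimnames(Y) <- list(gene_ids, sample_ids)

  rpkm <- pmax(2^Y - 1, 0)
  truth <- list(true_alpha = stats::setNames(true_alpha, gene_ids),
                true_dv_flag = stats::setNames(dv_flag, gene_ids),
                true_interactions = interactions,
                hidden_factor_loadings = loadings,
                factor_values = fac_vals)
  list(expression = expr_matrix(rpkm, "raw"), samples = samples,
       genotypes = genotypes, truth = truth)
}

#' Write a simulated dataset to TSV fixture files
#'
#' Writes `expression.tsv` (first column `gene_id`, one column per sample),
#' `samples.tsv`, `genotypes.tsv` (first column `snp_id`, one column per
#' donor), `truth_genes.tsv` and `truth_interactions.tsv` into `directory`.
#' The files round-trip through [read_expression()], [read_samples()] and
#' [read_genotypes()].
#'
#' @param dataset output of [simulate_dataset()].
#' @param directory output directory (created if absent).
#' @return invisibly, the named character vector of file paths.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", directory)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             samples = file.path(directory, "samples.tsv"),
             genotypes = file.path(directory, "genotypes.tsv"),
             truth_genes = file.path(directory, "truth_genes.tsv"),
             truth_interactions = file.path(directory, "truth_interactions.tsv"))
  write_matrix_tsv(dataset$expression, paths["expression"], "gene_id")
  write_tsv(dataset$samples, paths["samples"], digits = 10)
  write_matrix_tsv(dataset$genotypes, paths["genotypes"], "snp_id")
  tg <- data.frame(gene_id = names(dataset$truth$true_alpha),
                   true_alpha = dataset$truth$true_alpha,
                   true_dv_flag = dataset$truth$true_dv_flag,
                   stringsAsFactors = FALSE)
  write_tsv(tg, paths["truth_genes"], digits = 10)
  write_tsv(dataset$truth$true_interactions, paths["truth_interactions"],
            digits = 10)
  invisible(paths)
}
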