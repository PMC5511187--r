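#' Fit the per-gene PMI regression for a single gene
#'
#' Ordinary least squares of expression on intercept, PMI, age, gender, BMI
#' and the retained hidden factors; the PMI coefficient (alpha, expression
#' units per minute) is tested against zero with a two-sided t-test on
#' `n - p` residual degrees of freedom.
#'
#' @param expr_gene numeric vector of per-sample expression for one gene.
#' @param samples aligned sample table.
#' @param factors a (filtered) factor set, or `NULL`.
#' @return one-row data.frame: `alpha`, `alpha_se`, `t_stat`, `p_value`.
#' @export
fit_pmi_model <- function(expr_gene, samples, factors = NULL) {
  Y <- matrix(expr_gene, nrow = 1,
              dimnames = list("gene", samples$sample_id))
  X <- build_design(samples, factors, include_pmi = TRUE)
  fit <- ols_term_test(Y, X, "pmi")
  data.frame(alpha = unname(fit$estimate), alpha_se = unname(fit$se),
             t_stat = unname(fit$t), p_value = unname(fit$p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], monotone in p-rank.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation gate for one gene
#'
#' Permutes the sample PMI (all other covariates fixed), refits the model,
#' and counts how many permutations yield a smaller p-value than the
#' original fit. A gene passes the gate when that count is below
#' `pass_cutoff` (default 500 of 10,000).
#'
#' @param expr_gene per-sample expression vector.
#' @param samples aligned sample table.
#' @param factors factor set or `NULL`.
#' @param n_perm number of permutations (default 10000).
#' @param pass_cutoff maximum admissible count (default 500).
#' @param seed integer seed for the permutation set.
#' @return list with `perm_count` and `perm_pass`.
#' @export
permutation_gate <- function(expr_gene, samples, factors = NULL,
                             n_perm = 10000, pass_cutoff = 500, seed = 1L) {
  Y <- matrix(expr_gene, nrow = 1,
              dimnames = list("gene", samples$sample_id))
  cnt <- permutation_counts(Y, samples, factors, n_perm, seed)
  list(perm_count = cnt[[1]], perm_pass = cnt[[1]] < pass_cutoff)
}

# shared vectorised permutation engine: counts, per gene, permutations whose
# PMI |t| exceeds the observed |t| (equivalent to p_perm < p_original since
# both p-values share the same residual df)
permutation_counts <- function(Y, samples, factors, n_perm, seed) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  X <- build_design(samples, factors, include_pmi = TRUE)
  X <- drop_collinear(X, protect = "pmi")
  n <- nrow(X)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(samples$pmi_min), numeric(n))
  })
  t_obs <- perm_tstats(Y, X, matrix(samples$pmi_min, ncol = 1))[, 1]
  t_perm <- perm_tstats(Y, X, perms)
  as.integer(rowSums(t_perm > t_obs + 1e-12))
}

#' Genome-wide PMI association with FDR control and permutation gate
#'
#' Fits the PMI regression for every gene, adjusts p-values by
#' Benjamini-Hochberg, assigns up/down direction at the requested FDR, and
#' applies the permutation gate to the FDR-significant genes.
#'
#' @param expr normalized-stage expression matrix.
#' @param samples aligned sample table.
#' @param factors a (filtered) factor set, or `NULL`.
#' @param fdr FDR threshold for calling genes (default 0.05).
#' @param n_perm permutations for the gate; 0 disables the gate.
#' @param pass_cutoff permutation-count cutoff scaled to `n_perm`
#'   (default `round(0.05 * n_perm)`, i.e. 500 of 10,000).
#' @param seed permutation seed.
#' @return a `pmi_association` list: `table` (per-gene results: `gene_id`,
#'   `alpha`, `alpha_se`, `t_stat`, `p_value`, `q_value`, `direction`,
#'   `perm_count`, `perm_pass`), `counts` (up/down/total at FDR 1/5/10%,
#'   pre- and post-gate), `fdr`.
#' @export
run_association <- function(expr, samples, factors = NULL, fdr = 0.05,
                            n_perm = 0, pass_cutoff = round(0.05 * n_perm),
                            seed = 1L) {
  if (expr_stage(expr) == "raw")
    stop("association expects normalized-stage expression")
  if (!identical(colnames(expr), samples$sample_id))
    stop("expression columns and sample table rows are not aligned")
  X <- build_design(samples, factors, include_pmi = TRUE)
  fit <- ols_term_test(unclass(expr), X, "pmi")
  q <- bh_adjust(fit$p)
  direction <- rep("null", nrow(expr))
  direction[q <= fdr & fit$estimate > 0] <- "up"
  direction[q <= fdr & fit$estimate < 0] <- "down"
  tab <- data.frame(gene_id = rownames(expr), alpha = unname(fit$estimate),
                    alpha_se = unname(fit$se), t_stat = unname(fit$t),
                    p_value = unname(fit$p), q_value = unname(q),
                    direction = direction,
                    perm_count = NA_integer_, perm_pass = NA,
                    stringsAsFactors = FALSE)
  if (n_perm > 0) {
    sig <- which(direction != "null")
    if (length(sig) > 0) {
      cnt <- permutation_counts(unclass(expr)[sig, , drop = FALSE],
                                samples, factors, n_perm, seed)
      tab$perm_count[sig] <- cnt
      tab$perm_pass[sig] <- cnt < pass_cutoff
    }
  }
  counts <- do.call(rbind, lapply(c(0.01, 0.05, 0.10), function(f) {
    sig <- tab$q_value <= f
    gated <- sig & !is.na(tab$perm_pass) & tab$perm_pass
    data.frame(fdr = f,
               up = sum(sig & tab$alpha > 0), down = sum(sig & tab$alpha < 0),
               total = sum(sig),
               total_gated = if (n_perm > 0) sum(gated) else NA_integer_)
  }))
  structure(list(table = tab, counts = counts, fdr = fdr),
            class = "pmi_association")
}

#' @export
print.pmi_association <- function(x, ...) {
  cat(sprintf("<pmi_association> %d genes; %d up, %d down at FDR %.2g\n",
              nrow(x$table), sum(x$table$direction == "up"),
              sum(x$table$direction == "down"), x$fdr))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Bootstrap sample-size power curve
#'
#' For each size in `sizes`, draws `n_boot` subsamples without replacement,
#' reruns the PMI association (factors re-screened per subsample is not
#' done: the supplied factor set is subset), and averages the number of
#' FDR-significant genes. Also reports the fixed-size average used for
#' cross-tissue comparison.
#'
#' @param expr normalized-stage expression matrix.
#' @param samples aligned sample table.
#' @param factors factor set or `NULL`.
#' @param sizes strictly increasing sample-size grid (e.g. `seq(20, n, 10)`).
#' @param n_boot bootstrap replicates per size (default 100).
#' @param fixed_n reference size for cross-tissue comparison (default 80).
#' @param fdr FDR threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `sizes`, `mean_counts`, `n_boot`, `fixed_n`,
#'   `fixed_n_mean_count`.
#' @export
sample_size_bootstrap <- function(expr, samples, factors = NULL,
                                  sizes = NULL, n_boot = 100, fixed_n = 80,
                                  fdr = 0.05, seed = 1L) {
  n <- ncol(expr)
  if (is.null(sizes)) sizes <- seq(20, n, by = 10)
  if (any(diff(sizes) <= 0)) stop("`sizes` must be strictly increasing")
  if (max(sizes) > n) stop("max(sizes) exceeds the sample count")
  if (fixed_n > n) stop("fixed_n exceeds the sample count")
  count_once <- function(idx) {
    sub_expr <- expr_matrix(unclass(expr)[, idx, drop = FALSE],
                            expr_stage(expr))
    sub_samples <- samples[idx, , drop = FALSE]
    sub_factors <- subset_factors(factors, idx)
    res <- run_association(sub_expr, sub_samples, sub_factors, fdr = fdr)
    sum(res$table$q_value <= fdr)
  }
  with_seed(seed, {
    mean_counts <- vapply(sizes, function(s) {
      mean(vapply(seq_len(n_boot), function(b) {
        count_once(sort(sample.int(n, s)))
      }, numeric(1)))
    }, numeric(1))
    fixed_mean <- mean(vapply(seq_len(n_boot), function(b) {
      count_once(sort(sample.int(n, fixed_n)))
    }, numeric(1)))
    list(sizes = sizes, mean_counts = mean_counts, n_boot = n_boot,
         fixed_n = fixed_n, fixed_n_mean_count = fixed_mean)
  })
}

subset_factors <- function(factors, idx) {
  if (is.null(factors) || nrow(factors$values) == 0) return(factors)
  factors$values <- factors$values[, idx, drop = FALSE]
  factors
}

#' Cross-tissue multi-hit summary
#'
#' Given association tables from two or more tissues, counts for each gene
#' the tissues in which it is significant and flags whether the direction of
#' the PMI response is consistent across those tissues.
#'
#' @param results named list of `pmi_association` objects (or their
#'   `$table` data.frames), one per tissue.
#' @return data.frame `gene_id`, `n_tissues`, `direction_consistent`,
#'   restricted to genes significant in at least two tissues.
#' @export
summarize_cross_tissue <- function(results) {
  if (length(results) < 2) stop("need association results for >= 2 tissues")
  tabs <- lapply(results, function(r) if (inherits(r, "pmi_association")) r$table else r)
  sig <- do.call(rbind, lapply(tabs, function(t)
    t[t$direction != "null", c("gene_id", "direction")]))
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(0), n_tissues = integer(0),
                      direction_consistent = logical(0)))
  agg <- split(sig$direction, sig$gene_id)
  agg <- agg[lengths(agg) >= 2]
  data.frame(gene_id = names(agg),
             n_tissues = unname(lengths(agg)),
             direction_consistent = vapply(agg, function(d)
               length(unique(d)) == 1, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
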