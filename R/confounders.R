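#' Infer hidden expression factors
#'
#' Factor-analysis stand-in for hidden-confounder inference: the known
#' covariates (age, gender, BMI) are projected out of each gene, genes are
#' standardised, and the leading right singular vectors of the residual
#' matrix give `k` orthogonal sample factors ordered by variance explained.
#' The sign of each factor is fixed so its largest-magnitude gene loading is
#' positive.
#'
#' PMI participates through the screening step ([filter_factors_by_pmi()])
#' rather than the projection: if PMI were projected out here, every factor
#' would be exactly orthogonal to PMI, and the chance in-sample PMI
#' component of a real confounder could never be absorbed by any retained
#' factor — it would leak into every gene's PMI test and inflate the
#' false-positive rate. Leaving factors free to correlate with PMI lets the
#' screen discard PMI-signature factors (protecting genuine degradation
#' signal) while retained factors carry their full confounding pattern into
#' the regression design.
#'
#' @param expr normalized-stage expression matrix.
#' @param samples sample table aligned to the expression columns.
#' @param k maximum number of factors (default 15); must be < `n_samples`.
#' @param prune drop factors whose eigenvalue falls below the
#'   Marchenko-Pastur noise edge `(1 + sqrt(n/G))^2` (with a 5% margin), the
#'   analogue of the automatic-relevance pruning a variational factor
#'   analysis performs; without it, pure-noise factors soak up genuine
#'   per-gene variance (default `TRUE`).
#' @return a `pmi_factors` list: `values` (k x samples), `loadings`
#'   (k x genes), `var_explained`, `retained` (all `TRUE` until
#'   [filter_factors_by_pmi()]), `pearson_p`, `spearman_p`.
#' @export
infer_hidden_factors <- function(expr, samples, k = 15, prune = TRUE) {
  if (expr_stage(expr) != "normalized")
    stop("factor inference expects normalized-stage expression")
  n <- ncol(expr)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (!identical(colnames(expr), samples$sample_id))
    stop("expression columns and sample table rows are not aligned")
  empty <- function() {
    structure(list(values = matrix(numeric(0), 0, n,
                                   dimnames = list(NULL, colnames(expr))),
                   loadings = matrix(numeric(0), 0, nrow(expr)),
                   var_explained = numeric(0), retained = logical(0),
                   pearson_p = numeric(0), spearman_p = numeric(0)),
              class = "pmi_factors")
  }
  if (k == 0) return(empty())
  X <- cbind(1, samples$age, samples$gender, samples$bmi)
  R <- t(qr.resid(qr(X), t(unclass(expr))))      # genes x samples
  sds <- sqrt(rowSums(R^2) / (n - 1))
  ok <- sds > 0
  R <- R[ok, , drop = FALSE] / sds[ok]
  k <- min(k, nrow(R) - 1, n - 1)
  if (k < 1) return(empty())
  sv <- svd(R, nu = k, nv = k)
  if (prune) {
    G <- nrow(R)
    edge <- 1.05 * (1 + sqrt(n / G))^2
    k <- sum(sv$d[seq_len(k)]^2 / G > edge)
    if (k < 1) return(empty())
  }
  vals <- t(sv$v[, seq_len(k), drop = FALSE])    # k x samples
  load <- t(sv$u[, seq_len(k), drop = FALSE])    # k x genes(ok)
  for (i in seq_len(k)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) {
      load[i, ] <- -load[i, ]
      vals[i, ] <- -vals[i, ]
    }
  }
  dimnames(vals) <- list(sprintf("factor_%02d", seq_len(k)), colnames(expr))
  dimnames(load) <- list(rownames(vals), rownames(R))
  structure(list(values = vals, loadings = load,
                 var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 retained = rep(TRUE, k),
                 pearson_p = rep(NA_real_, k),
                 spearman_p = rep(NA_real_, k)),
            class = "pmi_factors")
}

#' @export
print.pmi_factors <- function(x, ...) {
  cat(sprintf("<pmi_factors> %d factors x %d samples (%d retained)\n",
              nrow(x$values), ncol(x$values), sum(x$retained)))
  invisible(x)
}

#' Screen factors for PMI correlation
#'
#' A factor is excluded if either its Pearson or its Spearman correlation
#' test against PMI has p < `alpha`; only factors passing both tests are
#' retained for the downstream designs.
#'
#' @param factors output of [infer_hidden_factors()].
#' @param pmi per-sample PMI in minutes, aligned to the factor columns.
#' @param alpha screening level (default 0.05).
#' @return the factor set with `retained`, `pearson_p`, `spearman_p` filled.
#' @export
filter_factors_by_pmi <- function(factors, pmi, alpha = 0.05) {
  K <- nrow(factors$values)
  if (K == 0) return(factors)
  if (length(pmi) != ncol(factors$values))
    stop("PMI vector length does not match factor sample count")
  for (i in seq_len(K)) {
    f <- factors$values[i, ]
    factors$pearson_p[i] <- stats::cor.test(f, pmi, method = "pearson")$p.value
    factors$spearman_p[i] <- suppressWarnings(
      stats::cor.test(f, pmi, method = "spearman"))$p.value
  }
  factors$retained <- factors$pearson_p >= alpha & factors$spearman_p >= alpha
  factors
}

#' Residualise expression on known covariates and retained factors
#'
#' Per gene, ordinary-least-squares residuals from a fit on intercept, age,
#' gender, BMI and the retained hidden factors. PMI is deliberately not in
#' the design: the corrected expression still carries the PMI signal, which
#' is what the clustering, variability and visualisation steps examine.
#'
#' @param expr normalized-stage expression matrix.
#' @param samples aligned sample table.
#' @param factors a (filtered) factor set, or `NULL` for covariates only.
#' @return expression matrix at stage `"residual"`.
#' @export
residualize <- function(expr, samples, factors = NULL) {
  if (expr_stage(expr) != "normalized")
    stop("residualisation expects normalized-stage expression")
  if (!identical(colnames(expr), samples$sample_id))
    stop("expression columns and sample table rows are not aligned")
  X <- build_design(samples, factors, include_pmi = FALSE)
  X <- drop_collinear(X)
  R <- t(qr.resid(qr(X), t(unclass(expr))))
  dimnames(R) <- dimnames(expr)
  expr_matrix(R, "residual")
}
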