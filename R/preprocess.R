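#' Sample-level quality filters
#'
#' Retains samples with RIN strictly greater than `min_rin`, a present and
#' non-negative PMI, and (after those two filters) a tissue group of at least
#' `min_tissue_n` samples. Exclusion reasons are recorded per sample as
#' `low_rin`, `missing_pmi`, `negative_pmi` or `small_tissue`.
#'
#' @param samples validated sample table.
#' @param min_rin RIN threshold (default 6.0, strict inequality).
#' @param min_tissue_n minimum per-tissue sample count (default 80).
#' @return list with `samples` (retained rows) and `report` (a
#'   preprocessing report; see Details).
#' @details The report is a list with `n_samples_in`, `n_samples_out` and
#'   `excluded_samples` (data.frame of `sample_id`, `reason`).
#' @export
filter_samples <- function(samples, min_rin = 6.0, min_tissue_n = 80) {
  samples <- validate_samples(samples)
  reason <- rep(NA_character_, nrow(samples))
  reason[samples$rin <= min_rin] <- "low_rin"
  reason[is.na(reason) & is.na(samples$pmi_min)] <- "missing_pmi"
  reason[is.na(reason) & samples$pmi_min < 0] <- "negative_pmi"
  keep1 <- is.na(reason)
  tn <- table(samples$tissue[keep1])
  small <- names(tn)[tn < min_tissue_n]
  reason[keep1 & samples$tissue %in% small] <- "small_tissue"
  keep <- is.na(reason)
  if (!any(keep)) warning("no samples survive filtering")
  report <- list(
    n_samples_in = nrow(samples), n_samples_out = sum(keep),
    excluded_samples = data.frame(sample_id = samples$sample_id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE))
  list(samples = samples[keep, , drop = FALSE], report = report)
}

#' Quantile normalisation across samples
#'
#' Forces every sample (column) onto the common distribution given by the
#' cross-sample mean of order statistics; ties receive the mean of the
#' reference quantiles they span.
#'
#' @param expr raw-stage expression matrix with at least 2 samples.
#' @return expression matrix, same stage (the log2 transform advances it).
#' @export
quantile_normalize <- function(expr) {
  if (expr_stage(expr) != "raw")
    stop("quantile normalisation expects raw-stage expression")
  if (ncol(expr) < 2)
    stop("quantile normalisation is undefined for a single sample")
  out <- limma::normalizeQuantiles(unclass(expr), ties = TRUE)
  dimnames(out) <- dimnames(expr)
  expr_matrix(out, "raw")
}

#' log2(x + 1) transform
#'
#' @param expr raw-stage expression matrix with non-negative values.
#' @return expression matrix at stage `"normalized"`.
#' @export
log2_transform <- function(expr) {
  if (any(expr < 0)) stop("log2 transform requires non-negative values")
  expr_matrix(log2(unclass(expr) + 1), "normalized")
}

#' Remove the lowest-expressed fraction of genes
#'
#' Drops the `ceiling(fraction * n_genes)` genes with the lowest mean
#' (log2-scale) expression across samples; ties are broken by gene id in
#' lexicographic order so the result is deterministic.
#'
#' @param expr normalized-stage expression matrix.
#' @param fraction fraction of genes to drop, in \[0, 1).
#' @return list with `expression` (filtered matrix) and `report` (list with
#'   `n_genes_in`, `n_genes_out`, `excluded_genes`).
#' @export
filter_low_expression <- function(expr, fraction = 0.2) {
  if (expr_stage(expr) != "normalized")
    stop("low-expression filter expects normalized-stage expression")
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)")
  G <- nrow(expr)
  k <- ceiling(fraction * G)
  ord <- order(rowMeans(expr), rownames(expr))
  drop_ids <- rownames(expr)[ord[seq_len(k)]]
  keep <- setdiff(rownames(expr), drop_ids)
  out <- expr_matrix(unclass(expr)[keep, , drop = FALSE], "normalized")
  list(expression = out,
       report = list(n_genes_in = G, n_genes_out = length(keep),
                     excluded_genes = drop_ids))
}

#' Per-tissue preprocessing
#'
#' Convenience wrapper running, for one tissue's samples: sample filters,
#' quantile normalisation, log2 transform and the low-expression filter.
#'
#' @param expr raw expression matrix covering (at least) the tissue samples.
#' @param samples sample table.
#' @param min_rin,min_tissue_n,low_expr_frac filter settings.
#' @return list with `expression` (normalized stage), `samples` (retained)
#'   and `report`.
#' @export
preprocess_tissue <- function(expr, samples, min_rin = 6.0, min_tissue_n = 80,
                              low_expr_frac = 0.2) {
  fs <- filter_samples(samples, min_rin, min_tissue_n)
  keep <- intersect(colnames(expr), fs$samples$sample_id)
  ex <- expr_matrix(unclass(expr)[, keep, drop = FALSE], expr_stage(expr))
  ex <- log2_transform(quantile_normalize(ex))
  fg <- filter_low_expression(ex, low_expr_frac)
  list(expression = fg$expression,
       samples = fs$samples[match(keep, fs$samples$sample_id), , drop = FALSE],
       report = c(fs$report, fg$report))
}
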