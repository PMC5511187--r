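#' Split samples into short- and long-PMI groups
#'
#' Samples at or below the median PMI form the S-PMI group, the rest the
#' L-PMI group; ties at the median deterministically go to S-PMI.
#'
#' @param samples sample table with `pmi_min` present for every row.
#' @return factor of labels `S-PMI` / `L-PMI`, one per sample.
#' @export
split_pmi_groups <- function(samples) {
  pmi <- samples$pmi_min
  if (length(pmi) < 4) stop("need at least 4 samples to form PMI groups")
  if (anyNA(pmi)) stop("PMI must be present for every sample")
  med <- stats::median(pmi)
  lab <- ifelse(pmi <= med, "S-PMI", "L-PMI")
  if (length(unique(lab)) < 2)
    stop("degenerate grouping: all PMI values are on one side of the median")
  factor(lab, levels = c("S-PMI", "L-PMI"))
}

#' Levene's test for variance homogeneity
#'
#' The statistic W is the one-way ANOVA F-ratio computed on the absolute
#' deviations `z_kj = |x_kj - mean_k|` from the group means (classic
#' Levene, mean-centred), with `(g - 1, N - g)` degrees of freedom.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return list with `W`, `p_value`, `df`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  g <- nlevels(groups)
  if (g < 2) stop("Levene's test needs at least 2 groups")
  nk <- tabulate(groups)
  if (any(nk < 2)) stop("every group needs at least 2 observations")
  N <- length(values)
  means <- tapply(values, groups, mean)
  z <- abs(values - means[groups])
  zbar_k <- tapply(z, groups, mean)
  zbar <- mean(z)
  ss_between <- sum(nk * (zbar_k - zbar)^2)
  ss_within <- sum((z - zbar_k[groups])^2)
  df <- c(g - 1, N - g)
  if (ss_within == 0) {
    if (ss_between == 0) return(list(W = 0, p_value = 1, df = df))
    warning("zero within-group deviation variance; F is infinite, p set to 0")
    return(list(W = Inf, p_value = 0, df = df))
  }
  W <- (ss_between / df[1]) / (ss_within / df[2])
  list(W = W, p_value = stats::pf(W, df[1], df[2], lower.tail = FALSE),
       df = df)
}

#' Detect differentially variable genes between PMI groups
#'
#' Runs Levene's test per gene on residual expression split at the PMI
#' median, adjusts by Benjamini-Hochberg, and labels significant genes
#' `increase` (long-PMI variance larger) or `decrease`.
#'
#' @param residuals residual-stage expression matrix.
#' @param samples aligned sample table.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame `gene_id`, `W`, `p_value`, `q_value`, `direction`
#'   (`increase`/`decrease`/`none`), `var_spmi`, `var_lpmi`; constant genes
#'   are excluded and listed in the `excluded_genes` attribute.
#' @export
detect_dv_genes <- function(residuals, samples, fdr = 0.05) {
  if (expr_stage(residuals) != "residual")
    stop("differential-variability detection expects residual-stage expression")
  if (!identical(colnames(residuals), samples$sample_id))
    stop("expression columns and sample table rows are not aligned")
  grp <- split_pmi_groups(samples)
  Y <- unclass(residuals)
  constant <- apply(Y, 1, function(y) stats::var(y) == 0)
  excluded <- rownames(Y)[constant]
  Y <- Y[!constant, , drop = FALSE]
  res <- lapply(seq_len(nrow(Y)), function(i) levene_test(Y[i, ], grp))
  W <- vapply(res, `[[`, numeric(1), "W")
  p <- vapply(res, `[[`, numeric(1), "p_value")
  q <- bh_adjust(p)
  var_s <- apply(Y[, grp == "S-PMI", drop = FALSE], 1, stats::var)
  var_l <- apply(Y[, grp == "L-PMI", drop = FALSE], 1, stats::var)
  direction <- rep("none", nrow(Y))
  direction[q <= fdr & var_l > var_s] <- "increase"
  direction[q <= fdr & var_l < var_s] <- "decrease"
  out <- data.frame(gene_id = rownames(Y), W = W, p_value = p, q_value = q,
                    direction = direction, var_spmi = var_s, var_lpmi = var_l,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded_genes") <- excluded
  out
}
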