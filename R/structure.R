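#' Ward clustering of samples into two PMI groups
#'
#' Agglomerative hierarchical clustering of samples on Euclidean distance
#' with Ward linkage (`hclust` method `"ward.D2"`), computed on the
#' PMI-associated gene subset of (by default row-standardised) residual
#' expression, cut at two clusters. `group1` is the cluster with the lower
#' mean PMI.
#'
#' @param residuals residual-stage expression matrix.
#' @param gene_subset ids of the PMI-associated genes to cluster on.
#' @param samples aligned sample table (used to orient group labels).
#' @param standardize row-standardise genes before clustering (default TRUE).
#' @return factor of labels `group1` / `group2`, one per sample.
#' @export
ward_cluster_two_groups <- function(residuals, gene_subset, samples,
                                    standardize = TRUE) {
  gene_subset <- intersect(gene_subset, rownames(residuals))
  if (length(gene_subset) < 2) stop("need at least 2 genes to cluster on")
  if (ncol(residuals) < 4) stop("need at least 4 samples to cluster")
  Y <- unclass(residuals)[gene_subset, , drop = FALSE]
  if (standardize) {
    sds <- apply(Y, 1, stats::sd)
    Y <- (Y - rowMeans(Y))[sds > 0, , drop = FALSE] / sds[sds > 0]
  }
  hc <- stats::hclust(stats::dist(t(Y)), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  mean_pmi <- tapply(samples$pmi_min, cl[samples$sample_id], mean)
  low_first <- names(sort(mean_pmi))
  lab <- factor(ifelse(cl == as.integer(low_first[1]), "group1", "group2"),
                levels = c("group1", "group2"))
  names(lab) <- names(cl)
  lab
}

#' Student's t-test on PMI between cluster groups
#'
#' Pooled-variance two-sided t-test comparing the PMI (minutes) of the two
#' cluster groups. When both groups have zero PMI variance the statistic is
#' degenerate: t is reported as `Inf` (p = 0) for differing means and 0
#' (p = 1) for equal means.
#'
#' @param labels two-level group factor from [ward_cluster_two_groups()].
#' @param samples aligned sample table.
#' @return list with `t_stat`, `p_value`, `group_mean_pmi`.
#' @export
compare_group_pmi <- function(labels, samples) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("need exactly 2 groups")
  x <- samples$pmi_min[labels == levels(labels)[1]]
  y <- samples$pmi_min[labels == levels(labels)[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 samples")
  means <- c(mean(x), mean(y))
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    if (means[1] == means[2]) return(list(t_stat = 0, p_value = 1,
                                          group_mean_pmi = means))
    return(list(t_stat = Inf, p_value = 0, group_mean_pmi = means))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       group_mean_pmi = means)
}
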