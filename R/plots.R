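#' Heatmap of PMI-associated gene expression
#'
#' Draws residual expression of the given genes across samples, genes
#' ordered by PMI-slope sign then magnitude, with a PMI annotation bar.
#' Purely a visual aid; requires the pheatmap package.
#'
#' @param residuals residual-stage expression matrix.
#' @param samples aligned sample table.
#' @param assoc_table association result table (for gene order by `alpha`).
#' @param genes gene ids to draw (default: non-null direction genes).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_pmi_heatmap <- function(residuals, samples, assoc_table,
                             genes = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_pmi_heatmap requires the 'pheatmap' package")
  if (is.null(genes))
    genes <- assoc_table$gene_id[assoc_table$direction != "null"]
  tab <- assoc_table[assoc_table$gene_id %in% genes, ]
  tab <- tab[order(sign(tab$alpha), -abs(tab$alpha)), ]
  ann <- data.frame(PMI_h = samples$pmi_min / 60,
                    row.names = samples$sample_id)
  ph <- pheatmap::pheatmap(unclass(residuals)[tab$gene_id, , drop = FALSE],
                           annotation_col = ann, cluster_rows = FALSE,
                           clustering_method = "ward.D2",
                           show_rownames = FALSE, show_colnames = FALSE, ...)
  invisible(ph)
}

#' Scatter plot of one gene's expression against PMI
#'
#' @param expr expression matrix (any stage).
#' @param samples aligned sample table.
#' @param gene_id gene to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot_gene_pmi <- function(expr, samples, gene_id, ...) {
  y <- unclass(expr)[gene_id, ]
  x <- samples$pmi_min / 60
  rho <- stats::cor(x, y, method = "spearman")
  graphics::plot(x, y, xlab = "PMI (hours)",
                 ylab = sprintf("%s expression (%s)", gene_id,
                                expr_stage(expr)),
                 main = sprintf("%s (Spearman R = %.2f)", gene_id, rho), ...)
  graphics::abline(stats::lm(y ~ x), col = "red")
  invisible(rho)
}
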