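#' Expression matrix constructor
#'
#' An expression matrix is a plain numeric gene-by-sample matrix carrying a
#' `stage` attribute that records where in the pipeline it sits: `"raw"`
#' (RPKM-like, non-negative), `"normalized"` (quantile-normalised,
#' log2-transformed) or `"residual"` (covariate/factor-corrected).
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique row and column names.
#' @param stage one of `"raw"`, `"normalized"`, `"residual"`.
#' @return the matrix with class `pmi_expr` and a `stage` attribute.
#' @export
expr_matrix <- function(values, stage = c("raw", "normalized", "residual")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (stage == "raw" && nrow(values) > 0 && any(values < 0, na.rm = TRUE))
    stop("raw (RPKM-like) expression values must be non-negative")
  structure(values, stage = stage, class = c("pmi_expr", class(values)))
}

#' @export
print.pmi_expr <- function(x, ...) {
  cat(sprintf("<pmi_expr> %d genes x %d samples, stage = %s\n",
              nrow(x), ncol(x), expr_stage(x)))
  invisible(x)
}

#' Processing stage of an expression matrix
#' @param x an expression matrix created by [expr_matrix()].
#' @return the stage label.
#' @export
expr_stage <- function(x) {
  st <- attr(x, "stage")
  if (is.null(st)) stop("matrix has no processing-stage tag; use expr_matrix()")
  st
}

`expr_stage<-` <- function(x, value) {
  attr(x, "stage") <- value
  x
}

#' Genotype matrix constructor
#'
#' SNP-by-donor matrix of alternative-allele counts in \{0, 1, 2\}.
#'
#' @param codes integer matrix, SNPs in rows, donors in columns, values 0/1/2.
#' @return the matrix with class `pmi_geno`.
#' @export
geno_matrix <- function(codes) {
  if (!is.matrix(codes) || !is.numeric(codes))
    stop("`codes` must be a numeric matrix")
  if ((nrow(codes) > 0 && is.null(rownames(codes))) ||
      (ncol(codes) > 0 && is.null(colnames(codes))))
    stop("genotype matrix needs SNP row names and donor column names")
  if (anyDuplicated(rownames(codes))) stop("duplicate SNP ids")
  if (anyDuplicated(colnames(codes))) stop("duplicate donor ids")
  bad <- which(matrix(!(codes %in% c(0, 1, 2)), nrow = nrow(codes)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("genotype code outside {0,1,2} at SNP '%s', donor '%s'",
                 rownames(codes)[bad[1, 1]], colnames(codes)[bad[1, 2]]))
  structure(codes, class = c("pmi_geno", class(codes)))
}

#' Per-SNP minor allele frequency
#'
#' The alternative-allele frequency is `f = sum(codes) / (2 * n_donors)`; the
#' minor allele frequency is `min(f, 1 - f)`.
#'
#' @param genotypes a genotype matrix from [geno_matrix()].
#' @return named numeric vector of MAFs in \[0, 0.5\].
#' @export
snp_maf <- function(genotypes) {
  if (ncol(genotypes) == 0) stop("genotype matrix has no donors")
  f <- rowSums(genotypes) / (2 * ncol(genotypes))
  pmin(f, 1 - f)
}

#' Validate a sample covariate table
#'
#' Required columns: `sample_id`, `donor_id`, `tissue`, `pmi_min` (minutes),
#' `age` (years), `gender` (0/1), `bmi`, `rin`. PMI may be `NA` (missing);
#' such samples are excluded by [filter_samples()].
#'
#' @param samples data.frame of per-sample covariates.
#' @return the validated data.frame.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "donor_id", "tissue", "pmi_min", "age", "gender",
            "bmi", "rin")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(samples$gender %in% c(0, 1)))
    stop("gender must be coded 0/1")
  samples
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# derive a named substream seed from a root seed, kept inside 32-bit range
substream_seed <- function(seed, stream) {
  offsets <- c(simulate = 11L, preprocess = 23L, confounders = 37L,
               association = 53L, permutation = 71L, bootstrap = 89L,
               interaction = 101L, dispersion = 131L, structure = 151L)
  off <- offsets[[stream]]
  (as.integer(seed) * 997L + off) %% 2147483647L
}
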