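# Shared multi-gene ordinary-least-squares engine.
#
# All per-gene model fits in the package (PMI association, interaction scan,
# residualisation) reduce to fitting the same n-by-p design against every gene
# at once, so the QR decomposition is computed once per design and reused.

# Build the Eq.-style design matrix: intercept, pmi, age, gender, bmi and the
# retained hidden factors. PMI sits right after the intercept so that pivoting
# on rank deficiency can never silently drop it.
build_design <- function(samples, factors = NULL, include_pmi = TRUE) {
  X <- cbind(`(Intercept)` = 1,
             pmi = if (include_pmi) samples$pmi_min else NULL,
             age = samples$age,
             gender = samples$gender,
             bmi = samples$bmi)
  if (!is.null(factors) && any(factors$retained)) {
    fv <- t(factors$values[factors$retained, , drop = FALSE])
    X <- cbind(X, fv)
  }
  rownames(X) <- samples$sample_id
  X
}

# Drop collinear columns (later-indexed first, never `protect`), erroring if a
# protected column itself is collinear with what precedes it.
drop_collinear <- function(X, protect = character(0)) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(X)
  keep <- logical(ncol(X))
  r <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(which(keep), j), drop = FALSE]
    if (qr(cand)$rank > r) {
      keep[j] <- TRUE
      r <- r + 1L
    }
  }
  dropped <- colnames(X)[!keep]
  if (any(protect %in% dropped))
    stop("design column(s) ", paste(intersect(protect, dropped), collapse = ", "),
         " are collinear with the remaining covariates")
  warning("dropping collinear design column(s): ", paste(dropped, collapse = ", "))
  X[, keep, drop = FALSE]
}

# Fit Y (genes x samples) against design X; return per-gene estimate, SE,
# t and two-sided p for column `term`, plus residuals and df.
ols_term_test <- function(Y, X, term) {
  n <- ncol(Y)
  if (nrow(X) != n) stop("design and expression sample counts differ")
  X <- drop_collinear(X, protect = term)
  p <- ncol(X)
  if (n <= p) stop(sprintf("n = %d samples cannot fit %d parameters", n, p))
  qrX <- qr(X)
  Yt <- t(Y)
  coefs <- qr.coef(qrX, Yt)              # p x G
  resid <- qr.resid(qrX, Yt)             # n x G
  df <- n - p
  rss <- colSums(resid^2)
  sigma2 <- rss / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  j <- match(term, colnames(X))
  est <- coefs[j, ]
  se <- sqrt(sigma2 * xtxinv[j, j])
  tstat <- est / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero-variance genes carry no information: estimate 0, p = 1
  ctr <- Y - rowMeans(Y)
  zerovar <- rowSums(ctr^2) == 0
  if (any(zerovar)) {
    est[zerovar] <- 0
    se[zerovar] <- NA_real_
    tstat[zerovar] <- 0
    pval[zerovar] <- 1
  }
  # perfect (noiseless) fits: sigma2 == 0 with a nonzero coefficient
  perfect <- !zerovar & sigma2 <= .Machine$double.eps * colSums(Yt^2)
  pval[perfect & abs(est) > 0] <- 0
  list(estimate = est, se = se, t = tstat, p = pval,
       residuals = t(resid), df = df, design = X)
}

# |t| statistics for `n_perm` permutations of the PMI column, all genes at
# once, via Frisch-Waugh: residualise Y and each permuted PMI vector on the
# non-PMI columns; the full-model t for PMI is then a correlation transform.
perm_tstats <- function(Y, X, perms) {
  stopifnot("pmi" %in% colnames(X))
  Z <- X[, setdiff(colnames(X), "pmi"), drop = FALSE]
  qrZ <- qr(Z)
  Yr <- qr.resid(qrZ, t(Y))                       # n x G
  Pr <- qr.resid(qrZ, perms)                      # n x B permuted PMI columns
  df <- nrow(Pr) - ncol(X)
  num <- crossprod(Yr, Pr)                        # G x B  <y_r, x_r>
  ynorm <- sqrt(colSums(Yr^2))
  xnorm <- sqrt(colSums(Pr^2))
  r <- num / outer(ynorm, xnorm)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
}
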