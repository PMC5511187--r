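# pmidecay

Postmortem mRNA degradation is not uniform: in banked human tissue, the
postmortem interval (PMI — minutes from death to sample preservation,
typically 1–27 hours) shifts the measured expression of thousands of genes,
in a tissue- and gene-specific way, and can even do so genotype-specifically.
`pmidecay` is an R package for quantifying these effects in bulk RNA-seq
abundance matrices. It is aimed at anyone analysing postmortem expression
data (tissue banks, forensic transcriptomics, eQTL studies on cadaveric
tissue) who needs to detect, correct for, or characterise PMI-driven
signal.

## What it computes

For each gene *j*, expression is modelled by multiple linear regression

    Y_ij = mu_j + alpha_j*PMI_i + beta_j*Age_i + gamma_j*BMI_i
           + delta_j*Gender_i + sum_k theta_jk*PC_ki + eps_ij

where the PC_k are hidden expression factors (an SVD-based stand-in for a
PEER-style factor analysis) that passed a PMI-correlation screen. The PMI
coefficient `alpha` is t-tested against zero and genes are called at a
Benjamini–Hochberg FDR, with an optional PMI-permutation gate (10,000
permutations, pass if fewer than 500 beat the observed p-value). On top of
this core regression the package provides:

* per-tissue preprocessing: RIN > 6 and non-negative-PMI sample filters,
  ≥ 80-sample tissue filter, quantile normalisation, log2(x+1), removal of
  the 20% lowest-expressed genes (18,763 → 15,010);
* a genotype-by-PMI interaction scan (`Y ~ ... + SNP + PMI:SNP`) with a
  ≥ 15% MAF filter and a Bonferroni-scale cutoff `0.05 / n_SNPs`
  (4.75E-8 for 1,051,649 SNPs), plus cross-tissue validation;
* Levene's test (ANOVA F on |x − group mean|) for genes whose expression
  *variance* differs between short- and long-PMI halves;
* Ward clustering of samples on the PMI-associated genes with a Student's
  t-test on the groups' PMI;
* bootstrap sample-size power curves;
* a synthetic GTEx-like generator with known true slopes, variability
  flags and planted interactions, used by the entire test suite.

## Worked example

```r
library(pmidecay)
cfg <- run_config(
  simulate = sim_config(n_genes = 500, n_samples = 120,
                        frac_pmi_genes = 0.1, frac_dv_genes = 0.05,
                        n_snps = 50, n_interaction_pairs = 2),
  k_factors = 10, n_perm = 1000, perm_cutoff = 50,
  n_genes_subsample = 100, seed = 1)
res <- run_pipeline(cfg)
```

which logs one line per stage:

```
[simulate] 500 genes x 120 samples
[preprocess] 120 samples, 400 genes retained
[correct] 3 of 6 factors retained
[associate] 50 PMI-associated genes at FDR 0.05
[interact] 6 significant pairs at p < 0.00104
[dv] 37 differentially variable genes at FDR 0.05
[cluster] group PMI t-test p = 6.09e-35
```

`res$association` holds the per-gene table and the up/down counts:

```
<pmi_association> 400 genes; 24 up, 26 down at FDR 0.05
  fdr up down total total_gated
 0.01 24   24    48          48
 0.05 24   26    50          50
 0.10 24   27    51          50
```

So of 400 genes surviving the low-expression filter, 50 are PMI-associated
at FDR 5% (24 rising with PMI, 26 falling — the generator planted 10% true
effects of both signs), and all 50 survive the permutation gate. `res$dv`
lists differentially variable genes with Levene's W, q-value and the
direction of the variance change, e.g.

```
     gene_id        W      p_value      q_value direction  var_spmi  var_lpmi
6  gene_0008 25.84187 1.407523e-06 2.950028e-05  increase  7.125828 21.023384
28 gene_0032 50.09275 1.131008e-10 3.770028e-09  decrease 69.096574 12.434903
```

(gene_0008's residual variance triples in the long-PMI half; gene_0032's
drops five-fold), and `res$cluster$p_value` (6.09e-35 here) shows the Ward
2-group cut separating short- from long-PMI samples. Ground truth for every
planted effect is in `res$truth` for comparison.

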