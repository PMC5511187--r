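# shared fixture builders: everything is generated in code at test time

make_dataset <- function(...) simulate_dataset(sim_config(...))

# log2-scale expression straight from the generator (common column scale,
# so quantile normalisation is unnecessary for simulated data)
log2_expr <- function(ds) log2_transform(ds$expression)

# infer + PMI-screen hidden factors in one step
fit_factors <- function(ex, samples, k = 10) {
  filter_factors_by_pmi(infer_hidden_factors(ex, samples, k = k),
                        samples$pmi_min)
}

# minimal hand-built sample table
toy_samples <- function(n, pmi = seq(100, 1500, length.out = n),
                        tissue = "t1", rin = 8) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             donor_id = sprintf("d%02d", seq_len(n)),
             tissue = tissue, pmi_min = pmi,
             age = rep(c(30, 45, 60), length.out = n),
             gender = rep(c(0, 1), length.out = n),
             bmi = rep(c(22, 27, 31), length.out = n),
             rin = rin, stringsAsFactors = FALSE)
}

toy_expr <- function(values, stage = "normalized") {
  expr_matrix(values, stage)
}

# independent brute-force Levene oracle: one-way ANOVA F on |x - group mean|
# via stats::lm / stats::anova (never the package's own sum formulas)
levene_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  z <- abs(values - ave(values, groups))
  av <- stats::anova(stats::lm(z ~ groups))
  list(W = av$`F value`[1], p_value = av$`Pr(>F)`[1])
}
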