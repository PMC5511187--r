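#' Pipeline run configuration
#'
#' Bundles every stage toggle and threshold of the analysis. Defaults are
#' the study settings: RIN > 6.0, tissues of >= 80 samples, 20%
#' low-expression filter, up to 15 hidden factors screened at 0.05, FDR
#' 0.05, 10,000 permutations with cutoff 500, MAF >= 0.15, interaction
#' family-wise level 0.05, DV FDR 0.05.
#'
#' @param simulate `NULL` to read inputs from `paths`, or a [sim_config()]
#'   to generate them.
#' @param paths named list of input paths (`expression`, `samples`,
#'   `genotypes`) when not simulating.
#' @param stages character vector of stages to run, a subset of
#'   `c("preprocess", "correct", "associate", "interact", "dv", "cluster")`.
#' @param min_rin,min_n,low_expr_frac,k_factors,factor_alpha,fdr,n_perm,
#'   perm_cutoff,maf_min,interaction_alpha,dv_fdr thresholds (see above).
#' @param n_genes_subsample genes subsampled in the interaction scan.
#' @param seed root seed; every stage derives a named substream from it.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = sim_config(), paths = NULL,
                       stages = c("preprocess", "correct", "associate",
                                  "interact", "dv", "cluster"),
                       min_rin = 6.0, min_n = 80, low_expr_frac = 0.2,
                       k_factors = 15, factor_alpha = 0.05, fdr = 0.05,
                       n_perm = 10000, perm_cutoff = 500, maf_min = 0.15,
                       interaction_alpha = 0.05, dv_fdr = 0.05,
                       n_genes_subsample = 2000, seed = 1L,
                       out_dir = NULL) {
  known <- c("preprocess", "correct", "associate", "interact", "dv", "cluster")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(simulate) && is.null(paths))
    stop("configuration error: either `simulate` or `paths` must be given")
  structure(list(simulate = simulate, paths = paths, stages = stages,
                 min_rin = min_rin, min_n = min_n,
                 low_expr_frac = low_expr_frac, k_factors = k_factors,
                 factor_alpha = factor_alpha, fdr = fdr, n_perm = n_perm,
                 perm_cutoff = perm_cutoff, maf_min = maf_min,
                 interaction_alpha = interaction_alpha, dv_fdr = dv_fdr,
                 n_genes_subsample = n_genes_subsample,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate` mapping
#' is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

#' Run the full PMI analysis pipeline
#'
#' Executes the enabled stages in order — simulate/load, preprocess,
#' confounder correction, PMI association (with permutation gate),
#' genotype-by-PMI interaction scan, differential-variability detection,
#' Ward clustering — logging one stage-tagged line per step, and returns
#' (and optionally writes) all result tables plus a machine-readable run
#' report.
#'
#' @param config a [run_config()].
#' @return list with elements `expression`, `samples`, `factors`,
#'   `residuals`, `association`, `interactions`, `dv`, `cluster`, `truth`
#'   (when simulated) and `report`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("configuration error: not a run_config")
  log_stage <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  report <- list(seed = config$seed,
                 thresholds = config[c("min_rin", "min_n", "low_expr_frac",
                                       "k_factors", "factor_alpha", "fdr",
                                       "n_perm", "perm_cutoff", "maf_min",
                                       "interaction_alpha", "dv_fdr")],
                 stages = config$stages, counts = list(),
                 r_version = as.character(getRversion()))
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  out <- list()

  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- substream_seed(config$seed, "simulate")
    ds <- run_stage("simulate", function() simulate_dataset(cfg))
    log_stage("simulate", "%d genes x %d samples", nrow(ds$expression),
              ncol(ds$expression))
    out$truth <- ds$truth
  } else {
    ds <- run_stage("load", function() list(
      expression = read_expression(config$paths$expression),
      samples = read_samples(config$paths$samples),
      genotypes = if (!is.null(config$paths$genotypes))
        read_genotypes(config$paths$genotypes)))
    log_stage("load", "%d genes x %d samples", nrow(ds$expression),
              ncol(ds$expression))
  }
  expr <- ds$expression; samples <- ds$samples

  if ("preprocess" %in% config$stages) {
    pp <- run_stage("preprocess", function()
      preprocess_tissue(expr, samples, config$min_rin, config$min_n,
                        config$low_expr_frac))
    expr <- pp$expression; samples <- pp$samples
    report$counts$preprocess <- pp$report[c("n_samples_in", "n_samples_out",
                                            "n_genes_in", "n_genes_out")]
    log_stage("preprocess", "%d samples, %d genes retained",
              ncol(expr), nrow(expr))
  } else if (expr_stage(expr) == "raw") {
    expr <- log2_transform(expr)
  }
  out$expression <- expr; out$samples <- samples

  factors <- NULL
  if ("correct" %in% config$stages) {
    factors <- run_stage("correct", function() {
      f <- infer_hidden_factors(expr, samples,
                                k = min(config$k_factors, ncol(expr) - 6))
      filter_factors_by_pmi(f, samples$pmi_min, config$factor_alpha)
    })
    report$counts$factors_retained <- sum(factors$retained)
    log_stage("correct", "%d of %d factors retained",
              sum(factors$retained), length(factors$retained))
  }
  resid <- run_stage("correct", function() residualize(expr, samples, factors))
  out$factors <- factors; out$residuals <- resid

  if ("associate" %in% config$stages) {
    assoc <- run_stage("associate", function()
      run_association(expr, samples, factors, fdr = config$fdr,
                      n_perm = config$n_perm,
                      pass_cutoff = config$perm_cutoff,
                      seed = substream_seed(config$seed, "permutation")))
    out$association <- assoc
    report$counts$association <- assoc$counts
    log_stage("associate", "%d PMI-associated genes at FDR %.2g",
              sum(assoc$table$direction != "null"), config$fdr)
  }

  if ("interact" %in% config$stages && !is.null(ds$genotypes) &&
      nrow(ds$genotypes) > 0) {
    inter <- run_stage("interact", function()
      scan_interactions(expr, samples, factors, ds$genotypes,
                        n_genes_subsample = config$n_genes_subsample,
                        min_maf = config$maf_min,
                        alpha = config$interaction_alpha,
                        seed = substream_seed(config$seed, "interaction")))
    out$interactions <- inter
    report$counts$interactions_significant <- sum(inter$significant)
    log_stage("interact", "%d significant pairs at p < %.3g",
              sum(inter$significant), attr(inter, "threshold"))
  }

  if ("dv" %in% config$stages) {
    dv <- run_stage("dv", function()
      detect_dv_genes(resid, samples, fdr = config$dv_fdr))
    out$dv <- dv
    report$counts$dv_genes <- sum(dv$direction != "none")
    log_stage("dv", "%d differentially variable genes at FDR %.2g",
              sum(dv$direction != "none"), config$dv_fdr)
  }

  if ("cluster" %in% config$stages && !is.null(out$association)) {
    sig <- out$association$table$gene_id[out$association$table$direction != "null"]
    if (length(sig) >= 2) {
      clu <- run_stage("cluster", function() {
        lab <- ward_cluster_two_groups(resid, sig, samples)
        c(list(labels = lab), compare_group_pmi(lab, samples))
      })
      out$cluster <- clu
      report$counts$cluster_t_p <- clu$p_value
      log_stage("cluster", "group PMI t-test p = %.3g", clu$p_value)
    } else {
      log_stage("cluster", "skipped: fewer than 2 PMI-associated genes")
    }
  }

  out$report <- report
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(out$association))
    write_results(out$association$table, p("association.tsv"))
  if (!is.null(out$interactions))
    write_results(out$interactions, p("interactions.tsv"))
  if (!is.null(out$dv)) write_results(out$dv, p("dv.tsv"))
  if (!is.null(out$cluster))
    write_results(data.frame(sample_id = names(out$cluster$labels),
                             group = as.character(out$cluster$labels)),
                  p("cluster.tsv"))
  if (!is.null(out$factors) && nrow(out$factors$values) > 0)
    write_results(data.frame(factor = rownames(out$factors$values),
                             retained = out$factors$retained,
                             pearson_p = out$factors$pearson_p,
                             spearman_p = out$factors$spearman_p),
                  p("factors.tsv"))
  jsonlite::write_json(out$report, p("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(config$out_dir)
}
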