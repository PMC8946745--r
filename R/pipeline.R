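# End-to-end pipeline: stages over a shared artifact directory, plus a thin
# CLI. Every intermediate is a plain-text table (TSV, '.' decimal, NA token
# "NA") or a PLINK 1 fileset, so stages compose across processes; all
# randomness flows from the single configured seed.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}
read_tsv <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
             stringsAsFactors = FALSE, ...)
}

stage_error <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      message(sprintf("[stage %s] warning: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Pipeline configuration
#'
#' @param simulation a [sim_config()] (the pipeline's data source).
#' @param fit a [fit_config()]; its family is taken from `simulation`.
#' @param qc a [qc_thresholds()].
#' @param out_dir artifact directory.
#' @param dev_population population label used for score development
#'   (default: the first label in `simulation`).
#' @param split_fractions train/validation/test fractions of the development
#'   population.
#' @param n_tests Bonferroni correction count for the significance flag.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            fit = fit_config(family = simulation$family),
                            qc = qc_thresholds(),
                            out_dir = tempfile("prs_run_"),
                            dev_population = names(simulation$n_per_population)[1],
                            split_fractions = c(0.7, 0.1, 0.2),
                            n_tests = 2000) {
  fit$family <- simulation$family
  structure(list(simulation = simulation, fit = fit, qc = qc,
                 out_dir = out_dir, dev_population = dev_population,
                 split_fractions = split_fractions, n_tests = n_tests),
            class = "pipeline_config")
}

save_pipeline_config <- function(config, dir) {
  jsonlite::write_json(
    list(simulation = unclass(config$simulation),
         fit = unclass(config$fit),
         qc = unclass(config$qc),
         dev_population = config$dev_population,
         split_fractions = config$split_fractions,
         n_tests = config$n_tests),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
}

load_pipeline_config <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  sim <- do.call(sim_config, j$simulation)
  fit <- do.call(fit_config, j$fit)
  qc <- do.call(qc_thresholds, j$qc[setdiff(names(j$qc), "mhc_region")])
  qc$mhc_region <- j$qc$mhc_region
  pipeline_config(simulation = sim, fit = fit, qc = qc, out_dir = dir,
                  dev_population = j$dev_population,
                  split_fractions = j$split_fractions, n_tests = j$n_tests)
}

#' Pipeline stage: simulate a cohort into the artifact directory
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_simulate <- function(config) stage_error("simulate", {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_pipeline_config(config, dir)
  cohort <- simulate_cohort(config$simulation)
  samples <- data.frame(fid = sprintf("F%06d", seq_len(nrow(cohort$G))),
                        iid = sprintf("S%06d", seq_len(nrow(cohort$G))),
                        father = "0", mother = "0", sex = 0L, pheno = -9)
  write_plink_bed(cohort$G, cohort$variants, samples,
                  file.path(dir, "genotypes"))
  ann <- cohort$annotation
  ann$chrom <- cohort$variants$chrom
  ann$pos <- cohort$variants$pos
  write_tsv(ann, file.path(dir, "annotation.tsv"))
  write_tsv(cbind(iid = samples$iid, cohort$covariates),
            file.path(dir, "covariates.tsv"))
  write_tsv(data.frame(iid = samples$iid, population = cohort$population,
                       trait1 = cohort$y),
            file.path(dir, "phenotype.tsv"))
  write_tsv(data.frame(variant_id = cohort$variants$variant_id,
                       beta_true = cohort$truth$beta_true,
                       causal_mask = cohort$truth$causal_mask),
            file.path(dir, "truth.tsv"))
  invisible(dir)
})

read_artifacts <- function(dir) {
  pl <- read_plink_bed(file.path(dir, "genotypes"))
  list(G = pl$G, variants = pl$variants,
       annotation = read_tsv(file.path(dir, "annotation.tsv")),
       covariates = read_tsv(file.path(dir, "covariates.tsv")),
       phenotype = read_tsv(file.path(dir, "phenotype.tsv")))
}

#' Pipeline stage: variant QC
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_qc <- function(config) stage_error("qc", {
  dir <- config$out_dir
  art <- read_artifacts(dir)
  dev <- art$phenotype$population == config$dev_population
  qc <- variant_qc(art$G[dev, , drop = FALSE], art$annotation, config$qc)
  write_tsv(qc$report, file.path(dir, "qc_report.tsv"))
  writeLines(art$annotation$variant_id[qc$keep],
             file.path(dir, "variants_kept.txt"))
  invisible(dir)
})

#' Pipeline stage: fit, select and refit the sparse PRS model
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_fit <- function(config) stage_error("fit", {
  dir <- config$out_dir
  art <- read_artifacts(dir)
  kept <- readLines(file.path(dir, "variants_kept.txt"))
  keep <- art$annotation$variant_id %in% kept
  ann <- art$annotation[keep, ]
  G <- art$G[, keep, drop = FALSE]
  dev_rows <- which(art$phenotype$population == config$dev_population)
  split <- split_samples(length(dev_rows), config$split_fractions,
                         config$simulation$seed)
  write_tsv(data.frame(iid = art$covariates$iid[dev_rows], split = split),
            file.path(dir, "split.tsv"))
  covs <- art$covariates[, setdiff(names(art$covariates), "iid")]
  y <- art$phenotype$trait1
  w <- assign_penalty_factor(ann$consequence_group, ann$clinvar_class,
                             ann$is_allelotype)
  devel <- dev_rows[split != "test"]
  G_dev <- G[devel, , drop = FALSE]
  val_local <- which(split[split != "test"] == "validation")
  path <- basil_fit(G_dev, covs[devel, ], y[devel], w, config$fit,
                    validation = val_local)
  k <- select_lambda(path)
  write_tsv(data.frame(lambda = path$lambdas,
                       active = path$active_counts,
                       validation_metric = path$validation_metric,
                       selected = seq_along(path$lambdas) == k),
            file.path(dir, "path_log.tsv"))
  model <- refit_final(G_dev, covs[devel, ], y[devel], path$lambdas[k], w,
                       config$fit,
                       alleles = art$variants[keep, c("variant_id", "a1", "a2")])
  write_score_file(model, file.path(dir, "score.tsv"))
  invisible(dir)
})

#' Pipeline stage: compute PRS for all samples
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_score <- function(config) stage_error("score", {
  dir <- config$out_dir
  art <- read_artifacts(dir)
  model <- read_score_file(file.path(dir, "score.tsv"))
  prs <- compute_prs(art$G, model,
                     alleles = data.frame(variant_id = art$variants$variant_id,
                                          a1 = art$variants$a1,
                                          a2 = art$variants$a2))
  write_tsv(data.frame(iid = art$covariates$iid,
                       prs = sprintf("%.17g", prs)),
            file.path(dir, "prs.tsv"))
  invisible(dir)
})

#' Pipeline stage: evaluate predictive performance per population
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_evaluate <- function(config) stage_error("evaluate", {
  dir <- config$out_dir
  art <- read_artifacts(dir)
  fam <- config$simulation$family
  prs <- as.numeric(read_tsv(file.path(dir, "prs.tsv"))$prs)
  split_df <- read_tsv(file.path(dir, "split.tsv"))
  y <- art$phenotype$trait1
  covs <- art$covariates[, setdiff(names(art$covariates), "iid")]
  dev_rows <- which(art$phenotype$population == config$dev_population)
  devel <- dev_rows[split_df$split != "test"]
  test_rows <- dev_rows[split_df$split == "test"]
  targets <- c(list(test = test_rows),
               lapply(setdiff(levels(factor(art$phenotype$population)),
                              config$dev_population),
                      function(p) which(art$phenotype$population == p)))
  names(targets) <- c("test", setdiff(levels(factor(art$phenotype$population)),
                                      config$dev_population))
  cm <- fit_covariate_model(covs[devel, ], y[devel], fam)
  rows <- lapply(names(targets), function(popname) {
    idx <- targets[[popname]]
    tc <- covs[idx, ]
    const <- vapply(tc, function(x) length(unique(x)) == 1, TRUE)
    cs <- predict(cm, tc[, !const, drop = FALSE])
    evaluate_models("trait1", popname, prs[idx], cs, y[idx], fam)
  })
  write_tsv(do.call(rbind, rows), file.path(dir, "evaluation.tsv"))
  invisible(dir)
})

#' Pipeline stage: association scan and LDSC heritability
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_h2 <- function(config) stage_error("h2", {
  dir <- config$out_dir
  art <- read_artifacts(dir)
  fam <- config$simulation$family
  kept <- readLines(file.path(dir, "variants_kept.txt"))
  keep <- art$annotation$variant_id %in% kept
  split_df <- read_tsv(file.path(dir, "split.tsv"))
  dev_rows <- which(art$phenotype$population == config$dev_population)
  devel <- dev_rows[split_df$split != "test"]
  G <- art$G[devel, keep, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  covs <- art$covariates[devel, setdiff(names(art$covariates), "iid")]
  assoc <- gwas_scan(G, art$phenotype$trait1[devel], covs, fam,
                     quantile_normalize = (fam == "gaussian"))
  write_tsv(assoc, file.path(dir, "gwas.tsv"))
  l <- ld_scores(G, window = 2 * config$simulation$ld_block_size)
  h2 <- ldsc_fit(assoc$chi2, l, N = nrow(G), M = ncol(G))
  write_tsv(data.frame(trait = "trait1", family = fam,
                       h2_obs = h2$h2_obs, h2_obs_se = h2$h2_obs_se,
                       lambda_GC = h2$lambda_GC, mean_chi2 = h2$mean_chi2,
                       intercept = h2$intercept, intercept_se = h2$intercept_se,
                       ratio = h2$ratio, ratio_se = h2$ratio_se),
            file.path(dir, "heritability.tsv"))
  invisible(dir)
})

#' Pipeline stage: phenome summary report
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
stage_report <- function(config) stage_error("report", {
  dir <- config$out_dir
  ev <- read_tsv(file.path(dir, "evaluation.tsv"))
  model <- read_score_file(file.path(dir, "score.tsv"))
  fam <- config$simulation$family
  summ <- build_phenome_table(ev, sizes = c(trait1 = length(model$weights)),
                              families = c(trait1 = fam),
                              n_tests = config$n_tests)
  write_tsv(summ$table, file.path(dir, "phenome_summary.tsv"))
  invisible(dir)
})

#' Run the full pipeline
#'
#' simulate -> qc -> fit/select/refit -> score -> evaluate -> gwas/h2 ->
#' report, all under `config$out_dir`. Identical config and seed give
#' byte-identical result tables.
#'
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stages <- list(simulate = stage_simulate, qc = stage_qc, fit = stage_fit,
                 score = stage_score, evaluate = stage_evaluate,
                 h2 = stage_h2, report = stage_report)
  for (nm in names(stages)) {
    t0 <- Sys.time()
    stages[[nm]](config)
    message(sprintf("[stage %s] done in %.1fs", nm,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' `prs_cli(c("run-all", "--out", dir, "--seed", "7"))` etc. Subcommands:
#' simulate, qc, fit, score, evaluate, h2, report, run-all. Later stages read
#' the config written by `simulate` into the artifact directory, so
#' subcommands compose to the same result as [run_pipeline()].
#'
#' @param args character vector of arguments (default: the process command
#'   line).
#' @return the artifact directory, invisibly.
#' @export
prs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop_config(
    "usage: prs_cli(c(<subcommand>, --out <dir> [--seed <int>] [--family <fam>]))")
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1] else default
  }
  out <- opt("--out")
  if (is.null(out)) stop_config("--out <dir> is required")
  config <- if (cmd %in% c("simulate", "run-all")) {
    pipeline_config(
      simulation = sim_config(seed = as.integer(opt("--seed", "1")),
                              family = opt("--family", "gaussian")),
      out_dir = out)
  } else load_pipeline_config(out)
  config$out_dir <- out
  switch(cmd,
         "simulate" = stage_simulate(config),
         "qc" = stage_qc(config),
         "fit" = stage_fit(config),
         "score" = stage_score(config),
         "evaluate" = stage_evaluate(config),
         "h2" = stage_h2(config),
         "report" = stage_report(config),
         "run-all" = run_pipeline(config),
         stop_config("unknown subcommand '%s'", cmd))
  invisible(out)
}
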