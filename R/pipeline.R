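#' Configure an end-to-end pipeline run
#'
#' Bundles every knob of the pipeline: data source (a [sim_config()] or
#' paths to genotype/phenotype files), preprocessing thresholds, CV
#' settings, stepwise criteria, bagging parameters, the master seed, and
#' the output directory. Every stochastic stage derives its seed
#' deterministically from the master seed and the stage name.
#'
#' @param sim A [sim_config()], or `NULL` to read files.
#' @param genotype_file,phenotype_file,truth_file Input paths when `sim`
#'   is `NULL` (`truth_file`: one causal SNP id per line, optional).
#' @param genotype_dialect Dialect for [read_genotypes()].
#' @param maf_threshold MAF filter cutoff (default 0.01).
#' @param collapse_duplicates Collapse identical SNP columns (default TRUE).
#' @param K,cv_repeats Cross-validation folds and repetitions.
#' @param bagging Run LASSO bagging on the first replicate (default TRUE).
#' @param bag_B Number of bootstrap resamples (default 100).
#' @param bag_lambda_rule Penalty fed to bagging: `"min"` (default) or
#'   `"1se"`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       genotype_file = NULL, phenotype_file = NULL,
                       truth_file = NULL,
                       genotype_dialect = "delimited",
                       maf_threshold = 0.01,
                       collapse_duplicates = TRUE,
                       K = 10L, cv_repeats = 1L,
                       bagging = TRUE, bag_B = 100L,
                       bag_lambda_rule = c("min", "1se"),
                       seed = 1L, out_dir = tempfile("snplasso_run_")) {
  bag_lambda_rule <- match.arg(bag_lambda_rule)
  if (is.null(sim) && (is.null(genotype_file) || is.null(phenotype_file))) {
    abort("either `sim` or both genotype_file and phenotype_file are required")
  }
  structure(
    list(sim = sim, genotype_file = genotype_file,
         phenotype_file = phenotype_file, truth_file = truth_file,
         genotype_dialect = genotype_dialect,
         maf_threshold = maf_threshold,
         collapse_duplicates = collapse_duplicates,
         K = as.integer(K), cv_repeats = as.integer(cv_repeats),
         bagging = isTRUE(bagging), bag_B = as.integer(bag_B),
         bag_lambda_rule = bag_lambda_rule,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

write_table6 <- function(df, path) {
  # fixed 6-significant-digit formatting keeps reruns byte-identical
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  readr::write_tsv(df, path, progress = FALSE)
}

#' Run the full pipeline and write stage outputs plus a manifest
#'
#' Executes simulate (when configured) -> sample alignment -> MAF filter ->
#' duplicate collapsing -> per-replicate CV + LASSO selection + stepwise
#' refinement -> selection summary/ranks -> optional bagging of the first
#' replicate, writing each stage's table to `out_dir` along with a JSON
#' manifest recording the config hash, seeds, and per-stage row/SNP counts.
#' Reruns with the same config produce byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(unclass(cfg)),
                   seed = cfg$seed, stages = list(), completed = FALSE)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result <- tryCatch({
    if (!is.null(cfg$sim)) {
      study <- simulate_study(cfg$sim)
      g <- study$genotypes; p <- study$phenotypes; truth <- study$truth
    } else {
      g <- read_genotypes(cfg$genotype_file, cfg$genotype_dialect)
      p <- read_phenotypes(cfg$phenotype_file)
      truth <- if (!is.null(cfg$truth_file)) readLines(cfg$truth_file)
               else character(0)
    }
    manifest$stages$input <- list(n_samples = nrow(g$dosages),
                                   n_snps = ncol(g$dosages),
                                   n_replicates = length(trait_ids(p)),
                                   n_truth = length(truth))
    al <- align_samples(g, p)
    g <- al$genotypes; p <- al$phenotypes

    g <- suppressMessages(filter_by_maf(g, cfg$maf_threshold))
    manifest$stages$maf_filter <- list(n_removed = attr(g, "n_removed"),
                                        n_snps = ncol(g$dosages))
    groups <- NULL
    if (cfg$collapse_duplicates) {
      cd <- suppressMessages(collapse_duplicates(g))
      g <- cd$genotypes; groups <- cd$groups
      write_table6(groups, file.path(cfg$out_dir, "duplicate_groups.tsv"))
      manifest$stages$collapse <- list(n_snps = ncol(g$dosages))
    }

    runs <- run_replicates(g, p, K = cfg$K, n_repeats = cfg$cv_repeats,
                           seed = cfg$seed)
    summ <- selection_summary(runs, truth)
    write_table6(summ$per_snp, file.path(cfg$out_dir, "per_snp.tsv"))
    write_table6(summ$totals, file.path(cfg$out_dir, "totals.tsv"))
    write_table6(proportion_correct(summ),
                 file.path(cfg$out_dir, "proportions.tsv"))
    write_table6(selection_ranks(summ), file.path(cfg$out_dir, "ranks.tsv"))
    lam <- dplyr::distinct(runs[, c("replicate", "lambda_min", "lambda_1se")])
    write_table6(lam, file.path(cfg$out_dir, "cv_lambdas.tsv"))
    writeLines(truth, file.path(cfg$out_dir, "truth.txt"))
    manifest$stages$selection <- list(
      n_replicates_run = length(unique(runs$replicate)),
      snps_into_lasso = ncol(g$dosages))

    bag <- NULL
    if (cfg$bagging) {
      tr1 <- trait_ids(p)[1L]
      lam1 <- lam[lam$replicate == tr1, ]
      lambda_bag <- if (cfg$bag_lambda_rule == "min") lam1$lambda_min
                    else lam1$lambda_1se
      bag <- bag_lasso(g, p, tr1, lambda = lambda_bag, B = cfg$bag_B,
                       seed = stage_seed(cfg$seed, "bagging"))
      rep_tab <- rmip_report(bag, truth = truth)
      write_table6(rep_tab, file.path(cfg$out_dir, "rmip.tsv"))
      manifest$stages$bagging <- list(B = cfg$bag_B,
                                       lambda = lambda_bag,
                                       n_nonzero_rmip = attr(rep_tab, "n_nonzero"))
    } else {
      manifest$stages$bagging <- "skipped"
    }
    manifest$completed <- TRUE
    list(genotypes = g, phenotypes = p, truth = truth, groups = groups,
         runs = runs, summary = summ, bag = bag, out_dir = cfg$out_dir)
  }, error = function(e) {
    manifest$failed_stage <<- conditionMessage(e)
    finish()
    abort(paste0("pipeline failed: ", conditionMessage(e)))
  })
  finish()
  invisible(result)
}
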