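procedure_labels <- c("lasso_min", "lasso_min+AIC", "lasso_min+BIC",
                      "lasso_1se", "lasso_1se+AIC", "lasso_1se+BIC")

#' Published per-replicate selection frequencies of the GAW17 Q1 benchmark
#'
#' The published benchmark summary for the seven common causal SNPs:
#' mean number of times each was selected over the 200 GAW17 phenotype
#' replicates, for the six procedure variants, together with the printed
#' "Total correct" and "Total selected" rows. Used for printed-arithmetic
#' checks (column-sum identity, proportion-correct) and as a qualitative
#' yardstick for the synthetic analog.
#'
#' @return A list with `per_snp` (tibble: `snp_id`, one column per
#'   procedure) and `totals` (tibble: `procedure`, `total_correct`,
#'   `total_selected`).
#' @export
gaw17_selection_reference <- function() {
  per_snp <- tibble::tribble(
    ~snp_id,     ~`lasso_min`, ~`lasso_min+AIC`, ~`lasso_min+BIC`,
                 ~`lasso_1se`, ~`lasso_1se+AIC`, ~`lasso_1se+BIC`,
    "C1S6533",   0.445, 0.440, 0.365, 0.040, 0.040, 0.040,
    "C13S431",   0.775, 0.665, 0.555, 0.185, 0.185, 0.180,
    "C13S522",   0.985, 0.970, 0.880, 0.850, 0.850, 0.850,
    "C13S523",   1.000, 1.000, 1.000, 1.000, 1.000, 1.000,
    "C14S1734",  0.085, 0.065, 0.035, 0.000, 0.000, 0.000,
    "C4S1878",   0.375, 0.265, 0.200, 0.045, 0.045, 0.045,
    "C4S1884",   0.425, 0.385, 0.285, 0.055, 0.055, 0.055
  )
  totals <- tibble::tibble(
    procedure = procedure_labels,
    total_correct = c(4.09, 3.79, 3.32, 2.175, 2.175, 2.170),
    total_selected = c(28.05, 21.18, 14.30, 3.29, 3.22, 3.10)
  )
  list(per_snp = per_snp, totals = totals)
}

#' Run the six-procedure selection pipeline over phenotype replicates
#'
#' For each trait replicate: chooses the penalty by K-fold CV (fresh CV per
#' replicate by default, or a fixed penalty pair reused across replicates),
#' records the LASSO selections at `lambda_min` and `lambda_1se`, and
#' refines each by stepwise AIC and BIC. Per-replicate seeds derive
#' deterministically from the master seed, so runs are reproducible and
#' independent of execution order. Replicates that fail are dropped from
#' summaries with a warning.
#'
#' @param g A `genotype_matrix` (post-filter, duplicates collapsed).
#' @param p A `phenotype_tbl` row-aligned with `g`.
#' @param K Folds for CV (default 10).
#' @param n_repeats CV repetitions per replicate (default 1).
#' @param lambda_mode `"per_replicate"` (default: CV re-run on every
#'   replicate) or `"fixed"` (reuse `fixed_lambda` across replicates, the
#'   replicate-1 style of analysis).
#' @param fixed_lambda Named numeric `c(min = ..., `1se` = ...)` used when
#'   `lambda_mode = "fixed"`.
#' @param seed Master seed.
#' @param traits Trait columns to analyze; default all.
#' @return A tibble of class `replicate_runs`: one row per (replicate,
#'   procedure) with a list-column `snps`, plus penalty bookkeeping.
#' @export
run_replicates <- function(g, p, K = 10L, n_repeats = 1L,
                           lambda_mode = c("per_replicate", "fixed"),
                           fixed_lambda = NULL, seed = 1L,
                           traits = trait_ids(p)) {
  lambda_mode <- match.arg(lambda_mode)
  if (lambda_mode == "fixed") {
    stopifnot(is.numeric(fixed_lambda),
              all(c("min", "1se") %in% names(fixed_lambda)))
  }
  rows <- purrr::imap(traits, function(tr, r) {
    tryCatch({
      d <- standardize_design(g, p, tr)
      if (lambda_mode == "per_replicate") {
        cv <- cross_validate(d, K = K, n_repeats = n_repeats,
                             seed = stage_seed(seed, "cv", r))
        lmin <- cv$lambda_min; l1se <- cv$lambda_1se
      } else {
        lmin <- fixed_lambda[["min"]]; l1se <- fixed_lambda[["1se"]]
      }
      sel <- list()
      for (rule in c("min", "1se")) {
        lam <- if (rule == "min") lmin else l1se
        s1 <- as.character(select_at(d, lam))
        sel[[paste0("lasso_", rule)]] <- s1
        pool <- cbind(d$X[, s1, drop = FALSE], d$Z)
        colnames(pool) <- c(s1, d$covariates)
        for (cr in c("AIC", "BIC")) {
          sw <- stepwise_select(d$y, pool, criterion = cr)
          sel[[paste0("lasso_", rule, "+", cr)]] <-
            intersect(sw$included_terms, s1)
        }
      }
      tibble::tibble(replicate = tr,
                     procedure = procedure_labels,
                     snps = sel[procedure_labels],
                     lambda_min = lmin, lambda_1se = l1se)
    }, error = function(e) {
      warn(paste0("replicate `", tr, "` failed and was excluded: ",
                  conditionMessage(e)))
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("replicate_runs", class(out))
  attr(out, "seed") <- seed
  attr(out, "n_requested") <- length(traits)
  out
}

#' Summarize selections over replicates, Table-2 style
#'
#' Per procedure: how often each SNP was selected across replicates, the
#' mean number of SNPs selected, and the mean number of those that belong
#' to the simulating model (the truth set).
#'
#' @param runs A `replicate_runs` tibble from [run_replicates()].
#' @param truth Character vector of causal SNP ids.
#' @return An object of class `selection_summary`: `per_snp` (tibble:
#'   `procedure`, `snp_id`, `n_selected`, `freq`, `is_truth`) and `totals`
#'   (tibble: `procedure`, `mean_selected`, `mean_correct`,
#'   `n_replicates`). Truth SNPs never selected appear with frequency 0.
#' @export
selection_summary <- function(runs, truth) {
  stopifnot(nrow(runs) > 0L)
  long <- tidyr::unnest(runs[, c("replicate", "procedure", "snps")],
                        cols = "snps", keep_empty = FALSE)
  n_rep <- length(unique(runs$replicate))
  per_snp <- long |>
    dplyr::count(.data$procedure, snp_id = .data$snps, name = "n_selected") |>
    tidyr::complete(procedure = procedure_labels,
                    snp_id = union(unique(long$snps), truth),
                    fill = list(n_selected = 0L)) |>
    dplyr::mutate(freq = .data$n_selected / n_rep,
                  is_truth = .data$snp_id %in% truth) |>
    dplyr::arrange(.data$procedure, dplyr::desc(.data$freq), .data$snp_id)
  totals <- runs |>
    dplyr::mutate(n_sel = purrr::map_int(.data$snps, length),
                  n_cor = purrr::map_int(.data$snps,
                                         ~ length(intersect(.x, truth)))) |>
    dplyr::group_by(.data$procedure) |>
    dplyr::summarise(mean_selected = mean(.data$n_sel),
                     mean_correct = mean(.data$n_cor),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$procedure, procedure_labels))
  structure(list(per_snp = per_snp, totals = totals, truth = truth),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("<selection_summary> over ", x$totals$n_replicates[1L],
      " replicate(s), ", length(x$truth), " truth SNP(s)\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Proportion of selected SNPs that are in the simulating model
#'
#' `mean total correct / mean total selected`, per procedure. Can also be
#' called directly on a pair of printed totals.
#'
#' @param x A `selection_summary`, or a scalar mean-total-correct.
#' @param total_selected Scalar mean-total-selected (only when `x` is a
#'   scalar).
#' @return A tibble (`procedure`, `proportion`) for a summary; a bare
#'   fraction for scalars. Procedures with zero selections get `NA` and a
#'   warning.
#' @export
#' @examples
#' proportion_correct(4.09, 28.05) # 0.1458...
proportion_correct <- function(x, total_selected = NULL) {
  if (is.numeric(x)) {
    stopifnot(is.numeric(total_selected))
    if (total_selected <= 0) abort("total_selected must be positive")
    return(x / total_selected)
  }
  stopifnot(inherits(x, "selection_summary"))
  out <- dplyr::mutate(
    x$totals,
    proportion = ifelse(.data$mean_selected > 0,
                        .data$mean_correct / .data$mean_selected, NA_real_)
  )[, c("procedure", "proportion")]
  if (anyNA(out$proportion)) {
    warn("proportion undefined for procedure(s) with zero mean selections")
  }
  out
}

#' Rank SNPs by selection frequency
#'
#' All SNPs ever selected (plus the truth set) ranked by descending
#' selection frequency under one procedure; tied SNPs share the minimum
#' rank, and rows are ordered by rank then id.
#'
#' @param summary A `selection_summary`.
#' @param procedure One of the six procedure labels (default `"lasso_min"`).
#' @return Tibble with columns `snp_id`, `freq`, `rank`, `is_truth`.
#' @export
selection_ranks <- function(summary, procedure = "lasso_min") {
  stopifnot(inherits(summary, "selection_summary"),
            procedure %in% procedure_labels)
  tab <- dplyr::filter(summary$per_snp, .data$procedure == !!procedure)
  tab <- dplyr::mutate(tab, rank = dplyr::min_rank(dplyr::desc(.data$freq)))
  dplyr::arrange(tab[, c("snp_id", "freq", "rank", "is_truth")],
                 .data$rank, .data$snp_id)
}
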