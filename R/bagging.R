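#' Draw a bootstrap resample of row indices
#'
#' `n` indices drawn uniformly with replacement from `1:n` (resample size
#' equal to the original data), seeded for reproducibility.
#'
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return Integer vector of length `n`.
#' @export
bootstrap_resample <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  with_seed(seed, sample.int(n, n, replace = TRUE))
}

#' Bootstrap bagging of the LASSO stage (RMIP)
#'
#' Refits the stage-1 LASSO on `B` bootstrap resamples of the individuals,
#' holding the penalty fixed at the value chosen on the original data, and
#' records each SNP's resample model inclusion proportion: the fraction of
#' resamples in which it receives a nonzero coefficient. RMIP measures how
#' stable a SNP's selection is under perturbation of the data.
#'
#' Standardization is recomputed within each resample (the model is refit
#' on the resample as if it were the data); SNPs monomorphic within a
#' resample are excluded from that fit and count as unselected.
#'
#' @param g A `genotype_matrix`.
#' @param p A `phenotype_tbl` row-aligned with `g`.
#' @param trait_id Trait column to use as response.
#' @param lambda Fixed positive penalty, e.g. `lambda_min` from
#'   [cross_validate()] on the original data.
#' @param B Number of resamples (default 100).
#' @param seed Master seed; resample `b` uses a seed derived from it.
#' @param covariates Unpenalized covariates, default `Sex`, `Age`, `Smoke`.
#' @inheritParams fit_lasso
#' @return An object of class `rmip_table`: tibble accessor via [tidy()],
#'   with per-resample supports retained for audit.
#' @export
bag_lasso <- function(g, p, trait_id, lambda, B = 100L, seed = NULL,
                      covariates = c("Sex", "Age", "Smoke"),
                      tol = 1e-7, max_iter = 1e5) {
  stopifnot(lambda > 0, B >= 1L)
  ids <- snp_ids(g)
  counts <- setNames(integer(length(ids)), ids)
  supports <- vector("list", B)
  master <- seed %||% stage_seed(0L, "bagging")
  pt <- tibble::as_tibble(p)
  for (b in seq_len(B)) {
    idx <- bootstrap_resample(nrow(g$dosages), stage_seed(master, "resample", b))
    dos_b <- g$dosages[idx, , drop = FALSE]
    poly <- apply(dos_b, 2L, function(x) any(x != x[1L]))
    rownames(dos_b) <- sprintf("r%06d", seq_len(nrow(dos_b))) # resample rows
    g_b <- genotype_matrix(dos_b[, poly, drop = FALSE])
    p_b <- pt[idx, , drop = FALSE]
    p_b$sample_id <- rownames(dos_b)
    p_b <- phenotype_replicates(p_b)
    d_b <- standardize_design(g_b, p_b, trait_id, covariates = covariates)
    fit <- fit_lasso(d_b, lambda, tol = tol, max_iter = max_iter)
    if (!fit$converged) {
      warn(paste0("bag_lasso: resample ", b, " did not converge"))
    }
    supports[[b]] <- fit$support
    counts[fit$support] <- counts[fit$support] + 1L
  }
  structure(
    list(rmip = tibble::tibble(snp_id = ids,
                               n_selected = unname(counts),
                               rmip = unname(counts) / B),
         lambda = lambda, B = B, seed = seed,
         supports = supports),
    class = "rmip_table")
}

#' @export
print.rmip_table <- function(x, ...) {
  cat("<rmip_table> B = ", x$B, " resamples at lambda = ",
      fmt_num(x$lambda), "; ", sum(x$rmip$rmip > 0),
      " SNP(s) with nonzero RMIP\n", sep = "")
  invisible(x)
}

#' Summarize an RMIP table against a truth set
#'
#' Sorts SNPs by descending RMIP, and — when the simulating-model SNPs are
#' known — counts how many true and how many spurious SNPs exceed the
#' stability threshold. The returned tibble is plot-ready (rank on x, RMIP
#' on y, truth flagged), the layout used to display RMIP distributions.
#'
#' @param t An `rmip_table` from [bag_lasso()].
#' @param truth Optional character vector of causal SNP ids.
#' @param threshold Stability threshold on RMIP (default 0.5).
#' @return Tibble with columns `rank`, `snp_id`, `rmip`, `is_truth`, and
#'   attributes `n_nonzero`, `n_true_above`, `n_spurious_above`.
#' @export
rmip_report <- function(t, truth = NULL, threshold = 0.5) {
  stopifnot(inherits(t, "rmip_table"))
  out <- dplyr::arrange(t$rmip, dplyr::desc(.data$rmip), .data$snp_id)
  out$rank <- seq_len(nrow(out))
  out$is_truth <- if (is.null(truth)) NA else out$snp_id %in% truth
  out <- out[, c("rank", "snp_id", "rmip", "is_truth")]
  attr(out, "n_nonzero") <- sum(out$rmip > 0)
  attr(out, "threshold") <- threshold
  if (!is.null(truth)) {
    above <- out$rmip > threshold
    attr(out, "n_true_above") <- sum(above & out$is_truth)
    attr(out, "n_spurious_above") <- sum(above & !out$is_truth)
  }
  out
}
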