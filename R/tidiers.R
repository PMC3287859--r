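# broom-style accessors for fitted objects

#' @describeIn fit_lasso Nonzero coefficients as a tibble (`term`,
#'   `estimate` on the standardized scale, `estimate_raw`, `penalized`).
#' @param x A `lasso_fit`.
#' @param ... Unused.
#' @export
tidy.lasso_fit <- function(x, ...) {
  nz <- x$beta[x$beta != 0]
  tibble::tibble(
    term = c(names(x$gamma), names(nz)),
    estimate = c(unname(x$gamma), unname(nz)),
    penalized = c(rep(FALSE, length(x$gamma)), rep(TRUE, length(nz)))
  )
}

#' @describeIn fit_lasso One-row fit summary.
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$support),
                 objective = x$objective, n_iterations = x$n_iterations,
                 converged = x$converged)
}

#' @describeIn fit_path Long tibble of the coefficient path (`lambda`,
#'   `term`, `estimate`, `penalized`); zero coefficients omitted.
#' @param x A `lasso_path`.
#' @param ... Unused.
#' @export
tidy.lasso_path <- function(x, ...) {
  long <- function(m, pen) {
    idx <- which(m != 0, arr.ind = TRUE)
    tibble::tibble(lambda = x$lambdas[idx[, 2L]],
                   term = rownames(m)[idx[, 1L]],
                   estimate = m[idx], penalized = pen)
  }
  out <- long(x$beta, TRUE)
  if (!is.null(x$gamma)) out <- dplyr::bind_rows(out, long(x$gamma, FALSE))
  dplyr::arrange(out, dplyr::desc(.data$lambda), .data$term)
}

#' @describeIn fit_path One row per penalty: support size and objective.
#' @export
glance.lasso_path <- function(x, ...) {
  tibble::tibble(lambda = x$lambdas, n_selected = unname(x$df),
                 objective = x$objective, converged = x$converged)
}

#' @describeIn cross_validate The CV curve as a tibble (`lambda`, `cvm`,
#'   `cvse`).
#' @param x A `cv_lasso`.
#' @param ... Unused.
#' @export
tidy.cv_lasso <- function(x, ...) x$curve

#' @describeIn cross_validate One-row summary with the chosen penalties.
#' @export
glance.cv_lasso <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
                 K = x$K, n_repeats = x$n_repeats)
}

#' @describeIn stepwise_select Final-model coefficients as a tibble.
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @export
tidy.stepwise_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn stepwise_select One-row summary of the search.
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(criterion = x$criterion_name,
                 n_terms = length(x$included_terms),
                 n_moves = nrow(x$trace) - 1L,
                 final_criterion = x$final_criterion)
}

#' @describeIn bag_lasso RMIP per SNP as a tibble, descending.
#' @param x An `rmip_table`.
#' @param ... Unused.
#' @export
tidy.rmip_table <- function(x, ...) {
  dplyr::arrange(x$rmip, dplyr::desc(.data$rmip), .data$snp_id)
}

#' @describeIn bag_lasso One-row summary of the bagging run.
#' @export
glance.rmip_table <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, B = x$B,
                 n_nonzero = sum(x$rmip$rmip > 0),
                 max_rmip = max(x$rmip$rmip))
}

#' @describeIn selection_summary Per-SNP selection frequencies, long form.
#' @param x A `selection_summary`.
#' @param ... Unused.
#' @export
tidy.selection_summary <- function(x, ...) x$per_snp

#' @describeIn selection_summary Table-2-style totals per procedure with
#'   the proportion correct.
#' @export
glance.selection_summary <- function(x, ...) {
  dplyr::mutate(x$totals,
                proportion_correct = ifelse(.data$mean_selected > 0,
                                            .data$mean_correct / .data$mean_selected,
                                            NA_real_))
}
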