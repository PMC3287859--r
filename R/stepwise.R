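#' Information criterion of an OLS model
#'
#' Fits `y` on an intercept plus the given term columns by least squares
#' and returns `n * log(RSS / n) + penalty * k`, where `k` counts every
#' estimated mean parameter including the intercept and the penalty is 2
#' (AIC) or `log(n)` (BIC). Additive constants of the Gaussian
#' log-likelihood are dropped; this is the `extractAIC()` convention, so
#' traces are comparable to the standard stepwise ecosystem.
#'
#' @param y Response vector.
#' @param terms Numeric matrix of term columns (0 columns = intercept-only).
#' @param criterion `"AIC"` or `"BIC"`.
#' @return Scalar criterion value.
#' @export
model_criterion <- function(y, terms, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  n <- length(y)
  terms <- as.matrix(terms)
  if (nrow(terms) == 0L) terms <- matrix(numeric(0), n, 0L)
  stopifnot(nrow(terms) == n)
  X <- cbind(`(Intercept)` = 1, terms)
  if (n <= ncol(X)) abort("more parameters than observations")
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  rss <- sum(fit$residuals^2)
  pen <- if (criterion == "AIC") 2 else log(n)
  n * log(rss / n) + pen * ncol(X)
}

# criterion of the model given by `included` (logical over pool columns);
# returns +Inf instead of erroring on rank deficiency (move is then skipped)
crit_or_inf <- function(y, pool, included, penalty) {
  X <- cbind(1, pool[, included, drop = FALSE])
  n <- length(y)
  if (n <= ncol(X)) return(Inf)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) return(Inf)
  n * log(sum(fit$residuals^2) / n) + penalty * ncol(X)
}

#' Bidirectional stepwise selection under AIC or BIC
#'
#' Greedy refinement starting from the full candidate model: at each step
#' every single-term deletion from the current model and every single-term
#' addition from the excluded pool is scored, and the move with the lowest
#' criterion is applied if it is strictly below the current value; the
#' search stops when no move improves. Deleted terms may be added back
#' later. Ties prefer deletions over additions, then pool order, so the
#' search is deterministic.
#'
#' @param y Response vector.
#' @param pool Named numeric matrix of candidate term columns (stage-1 SNPs
#'   plus covariates); all columns are eligible for deletion and
#'   re-addition.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param start Character vector of terms in the initial model; default the
#'   full pool.
#' @return An object of class `stepwise_fit` with the included terms, the
#'   move trace, and the final criterion.
#' @export
stepwise_select <- function(y, pool, criterion = c("AIC", "BIC"),
                            start = colnames(pool)) {
  criterion <- match.arg(criterion)
  pool <- as.matrix(pool)
  if (ncol(pool) == 0L) abort("empty candidate pool")
  if (is.null(colnames(pool))) abort("pool columns must be named")
  if (anyDuplicated(colnames(pool))) abort("duplicate pool column names")
  stopifnot(all(start %in% colnames(pool)))
  n <- length(y)
  penalty <- if (criterion == "AIC") 2 else log(n)

  included <- colnames(pool) %in% start
  names(included) <- colnames(pool)
  current <- crit_or_inf(y, pool, included, penalty)
  if (!is.finite(current)) {
    abort("starting model is rank-deficient; collapse collinear terms upstream")
  }
  trace <- list(list(step = 0L, move = "start", term = NA_character_,
                     criterion = current))
  step_i <- 0L
  repeat {
    best_val <- current
    best_j <- NA_integer_
    best_move <- NA_character_
    # deletions first, then additions, each in pool order: first strict
    # minimum wins, giving the documented tie preference
    for (j in which(included)) {
      cand <- included; cand[j] <- FALSE
      v <- crit_or_inf(y, pool, cand, penalty)
      if (v < best_val) { best_val <- v; best_j <- j; best_move <- "drop" }
    }
    for (j in which(!included)) {
      cand <- included; cand[j] <- TRUE
      v <- crit_or_inf(y, pool, cand, penalty)
      if (v < best_val) { best_val <- v; best_j <- j; best_move <- "add" }
    }
    if (is.na(best_j)) break
    included[best_j] <- (best_move == "add")
    current <- best_val
    step_i <- step_i + 1L
    trace[[length(trace) + 1L]] <- list(step = step_i, move = best_move,
                                        term = colnames(pool)[best_j],
                                        criterion = current)
  }

  final_terms <- colnames(pool)[included]
  X <- cbind(`(Intercept)` = 1, pool[, included, drop = FALSE])
  ols <- lm.fit(X, y)
  structure(
    list(criterion_name = criterion,
         included_terms = final_terms,
         coefficients = setNames(ols$coefficients, colnames(X)),
         trace = dplyr::bind_rows(lapply(trace, tibble::as_tibble)),
         final_criterion = current,
         n = n, pool_terms = colnames(pool)),
    class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", x$criterion_name, ": ",
      length(x$included_terms), " of ", length(x$pool_terms),
      " term(s) retained after ", nrow(x$trace) - 1L, " move(s), ",
      x$criterion_name, " = ", fmt_num(x$final_criterion), "\n", sep = "")
  invisible(x)
}

#' Two-stage SNP selection: LASSO screen then stepwise refinement
#'
#' Stage 1 chooses the penalty by K-fold cross-validation (`lambda_min` or
#' `lambda_1se` rule, optionally median-aggregated over repeated CV) and
#' keeps the SNPs with nonzero LASSO coefficients. Stage 2 runs
#' bidirectional stepwise selection over those SNPs plus the covariates,
#' starting from the full stage-1 model. If stage 1 selects nothing, stage
#' 2 runs on the covariates alone and the SNP set is empty.
#'
#' @param d A `standardized_design`.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param criterion `"AIC"` or `"BIC"`, or `NULL` to skip stage 2.
#' @param K,n_repeats,seed Passed to [cross_validate()].
#' @param cv Optional precomputed `cv_lasso` to reuse across variants.
#' @return A list of class `two_stage_fit`: `snps` (final SNP set),
#'   `stage1_snps`, `lambda`, `covariates_kept`, and the underlying
#'   `stepwise_fit` (or `NULL`).
#' @export
two_stage_select <- function(d, lambda_rule = c("min", "1se"),
                             criterion = c("AIC", "BIC"),
                             K = 10L, n_repeats = 1L, seed = NULL,
                             cv = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(cv)) cv <- cross_validate(d, K = K, n_repeats = n_repeats, seed = seed)
  lambda <- if (lambda_rule == "min") cv$lambda_min else cv$lambda_1se
  stage1 <- as.character(select_at(d, lambda))
  if (is.null(criterion)) {
    return(structure(list(snps = stage1, stage1_snps = stage1,
                          lambda = lambda, lambda_rule = lambda_rule,
                          covariates_kept = d$covariates,
                          stepwise = NULL, cv = cv),
                     class = "two_stage_fit"))
  }
  criterion <- match.arg(criterion)
  pool <- cbind(d$X[, stage1, drop = FALSE], d$Z)
  colnames(pool) <- c(stage1, d$covariates)
  sw <- stepwise_select(d$y, pool, criterion = criterion)
  structure(
    list(snps = intersect(sw$included_terms, stage1),
         stage1_snps = stage1,
         lambda = lambda, lambda_rule = lambda_rule,
         covariates_kept = intersect(sw$included_terms, d$covariates),
         stepwise = sw, cv = cv),
    class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("<two_stage_fit> lambda_", x$lambda_rule, " = ", fmt_num(x$lambda),
      ": stage 1 kept ", length(x$stage1_snps), " SNP(s)", sep = "")
  if (!is.null(x$stepwise)) {
    cat(", ", x$stepwise$criterion_name, " refinement kept ",
        length(x$snps), sep = "")
  }
  cat("\n")
  invisible(x)
}
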