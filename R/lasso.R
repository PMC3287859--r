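#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)` — the closed-form solution of the
#' one-dimensional LASSO subproblem, applied at every coordinate update.
#'
#' @param z Numeric vector.
#' @param gamma Nonnegative threshold.
#' @return Shrunken vector, same length as `z`.
#' @export
#' @examples
#' soft_threshold(c(3, -0.5, -3), 1) # 2, 0, -2
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) abort("gamma must be nonnegative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

# solve a penalty path with the naive (residual-update) or Gram-space
# solver; the Gram route precomputes W'W/n once (BLAS) so sweep cost is
# independent of n, and accelerates each penalty with an exact active-set
# solve -- the two routes share the objective and agree to tolerance
solve_path <- function(W, y, pf, lambdas, tol, max_iter, method = "auto") {
  use_gram <- switch(method,
                     gram = TRUE, naive = FALSE,
                     auto = ncol(W) <= 5000L && nrow(W) >= 10L)
  if (use_gram) {
    n <- nrow(W)
    G <- crossprod(W) / n
    cy <- as.vector(crossprod(W, y)) / n
    cd_lasso_gram_cpp(G, cy, mean(y^2), pf, lambdas, tol,
                      as.integer(max_iter), n, TRUE)
  } else {
    cd_lasso_path_cpp(W, y, pf, lambdas, tol, as.integer(max_iter),
                      FALSE, NULL)
  }
}

# stack [Z | X] with penalty factors (0 for covariates, 1 for SNPs)
design_blocks <- function(d, intercept = FALSE) {
  q <- if (is.null(d$Z)) 0L else ncol(d$Z)
  W <- cbind(d$Z, d$X)
  pf <- c(rep(0, q), rep(1, ncol(d$X)))
  if (intercept) {
    W <- cbind(1, W)
    pf <- c(0, pf)
  }
  list(W = W, pf = pf, q = q)
}

#' Smallest penalty with an empty SNP support
#'
#' With `r0` the residual of the response after least squares on the
#' unpenalized covariates alone, returns `max_j |<x_j, r0>| / n` over the
#' penalized SNP columns. At or above this value the LASSO selects no SNP.
#'
#' @param d A `standardized_design`.
#' @return Nonnegative scalar.
#' @export
lambda_max <- function(d) {
  r0 <- if (is.null(d$Z)) d$y else {
    fit <- lm.fit(d$Z, d$y)
    fit$residuals
  }
  max(abs(crossprod(d$X, r0))) / d$n
}

default_lambda_grid <- function(d, n_lambda = 100L, lambda_min_ratio = NULL) {
  lmax <- lambda_max(d)
  if (lmax <= 0) abort("lambda_max is zero; response is orthogonal to all SNPs")
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (d$n < ncol(d$X)) 0.01 else 1e-4
  }
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

new_lasso_fit <- function(d, lambda, coefs, n_sweeps, converged, objective,
                          trace = NULL) {
  q <- if (is.null(d$Z)) 0L else ncol(d$Z)
  gamma <- if (q > 0L) setNames(coefs[seq_len(q)], d$covariates) else numeric(0)
  beta <- setNames(coefs[q + seq_len(ncol(d$X))], d$snp_ids)
  beta[abs(beta) < 1e-10] <- 0 # numerically-zero boundary coefficients
  raw <- backtransform_coefs(d, beta[beta != 0], gamma)
  structure(
    list(lambda = lambda,
         beta = beta, gamma = gamma,
         support = names(beta)[beta != 0],
         intercept = raw$estimate[1L],
         n_iterations = n_sweeps, converged = converged,
         objective = objective, objective_trace = trace),
    class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> lambda = ", fmt_num(x$lambda), ", ",
      length(x$support), " SNP(s) selected, objective ",
      fmt_num(x$objective),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Fit the LASSO at a single penalty value
#'
#' Minimizes `(1/2n) ||y - X beta - Z gamma||^2 + lambda * ||beta||_1` by
#' cyclical coordinate descent with an active-set accelerator. The covariate
#' block `Z` carries penalty factor 0, so `Sex`, `Age` and `Smoke` are free
#' to be nonzero at every penalty. Convergence is declared when a full sweep
#' changes no coefficient by more than `tol`.
#'
#' @param d A `standardized_design`.
#' @param lambda Nonnegative penalty.
#' @param init Optional warm start: a `lasso_fit` on the same design.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (standardized scale), default `1e-7`.
#' @param max_iter Sweep budget, default `1e5`. A fit that exhausts it is
#'   returned with `converged = FALSE` and a warning.
#' @param track_objective If `TRUE`, record the objective after every sweep
#'   in `objective_trace`.
#' @return A `lasso_fit`.
#' @export
fit_lasso <- function(d, lambda, init = NULL, tol = 1e-7, max_iter = 1e5,
                      track_objective = FALSE) {
  stopifnot(inherits(d, "standardized_design"), lambda >= 0, tol > 0)
  blk <- design_blocks(d)
  b0 <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "lasso_fit"))
    b0 <- c(unname(init$gamma), unname(init$beta))
  }
  res <- cd_lasso_path_cpp(blk$W, d$y, blk$pf, lambda, tol,
                           as.integer(max_iter), track_objective, b0)
  if (!res$converged[1L]) {
    warn(paste0("fit_lasso did not converge in ", max_iter, " sweeps"))
  }
  new_lasso_fit(d, lambda, res$coefs[, 1L], res$n_sweeps[1L],
                res$converged[1L], res$objective[1L],
                if (track_objective) res$objective_trace[[1L]])
}

#' Fit the LASSO along a decreasing penalty path
#'
#' The penalty grid is log-spaced from [lambda_max()] down to
#' `lambda_max * lambda_min_ratio`; each fit is warm-started from the
#' previous one. Warm starts only accelerate: cold refits at any grid point
#' give the same solution to tolerance.
#'
#' @inheritParams fit_lasso
#' @param n_lambda Number of grid points (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`;
#'   default `0.01` when `n < p`, else `1e-4`.
#' @param lambdas Optional explicit decreasing penalty sequence overriding
#'   the grid.
#' @param method Solver route: `"auto"` (default), `"gram"` (Gram-space
#'   with exact active-set acceleration), or `"naive"` (residual updates).
#'   Both minimize the same objective and agree to tolerance.
#' @return A `lasso_path`.
#' @export
fit_path <- function(d, n_lambda = 100L, lambda_min_ratio = NULL,
                     lambdas = NULL, tol = 1e-7, max_iter = 1e5,
                     method = c("auto", "gram", "naive")) {
  stopifnot(inherits(d, "standardized_design"))
  method <- match.arg(method)
  if (is.null(lambdas)) {
    lambdas <- default_lambda_grid(d, n_lambda, lambda_min_ratio)
  }
  if (is.unsorted(rev(lambdas), strictly = FALSE)) {
    abort("lambdas must be decreasing")
  }
  blk <- design_blocks(d)
  res <- solve_path(blk$W, d$y, blk$pf, lambdas, tol, max_iter, method)
  q <- blk$q
  beta <- res$coefs[q + seq_len(ncol(d$X)), , drop = FALSE]
  beta[abs(beta) < 1e-10] <- 0
  rownames(beta) <- d$snp_ids
  gamma <- if (q > 0L) {
    gm <- res$coefs[seq_len(q), , drop = FALSE]
    rownames(gm) <- d$covariates
    gm
  } else NULL
  structure(
    list(lambdas = lambdas, beta = beta, gamma = gamma,
         df = colSums(beta != 0),
         objective = res$objective,
         n_iterations = res$n_sweeps,
         converged = res$converged,
         design = d),
    class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("<lasso_path> ", length(x$lambdas), " penalties in [",
      fmt_num(min(x$lambdas)), ", ", fmt_num(max(x$lambdas)),
      "], support size ", min(x$df), "-", max(x$df), "\n", sep = "")
  invisible(x)
}

#' Verify the KKT stationarity conditions of a LASSO fit
#'
#' For the objective `(1/2n)||y - X beta - Z gamma||^2 + lambda ||beta||_1`
#' a solution must satisfy `|<x_j, r>/n| <= lambda` at zero coefficients,
#' `<x_j, r>/n = lambda * sign(beta_j)` at nonzero ones, and `<z_k, r>/n = 0`
#' for unpenalized columns. Used as a self-contained correctness instrument
#' for the solver.
#'
#' @param fit A `lasso_fit`.
#' @param d The `standardized_design` it was fit on.
#' @param tol Violation tolerance (default `1e-6`).
#' @return A list with `ok`, `worst_violation`, and a per-term tibble
#'   `details`.
#' @export
check_kkt <- function(fit, d, tol = 1e-6) {
  r <- d$y - as.vector(d$X %*% fit$beta) -
    (if (is.null(d$Z)) 0 else as.vector(d$Z %*% fit$gamma))
  gx <- as.vector(crossprod(d$X, r)) / d$n
  viol_x <- ifelse(fit$beta == 0,
                   pmax(abs(gx) - fit$lambda, 0),
                   abs(gx - fit$lambda * sign(fit$beta)))
  viol_z <- if (is.null(d$Z)) numeric(0) else abs(crossprod(d$Z, r)) / d$n
  details <- tibble::tibble(
    term = c(d$snp_ids, d$covariates),
    penalized = c(rep(TRUE, length(gx)), rep(FALSE, length(viol_z))),
    violation = c(viol_x, as.vector(viol_z))
  )
  worst <- max(details$violation)
  list(ok = worst <= tol, worst_violation = worst, details = details)
}

#' K-fold cross-validation of the LASSO penalty
#'
#' Randomly assigns individuals to `K` near-equal folds, fits the penalty
#' path on each training portion (penalty grid computed once from the full
#' data), and scores held-out mean squared prediction error. `lambda_min`
#' minimizes the CV error curve; `lambda_1se` is the largest penalty whose
#' CV error is within one standard error of that minimum. With
#' `n_repeats > 1` the whole procedure is repeated on fresh fold
#' assignments and the median `lambda_min` / `lambda_1se` across repeats is
#' reported, stabilizing the choice against the random partitioning.
#'
#' Fold fits include an unpenalized intercept column (training rows of a
#' centered design are not exactly centered). SNP columns monomorphic
#' within a training fold are pinned to zero for that fold.
#'
#' Fold fits default to a coarser convergence tolerance (`1e-4`) than
#' full-data fits: held-out mean squared error is insensitive to
#' coefficient wiggle at that scale, while the dense low-penalty end of
#' the path (support near the sample count when `n < p`) converges slowly
#' under a strict tolerance. The final selection fit at the chosen penalty
#' (see [select_at()]) always runs at the strict default.
#'
#' @param d A `standardized_design`.
#' @param K Number of folds (default 10).
#' @param n_repeats Number of CV repetitions (default 1).
#' @param seed Seed for the fold assignments.
#' @inheritParams fit_path
#' @return An object of class `cv_lasso`: CV curve (averaged over repeats),
#'   `lambda_min`, `lambda_1se`, and per-repeat values.
#' @export
cross_validate <- function(d, K = 10L, n_repeats = 1L, seed = NULL,
                           n_lambda = 100L, lambda_min_ratio = NULL,
                           tol = 1e-4, max_iter = 1e5) {
  stopifnot(inherits(d, "standardized_design"), K >= 2L, d$n >= 2L * K)
  lambdas <- default_lambda_grid(d, n_lambda, lambda_min_ratio)
  blk <- design_blocks(d, intercept = TRUE)
  L <- length(lambdas)

  run_one <- function() {
    fold <- sample(rep_len(seq_len(K), d$n))
    fold_mse <- matrix(NA_real_, K, L)
    for (k in seq_len(K)) {
      tr <- fold != k
      res <- solve_path(blk$W[tr, , drop = FALSE], d$y[tr], blk$pf,
                        lambdas, tol, max_iter)
      pred <- blk$W[!tr, , drop = FALSE] %*% res$coefs
      fold_mse[k, ] <- colMeans((d$y[!tr] - pred)^2)
    }
    cvm <- colMeans(fold_mse)
    cvse <- apply(fold_mse, 2L, sd) / sqrt(K)
    i_min <- which.min(cvm)
    list(cvm = cvm, cvse = cvse,
         lambda_min = lambdas[i_min],
         lambda_1se = max(lambdas[cvm <= cvm[i_min] + cvse[i_min]]))
  }

  reps <- with_seed(seed, lapply(seq_len(n_repeats), function(i) run_one()))
  per_repeat <- tibble::tibble(
    repetition = seq_len(n_repeats),
    lambda_min = purrr::map_dbl(reps, "lambda_min"),
    lambda_1se = purrr::map_dbl(reps, "lambda_1se")
  )
  curve <- tibble::tibble(
    lambda = lambdas,
    cvm = rowMeans(vapply(reps, `[[`, numeric(L), "cvm")),
    cvse = rowMeans(vapply(reps, `[[`, numeric(L), "cvse"))
  )
  structure(
    list(curve = curve,
         lambda_min = median(per_repeat$lambda_min),
         lambda_1se = median(per_repeat$lambda_1se),
         per_repeat = per_repeat,
         K = K, n_repeats = n_repeats, seed = seed),
    class = "cv_lasso")
}

#' @export
print.cv_lasso <- function(x, ...) {
  cat("<cv_lasso> ", x$K, "-fold CV",
      if (x$n_repeats > 1L) paste0(" x ", x$n_repeats, " repeats (medians)"),
      ": lambda_min = ", fmt_num(x$lambda_min),
      ", lambda_1se = ", fmt_num(x$lambda_1se), "\n", sep = "")
  invisible(x)
}

#' SNPs selected by the LASSO at a given penalty
#'
#' Refits on the full design at `lambda` (warm-started down a short path
#' from [lambda_max()] for stability) and returns the SNP ids with nonzero
#' penalized coefficients.
#'
#' @param d A `standardized_design`.
#' @param lambda Nonnegative penalty, e.g. `lambda_min` or `lambda_1se`
#'   from [cross_validate()].
#' @inheritParams fit_lasso
#' @return Character vector of selected SNP ids; the underlying `lasso_fit`
#'   is attached as attribute `"fit"`.
#' @export
select_at <- function(d, lambda, tol = 1e-7, max_iter = 1e5) {
  stopifnot(lambda >= 0)
  lmax <- lambda_max(d)
  fit <- if (lambda >= lmax || lambda == 0) {
    fit_lasso(d, lambda, tol = tol, max_iter = max_iter)
  } else {
    grid <- exp(seq(log(lmax), log(lambda), length.out = 30L))
    grid[length(grid)] <- lambda
    path <- fit_path(d, lambdas = grid, tol = tol, max_iter = max_iter)
    path_fit(path, length(grid))
  }
  out <- fit$support
  attr(out, "fit") <- fit
  out
}

# materialize one path point as a lasso_fit
path_fit <- function(path, i) {
  d <- path$design
  coefs <- c(if (!is.null(path$gamma)) path$gamma[, i], path$beta[, i])
  new_lasso_fit(d, path$lambdas[i], coefs, path$n_iterations[i],
                path$converged[i], path$objective[i])
}
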