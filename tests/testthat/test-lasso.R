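test_that("soft_threshold implements the scalar LASSO solution", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2) # odd symmetry
  expect_equal(soft_threshold(c(3, -0.5, -3), 1), c(2, 0, -2))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("lambda_max is the entry penalty of the first SNP", {
  # single penalized column with <x, y>/n = 0.7, no covariates
  withr::with_seed(21, {
    d <- gauss_design(40, 1)
    e <- stats::residuals(stats::lm(rnorm(40) ~ d$X[, 1] - 1))
    d$y <- 0.7 * d$X[, 1] + e - mean(0.7 * d$X[, 1] + e)
    d$y <- d$y - d$X[, 1] * (sum(d$X[, 1] * d$y) / 40 - 0.7) # pin inner product
    expect_equal(lambda_max(d), 0.7, tolerance = 1e-10)
  })

  # orthogonal response: lambda_max 0
  d0 <- gauss_design(20, 2, seed = 22)
  d0$y <- rep(0, 20)
  expect_equal(lambda_max(d0), 0)

  # empty support just above, nonempty just below
  d2 <- rand_design(50, 10, beta = c(S0001 = 0.8), sd = 0.5, seed = 23)
  lmax <- lambda_max(d2)
  expect_length(fit_lasso(d2, lmax * 1.000001)$support, 0L)
  expect_gt(length(fit_lasso(d2, lmax * 0.99)$support), 0L)
})

test_that("at lambda >= lambda_max covariates equal their OLS fit", {
  d <- rand_design(80, 12, beta = c(S0002 = 0.6), sd = 1, seed = 24)
  f <- fit_lasso(d, lambda_max(d) * 1.01)
  expect_length(f$support, 0L)
  gamma_ols <- lm.fit(d$Z, d$y)$coefficients
  expect_equal(unname(f$gamma), unname(gamma_ols), tolerance = 1e-7)
})

test_that("the lambda = 0 fit matches ordinary least squares", {
  d <- gauss_design(60, 8, q = 3, seed = 25)
  f <- fit_lasso(d, 0)
  ref <- lm.fit(cbind(d$Z, d$X), d$y)$coefficients
  expect_equal(unname(c(f$gamma, f$beta)), unname(ref), tolerance = 1e-6)
})

test_that("coordinate descent agrees with a proximal-gradient oracle", {
  # >= 20 random small instances, mixed penalized/unpenalized blocks
  worst_obj <- 0
  for (seed in 1:20) {
    q <- seed %% 3
    d <- gauss_design(30 + seed, 5 + seed %% 5, q = q, seed = 100 + seed)
    W <- cbind(d$Z, d$X)
    pf <- c(rep(0, q), rep(1, ncol(d$X)))
    lam <- 0.05 + 0.02 * (seed %% 4)
    f <- fit_lasso(d, lam)
    mine <- c(f$gamma, f$beta)
    oracle <- fista_lasso(W, d$y, pf, lam)
    obj_mine <- sum((d$y - W %*% mine)^2) / (2 * d$n) + lam * sum(abs(f$beta))
    rel <- abs(obj_mine - oracle$objective) / max(1, abs(oracle$objective))
    worst_obj <- max(worst_obj, rel)
    expect_lt(rel, 1e-5)
    expect_lt(max(abs(mine - oracle$beta)), 1e-4)
  }
  expect_lt(worst_obj, 1e-5)
})

test_that("solutions agree with glmnet on all-penalized instances", {
  skip_if_not_installed("glmnet")
  for (seed in c(31, 32, 33)) {
    d <- gauss_design(50, 8, seed = seed)
    for (lam in c(0.02, 0.08, 0.2)) {
      gf <- glmnet::glmnet(d$X, d$y, lambda = lam, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-14)
      f <- fit_lasso(d, lam)
      expect_equal(unname(f$beta),
                   as.vector(stats::coef(gf))[-1], tolerance = 1e-6)
    }
  }
})

test_that("KKT conditions certify converged fits and expose perturbed ones", {
  d <- rand_design(60, 15, beta = c(S0003 = 0.7), sd = 0.8, seed = 26)
  f <- fit_lasso(d, 0.08)
  rep1 <- check_kkt(f, d)
  expect_true(rep1$ok)
  expect_lt(rep1$worst_violation, 1e-6)

  f_bad <- f
  j <- which(f$beta != 0)[1]
  f_bad$beta[j] <- f_bad$beta[j] + 0.1
  expect_gt(check_kkt(f_bad, d)$worst_violation, 1e-6)

  f_empty <- fit_lasso(d, lambda_max(d) * 1.05)
  expect_true(check_kkt(f_empty, d)$ok)
})

test_that("the objective is nonincreasing across coordinate sweeps", {
  d <- gauss_design(40, 10, q = 2, seed = 27)
  f <- fit_lasso(d, 0.05, track_objective = TRUE)
  expect_true(all(diff(f$objective_trace) <= 1e-12))
})

test_that("column order is bookkeeping only", {
  d <- rand_design(50, 12, beta = c(S0001 = 0.9, S0007 = -0.5), sd = 0.5,
                   seed = 28)
  f1 <- fit_lasso(d, 0.06)
  perm <- withr::with_seed(1, sample(ncol(d$X)))
  d2 <- d
  d2$X <- d$X[, perm]
  d2$snp_ids <- d$snp_ids[perm]
  d2$x_center <- d$x_center[perm]
  d2$x_scale <- d$x_scale[perm]
  f2 <- fit_lasso(d2, 0.06)
  expect_setequal(f1$support, f2$support)
  expect_equal(f1$beta[d$snp_ids], f2$beta[d$snp_ids], tolerance = 1e-8)
})

test_that("path fits start empty, grow, and match cold restarts", {
  d <- rand_design(60, 20, beta = c(S0002 = 0.8), sd = 0.7, seed = 29)
  path <- fit_path(d, n_lambda = 30)
  expect_equal(path$df[[1]], 0L)
  expect_gte(path$df[[30]], path$df[[1]])
  expect_true(all(diff(path$lambdas) < 0))
  # warm starts are an accelerator, not a semantics change
  for (i in c(5, 15, 30)) {
    cold <- fit_lasso(d, path$lambdas[i])
    expect_equal(unname(cold$beta), unname(path$beta[, i]), tolerance = 1e-6)
  }
  # the two solver routes agree
  pg <- fit_path(d, n_lambda = 30, method = "gram")
  pn <- fit_path(d, n_lambda = 30, method = "naive")
  expect_equal(pg$beta, pn$beta, tolerance = 1e-6)
})

test_that("cross-validation honors the one-standard-error ordering", {
  d <- rand_design(120, 20, beta = c(S0001 = 0.8, S0005 = -0.6), sd = 1,
                   seed = 30)
  cv <- cross_validate(d, K = 5, n_repeats = 3, seed = 77)
  expect_true(all(cv$per_repeat$lambda_1se >= cv$per_repeat$lambda_min))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_true(all(is.finite(cv$curve$cvm)) && all(cv$curve$cvm > 0))
  expect_true(all(cv$curve$cvse >= 0))
})

test_that("pure-noise designs select nothing at lambda_1se", {
  hits <- 0L
  n_seeds <- 25L
  for (seed in seq_len(n_seeds)) {
    d <- rand_design(200, 50, beta = NULL, sd = 1, seed = 400 + seed)
    cv <- cross_validate(d, K = 10, seed = 500 + seed)
    sel <- select_at(d, cv$lambda_1se)
    if (length(sel) == 0L) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("a dominant SNP is always selected at both penalty rules", {
  for (seed in 1:5) {
    d <- rand_design(200, 30, beta = c(S0004 = 2), sd = 0.1,
                     seed = 600 + seed)
    cv <- cross_validate(d, K = 10, seed = 700 + seed)
    expect_true("S0004" %in% select_at(d, cv$lambda_min))
    expect_true("S0004" %in% select_at(d, cv$lambda_1se))
  }
})

test_that("select_at reproduces the support of the matching path point", {
  d <- rand_design(80, 15, beta = c(S0001 = 0.7), sd = 0.6, seed = 31)
  path <- fit_path(d, n_lambda = 20)
  i <- 12
  sel <- select_at(d, path$lambdas[i])
  expect_setequal(as.character(sel), names(which(path$beta[, i] != 0)))
  # at or above lambda_max the selection is empty
  expect_length(select_at(d, lambda_max(d)), 0L)
})
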