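# build a response with an exact residual sum of squares over [1, X]
exact_rss_response <- function(X, rss, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(X)
    raw <- rnorm(n)
    e <- stats::residuals(stats::lm(raw ~ X))
    e * sqrt(rss / sum(e^2))
  })
}

test_that("model_criterion reproduces the closed-form AIC and BIC", {
  withr::with_seed(51, {
    X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  })
  y <- exact_rss_response(X, rss = 100) # n = 100, RSS = 100, k = 3
  expect_equal(model_criterion(y, X, "AIC"), 6, tolerance = 1e-9)
  expect_equal(model_criterion(y, X, "BIC"), 3 * log(100), tolerance = 1e-9)
})

test_that("adding a noise column changes the criterion by the known amount", {
  withr::with_seed(52, {
    X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X[, 1] * 0.5 + rnorm(100)
    noise <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "junk"))
  })
  for (crit in c("AIC", "BIC")) {
    before <- model_criterion(y, X, crit)
    after <- model_criterion(y, cbind(X, noise), crit)
    # independent lm oracle for the RSS ratio
    rss_old <- sum(stats::residuals(stats::lm(y ~ X))^2)
    rss_new <- sum(stats::residuals(stats::lm(y ~ cbind(X, noise)))^2)
    pen <- if (crit == "AIC") 2 else log(100)
    expect_gte(rss_old, rss_new)
    expect_equal(after - before, pen - 100 * log(rss_old / rss_new),
                 tolerance = 1e-9)
    expect_equal(before, ols_criterion(y, X, crit), tolerance = 1e-9)
  }
  expect_error(model_criterion(y, cbind(X, X[, 1, drop = FALSE]), "AIC"),
               "collinear")
})

test_that("a dominant predictor survives stepwise under both criteria", {
  withr::with_seed(53, {
    pool <- matrix(rnorm(200 * 6), 200, 6,
                   dimnames = list(NULL, paste0("t", 1:6)))
    y <- 2 * pool[, 3] + rnorm(200, 0, 0.1)
  })
  for (crit in c("AIC", "BIC")) {
    sw <- stepwise_select(y, pool, crit)
    expect_true("t3" %in% sw$included_terms)
    expect_lte(sw$final_criterion, sw$trace$criterion[1])
  }
})

test_that("BIC prunes pure-noise pools almost always", {
  good <- 0L
  for (seed in 1:50) {
    withr::with_seed(800 + seed, {
      pool <- matrix(rnorm(500 * 10), 500, 10,
                     dimnames = list(NULL, paste0("n", 1:10)))
      y <- rnorm(500)
    })
    sw <- stepwise_select(y, pool, "BIC")
    if (length(sw$included_terms) <= 1L) good <- good + 1L
  }
  expect_gte(good / 50, 0.9)
})

test_that("the trace decreases strictly and the end point is single-move stable", {
  for (seed in c(61, 62, 63)) {
    withr::with_seed(seed, {
      pool <- matrix(rnorm(150 * 8), 150, 8,
                     dimnames = list(NULL, paste0("v", 1:8)))
      y <- 0.6 * pool[, 1] - 0.4 * pool[, 5] + rnorm(150)
    })
    sw <- stepwise_select(y, pool, "AIC")
    expect_true(all(diff(sw$trace$criterion) < 0))
    # exhaustive post-hoc audit: no single add or drop improves
    inc <- colnames(pool) %in% sw$included_terms
    base <- sw$final_criterion
    for (j in seq_len(ncol(pool))) {
      cand <- inc
      cand[j] <- !cand[j]
      v <- tryCatch(model_criterion(y, pool[, cand, drop = FALSE], "AIC"),
                    error = function(e) Inf)
      expect_gte(v, base - 1e-10)
    }
  }
})

test_that("greedy search lands in the exhaustively enumerated stable set", {
  for (seed in c(71, 72, 73, 74)) {
    withr::with_seed(seed, {
      pool <- matrix(rnorm(60 * 8), 60, 8,
                     dimnames = list(NULL, paste0("c", 1:8)))
      y <- 0.8 * pool[, 2] + 0.5 * pool[, 7] + rnorm(60)
    })
    for (crit in c("AIC", "BIC")) {
      sw <- stepwise_select(y, pool, crit)
      stable <- stable_models(y, pool, crit)
      expect_true(any(vapply(stable, identical, logical(1),
                             sort(sw$included_terms))))
    }
  }
})

test_that("the search matches the standard stepwise implementation", {
  withr::with_seed(81, {
    pool <- matrix(rnorm(100 * 5), 100, 5,
                   dimnames = list(NULL, paste0("s", 1:5)))
    y <- 0.7 * pool[, 1] + 0.3 * pool[, 4] + rnorm(100)
  })
  df <- data.frame(y = y, pool)
  full <- stats::lm(y ~ ., data = df)
  for (crit in c("AIC", "BIC")) {
    k <- if (crit == "AIC") 2 else log(100)
    ref <- stats::step(full, direction = "both", trace = 0, k = k)
    kept_ref <- setdiff(names(stats::coef(ref)), "(Intercept)")
    sw <- stepwise_select(y, pool, crit)
    expect_setequal(sw$included_terms, kept_ref)
    expect_equal(sw$final_criterion,
                 stats::extractAIC(ref, k = k)[2], tolerance = 1e-8)
  }
})

test_that("two-stage selection composes CV, LASSO, and stepwise", {
  d <- rand_design(150, 25, beta = c(S0002 = 1.2, S0009 = -0.8), sd = 0.5,
                   seed = 82)
  ts <- two_stage_select(d, "min", "BIC", K = 5, seed = 83)
  # pool closure: nothing outside stage 1 + covariates
  expect_true(all(ts$snps %in% ts$stage1_snps))
  expect_true(all(ts$stepwise$included_terms %in%
                    c(ts$stage1_snps, d$covariates)))
  expect_true(all(c("S0002", "S0009") %in% ts$snps))

  # degenerate composition: empty stage 1 gives an empty SNP set
  fake_cv <- list(lambda_min = lambda_max(d) * 2,
                  lambda_1se = lambda_max(d) * 2)
  ts0 <- two_stage_select(d, "min", "AIC", cv = fake_cv)
  expect_length(ts0$stage1_snps, 0L)
  expect_length(ts0$snps, 0L)
})

test_that("BIC models are no larger than AIC models on average", {
  sizes <- purrr::map_dfr(1:8, function(seed) {
    d <- rand_design(150, 20,
                     beta = c(S0001 = 0.5, S0004 = 0.4, S0008 = -0.3),
                     sd = 1, seed = 900 + seed)
    cv <- cross_validate(d, K = 5, seed = 950 + seed)
    s1 <- as.character(select_at(d, cv$lambda_min))
    pool <- cbind(d$X[, s1, drop = FALSE], d$Z)
    colnames(pool) <- c(s1, d$covariates)
    tibble::tibble(
      lasso = length(s1),
      aic = sum(stepwise_select(d$y, pool, "AIC")$included_terms %in% s1),
      bic = sum(stepwise_select(d$y, pool, "BIC")$included_terms %in% s1)
    )
  })
  expect_lte(mean(sizes$bic), mean(sizes$aic))
  expect_lte(mean(sizes$aic), mean(sizes$lasso))
})
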