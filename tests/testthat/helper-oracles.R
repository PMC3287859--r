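# independent oracles, deliberately implemented with different algorithms
# than the package (proximal gradient vs coordinate descent; exhaustive
# enumeration vs greedy search)

# FISTA proximal-gradient solver for
#   (1/2n) ||y - W b||^2 + lambda * sum_j pf_j |b_j|
fista_lasso <- function(W, y, pf, lambda, iters = 20000L) {
  n <- nrow(W)
  L <- max(eigen(crossprod(W) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  b <- rep(0, ncol(W))
  v <- b
  t_k <- 1
  for (i in seq_len(iters)) {
    grad <- -as.vector(crossprod(W, y - W %*% v)) / n
    b_new <- sign(v - grad / L) * pmax(abs(v - grad / L) - lambda * pf / L, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    if (max(abs(b_new - b)) < 1e-12 && i > 10) { b <- b_new; break }
    b <- b_new
    t_k <- t_new
  }
  obj <- sum((y - W %*% b)^2) / (2 * n) + lambda * sum(pf * abs(b))
  list(beta = b, objective = obj)
}

# criterion via a separate code path (stats::lm on a data frame)
ols_criterion <- function(y, terms, criterion) {
  df <- as.data.frame(terms)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit))
  pen <- if (criterion == "AIC") 2 else log(length(y))
  length(y) * log(rss / length(y)) + pen * k
}

# all single-move-stable subsets of a candidate pool (<= 12 columns)
stable_models <- function(y, pool, criterion) {
  p <- ncol(pool)
  stopifnot(p <= 12)
  crit_of <- function(sel) {
    tryCatch(model_criterion(y, pool[, sel, drop = FALSE], criterion),
             error = function(e) Inf)
  }
  subsets <- lapply(0:(2^p - 1), function(code) which(bitwAnd(code, 2^(0:(p - 1))) > 0))
  crits <- vapply(subsets, crit_of, numeric(1))
  stable <- vapply(seq_along(subsets), function(i) {
    sel <- subsets[[i]]
    if (!is.finite(crits[i])) return(FALSE)
    for (j in seq_len(p)) {
      nb <- if (j %in% sel) setdiff(sel, j) else sort(c(sel, j))
      code <- sum(2^(nb - 1)) + 1
      if (crits[code] < crits[i]) return(FALSE)
    }
    TRUE
  }, logical(1))
  lapply(subsets[stable], function(sel) sort(colnames(pool)[sel]))
}
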