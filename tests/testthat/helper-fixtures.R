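# fixture builders: every data set used by the tests is generated in code

# random Hardy-Weinberg genotype matrix, all columns polymorphic
rand_genotypes <- function(n, p, mafs = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(mafs)) mafs <- runif(p, 0.05, 0.5)
    dos <- vapply(mafs, function(m) {
      repeat {
        x <- rbinom(n, 2L, m)
        if (length(unique(x)) > 1L) return(as.numeric(x))
      }
    }, numeric(n))
    dimnames(dos) <- list(sprintf("I%04d", seq_len(n)),
                          sprintf("S%04d", seq_len(p)))
    genotype_matrix(dos)
  })
}

# phenotype table over g: y_r = G beta + eps_r, covariates random
rand_phenotypes <- function(g, beta = NULL, sd = 1, n_rep = 1, seed = 2) {
  withr::with_seed(seed, {
    n <- nrow(g$dosages)
    genetic <- if (is.null(beta)) rep(0, n) else {
      as.vector(g$dosages[, names(beta), drop = FALSE] %*% beta)
    }
    df <- tibble::tibble(
      sample_id = rownames(g$dosages),
      Sex = as.numeric(rbinom(n, 1, 0.5)),
      Age = as.numeric(round(rnorm(n, 50, 10))),
      Smoke = as.numeric(rbinom(n, 1, 0.3))
    )
    for (r in seq_len(n_rep)) {
      df[[paste0("y_", r)]] <- genetic + rnorm(n, 0, sd)
    }
    phenotype_replicates(df)
  })
}

# genotype-backed standardized design in one call
rand_design <- function(n, p, beta = NULL, sd = 1, seed = 3,
                        trait = "y_1", n_rep = 1) {
  g <- rand_genotypes(n, p, seed = seed)
  ph <- rand_phenotypes(g, beta = beta, sd = sd, n_rep = n_rep,
                        seed = seed + 1000)
  standardize_design(g, ph, trait)
}

# standardized design straight from Gaussian matrices (solver tests)
gauss_design <- function(n, p, q = 0, seed = 4, y = NULL) {
  withr::with_seed(seed, {
    X <- standardize_columns(matrix(rnorm(n * p), n, p,
                                    dimnames = list(NULL, paste0("x", seq_len(p)))))
    Z <- NULL
    covs <- character(0)
    if (q > 0) {
      covs <- c("Sex", "Age", "Smoke")[seq_len(q)]
      Z <- standardize_columns(matrix(rnorm(n * q), n, q,
                                      dimnames = list(NULL, covs)))
    }
    if (is.null(y)) y <- rnorm(n)
    y <- y - mean(y)
    structure(
      list(X = unclass(X)[, , drop = FALSE], Z = if (q > 0) unclass(Z) else NULL,
           y = y,
           x_center = attr(X, "center"), x_scale = attr(X, "scale"),
           z_center = if (q > 0) attr(Z, "center") else numeric(0),
           z_scale = if (q > 0) attr(Z, "scale") else numeric(0),
           y_center = 0,
           snp_ids = colnames(X), covariates = covs,
           trait_id = "y", n = n),
      class = "standardized_design")
  })
}

# write a small delimited genotype file and return its path
write_geno_text <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
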