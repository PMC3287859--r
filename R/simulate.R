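#' Common causal SNPs of the emulated GAW17 Q1 simulating model
#'
#' The seven common variants (MAF > 0.01) that carry additive effects on the
#' quantitative trait Q1 in the GAW17 simulating model for unrelated
#' individuals, with their published MAFs and per-allele effect sizes. These
#' are the default causal table of [sim_config()] and the default truth set
#' against which selections are scored.
#'
#' @return A tibble with columns `snp_id`, `gene`, `chromosome`, `maf`,
#'   `beta`, one row per causal SNP.
#' @export
#' @examples
#' gaw17_causal_snps()
gaw17_causal_snps <- function() {
  tibble::tribble(
    ~snp_id,    ~gene,   ~chromosome, ~maf,     ~beta,
    "C1S6533",  "ARNT",  "1",         0.011478, 0.56190,
    "C13S431",  "FLT1",  "13",        0.017217, 0.74136,
    "C13S522",  "FLT1",  "13",        0.027977, 0.61830,
    "C13S523",  "FLT1",  "13",        0.066714, 0.64997,
    "C14S1734", "HIF1A", "14",        0.012195, 0.21203,
    "C4S1878",  "KDR",   "4",         0.164993, 0.13573,
    "C4S1884",  "KDR",   "4",         0.020803, 0.29558
  )
}

#' Configure the synthetic study generator
#'
#' Parameterizes a GAW17-Q1-like study: a fixed genotype matrix of unrelated
#' individuals (independent Hardy-Weinberg SNPs, optionally with LD blocks),
#' fixed covariates `Sex`, `Age`, `Smoke`, and any number of phenotype
#' replicates sharing the genotypes, each with fresh Gaussian residual
#' noise. Defaults mirror the emulated study: 697 individuals and a
#' post-filter panel of 6,321 common SNPs (7 causal + 6,314 null).
#'
#' @param n_individuals Number of individuals (default 697).
#' @param n_null_snps Number of non-causal SNPs (default 6314).
#' @param causal Causal-SNP table: tibble with columns `snp_id`, `maf`,
#'   `beta` (and optionally `gene`, `chromosome`). Default
#'   [gaw17_causal_snps()].
#' @param null_maf_law Law for null-SNP MAFs: `"uniform"` (uniform on
#'   `[maf_range[1], maf_range[2]]`) or `"beta"` (rare-leaning
#'   `Beta(0.3, 1)` truncated to the range), the latter closer to a real
#'   exome spectrum.
#' @param maf_range Range for null-SNP MAFs, default `c(0.01, 0.5)` — the
#'   post-filter world of common variants.
#' @param covariate_effects Named numeric: effects of `Sex`, `Age`, `Smoke`
#'   on the trait. Default all 0 (covariates act as adjustment terms only).
#' @param residual_sd Standard deviation of the Gaussian residual, default 1.
#' @param n_replicates Number of phenotype replicates (default 200).
#' @param ld_blocks Optional tibble/data frame with columns `size` and `r`
#'   (latent pairwise correlation target); each block groups consecutive
#'   null SNPs generated from a shared latent Gaussian (Gaussian copula),
#'   thresholded at the block's MAF (drawn once per block, so `r = 1`
#'   yields identical columns).
#' @param seed Master seed for the generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 697L,
                       n_null_snps = 6314L,
                       causal = gaw17_causal_snps(),
                       null_maf_law = c("uniform", "beta"),
                       maf_range = c(0.01, 0.5),
                       covariate_effects = c(Sex = 0, Age = 0, Smoke = 0),
                       residual_sd = 1.0,
                       n_replicates = 200L,
                       ld_blocks = NULL,
                       seed = 1L) {
  null_maf_law <- match.arg(null_maf_law)
  causal <- tibble::as_tibble(causal)
  if (nrow(causal) > 0L) {
    stopifnot(all(c("snp_id", "maf", "beta") %in% names(causal)))
    if (any(causal$maf <= 0 | causal$maf > 0.5)) {
      abort("causal MAFs must lie in (0, 0.5]")
    }
  }
  if (residual_sd <= 0) abort("residual_sd must be positive")
  stopifnot(n_individuals >= 1L, n_null_snps >= 0L, n_replicates >= 1L)
  if (!is.null(ld_blocks)) {
    ld_blocks <- tibble::as_tibble(ld_blocks)
    stopifnot(all(c("size", "r") %in% names(ld_blocks)),
              sum(ld_blocks$size) <= n_null_snps,
              all(ld_blocks$r >= 0 & ld_blocks$r <= 1))
  }
  ce <- c(Sex = 0, Age = 0, Smoke = 0)
  ce[names(covariate_effects)] <- covariate_effects
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_null_snps = as.integer(n_null_snps),
         causal = causal,
         null_maf_law = null_maf_law,
         maf_range = maf_range,
         covariate_effects = ce,
         residual_sd = residual_sd,
         n_replicates = as.integer(n_replicates),
         ld_blocks = ld_blocks,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_individuals, " individuals, ",
      nrow(x$causal), " causal + ", x$n_null_snps, " null SNPs, ",
      x$n_replicates, " replicate(s), residual sd ", x$residual_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Causal SNP ids of a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return Character vector of causal SNP ids (the truth set used to score
#'   selections).
#' @export
truth_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$causal$snp_id
}

# draw one Hardy-Weinberg dosage column, regenerating monomorphic draws
draw_dosage <- function(n, maf, label, max_retry = 100L) {
  for (i in seq_len(max_retry)) {
    x <- rbinom(n, 2L, maf)
    if (length(unique(x)) > 1L) return(x)
  }
  abort(paste0("could not draw a polymorphic column for ", label,
               " (maf = ", maf, ") in ", max_retry, " attempts"))
}

#' Simulate a genotype matrix
#'
#' Each SNP column is drawn independently as `Binomial(2, maf)` per
#' individual (Hardy-Weinberg equilibrium). SNPs inside an LD block are
#' instead generated from a shared latent Gaussian per allele copy
#' (correlation `r` within the block), thresholded at each SNP's MAF
#' quantile, so `r = 1` gives identical columns. Causal SNPs are placed at
#' evenly spaced, known column positions. Monomorphic draws are regenerated
#' up to a retry limit.
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_matrix` with null SNPs labelled `N000001, ...` and
#'   causal SNPs carrying their configured ids and annotation.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(stage_seed(cfg$seed, "genotypes"), {
    n <- cfg$n_individuals
    n_causal <- nrow(cfg$causal)
    p <- cfg$n_null_snps + n_causal

    null_maf <- switch(cfg$null_maf_law,
      uniform = runif(cfg$n_null_snps, cfg$maf_range[1L], cfg$maf_range[2L]),
      beta = {
        lo <- stats::pbeta(cfg$maf_range[1L], 0.3, 1)
        hi <- stats::pbeta(cfg$maf_range[2L], 0.3, 1)
        stats::qbeta(runif(cfg$n_null_snps, lo, hi), 0.3, 1)
      })

    dos <- matrix(0, n, p)
    null_ids <- sprintf("N%06d", seq_len(cfg$n_null_snps))

    # LD blocks claim the leading null columns, consecutively
    in_block <- integer(0)
    if (!is.null(cfg$ld_blocks) && nrow(cfg$ld_blocks) > 0L) {
      at <- 1L
      for (b in seq_len(nrow(cfg$ld_blocks))) {
        sz <- cfg$ld_blocks$size[b]
        r <- cfg$ld_blocks$r[b]
        cols <- at:(at + sz - 1L)
        # block members share one MAF so r = 1 yields exact duplicates
        null_maf[cols] <- null_maf[cols[1L]]
        # two allele copies per individual, each from the block's copula
        for (copy in 1:2) {
          shared <- rnorm(n)
          for (k in seq_along(cols)) {
            latent <- sqrt(r) * shared + sqrt(1 - r) * rnorm(n)
            dos[, cols[k]] <- dos[, cols[k]] +
              (latent < stats::qnorm(null_maf[cols[k]]))
          }
        }
        in_block <- c(in_block, cols)
        at <- at + sz
      }
    }

    null_cols <- seq_len(cfg$n_null_snps)
    for (j in setdiff(null_cols, in_block)) {
      dos[, j] <- draw_dosage(n, null_maf[j], null_ids[j])
    }

    # interleave causal SNPs at evenly spaced known positions
    if (n_causal > 0L) {
      pos <- round(seq_len(n_causal) * (p + 1) / (n_causal + 1))
      pos <- pmin(pmax(pos, 1L), p)
      if (anyDuplicated(pos)) pos <- seq_len(n_causal)
      ord <- rep(NA_character_, p)
      ord[pos] <- cfg$causal$snp_id
      ord[is.na(ord)] <- null_ids
      full <- matrix(0, n, p)
      full[, match(null_ids, ord)] <- dos[, null_cols, drop = FALSE]
      for (k in seq_len(n_causal)) {
        full[, pos[k]] <- draw_dosage(n, cfg$causal$maf[k], cfg$causal$snp_id[k])
      }
      dos <- full
      ids <- ord
    } else {
      ids <- null_ids
    }

    rownames(dos) <- sprintf("I%04d", seq_len(n))
    colnames(dos) <- ids
    info <- tibble::tibble(
      snp_id = ids,
      chromosome = as.character(1L + (seq_len(p) - 1L) %% 22L),
      gene = "",
      maf_declared = NA_real_
    )
    info$maf_declared[match(null_ids, ids)] <- null_maf
    if (n_causal > 0L) {
      m <- match(cfg$causal$snp_id, ids)
      info$maf_declared[m] <- cfg$causal$maf
      if ("gene" %in% names(cfg$causal)) info$gene[m] <- cfg$causal$gene
      if ("chromosome" %in% names(cfg$causal)) {
        info$chromosome[m] <- as.character(cfg$causal$chromosome)
      }
    }
    genotype_matrix(dos, info)
  })
}

#' Simulate phenotype replicates over a fixed genotype matrix
#'
#' Covariates are drawn once: `Sex ~ Bernoulli(0.5)`,
#' `Age ~ round(Normal(50, 10))`, `Smoke ~ Bernoulli(0.3)`. For each
#' replicate `r` the trait is
#' `y_r = sum_j beta_j G_j + gamma' (Sex, Age, Smoke) + eps_r`, with
#' `eps_r ~ Normal(0, residual_sd^2)` drawn independently per replicate.
#' Genotypes and covariates are identical across replicates; only the noise
#' differs.
#'
#' @param g A `genotype_matrix` containing every causal SNP of `cfg`.
#' @param cfg A [sim_config()].
#' @return A `phenotype_tbl` with trait columns `Q1_1, ..., Q1_R`.
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(g, "genotype_matrix"))
  missing_causal <- setdiff(cfg$causal$snp_id, snp_ids(g))
  if (length(missing_causal) > 0L) {
    abort(paste0("causal SNP(s) absent from genotypes: ",
                 paste(missing_causal, collapse = ", ")))
  }
  if (cfg$residual_sd <= 0) abort("residual_sd must be positive")
  n <- nrow(g$dosages)
  with_seed(stage_seed(cfg$seed, "phenotypes"), {
    sex <- rbinom(n, 1L, 0.5)
    age <- round(rnorm(n, 50, 10))
    smoke <- rbinom(n, 1L, 0.3)
    genetic <- if (nrow(cfg$causal) > 0L) {
      as.vector(g$dosages[, cfg$causal$snp_id, drop = FALSE] %*% cfg$causal$beta)
    } else rep(0, n)
    fixed <- genetic +
      cfg$covariate_effects[["Sex"]] * sex +
      cfg$covariate_effects[["Age"]] * age +
      cfg$covariate_effects[["Smoke"]] * smoke
    traits <- lapply(seq_len(cfg$n_replicates), function(r) {
      fixed + rnorm(n, 0, cfg$residual_sd)
    })
    names(traits) <- paste0("Q1_", seq_len(cfg$n_replicates))
    df <- tibble::tibble(sample_id = sample_ids(g),
                         Sex = as.numeric(sex),
                         Age = as.numeric(age),
                         Smoke = as.numeric(smoke))
    df <- dplyr::bind_cols(df, tibble::as_tibble(traits))
    phenotype_replicates(df)
  })
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: genotypes, phenotype replicates, and the truth set.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genotypes`, `phenotypes`, `truth`, `config`.
#' @export
simulate_study <- function(cfg) {
  g <- simulate_genotypes(cfg)
  p <- simulate_phenotypes(g, cfg)
  list(genotypes = g, phenotypes = p, truth = truth_set(cfg), config = cfg)
}
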