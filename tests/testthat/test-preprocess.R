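test_that("compute_maf folds at 0.5 and is flip-invariant", {
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)
  expect_equal(compute_maf(c(0, 1, 2, 1)), 0.5)
  expect_error(compute_maf(numeric(0)), "empty")
  expect_error(compute_maf(c(0, 3)), "\\{0, 1, 2\\}")
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rbinom(30, 2, runif(1, 0.05, 0.95))
      expect_equal(compute_maf(x), compute_maf(2 - x))
      expect_lte(compute_maf(x), 0.5)
    }
  })
})

test_that("filter_by_maf keeps SNPs at or above the threshold", {
  # 10 SNPs, 3 rare (MAF < 0.01), one exactly at the boundary
  n <- 500
  dos <- withr::with_seed(8, vapply(
    c(0.001, 0.004, 0.009, 0.01, rep(0.2, 6)),
    function(m) {
      x <- numeric(n)
      x[seq_len(round(m * 2 * n))] <- 1 # exact allele counts
      sample(x)
    }, numeric(n)))
  dimnames(dos) <- list(sprintf("I%03d", 1:n), sprintf("S%02d", 1:10))
  g <- genotype_matrix(dos)
  expect_message(kept <- filter_by_maf(g, 0.01), "removed 3")
  expect_equal(ncol(kept$dosages), 7L)
  expect_true("S04" %in% snp_ids(kept)) # exactly 0.01 is retained

  # idempotent, and monotone in the threshold
  again <- suppressMessages(filter_by_maf(kept, 0.01))
  expect_identical(again$dosages, kept$dosages)
  counts <- vapply(c(0, 0.005, 0.01, 0.1, 0.3), function(thr) {
    ncol(suppressMessages(filter_by_maf(g, thr))$dosages)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every published causal SNP passes the common-variant filter", {
  expect_true(all(gaw17_causal_snps()$maf >= 0.01))
})

test_that("collapse_duplicates groups identical columns, first kept", {
  g <- rand_genotypes(30, 30, seed = 9)
  dos <- g$dosages
  # plant 5 duplicate pairs (originals at 1..5, copies at 26..30)
  for (k in 1:5) dos[, 25 + k] <- dos[, k]
  colnames(dos) <- sprintf("S%02d", 1:30)
  g <- genotype_matrix(dos)
  res <- suppressMessages(collapse_duplicates(g))
  expect_equal(ncol(res$genotypes$dosages), 25L)
  expect_setequal(res$groups$member, colnames(dos))
  expect_true(all(c("S01", "S02") %in% snp_ids(res$genotypes)))
  expect_false(any(sprintf("S%02d", 26:30) %in% snp_ids(res$genotypes)))
  # re-expansion recovers every original id from the representatives
  expanded <- res$groups$member[res$groups$representative %in%
                                  snp_ids(res$genotypes)]
  expect_setequal(expanded, colnames(dos))

  # no duplicates: identity, trivial groups
  g2 <- rand_genotypes(40, 6, seed = 10)
  res2 <- collapse_duplicates(g2)
  expect_identical(res2$genotypes$dosages, g2$dosages)
  expect_identical(res2$groups$representative, res2$groups$member)
})

test_that("standardization hits exact mean-0 unit-1/n-variance columns", {
  m <- matrix(c(0, 2, 1, 0, 1, 2), 2, 3)
  std <- standardize_columns(m)
  expect_equal(std[, 1], c(-1, 1)) # two-point symmetry
  expect_true(all(abs(colMeans(std)) < 1e-12))
  expect_true(all(abs(colMeans(std^2) - 1) < 1e-12))
  # idempotence
  expect_equal(unclass(standardize_columns(std))[, ], std[, ], tolerance = 1e-12)
  # zero-variance rejected by name
  bad <- matrix(c(1, 1, 0, 2), 2, 2, dimnames = list(NULL, c("flat", "ok")))
  expect_error(standardize_columns(bad), "flat")
})

test_that("standardized-scale OLS back-transforms to raw-scale OLS", {
  g <- rand_genotypes(20, 3, seed = 12)
  ph <- rand_phenotypes(g, beta = c(S0001 = 0.5), sd = 0.3, seed = 13)
  d <- standardize_design(g, ph, "y_1")
  W <- cbind(d$X, d$Z)
  b_std <- lm.fit(W, d$y)$coefficients
  raw <- backtransform_coefs(d, b_std[seq_len(3)],
                             b_std[3 + seq_len(3)])
  ref <- stats::lm(ph$y_1 ~ g$dosages + ph$Sex + ph$Age + ph$Smoke)
  expect_equal(unname(raw$estimate),
               unname(stats::coef(ref)), tolerance = 1e-8)
})

test_that("pairwise r2 matches squared correlation and its symmetries", {
  withr::with_seed(14, {
    a <- rbinom(60, 2, 0.4)
    expect_equal(pairwise_r2(a, a), 1)
    expect_equal(pairwise_r2(a, 2 - a), 1) # coding flip
    x <- rbinom(1e4, 2, 0.3)
    y <- rbinom(1e4, 2, 0.3)
    expect_lt(pairwise_r2(x, y), 0.01) # independent columns
    expect_error(pairwise_r2(rep(1, 60), a), "constant")
  })
})

test_that("ld_screen finds the strongest partner of each focal SNP", {
  # a duplicated focal SNP reports r2 = 1 with its copy
  g <- rand_genotypes(80, 6, seed = 15)
  dos <- cbind(g$dosages, dup = g$dosages[, 1L])
  colnames(dos)[7] <- "DUP"
  g <- genotype_matrix(dos)
  scr <- ld_screen(g, "S0001")
  expect_equal(scr$partner, "DUP")
  expect_equal(scr$r2, 1)
  expect_true(scr$in_ld)

  # independent panel at large n: everything below threshold
  g2 <- rand_genotypes(5000, 10, seed = 16)
  scr2 <- ld_screen(g2, snp_ids(g2)[1:3])
  expect_true(all(!scr2$in_ld))

  # a generated LD block pair is each other's best partner
  cfg <- sim_config(n_individuals = 800, n_null_snps = 20,
                    causal = gaw17_causal_snps()[0, ],
                    ld_blocks = tibble::tibble(size = 2, r = 0.85),
                    n_replicates = 1, seed = 17)
  g3 <- simulate_genotypes(cfg)
  pair <- snp_ids(g3)[1:2]
  scr3 <- ld_screen(g3, pair)
  expect_equal(scr3$partner[1], pair[2])
  expect_equal(scr3$partner[2], pair[1])
})
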