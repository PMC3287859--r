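# a tiny replicate-runs table built by hand for the counting checks
toy_runs <- function() {
  procs <- c("lasso_min", "lasso_min+AIC", "lasso_min+BIC",
             "lasso_1se", "lasso_1se+AIC", "lasso_1se+BIC")
  rows <- purrr::map(1:20, function(r) {
    sel <- if (r <= 17) c("T1", "N1") else "N1"
    tibble::tibble(replicate = paste0("y_", r), procedure = procs,
                   snps = rep(list(sel), 6),
                   lambda_min = 0.1, lambda_1se = 0.2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("replicate_runs", class(out))
  out
}

test_that("selection frequencies count replicates exactly", {
  summ <- selection_summary(toy_runs(), truth = c("T1", "T2"))
  pm <- summ$per_snp[summ$per_snp$procedure == "lasso_min", ]
  expect_equal(pm$freq[pm$snp_id == "T1"], 17 / 20)
  expect_equal(pm$freq[pm$snp_id == "T2"], 0) # never-selected truth SNP kept
  tot <- summ$totals[summ$totals$procedure == "lasso_min", ]
  expect_equal(tot$mean_correct, 17 / 20)
  expect_equal(tot$mean_selected, (17 * 2 + 3) / 20)

  # empty truth set: nothing is ever correct
  s0 <- selection_summary(toy_runs(), truth = character(0))
  expect_true(all(s0$totals$mean_correct == 0))
})

test_that("mean total correct equals the sum of per-truth-SNP frequencies", {
  summ <- selection_summary(toy_runs(), truth = c("T1", "T2"))
  for (proc in unique(summ$totals$procedure)) {
    per <- summ$per_snp[summ$per_snp$procedure == proc &
                          summ$per_snp$is_truth, ]
    tot <- summ$totals$mean_correct[summ$totals$procedure == proc]
    expect_equal(sum(per$freq), tot)
  }
})

test_that("the published benchmark totals obey the same arithmetic", {
  ref <- gaw17_selection_reference()
  expect_equal(sum(ref$per_snp[["lasso_min"]]), 4.09, tolerance = 1e-12)
  expect_equal(
    proportion_correct(4.09, 28.05) * 100, 14.6, tolerance = 0.05)
  expect_equal(
    proportion_correct(3.32, 14.30) * 100, 23.2, tolerance = 0.05)
})

test_that("proportion_correct handles summaries, scalars, and degenerate input", {
  summ <- selection_summary(toy_runs(), truth = "T1")
  pc <- proportion_correct(summ)
  expect_equal(pc$proportion[pc$procedure == "lasso_min"],
               (17 / 20) / ((17 * 2 + 3) / 20))
  expect_equal(proportion_correct(5, 5), 1) # all-correct selection
  expect_error(proportion_correct(1, 0), "positive")
})

test_that("selection ranks use the minimum-rank tie convention", {
  runs <- toy_runs()
  # craft frequencies a: 0.9, b: 0.9, c: 0.1 under one procedure
  rows <- purrr::map(1:20, function(r) {
    sel <- if (r <= 18) c("a", "b") else "c"
    tibble::tibble(replicate = paste0("y_", r), procedure = "lasso_min",
                   snps = list(sel), lambda_min = 0.1, lambda_1se = 0.2)
  })
  runs2 <- dplyr::bind_rows(rows)
  class(runs2) <- class(runs)
  summ <- selection_summary(runs2, truth = "a")
  rk <- selection_ranks(summ, "lasso_min")
  expect_equal(rk$rank[rk$snp_id == "a"], 1L)
  expect_equal(rk$rank[rk$snp_id == "b"], 1L)
  expect_equal(rk$rank[rk$snp_id == "c"], 3L)
  expect_true(rk$is_truth[rk$snp_id == "a"])
})

test_that("run_replicates is deterministic and structurally complete", {
  g <- rand_genotypes(100, 15, seed = 111)
  ph <- rand_phenotypes(g, beta = c(S0003 = 1.5), sd = 0.4, n_rep = 2,
                        seed = 112)
  runs <- suppressWarnings(run_replicates(g, ph, K = 5, seed = 7))
  expect_equal(nrow(runs), 12L) # 2 replicates x 6 procedures
  expect_setequal(unique(runs$procedure),
                  c("lasso_min", "lasso_min+AIC", "lasso_min+BIC",
                    "lasso_1se", "lasso_1se+AIC", "lasso_1se+BIC"))
  runs2 <- suppressWarnings(run_replicates(g, ph, K = 5, seed = 7))
  expect_identical(runs$snps, runs2$snps)
  expect_true(all(runs$lambda_1se >= runs$lambda_min))

  # stepwise refinements stay inside their stage-1 pools
  for (rule in c("min", "1se")) {
    base <- runs$snps[runs$procedure == paste0("lasso_", rule)]
    for (cr in c("AIC", "BIC")) {
      ref <- runs$snps[runs$procedure == paste0("lasso_", rule, "+", cr)]
      expect_true(all(purrr::map2_lgl(ref, base, ~ all(.x %in% .y))))
    }
  }
})

test_that("a dominant causal SNP is found by all six procedures", {
  g <- rand_genotypes(150, 20, seed = 113)
  ph <- rand_phenotypes(g, beta = c(S0006 = 2), sd = 0.1, n_rep = 3,
                        seed = 114)
  runs <- suppressWarnings(run_replicates(g, ph, K = 5, seed = 8))
  expect_true(all(purrr::map_lgl(runs$snps, ~ "S0006" %in% .x)))
  summ <- selection_summary(runs, truth = "S0006")
  expect_true(all(summ$totals$mean_correct == 1))
  rk <- selection_ranks(summ, "lasso_min")
  expect_equal(rk$rank[rk$snp_id == "S0006"], 1L)
})
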