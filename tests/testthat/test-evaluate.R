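test_that("bias, CV, RMSE and coverage follow their definitions", {
  expect_equal(compute_bias(110, 100), c(mean_bias = 1.1, median_bias = 1.1))
  expect_equal(compute_bias(c(100, 100), 100),
               c(mean_bias = 1, median_bias = 1))
  expect_equal(compute_bias(c(50, 150), 100),
               c(mean_bias = 1, median_bias = 1))
  expect_error(compute_bias(numeric(0), 100), "no estimates")

  expect_equal(compute_cv(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(compute_cv(rep(42, 5)), 0)
  expect_equal(compute_cv(c(90, 110)), compute_cv(c(90, 110) * 7.3))
  expect_error(compute_cv(5), "at least 2")

  expect_equal(compute_rmse(c(100, 100), 100), 0)
  expect_equal(compute_rmse(c(90, 110), 100), 10)
  set.seed(3)
  for (i in 1:20) {
    est <- rnorm(10, 100, 20)
    expect_gte(compute_rmse(est, 100), abs(mean(est) - 100) - 1e-12)
  }

  expect_equal(compute_coverage(rep(100, 4), rep(100, 4), 100), 1)
  expect_equal(compute_coverage(c(1, 2), c(3, 4), 100), 0)
  expect_equal(compute_coverage(c(90, 101, 80), c(110, 102, 90), 100), 1 / 3)
})

fast_cfg <- function(...) {
  utils::modifyList(
    list(mode = "grid", n_p = c(8, 12), n_obs = 20, replicates = 2,
         estimators = "chao1", fecundity = c(30, 60), seed = 5), list(...))
}

test_that("grid runs produce one row per replicate, treatment and method", {
  g <- run_grid(fast_cfg(estimators = c("chao1", "ichao")))
  expect_identical(nrow(g$results), 2L * 2L * 2L)  # cells x reps x methods
  expect_true(all(g$results$estimate >= g$results$n_det))
  expect_identical(sort(unique(g$results$method)), c("chao1", "ichao"))
  expect_true(all(g$metrics$coverage >= 0 & g$metrics$coverage <= 1))
  expect_true(all(g$metrics$n_replicates == 2L))
})

test_that("grid runs are reproducible and configurable from YAML", {
  g1 <- run_grid(fast_cfg())
  g2 <- run_grid(fast_cfg())
  expect_identical(g1, g2)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(fast_cfg(), path)
  g3 <- run_grid(path)
  expect_identical(g3$results, g1$results)
})

test_that("uniform-draw mode draws both axes and summarizes over all rows", {
  g <- run_grid(list(mode = "uniform", n_range = c(10, 30), replicates = 6,
                     estimators = "chao1", fecundity = c(30, 60), seed = 9))
  r <- g$results
  expect_identical(nrow(r), 6L)
  expect_true(all(r$n_p_true >= 10 & r$n_p_true <= 30))
  expect_true(all(r$n_obs >= 10 & r$n_obs <= 30))
  expect_gt(length(unique(r$n_p_true)), 1L)
  expect_identical(nrow(g$metrics), 1L)
})

test_that("every error treatment within a replicate shares the base sample", {
  cfg0 <- fast_cfg(n_p = 10, n_obs = 25, replicates = 3)
  base_only <- run_grid(cfg0)
  with_err <- run_grid(utils::modifyList(cfg0, list(type2_rates = 0.05,
                                                    type1_rates = 0.05)))
  r0 <- base_only$results
  re <- with_err$results
  # the error-free rows are byte-identical whether or not treatments ran
  none <- re[re$error_type == "none", names(r0)]
  rownames(none) <- NULL
  expect_identical(none, r0)
  # pairing by replicate: type II never lowers, type I never raises N_DET
  for (rep in 1:3) {
    nd0 <- none$n_det[none$replicate == rep]
    nd2 <- re$n_det[re$error_type == "type2" & re$replicate == rep]
    nd1 <- re$n_det[re$error_type == "type1" & re$replicate == rep]
    expect_gte(nd2, nd0)
    expect_lte(nd1, nd0)
  }
})

test_that("convergence filtering drops only failed Bayesian rows", {
  res <- data.frame(
    mode = "grid", n_p_true = 10L, n_obs = 20L, prop_female = 0.5,
    error_type = "none", error_rate = 0, replicate = 1:4, seed = 1:4,
    method = c("chao1", "bayes", "bayes", "bayes"),
    n_det = 8L, estimate = c(10, 10, 11, 30),
    ci_low = c(9, 9, 10, 29), ci_high = c(12, 12, 12, 31),
    rhat_max = c(NA, 1.01, 1.01, 2),
    converged = c(NA, TRUE, TRUE, FALSE))
  m_all <- summarize_metrics(res)
  m_conv <- summarize_metrics(res, converged_only = TRUE)
  b_all <- m_all[m_all$method == "bayes", ]
  b_conv <- m_conv[m_conv$method == "bayes", ]
  expect_identical(b_all$n_replicates, 3L)
  expect_identical(b_conv$n_replicates, 2L)
  expect_equal(b_conv$mean_bias, mean(c(10, 11) / 10))
  # chao rows untouched by the filter
  expect_identical(m_all[m_all$method == "chao1", ],
                   m_conv[m_conv$method == "chao1", ])
})
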