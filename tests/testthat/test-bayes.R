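test_that("augmentation pads with zeros to L = factor * n_det", {
  d <- detection_vector(c(3, 1, 1, 1), n_obs = 3)
  aug <- np_augment(d, factor = 50)
  expect_identical(aug$L, 200L)
  expect_identical(sum(aug$y_aug == 0L), 196L)
  expect_identical(aug$y_aug[1:4], d$y)
  expect_warning(np_augment(d, factor = 1.5), "bound")
  expect_error(np_augment(d, factor = 0.5), ">= 1")
  expect_error(np_augment(detection_vector(c(5, 1), n_obs = 3)), "exceed")
})

test_that("the latent-occupancy conditional matches its closed form", {
  # psi = p = 0.5, one offspring draw: 0.25 / 0.75 = 1/3
  expect_equal(pedacc:::zero_occupancy_prob(0.5, 0.5, 1), 1 / 3)
  # deep sampling makes an undetected parent nearly impossible
  expect_lt(pedacc:::zero_occupancy_prob(0.5, 0.1, 500), 1e-20)
  # p = 1 underflow handled
  expect_identical(pedacc:::zero_occupancy_prob(0.5, 1, 10), 0)
})

test_that("the Gibbs posterior matches the enumerated posterior mean", {
  d <- detection_vector(c(2, 2, 1, 1), n_obs = 3)
  aug <- np_augment(d, factor = 4)          # L = 16, enumerable
  ex <- exact_np_posterior(aug)
  expect_equal(sum(ex$prob), 1, tolerance = 1e-12)
  fit <- np_bayes(aug, chains = 2, burnin = 500, iters = 10000, thin = 1,
                  seed = 8)
  np <- unlist(lapply(fit$chains, function(m) m[, "n_p"]))
  expect_lt(abs(mean(np) - sum(ex$n_p * ex$prob)), 0.15)
})

test_that("enumeration is log-space stable and degenerates without zeros", {
  d <- detection_vector(c(4, 3, 1), n_obs = 4)
  # no augmentation: point mass at n_det
  ex1 <- exact_np_posterior(suppressWarnings(np_augment(d, factor = 1)))
  expect_identical(nrow(ex1), 1L)
  expect_equal(ex1$prob, 1)
  # large L stays finite and normalized
  ex2 <- exact_np_posterior(d, factor = 3000)   # L = 9000
  expect_true(all(is.finite(ex2$prob)))
  expect_equal(sum(ex2$prob), 1, tolerance = 1e-9)
})

test_that("posterior draws respect the structural support bounds", {
  d <- detection_vector(c(1, 1, 1, 1, 2, 2), n_obs = 4)
  fit <- np_bayes(d, factor = 10, chains = 3, burnin = 200, iters = 2000,
                  thin = 10, seed = 2)
  np <- unlist(lapply(fit$chains, function(m) m[, "n_p"]))
  expect_true(all(np >= d$n_det & np <= fit$L))
  psi <- unlist(lapply(fit$chains, function(m) m[, "psi"]))
  p <- unlist(lapply(fit$chains, function(m) m[, "p"]))
  expect_true(all(psi > 0 & psi < 1 & p > 0 & p < 1))
  # factor 1 forces the posterior to the detected count
  fit1 <- suppressWarnings(np_bayes(d, factor = 1, chains = 2, burnin = 50,
                                    iters = 500, thin = 5, seed = 3))
  s1 <- summary(fit1)
  expect_identical(s1$n_p_median, as.numeric(d$n_det))
  expect_identical(c(s1$hpd_low, s1$hpd_high), rep(as.numeric(d$n_det), 2))
  expect_true(s1$converged)
})

test_that("fits are deterministic given seed and settings", {
  d <- detection_vector(c(3, 2, 1, 1, 1), n_obs = 4)
  f1 <- np_bayes(d, seed = 11, burnin = 100, iters = 500, thin = 10)
  f2 <- np_bayes(d, seed = 11, burnin = 100, iters = 500, thin = 10)
  expect_identical(f1$chains, f2$chains)
  expect_error(np_bayes(d, chains = 1), "2 chains")
})

test_that("more offspring draws shift p down and abundance up", {
  means <- p_med <- numeric(3)
  for (i in seq_along(c(2, 8, 32))) {
    n_obs <- c(2, 8, 32)[i]
    di <- suppressWarnings(detection_vector(c(2, 1, 1), n_obs = n_obs))
    ex <- exact_np_posterior(di, factor = 20)
    means[i] <- sum(ex$n_p * ex$prob)
    fit <- np_bayes(di, factor = 20, chains = 2, burnin = 500, iters = 20000,
                    thin = 10, seed = 40 + i)
    p_med[i] <- summary(fit)$p_median
  }
  expect_true(all(diff(means) >= 0))
  expect_true(all(diff(p_med) < 0))
})

test_that("Gelman-Rubin matches the classic formula and flags degeneracy", {
  # exact copies: B = 0, Rhat = sqrt((n-1)/n) < 1
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  # hand example: W = 1, B/n = var(c(2, 102)) = 5000
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(101, 102, 103))),
               sqrt(2 / 3 + 5000))
  # point-mass chains: flagged sentinel
  r <- gelman_rubin(list(c(5, 5), c(5, 5)))
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "degenerate"))
  expect_identical(gelman_rubin(list(c(5, 5), c(6, 6))), Inf)
  expect_error(gelman_rubin(list(1:3)), ">= 2 chains")
})

test_that("HPD intervals are the shortest windows", {
  expect_equal(hpd_interval(rep(7, 10)), c(7, 7))
  h <- hpd_interval(1:100, 0.95)
  expect_equal(h[2] - h[1], 94)        # 95 consecutive integers
  expect_equal(h, c(1, 95))            # ties resolved to the lowest window
  # brute-force oracle on random draws
  set.seed(13)
  for (i in 1:20) {
    x <- sort(rgamma(sample(20:60, 1), shape = 2))
    m <- ceiling(0.9 * length(x))
    best <- c(Inf, NA, NA)
    for (a in seq_len(length(x) - m + 1)) {
      w <- x[a + m - 1] - x[a]
      if (w < best[1]) best <- c(w, x[a], x[a + m - 1])
    }
    expect_equal(hpd_interval(x, 0.9), best[2:3])
    # shortest window is no wider than the equal-tail interval
    et <- unname(quantile(x, c(0.05, 0.95), type = 1))
    expect_lte(best[1], et[2] - et[1] + 1e-12)
  }
})

test_that("summaries pool chains and drive convergence off max R-hat", {
  d <- detection_vector(c(1, 1, 1, 1, 2, 2), n_obs = 4)
  fit <- np_bayes(d, factor = 10, chains = 3, burnin = 500, iters = 3000,
                  thin = 10, seed = 21)
  s <- summary(fit)
  expect_true(s$hpd_low <= s$n_p_median && s$n_p_median <= s$hpd_high)
  expect_gte(s$n_p_median, d$n_det)
  expect_named(s$rhat, c("n_p", "psi", "p"))
  expect_identical(s$converged, all(s$rhat < 1.1))
  # stricter threshold can only flip converged off, never on
  s05 <- summary(fit, rhat_threshold = 1.0000001)
  expect_true(s$converged >= s05$converged)
  expect_equal(coef(fit), c(n_p = s$n_p_median, psi = s$psi_median,
                            p = s$p_median))
})

test_that("posterior-predictive simulations respect the sampling design", {
  d <- detection_vector(c(3, 2, 1, 1, 1), n_obs = 4)
  fit <- np_bayes(d, burnin = 200, iters = 1000, thin = 10, seed = 5)
  sims <- simulate(fit, nsim = 8, seed = 9)
  expect_length(sims, 8)
  for (y in sims) {
    expect_true(all(y >= 1))
    expect_true(all(y <= d$n_obs))
  }
})
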