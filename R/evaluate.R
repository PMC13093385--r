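# Benchmarking harness: scenario grids, replicate execution, and the
# bias / CV / RMSE / coverage metrics used to evaluate the estimators.

#' Performance metrics for repeated abundance estimates
#'
#' `compute_bias()` reports the mean and median of the per-replicate ratio
#' estimate/truth (1 is unbiased). `compute_cv()` is the coefficient of
#' variation, `100 * sd / mean`, with the sample (n-1) standard deviation.
#' `compute_rmse()` is `sqrt(mean((estimate - truth)^2))`.
#' `compute_coverage()` is the fraction of closed intervals containing the
#' truth.
#'
#' @param estimates Numeric vector of point estimates across replicates.
#' @param truth True abundance (positive scalar).
#' @return `compute_bias()`: named numeric `c(mean_bias, median_bias)`;
#'   the others: a scalar.
#' @examples
#' compute_bias(c(50, 150), 100)   # mean 1, median 1
#' compute_cv(c(90, 110))          # ~14.14
#' compute_rmse(c(90, 110), 100)   # 10
#' @export
compute_bias <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("no estimates supplied")
  stopifnot(is.numeric(truth), length(truth) == 1L, truth > 0)
  r <- estimates / truth
  c(mean_bias = mean(r), median_bias = stats::median(r))
}

#' @rdname compute_bias
#' @export
compute_cv <- function(estimates) {
  if (length(estimates) < 2L) stop("CV needs at least 2 estimates")
  m <- mean(estimates)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(estimates) / m
}

#' @rdname compute_bias
#' @export
compute_rmse <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("no estimates supplied")
  stopifnot(is.finite(truth))
  sqrt(mean((estimates - truth)^2))
}

#' @rdname compute_bias
#' @param low,high Numeric vectors of interval endpoints (recycled
#'   pairwise).
#' @export
compute_coverage <- function(low, high, truth) {
  if (length(low) == 0L) stop("no intervals supplied")
  stopifnot(length(low) == length(high))
  mean(low <= truth & truth <= high)
}

# deterministic seed mixing, kept below 2^31 (doubles are exact here)
mix_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) s <- (s * 48271 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

# run every requested estimator on one detection vector; returns a
# data.frame with one row per method
estimate_all <- function(d, estimators, mcmc, bayes_seed) {
  rows <- lapply(estimators, function(m) {
    if (m == "chao1" || m == "ichao") {
      e <- if (m == "chao1") chao1(d) else ichao(d)
      data.frame(method = m, n_det = d$n_det, estimate = e$n_p_hat,
                 ci_low = e$ci_low, ci_high = e$ci_high,
                 rhat_max = NA_real_, converged = NA)
    } else if (m == "bayes") {
      fit <- np_bayes(d, factor = mcmc$factor, chains = mcmc$chains,
                      burnin = mcmc$burnin, iters = mcmc$iters,
                      thin = mcmc$thin, seed = bayes_seed,
                      rhat_threshold = mcmc$rhat_threshold)
      s <- summary(fit)
      data.frame(method = m, n_det = d$n_det, estimate = s$n_p_median,
                 ci_low = s$hpd_low, ci_high = s$hpd_high,
                 rhat_max = max(s$rhat), converged = s$converged)
    } else stop("unknown estimator: ", m)
  })
  do.call(rbind, rows)
}

default_mcmc <- function(mcmc = NULL) {
  base <- list(factor = 50, chains = 3L, burnin = 3500L, iters = 5000L,
               thin = 50L, rhat_threshold = 1.1)
  if (!is.null(mcmc)) base[names(mcmc)] <- mcmc
  base
}

# expand the requested error treatments into (type, rate) rows; a zero rate
# for either type collapses to the shared error-free baseline
error_specs <- function(type1_rates, type2_rates) {
  specs <- data.frame(error_type = "none", error_rate = 0)
  for (r in setdiff(type1_rates, 0))
    specs <- rbind(specs, data.frame(error_type = "type1", error_rate = r))
  for (r in setdiff(type2_rates, 0))
    specs <- rbind(specs, data.frame(error_type = "type2", error_rate = r))
  unique(specs)
}

run_one_replicate <- function(n_p, n_obs, prop_female, specs, estimators,
                              mcmc, sim_seed, mate_lambda, fecundity) {
  ss <- split_sexes(n_p, prop_female)
  sc <- breeding_scenario(ss[1L], ss[2L], mate_lambda = mate_lambda,
                          fecundity = fecundity)
  ped <- simulate_breeding(sc, seed = sim_seed)
  base <- sample_offspring(ped, n_obs, seed = mix_seed(sim_seed, 1L))
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    type <- specs$error_type[i]
    rate <- specs$error_rate[i]
    samp <- switch(type,
      none = base,
      type1 = inject_type1(base, rate, seed = mix_seed(sim_seed, 2L, i)),
      type2 = inject_type2(base, rate, seed = mix_seed(sim_seed, 2L, i)))
    d <- detection_vector(samp)
    est <- estimate_all(d, estimators, mcmc, mix_seed(sim_seed, 3L, i))
    est$error_type <- type
    est$error_rate <- rate
    out[[i]] <- est
  }
  res <- do.call(rbind, out)
  res$n_p_true <- n_p
  res$n_obs <- n_obs
  res$prop_female <- prop_female
  res
}

#' Run a benchmark grid of simulation scenarios
#'
#' Executes the full pipeline (simulate a cohort, sample offspring,
#' optionally inject pedigree-reconstruction errors, build the detection
#' vector, run the requested estimators) over either a factorial grid of
#' abundances and sample sizes or a uniform-draw design where both are
#' drawn integer-uniform from a range, with a fixed number of replicates.
#' Within a replicate, every error rate and type is applied to the same
#' base sample, so error treatments are directly comparable.
#'
#' @param config A named list, or the path of a YAML file holding one, with
#'   fields:
#' \describe{
#'   \item{mode}{`"grid"` (default) or `"uniform"`.}
#'   \item{n_p, n_obs}{Vectors of true abundances and sample sizes (grid
#'     mode; crossed).}
#'   \item{n_range}{Length-2 inclusive range for the integer-uniform draws
#'     of both N_P and N_OBS (uniform mode; default `c(25, 500)`).}
#'   \item{replicates}{Replicates per cell (grid) or total (uniform).}
#'   \item{estimators}{Subset of `c("chao1", "ichao", "bayes")`.}
#'   \item{type1_rates, type2_rates}{Error rates to apply (0 = baseline).}
#'   \item{prop_female}{Female proportion of N_P (default 0.5; remainder of
#'     the integer split goes to the males).}
#'   \item{mate_lambda, fecundity}{Mating-system settings, defaults 4 and
#'     `c(2500, 6500)`.}
#'   \item{mcmc}{List overriding the Bayesian defaults (`factor`, `chains`,
#'     `burnin`, `iters`, `thin`, `rhat_threshold`).}
#'   \item{seed}{Master seed; every replicate derives its own stream.}
#' }
#' @return A list with `results` (one row per replicate x error treatment x
#'   method) and `metrics` (per-scenario summaries from
#'   [summarize_metrics()]).
#' @examples
#' \donttest{
#' g <- run_grid(list(mode = "grid", n_p = 25, n_obs = 50, replicates = 3,
#'                    estimators = "chao1", seed = 1,
#'                    fecundity = c(100, 200)))
#' g$metrics
#' }
#' @export
run_grid <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- if (is.null(config$mode)) "grid" else config$mode
  reps <- if (is.null(config$replicates)) 100L else as.integer(config$replicates)
  estimators <- if (is.null(config$estimators))
    c("chao1", "ichao", "bayes") else config$estimators
  t1 <- if (is.null(config$type1_rates)) 0 else config$type1_rates
  t2 <- if (is.null(config$type2_rates)) 0 else config$type2_rates
  pf <- if (is.null(config$prop_female)) 0.5 else config$prop_female
  lam <- if (is.null(config$mate_lambda)) 4 else config$mate_lambda
  fec <- if (is.null(config$fecundity)) c(2500L, 6500L) else config$fecundity
  mcmc <- default_mcmc(config$mcmc)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  specs <- error_specs(t1, t2)

  rows <- list()
  if (mode == "grid") {
    stopifnot(!is.null(config$n_p), !is.null(config$n_obs))
    cells <- expand.grid(n_p = config$n_p, n_obs = config$n_obs)
    for (ci in seq_len(nrow(cells))) {
      for (r in seq_len(reps)) {
        sim_seed <- mix_seed(seed, ci, r)
        res <- run_one_replicate(cells$n_p[ci], cells$n_obs[ci], pf, specs,
                                 estimators, mcmc, sim_seed, lam, fec)
        res$replicate <- r
        res$seed <- sim_seed
        rows[[length(rows) + 1L]] <- res
      }
    }
  } else if (mode == "uniform") {
    rng <- if (is.null(config$n_range)) c(25L, 500L) else config$n_range
    set.seed(mix_seed(seed, 0L))
    n_p_draw <- sample(rng[1L]:rng[2L], reps, replace = TRUE)
    n_obs_draw <- sample(rng[1L]:rng[2L], reps, replace = TRUE)
    for (r in seq_len(reps)) {
      sim_seed <- mix_seed(seed, 1L, r)
      res <- run_one_replicate(n_p_draw[r], n_obs_draw[r], pf, specs,
                               estimators, mcmc, sim_seed, lam, fec)
      res$replicate <- r
      res$seed <- sim_seed
      rows[[length(rows) + 1L]] <- res
    }
  } else stop("unknown mode: ", mode)

  results <- do.call(rbind, rows)
  results$mode <- mode
  ord <- c("mode", "n_p_true", "n_obs", "prop_female", "error_type",
           "error_rate", "replicate", "seed", "method", "n_det", "estimate",
           "ci_low", "ci_high", "rhat_max", "converged")
  results <- results[, ord]
  rownames(results) <- NULL
  list(results = results, metrics = summarize_metrics(results))
}

#' Summarize benchmark results into per-scenario metrics
#'
#' Groups a results table from [run_grid()] by scenario cell, error
#' treatment and method, and reports mean/median bias (estimate/truth),
#' the coefficient of variation of the bias ratios (identical to the CV of
#' the raw estimates within a fixed-truth cell, by scale invariance), RMSE
#' (of raw estimates against truth within a cell; of bias ratios against 1
#' in uniform-draw designs, where truth varies by replicate), interval
#' coverage, and replicate/convergence counts.
#'
#' @param results The `results` data.frame from [run_grid()].
#' @param converged_only If `TRUE`, Bayesian rows that failed the R-hat
#'   threshold are dropped before summarizing (their count is still
#'   reported via `n_replicates` vs `n_converged`).
#' @return A data.frame with one row per scenario x error treatment x
#'   method.
#' @export
summarize_metrics <- function(results, converged_only = FALSE) {
  df <- results
  if (converged_only) {
    drop <- df$method == "bayes" & !is.na(df$converged) & !df$converged
    df <- df[!drop, , drop = FALSE]
  }
  uniform <- any(df$mode == "uniform")
  key_np <- if (uniform) rep("all", nrow(df)) else as.character(df$n_p_true)
  key_no <- if (uniform) rep("all", nrow(df)) else as.character(df$n_obs)
  g <- interaction(key_np, key_no, df$error_type, df$error_rate, df$method,
                   drop = TRUE)
  out <- lapply(split(df, g), function(s) {
    ratio <- s$estimate / s$n_p_true
    single_truth <- length(unique(s$n_p_true)) == 1L
    data.frame(
      n_p_true = if (single_truth) s$n_p_true[1L] else NA_integer_,
      n_obs = if (length(unique(s$n_obs)) == 1L) s$n_obs[1L] else NA_integer_,
      error_type = s$error_type[1L], error_rate = s$error_rate[1L],
      method = s$method[1L],
      mean_bias = mean(ratio), median_bias = stats::median(ratio),
      cv = if (length(ratio) >= 2L) compute_cv(ratio) else NA_real_,
      rmse = if (single_truth) compute_rmse(s$estimate, s$n_p_true[1L])
             else compute_rmse(ratio, 1),
      coverage = mean(s$ci_low <= s$n_p_true & s$n_p_true <= s$ci_high),
      n_replicates = nrow(s),
      n_converged = if (all(is.na(s$converged))) NA_integer_
                    else sum(s$converged, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, out$error_type, out$error_rate,
            out$n_p_true, out$n_obs), ]
}
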