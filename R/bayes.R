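# Hierarchical Bayesian data-augmentation estimator of parental abundance.
#
# Model: the detection vector y (one entry per detected parent) is padded
# with zeros up to length L. Each slot j has a latent presence indicator
#   z_j ~ Bernoulli(psi)
# and detections are binomial in the number of sampled offspring,
#   y_j ~ Binomial(N_OBS, z_j * p),
# with Beta priors on psi and p. The estimand is N_P = sum_j z_j.
#
# All conditionals are conjugate. Slots with y_j >= 1 have z_j = 1 with
# probability one; the L - N_DET zero slots are conditionally iid with
#   P(z_j = 1 | y_j = 0, psi, p) = psi*q / (psi*q + 1 - psi),  q = (1-p)^N_OBS,
# so their sum n0 is Binomial(L - N_DET, .) and the Gibbs sweep collapses to
# three scalar draws (n0, p, psi) that are exactly equivalent in law to
# updating every z_j individually.

#' Augment a detection vector with all-zero histories
#'
#' Pads the detection vector with `L - n_det` zeros, `L = ceiling(factor *
#' n_det)`, turning the unknown abundance into a sum of latent presence
#' indicators under a fixed-dimension model. The augmented length acts as a
#' uniform prior upper bound on N_P: factors that are too small bound the
#' estimate from above, while very large factors waste computation.
#'
#' @param d A [detection_vector()].
#' @param factor Augmentation factor (>= 1); default 50, i.e. `L = 50 *
#'   n_det`. A warning is issued below 2 since the posterior is then likely
#'   to be truncated by the augmentation bound.
#' @return An object of class `"augmented_data"`: list with `y_aug` (length
#'   `L`; the detected counts followed by zeros), `n_obs`, `n_det`, `L`.
#' @examples
#' d <- detection_vector(c(3, 1, 1, 1), n_obs = 3)
#' np_augment(d)$L   # 200
#' @export
np_augment <- function(d, factor = 50) {
  stopifnot(inherits(d, "detection_vector"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    stop("augmentation factor must be >= 1")
  if (d$n_det < 1L) stop("nothing detected: model undefined")
  if (any(d$y > d$n_obs))
    stop("detection counts exceed n_obs; model likelihood undefined")
  if (factor < 2)
    warning("augmentation factor < 2 is likely to bound the abundance estimate")
  L <- as.integer(ceiling(factor * d$n_det))
  structure(
    list(y_aug = c(d$y, integer(L - d$n_det)), n_obs = d$n_obs,
         n_det = d$n_det, L = L),
    class = "augmented_data"
  )
}

# P(z_j = 1 | y_j = 0, psi, p): an undetected slot is occupied iff the
# parent exists but all N_OBS offspring draws missed it
zero_occupancy_prob <- function(psi, p, n_obs) {
  q <- exp(n_obs * log1p(-p))
  pr <- psi * q / (psi * q + 1 - psi)
  if (!is.finite(pr)) 0 else pr
}

# one chain of the collapsed conjugate Gibbs sampler
run_gibbs_chain <- function(n_det, n_obs, L, S, n_iter, burnin, thin, priors) {
  M <- L - n_det
  n_keep <- n_iter %/% thin
  draws <- matrix(NA_real_, n_keep, 3L,
                  dimnames = list(NULL, c("n_p", "psi", "p")))
  # overdispersed start from the priors
  psi <- stats::rbeta(1L, priors[["psi_a"]], priors[["psi_b"]])
  p <- stats::rbeta(1L, priors[["p_a"]], priors[["p_b"]])
  row <- 0L
  for (it in seq_len(burnin + n_iter)) {
    pi0 <- zero_occupancy_prob(psi, p, n_obs)
    n0 <- if (M > 0L) stats::rbinom(1L, M, pi0) else 0L
    n_occ <- n_det + n0
    p <- stats::rbeta(1L, priors[["p_a"]] + S,
                      priors[["p_b"]] + n_occ * n_obs - S)
    psi <- stats::rbeta(1L, priors[["psi_a"]] + n_occ,
                        priors[["psi_b"]] + L - n_occ)
    if (!is.finite(p) || !is.finite(psi))
      stop("non-finite conditional parameters in Gibbs update")
    if (it > burnin && (it - burnin) %% thin == 0L) {
      row <- row + 1L
      draws[row, ] <- c(n_occ, psi, p)
    }
  }
  draws
}

#' Fit the Bayesian data-augmentation abundance model
#'
#' Fits the latent-presence binomial model to a pedigree detection vector by
#' an exact conjugate Gibbs sampler (no tuning or adaptation is required:
#' all full conditionals are sampled in closed form). Default protocol:
#' three chains, 3500 discarded sweeps per chain, 5000 retained-period
#' sweeps thinned by 50 (100 retained draws per chain, 300 pooled).
#'
#' @param d A [detection_vector()], or an `"augmented_data"` object from
#'   [np_augment()] (in which case `factor` is ignored).
#' @param factor Augmentation factor passed to [np_augment()].
#' @param chains Number of MCMC chains (>= 2, needed for R-hat).
#' @param burnin Discarded sweeps per chain.
#' @param iters Post-burn-in sweeps per chain.
#' @param thin Thinning interval: every `thin`-th post-burn-in sweep is
#'   retained.
#' @param priors Named numeric vector of Beta hyperparameters
#'   `c(psi_a, psi_b, p_a, p_b)`; default flat Beta(1, 1) on both.
#' @param seed Optional integer seed (reproducible fits).
#' @param rhat_threshold Gelman-Rubin convergence threshold (default 1.1).
#' @return An object of class `"np_bayes"`: list with `chains` (list of
#'   retained draw matrices with columns `n_p`, `psi`, `p`), `n_det`,
#'   `n_obs`, `L`, `priors`, `settings` and `rhat_threshold`. Use
#'   [summary.np_bayes()] for the posterior summary.
#' @examples
#' d <- detection_vector(c(3, 2, 1, 1, 1), n_obs = 4)
#' fit <- np_bayes(d, seed = 1)
#' summary(fit)
#' @export
np_bayes <- function(d, factor = 50, chains = 3L, burnin = 3500L,
                     iters = 5000L, thin = 50L,
                     priors = c(psi_a = 1, psi_b = 1, p_a = 1, p_b = 1),
                     seed = NULL, rhat_threshold = 1.1) {
  aug <- if (inherits(d, "augmented_data")) d else np_augment(d, factor)
  chains <- as.integer(chains)
  if (chains < 2L) stop("at least 2 chains are required for R-hat")
  if (iters < thin) stop("iters must be >= thin (no draws would be retained)")
  need <- c("psi_a", "psi_b", "p_a", "p_b")
  if (!all(need %in% names(priors)) || any(priors[need] <= 0))
    stop("priors must be positive and named ", paste(need, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  S <- sum(aug$y_aug)
  out <- lapply(seq_len(chains), function(ch)
    run_gibbs_chain(aug$n_det, aug$n_obs, aug$L, S, as.integer(iters),
                    as.integer(burnin), as.integer(thin), priors))
  structure(
    list(chains = out, n_det = aug$n_det, n_obs = aug$n_obs, L = aug$L,
         priors = priors,
         settings = list(chains = chains, burnin = as.integer(burnin),
                         iters = as.integer(iters), thin = as.integer(thin)),
         rhat_threshold = rhat_threshold),
    class = "np_bayes"
  )
}

pooled_draws <- function(object, par) {
  unlist(lapply(object$chains, function(m) m[, par]), use.names = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (1992-style) R-hat from between- and within-chain variances,
#' without split chains or rank normalization: with m chains of n draws,
#' `W` the mean within-chain variance and `B/n` the variance of chain
#' means, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate
#' convergence; the reference protocol flags `Rhat < 1.1`.
#'
#' If every chain has zero internal variance the statistic is undefined:
#' the function returns 1 with attribute `degenerate = TRUE` when the chain
#' means also coincide (a genuine point-mass posterior), and `Inf` when
#' they disagree.
#'
#' @param chains A list of numeric vectors (one per chain, equal lengths
#'   >= 2), or a matrix with one column per chain.
#' @return A scalar R-hat value.
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(101, 102, 103)))  # far from 1
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  m <- length(chains)
  if (m < 2L) stop("need >= 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L || n < 2L) stop("chains must have equal lengths >= 2")
  means <- vapply(chains, mean, numeric(1L))
  vars <- vapply(chains, stats::var, numeric(1L))
  W <- mean(vars)
  B_over_n <- stats::var(means)      # = B/n in the classic notation
  if (W == 0) {
    if (B_over_n == 0) return(structure(1, degenerate = TRUE))
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Highest posterior density interval
#'
#' Shortest interval containing at least `prob` of the sample: among all
#' windows of `ceiling(prob * n)` consecutive sorted draws, the narrowest
#' (ties broken by the lowest window).
#'
#' @param draws Numeric sample from the posterior.
#' @param prob Target probability mass (default 0.95).
#' @return Numeric `c(low, high)`.
#' @examples
#' hpd_interval(1:100, 0.95)  # width 94
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  stopifnot(length(draws) >= 1L, prob > 0, prob < 1)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)            # which.min takes the first minimum
  c(x[i], x[i + m - 1L])
}

#' Summarize a fitted abundance model
#'
#' Posterior medians of pooled draws (medians rather than means, to resist
#' the right skew of abundance posteriors), the 95% highest-posterior-
#' density interval for N_P, per-parameter Gelman-Rubin statistics, and a
#' convergence flag (`max R-hat < threshold` across N_P, psi and p).
#'
#' @param object A fitted `"np_bayes"` model.
#' @param prob Mass of the HPD interval (default 0.95).
#' @param rhat_threshold Convergence threshold; defaults to the one stored
#'   in the fit (1.1 unless overridden).
#' @param ... Unused.
#' @return An object of class `"summary.np_bayes"`: list with `n_p_median`,
#'   `hpd_low`, `hpd_high`, `psi_median`, `p_median`, `rhat` (named vector),
#'   `converged`, plus the fit's dimensions.
#' @export
summary.np_bayes <- function(object, prob = 0.95, rhat_threshold = NULL, ...) {
  if (is.null(rhat_threshold)) rhat_threshold <- object$rhat_threshold
  np <- pooled_draws(object, "n_p")
  hpd <- hpd_interval(np, prob)
  rhat <- vapply(c("n_p", "psi", "p"), function(par)
    as.numeric(gelman_rubin(lapply(object$chains, function(m) m[, par]))),
    numeric(1L))
  structure(
    list(n_p_median = stats::median(np),
         hpd_low = hpd[1L], hpd_high = hpd[2L], prob = prob,
         psi_median = stats::median(pooled_draws(object, "psi")),
         p_median = stats::median(pooled_draws(object, "p")),
         rhat = rhat, rhat_threshold = rhat_threshold,
         converged = all(rhat < rhat_threshold),
         n_det = object$n_det, n_obs = object$n_obs, L = object$L),
    class = "summary.np_bayes"
  )
}

#' @export
print.summary.np_bayes <- function(x, ...) {
  cat("Bayesian data-augmentation abundance estimate\n")
  cat(sprintf("  N_DET = %d, N_OBS = %d, L = %d\n", x$n_det, x$n_obs, x$L))
  cat(sprintf("  N_P posterior median = %.2f, %d%% HPD [%.1f, %.1f]\n",
              x$n_p_median, round(100 * x$prob), x$hpd_low, x$hpd_high))
  cat(sprintf("  psi median = %.4f, p median = %.4f\n",
              x$psi_median, x$p_median))
  cat(sprintf("  R-hat: n_p %.3f, psi %.3f, p %.3f -> %s (threshold %.2f)\n",
              x$rhat[["n_p"]], x$rhat[["psi"]], x$rhat[["p"]],
              if (x$converged) "converged" else "NOT converged",
              x$rhat_threshold))
  invisible(x)
}

#' @export
print.np_bayes <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
coef.np_bayes <- function(object, ...) {
  s <- summary(object)
  c(n_p = s$n_p_median, psi = s$psi_median, p = s$p_median)
}

#' Posterior-predictive detection vectors
#'
#' Draws new detection vectors from the fitted model: for each simulation a
#' pooled posterior draw of (N_P, p) is taken, each of the N_P parents
#' receives a Binomial(N_OBS, p) detection count, and parents with zero
#' detections are dropped (they would not be observed). Useful for
#' posterior-predictive checks against the observed frequency counts.
#'
#' @param object A fitted `"np_bayes"` model.
#' @param nsim Number of predictive draws.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` integer vectors of per-parent detection counts.
#' @export
simulate.np_bayes <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  np <- pooled_draws(object, "n_p")
  p <- pooled_draws(object, "p")
  idx <- sample.int(length(np), nsim, replace = TRUE)
  lapply(idx, function(i) {
    y <- stats::rbinom(np[i], object$n_obs, p[i])
    y[y > 0L]
  })
}

#' Trace and posterior plots for a fitted abundance model
#'
#' @param x A fitted `"np_bayes"` model.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.np_bayes <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  n_keep <- nrow(x$chains[[1L]])
  graphics::matplot(seq_len(n_keep),
                    sapply(x$chains, function(m) m[, "n_p"]),
                    type = "l", lty = 1, xlab = "retained draw",
                    ylab = expression(N[P]), main = "Trace (per chain)")
  graphics::hist(pooled_draws(x, "n_p"), xlab = expression(N[P]),
                 main = "Pooled posterior", ...)
  invisible(x)
}

#' Exact posterior of abundance by enumeration
#'
#' Closed-form marginal posterior of N_P for the data-augmentation model,
#' obtained by integrating psi and p analytically and enumerating the
#' number of occupied zero slots `n0`:
#' \deqn{P(N_P = n_{det} + n_0) \propto \binom{L-n_{det}}{n_0}
#'   B(\alpha_\psi + n_{det} + n_0,\ \beta_\psi + L - n_{det} - n_0)\,
#'   B(\alpha_p + S,\ \beta_p + (n_{det}+n_0) N_{OBS} - S)}
#' with `S = sum(y)`. Computed in log space (stable up to `L` of order
#' 1e4); intended as a small-instance oracle for the Gibbs sampler and for
#' exact inference on small problems.
#'
#' @param aug An `"augmented_data"` object (or a [detection_vector()], in
#'   which case `factor` is applied first).
#' @param factor Augmentation factor when `aug` is a detection vector.
#' @param priors Beta hyperparameters as in [np_bayes()].
#' @return A data.frame with columns `n_p` and `prob` (normalized to 1).
#' @examples
#' d <- detection_vector(c(2, 1, 1), n_obs = 2)
#' ex <- exact_np_posterior(np_augment(d, factor = 4))
#' sum(ex$prob)
#' @export
exact_np_posterior <- function(aug, factor = 50,
                               priors = c(psi_a = 1, psi_b = 1,
                                          p_a = 1, p_b = 1)) {
  if (inherits(aug, "detection_vector")) aug <- np_augment(aug, factor)
  stopifnot(inherits(aug, "augmented_data"))
  M <- aug$L - aug$n_det
  S <- sum(aug$y_aug)
  n0 <- 0:M
  n_occ <- aug$n_det + n0
  lp <- lchoose(M, n0) +
    lbeta(priors[["psi_a"]] + n_occ, priors[["psi_b"]] + aug$L - n_occ) +
    lbeta(priors[["p_a"]] + S, priors[["p_b"]] + n_occ * aug$n_obs - S)
  lp <- lp - max(lp)
  pr <- exp(lp)
  data.frame(n_p = n_occ, prob = pr / sum(pr))
}
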