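---
title: "Pedigree accumulation: models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree accumulation: models, simulator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedacc)
```

## The estimation problem

For semelparous species such as Pacific salmon, the spawning adults of one
breeding event are effectively unobservable: capture before spawning disrupts
reproduction, and carcass surveys afterwards are unreliable. Every surviving
offspring, however, is genetically "marked" by exactly two successful
spawners. Given a reconstructed pedigree for a single within-cohort sample of
offspring — which parents are shared among which sampled juveniles — the
number of parents $N_P$ that produced the cohort can be estimated from the
rate at which *new* unique parents accumulate as more offspring are sampled,
exactly as species richness is estimated from sighting frequencies.

The sufficient statistic throughout is the **detection vector** $y$: one
entry per detected parent, counting the sampled offspring that name it. Each
offspring contributes one count to its mother and one to its father, so
$\sum_j y_j = 2 N_{OBS}$ always (a conservation law the test suite checks
under every error treatment). From $y$ we take $N_{DET}$ (its length) and the
frequency counts $a_k$ = number of parents detected exactly $k$ times.

## The estimators

**Chao1.** The bias-corrected lower-bound estimator,
$$\hat N_P = N_{DET} + \frac{a_1 (a_1 - 1)}{2 (a_2 + 1)}
  \cdot \frac{N_{OBS}-1}{N_{OBS}},$$
with the standard bias-corrected variance
$\operatorname{var} = a_2\!\left[\tfrac{k^2}{4} r^4 + k^2 r^3 +
\tfrac{k}{2} r^2\right]$, $r = a_1/a_2$, $k = (N_{OBS}-1)/N_{OBS}$ when
$a_2 > 0$, and the classical $a_2 = 0$ form otherwise. When $a_1 = 0$ the
estimate equals $N_{DET}$ and carries no information about undetected
parents; we report zero variance and a flagged degenerate interval rather
than pick among the several published $a_1 = 0$ variance variants.

**iChao.** Adds tripleton/quadrupleton information:
$$\hat N_P^{iChao} = \hat N_P^{Chao1} + \frac{a_3}{4 a_4}
  \max\!\left(a_1 - \frac{a_2 a_3}{2 a_4},\, 0\right) \ge \hat N_P^{Chao1}.$$
When $a_4 = 0$ we substitute 1 for $a_4$ in the added term, mirroring the
$(a_2+1)$ device of Chao1; this keeps the estimator finite and preserves
dominance over Chao1. Its variance is the asymptotic delta-method variance
under the multinomial frequency covariance
$\operatorname{cov}(a_i, a_j) = a_i(\delta_{ij} - a_j/\hat N_P)$, with the
gradient of the point estimator computed by central differences (the
estimator is piecewise smooth; at the `max()` kink the computed one-sided
slope is used). Frequencies above 4 enter only through $N_{DET}$, so their
partials are exactly 1.

**Confidence intervals** for both use the log transform that respects the
right skew of richness estimates: with $T = \hat N_P - N_{DET}$ and
$R = \exp\!\big(z \sqrt{\log(1 + \operatorname{var}/T^2)}\big)$, the
interval is $[N_{DET} + T/R,\; N_{DET} + T R]$ — never below the number of
parents actually observed.

**Bayesian data augmentation.** The detection vector is padded with zeros to
length $L = 50\,N_{DET}$ and modeled with a latent presence indicator per
slot:
$$z_j \sim \mathrm{Bern}(\psi), \qquad
  y_j \sim \mathrm{Bin}(N_{OBS},\, z_j\, p), \qquad
  N_P = \sum_{j=1}^{L} z_j,$$
with flat $\mathrm{Beta}(1,1)$ priors on both $\psi$ (the probability that
an augmented slot is a real parent) and $p$ (the per-offspring-draw
probability of detecting a present parent). The augmentation factor is a
tunable: values below ~2 visibly truncate the posterior (the package warns),
while very large values waste computation; 50 is the default working value.

## An exact collapsed Gibbs sampler

Every full conditional of this model is conjugate, so no generic MCMC engine
or tuning phase is needed. Slots with $y_j \ge 1$ have $z_j = 1$ with
probability one. The $L - N_{DET}$ zero slots are *conditionally iid* with
$$P(z_j = 1 \mid y_j = 0, \psi, p)
  = \frac{\psi (1-p)^{N_{OBS}}}{\psi (1-p)^{N_{OBS}} + 1 - \psi},$$
so their sum $n_0$ is Binomial, and the sweep collapses to three scalar
draws:
$n_0$, then $p \mid \cdot \sim \mathrm{Beta}(1 + S,\; 1 + (N_{DET}+n_0)
N_{OBS} - S)$ with $S = \sum_j y_j$, then $\psi \mid \cdot \sim
\mathrm{Beta}(1 + N_{DET} + n_0,\; 1 + L - N_{DET} - n_0)$. This is
*exactly equivalent in law* to updating each $z_j$ individually and makes a
sweep O(1) instead of O($L$). $(1-p)^{N_{OBS}}$ is evaluated as
`exp(n_obs * log1p(-p))` to avoid underflow.

Because $\psi$ and $p$ integrate out analytically, the marginal posterior of
$N_P$ is available in closed form
(`exact_np_posterior()`, computed in log space with `lchoose`/`lbeta`); the
test suite requires the Gibbs draws to match this enumeration to total
variation distance below 0.02, which pins the sampler's correctness
independently of its implementation.

The default protocol: 3 chains, 3500 discarded
sweeps per chain, 5000 further sweeps thinned by 50 (100 retained per chain,
300 pooled); `iters`/`thin` make any other retention scheme expressible. An
adaptation period would be meaningless for an exact conjugate sampler, so
the conventional 1000-sweep adaptation + 2500-sweep burn-in budget is folded
into the single 3500-sweep discard. Summaries use posterior *medians* (robust to the right skew; a
half-integer median of integer draws is reported unrounded), a 95% highest
posterior density interval (shortest window of $\lceil 0.95 n \rceil$ sorted
draws, ties resolved to the lowest window), and the classic Gelman–Rubin
$\hat R$ — no split-chain or rank normalization — computed for $N_P$, $\psi$
and $p$, with convergence declared when the maximum is below 1.1 (the
threshold is a parameter; 1.05 is a common stricter choice). If every chain
is a point mass the statistic is undefined: we return 1 flagged
`degenerate` when the chains agree and `Inf` when they do not.

```{r}
d <- detection_vector(c(3, 2, 2, 1, 1, 1, 1, 1), n_obs = 6)
fit <- np_bayes(d, seed = 1)
summary(fit)
```

## The breeding-cohort simulator

`simulate_breeding()` emulates salmonid-style reproductive ecology: each
female takes a zero-truncated Poisson($\lambda = 4$) number of distinct
mates (capped at the number of males and at her fecundity) and a total
offspring count uniform on $\{2500, \ldots, 6500\}$. Three details are
deliberate choices where the mating system is underdetermined:

* **Zero truncation and the male-side guarantee.** Mate counts are
  zero-truncated, and any male left unmated after the female draws is
  assigned one uniformly chosen female. Together these ensure every
  configured adult truly parents offspring, so the configured
  $N_P = n_{females} + n_{males}$ is *exactly* the estimand. Allowing
  sterile adults would silently shrink the estimable quantity below the
  nominal truth.
* **Offspring allocation.** A female's fecundity is split among her mates as
  one offspring per mate plus an equal-probability multinomial remainder.
  The +1 floor is what guarantees the previous point at any fecundity (a
  pure multinomial only achieves it with overwhelming probability at
  salmonid fecundities, and unit tests exercise small fecundities); at the
  default 2500–6500 range its effect is negligible.
* **Sex ratios.** `split_sexes()` rounds the female share down and gives the
  remainder to the males, so a 1:1 ratio at $N_P = 25$ means 12 females and
  13 males; any ratio is expressible via `prop_female`.

Sampling is uniform without replacement from the full cohort, carrying true
parent identifiers (mothers are `1..n_females`, fathers follow).

**What the simulator does and does not emulate.** Parent detection
probabilities are *heterogeneous* here — fecundity varies 2.6-fold across
females and father shares vary more through the mating lottery — while the
Bayesian observation model assumes one common $p$. Passing parameter-
recovery tests therefore show robustness to this realistic violation, not
correctness under arbitrary heterogeneity. The simulator does not model
genotyping or sibship-inference mechanics (reconstruction error is injected
directly at the pedigree level, below), survival differences among families,
or multi-cohort structure.

## Pedigree reconstruction errors

Two injectors perturb a sample the way sibship-reconstruction errors would,
with eligibility decided once, on the input sample, before any flips:

* **Type I (false positive)** — offspring with *no* detected sibling are
  eligible; each of their two parent slots flips with the given rate to a
  uniformly chosen *different* same-sex parent from the original sample's
  pool. Each flip merges away a singleton parent, so $N_{DET}$ can only
  decrease. If no alternative same-sex parent exists the slot is kept with a
  warning.
* **Type II (false negative)** — offspring with at least one detected
  sibling are eligible; flipped slots are reassigned to brand-new, unique
  same-sex parents, so $N_{DET}$ can only increase. A Type II storm of
  novel singletons inflates $a_1$, which is precisely what detonates the
  Chao correction term while the Bayesian model absorbs part of it.

In comparative experiments every error type and rate is applied to the *same*
base sample per replicate (the harness reconstructs treatments from one
stored replicate seed), so contrasts across rates are not confounded by
simulation noise.

## The benchmarking harness

`run_grid()` executes simulate → sample → (inject) → detect → estimate over
either a factorial grid of $(N_P, N_{OBS})$ cells or a uniform-draw design
with both drawn integer-uniform from a range (default 25–500), and
summarizes bias (mean and median of estimate/truth), the coefficient of
variation ($100 \times$ sample-SD/mean, computed on bias ratios — identical
to the CV of raw estimates within a fixed-truth cell by scale invariance),
RMSE (against truth within a cell; of ratios against 1 in uniform designs),
and closed-interval coverage. Bayesian rows carry $\hat R$ and a convergence
flag; `summarize_metrics(converged_only = TRUE)` reproduces
convergence-filtered summaries. Every replicate derives its own RNG stream
from the master seed by deterministic mixing, so runs are reproducible and
order-independent.

Problem sizes used by the shipped tests and by `scripts/acceptance.R` are
desk-scale choices: 200 replicates for the uniform-draw coverage
experiments and 100 per error-grid cell (the error grid's native replicate
count), with Monte-Carlo bands widened accordingly; the full
1000-replicate design is available by raising `replicates`.

## Known limitations

* The homogeneous-$p$ observation model concentrates its posterior sharply
  once $\bar y = 2 N_{OBS}/N_{DET}$ is large: $P(y = 0 \mid z = 1) =
  (1-p)^{N_{OBS}}$ becomes astronomically small, so at high sampling depth
  the posterior of $N_P$ collapses onto $N_{DET}$. Under heterogeneous
  detection this makes the HPD interval overconfident — parents with small
  offspring shares are systematically likelier to be missed than the common
  $p$ admits. The mid-depth underestimation (posterior medians near 90% of
  truth at $N_{OBS}:N_P$ between 0.5 and 5) is the same misfit seen from the
  bias side. Covariate or hierarchical structure on $p$ would be the
  remedy and is out of scope here.
* Every estimator in the package is bounded below by $N_{DET}$; none can
  compensate for Type II inflation beyond discounting the excess singletons'
  effect on the *correction*, so under heavy false-negative error the
  Bayesian estimate tends to the inflated $N_{DET}$ itself (e.g. a floor of
  $\approx 3\times$ truth at a 20:1 sampling ratio with 5% error), while the
  Chao estimators overshoot that floor by another order of magnitude.
* The Chao variance branch for $a_1 = 0$ and the iChao gradient at the
  `max()` kink are documented conventions among several defensible ones;
  both matter only in edge cases.

## Interfaces

Functions are the primary interface. A thin command-line wrapper
(`system.file("cli", "pedacc.R", package = "pedacc")`) exposes `simulate`,
`inject-errors`, `detect`, `estimate chao|ichao|bayes` and `run-grid` over
delimited-text samples (3 columns, header mandatory), one-count-per-line
detection vectors with a JSON sidecar, RFC-4180 CSV outputs, and a
`.prov.json` provenance sidecar (package version, invocation hash, seed)
next to every file it writes.
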