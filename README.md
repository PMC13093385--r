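# pedacc — pedigree accumulation estimators of parental abundance

For semelparous fishes (Pacific salmon being the extreme case), the adults of
one breeding event die after spawning and are effectively unobservable — yet
every surviving offspring is genetically "marked" by its two parents.
Reconstructing the pedigree of a single within-cohort offspring sample turns
spawner censusing into a species-richness problem: the number of parents
N<sub>P</sub> is the asymptote of the curve along which *new* unique parents
accumulate as more offspring are sampled. This package is for molecular
ecologists and fisheries scientists who have (or want to simulate) such
within-cohort pedigree data.

All estimators consume the **detection vector** *y* — one count per detected
parent, each offspring contributing one count to its mother and one to its
father (so Σy = 2·N<sub>OBS</sub>) — summarized by N<sub>DET</sub> detected
parents and the frequencies a<sub>k</sub> of parents detected exactly *k*
times:

* **Chao1** (bias-corrected, with variance and log-transform 95% CI):

  N̂<sub>P</sub> = N<sub>DET</sub> + [a₁(a₁−1) / (2(a₂+1))] · (N<sub>OBS</sub>−1)/N<sub>OBS</sub>

* **iChao**, which adds tripleton/quadrupleton information and always
  dominates Chao1:

  N̂<sub>P</sub><sup>iChao</sup> = N̂<sub>P</sub><sup>Chao1</sup> + (a₃/4a₄) · max(a₁ − a₂a₃/2a₄, 0)

* A **hierarchical Bayesian data-augmentation model**: *y* padded with zeros
  to length L = 50·N<sub>DET</sub>, latent presence indicators
  z<sub>j</sub> ~ Bern(ψ), detections y<sub>j</sub> ~ Bin(N<sub>OBS</sub>,
  z<sub>j</sub>·p), flat Beta priors, N<sub>P</sub> = Σz. The model is fully
  conjugate and is fitted by an exact collapsed Gibbs sampler (verified
  against the closed-form enumerated posterior), with classic Gelman–Rubin
  R̂ diagnostics and highest-posterior-density intervals.

A breeding-cohort simulator (Poisson mate numbers, uniform 2500–6500 female
fecundity), Type I / Type II pedigree-error injectors, and a benchmarking
harness (bias, CV, RMSE, interval coverage over scenario grids) round out
the package; see the methods vignette in `vignettes/` for the modeling
details and design choices.

## Worked example

Simulate a breeding population of 100 adults (50 females, 50 males), sample
60 offspring from the ~228k-strong cohort, and estimate N<sub>P</sub> three
ways:

```r
library(pedacc)

ped  <- simulate_breeding(breeding_scenario(50, 50), seed = 7)
samp <- sample_offspring(ped, 60, seed = 8)
d    <- detection_vector(samp)
d
#> Detection vector: n_det = 64 , n_obs = 60
#>    a1 = 31, a2 = 21, a3 = 6, a4 = 4

chao1(d)
#> Chao1 estimate of parental abundance
#>   N_DET = 64, N_OBS = 60
#>   N_P = 84.784  (var 111.926, 95% CI 72.113 - 117.248)

ichao(d)
#> iChao estimate of parental abundance
#>   N_DET = 64, N_OBS = 60
#>   N_P = 90.503  (var 151.719, 95% CI 75.139 - 127.055)

summary(np_bayes(d, seed = 9))
#> Bayesian data-augmentation abundance estimate
#>   N_DET = 64, N_OBS = 60, L = 3200
#>   N_P posterior median = 83.00, 95% HPD [70.0, 94.0]
#>   psi median = 0.0263, p median = 0.0243
#>   R-hat: n_p 0.995, psi 0.997, p 0.996 -> converged (threshold 1.10)
```

The 60 sampled offspring detected 64 of the 100 true parents; the 31
singletons signal that many parents remain unseen. Chao1 raises the floor of
64 to ~85, iChao to ~91, and the Bayesian posterior median is 83 with a 95%
HPD of [70, 94] — all bracketing or approaching the true value of 100 from
below, as expected at this sampling depth (0.6 offspring per parent).

Users with a real reconstructed pedigree can enter the same pipeline either
from a 3-column parentage table (`read_offspring_sample()`) or directly from
per-parent counts (`detection_vector(y, n_obs = ...)` or
`read_detection_vector()`). A thin command-line wrapper is installed at
`system.file("cli", "pedacc.R", package = "pedacc")` with subcommands
`simulate`, `inject-errors`, `detect`, `estimate chao|ichao|bayes`, and
`run-grid`.

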