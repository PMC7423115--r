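# expotraj

Latent-class trajectories of lifetime exposure intensity, and their
association with disease, for case-control studies.

## What it does

A cumulative exposure index (f/mL-years of asbestos, cigarette-years of
smoking) collapses a lifetime of exposure into one number and discards
*when* and *how intensely* the dose was accumulated. `expotraj` implements
a two-stage alternative:

1. **Trajectory classes.** Annual exposure-intensity series on a backward
   time axis (years before the index date) are clustered by a latent class
   mixed model (LCMM): a multinomial membership sub-model with class
   intercepts, and per-class latent trajectories over natural cubic splines
   of time (inner knots 12/24/36 years) with class-specific random
   intercepts. Skewed, zero-heavy intensities are normalised by a monotone
   I-spline link `H(y) = Σ w_k² I_k(y)` whose Jacobian is part of the
   likelihood; the class-conditional density is closed-form multivariate
   normal (random intercept + unit measurement error). Estimation is
   multi-start maximum likelihood (analytic-gradient BFGS, 50-start grid by
   default); models with G = 1..6 classes are compared by BIC/AIC, relative
   entropy and the posterior classification table.
2. **Association.** Each subject enters a logistic regression once per
   class, weighted by the posterior membership probability, with
   never-exposed subjects as the reference class, fractional-polynomial
   confounder adjustment (e.g. powers (-2,-2) for age, 0 for a cumulative
   dose), cluster-robust sandwich intervals, and three AIC-compared
   strategies for mutual adjustment between two exposures (none /
   cumulative dose / the other exposure's trajectory class).

Exposure assessment utilities cover job-exposure-matrix annual levels
(mean over jobs of intensity x probability x frequency), cumulative
indices, the comprehensive smoking index (half-life/lag construction),
and the a priori partition of very-low-cumulative-exposure subjects
(strictly below 0.26 f/mL-years by default) that makes the asbestos LCMM
tractable despite the spike of annual intensities at zero.

A synthetic-data generator with known latent-class structure
(`generate_trajectories()`, `preset_two_class()`, `icarelike_preset()`,
`generate_association_data()`) supports parameter-recovery validation and
demos; no individual-level data ship with the package.

## Worked example

```r
library(expotraj)

dat  <- generate_trajectories(preset_two_class(), 400, seed = 7)
spec <- lcmm_spec(2, link_spline(c(0, 20, 100)),
                  time_basis(boundary_knots = c(0, 50)),
                  n_starts = 10, seed = 11)
fit <- lcmm_fit(dat$series, spec)
fit
#> LCMM fit: G = 2 classes, 400 subjects, 14303 observations
#>   loglik -21479.205 | AIC 42992.4 | BIC 43060.3 | converged: TRUE
#>   class proportions: 0.565 0.435
#>   random-intercept SDs: 1.902 1.914

predict_trajectory(fit, 1, times = c(5, 15, 25), scale = "natural")
#> [1] 7.862807 7.847872 7.843994
```

The two classes recover the generating plateaus (8 and 22 cig/day on the
natural scale) and the class proportions of the simulated draw. Feeding
the posterior matrix to the weighted second stage:

```r
rec <- expand_weighted(dat$subjects, fit$posterior,
                       reference_ids = character(0))
rec$class <- droplevels(rec$class)
weighted_logistic(rec, outcome ~ class)
#> Weighted logistic fit: 800 records, weighted loglik -257.899, AIC 519.8
#>         term     OR  ci_lo  ci_hi
#>  (Intercept) 0.4304 0.3238 0.5721
#>  classclass2 2.8598 1.8924 4.3218
```

The posterior classification is essentially crisp
(`lcmm_entropy(fit$posterior)` is 0.99995), and the `classclass2` odds
ratio estimates the generating class-2 log-odds contrast (true value 1.2,
i.e. OR 3.32) with its cluster-robust 95% CI.

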