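---
title: "Latent-class trajectories of lifetime exposure intensity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class trajectories of lifetime exposure intensity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control studies of occupational and behavioural exposures usually
summarise a lifetime of exposure in one number — a cumulative index such as
f/mL-years of asbestos or cigarette-years of smoking. Two subjects with the
same cumulative dose can have accumulated it very differently: briefly at
high intensity long ago, or steadily at moderate intensity up to diagnosis.
`expotraj` implements a two-stage analysis that keeps this temporal
dimension: stage 1 groups subjects into latent classes of lifetime
intensity trajectories; stage 2 estimates the association between class
membership and a binary disease outcome, carrying classification
uncertainty through as posterior-probability weights.

## Stage 1: the latent class mixed model

Each subject $i$ contributes an annual series $Y_{ij}$ of exposure
intensities (cigarettes/day, or equivalent f/mL from a job-exposure
matrix) at integer times $t_{ij}$ counted backwards from the index date
(diagnosis for cases, interview for controls). The population is assumed
to consist of $G$ unobserved classes. Membership follows a multinomial
logistic sub-model with class intercepts only,
$\pi_g = \exp(\xi_g) / \sum_l \exp(\xi_l)$ (the last class is the
reference with $\xi_G = 0$). Given class $g$, a monotone transform of
intensity follows a linear mixed model over a natural cubic spline basis
of time,
$$H(Y_{ij}) = X(t_{ij})^\top \beta_g + u_i + \epsilon_{ij}, \qquad
  u_i \sim N(0, \sigma_g^2), \quad \epsilon_{ij} \sim N(0, 1),$$
with a class-specific random-intercept SD $\sigma_g$ that induces the
within-subject correlation a latent-class growth analysis would ignore.

**The link.** Annual intensities are right-skewed with a point mass at
zero, and a log(x+1) transform is not flexible enough in practice. $H$ is
therefore a monotone I-spline transform
$H(y) = \eta_0 + \sum_k w_k^2 I_k(y)$: the $I_k$ are running integrals of
an order-3 M-spline basis (quadratic pieces, continuously differentiable),
so $H$ is non-decreasing by construction with the analytic derivative
$H'(y) = \sum_k w_k^2 M_k(y)$ that enters the likelihood as a Jacobian,
once per observation. The three conventional knots are boundary,
interior, boundary — defaults 0/20/100 cig/day for smoking and
0/0.05/12.6 equivalent f/mL for asbestos. Order 3 is the lowest order
giving a smooth $H$ with an analytic derivative; squaring the
coefficients keeps the optimisation unconstrained. Intensities above the
upper boundary knot are clamped with a warning. Knot search is left to
the user (the defaults can be compared by AIC across candidate sets).

**Identifiability.** One location and one scale are redundant between the
link and the latent process. We fix them in the measurement part —
$\eta_0 = 0$ and $\sigma_\epsilon = 1$ — so all class parameters
($\beta_g$, $\sigma_g$) remain free.

**Time.** $X(t)$ is an intercept plus a natural cubic spline with inner
knots at 12, 24 and 36 years before the index date (quartiles of exposure
time in the motivating design) and boundary knots at the observed time
range; beyond the boundaries the basis continues linearly.

**Likelihood.** With a single random intercept, the class-conditional
density of a subject's series is multivariate normal with covariance
$\sigma_g^2 \mathbf{1}\mathbf{1}^\top + I$, evaluated in closed form via
the Woodbury identity — no numerical integration. The observed-data
log-likelihood is
$\sum_i \log \sum_g \pi_g \phi(H(Y_i); X_i \beta_g, V_{ig}) \prod_j H'(Y_{ij})$,
computed with log-sum-exp stabilisation.

**Optimisation.** The full parameter vector (membership intercepts,
trajectory coefficients, random-intercept SDs via $|s_g|$, link
coefficients via $w_k^2$) is maximised by BFGS with an analytic gradient
(one vectorised pass computes both value and gradient). We chose this
over a damped Newton scheme: the parameterisation is smooth and
unconstrained, the analytic gradient is cheap, and BFGS's implicit
curvature estimate avoids the cost and fragility of a numeric Hessian.
Multi-start: the one-class model is fitted first from a deterministic
start (link initialised by projecting a standardised identity onto the
I-spline basis); for $G > 1$ a grid of `n_starts` (default 50, matching
standard practice for these models) perturbed starts — trajectory
intercepts jittered around the one-class solution by about 1.5 marginal
SDs, membership intercepts standard normal — each runs for 15 BFGS
iterations, and the best candidate is refined to convergence twice.
Convergence reports three criteria: max parameter change between the two
refinement passes < 1e-4, log-likelihood change < 1e-8, and mean squared
gradient < 1e-4 (all configurable in `lcmm_control()`). A start whose
posterior mass in any class falls below 5 subjects is discarded as
degenerate. With the seed fixed the whole procedure is deterministic.

**Zeros.** Interruption years inside the exposure window enter the series
as zeros; the model accommodates a moderate point mass at zero through
the link, but a dominant spike prevents convergence. The a priori
partition exists for exactly that case: subjects with a cumulative index
of exposure strictly below a cutoff (default 0.26 f/mL-years = the 0.01
f/mL legal 8-hour limit times a 26-year mean exposure duration) are
assigned to a very-low-exposure class up front, and the LCMM is fitted to
the remainder. Values exactly at the cutoff are modelled ("lower than"
is strict).

## Model selection

`lcmm_select()` fits $G = 1 \dots G_{max}$ and tabulates log-likelihood,
AIC, BIC, relative entropy
$E = 1 - \sum_{i,g} (-\hat p_{ig} \ln \hat p_{ig}) / (N \ln G)$ (1 =
perfectly crisp; the standard growth-mixture normalisation), the smallest
class, class percentages, and the posterior classification table (mean
posterior probability of class $l$ among subjects modally assigned to
class $g$). No winner is declared automatically — substantive relevance
of the trajectory shapes is part of the choice — but the BIC-minimising
$G$ is flagged. Failures at one $G$ (typically the degenerate-class guard
when $G$ exceeds the data's support) are recorded in the report and do
not abort the ladder.

## Stage 2: posterior-weighted logistic regression

Each LCMM-classified subject is expanded into $G$ records, one per class,
weighted by the posterior membership probability; a priori low-exposure
subjects and never-exposed subjects contribute one record each with
weight 1, the never-exposed forming the reference level. The weighted
Bernoulli log-likelihood is maximised by IRLS (`glm` with prior
weights). Because records of one subject are correlated by construction,
confidence intervals default to a sandwich variance clustered by subject;
naive information-based intervals are reported alongside. AIC is
$-2 \times$ (weighted log-likelihood) $+ 2k$.

Confounders enter through fractional polynomials with powers from
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 = log; a repeated power $(p,p)$
expands to $x^p$ and $x^p \ln x$), after shifting to positivity by the
Royston–Altman increment rule and scaling by a power of 10 of the range.
Typical choices are $(-2,-2)$ for age and power 0 for a cumulative dose.
Powers are user-specified; an exhaustive FP search is deliberately not
the default.

For mutual adjustment between two exposures, `compare_adjustments()` fits
(i) no mutual adjustment, (ii) adjustment for the other exposure's
cumulative dose (CIE, or the comprehensive smoking index for smoking),
and (iii) adjustment for the other exposure's trajectory class, comparing
AICs. Strategy (iii) expands records over the cross-classification with
product weights $\hat p_{ig} \hat p_{ih}$ — the two classifications
treated as independent given the data — with modal assignment available
as an option, since either convention is defensible.

The comprehensive smoking index is
$\mathrm{CSI} = (1 - 0.5^{d^*/\tau})\, 0.5^{t^*/\tau} \ln(I + 1)$ with
lag-adjusted duration $d^* = \max(0, d - \max(0, \delta - c))$ and
cessation time $t^* = \max(0, c - \delta)$. The half-life $\tau$ and lag
$\delta$ are study-specific estimates and must be supplied explicitly;
the package sets no hidden defaults.

## The synthetic generator, and what passing tests show

No individual-level data from the motivating study design are public, so
validation rests on `generate_trajectories()`: class drawn from $\pi$, a
class-specific exposure window (first exposure and cessation, whole years
before index), latent values $X(t)\beta_g + u_i$, and observed
intensities $\max(0, \Lambda + \epsilon)$ — zeros arise structurally from
pre-initiation years, post-cessation years and truncation, not from an
ad hoc mixture. Window distributions are class-specific so that
duration/timing confounding can be switched on or off.

Presets (fixed once, documented here):

* `preset_two_class()` / `preset_three_class()` — flat plateaus
  (8/22 and 5/15/28 cig/day), $\sigma_g = 2$, unit measurement SD, first
  exposure 25–45 years before index, no cessation gap. Latent means are
  $\geq 4.5$ total SDs apart: these are *well-separated* recovery
  benchmarks.
* `icarelike_preset("smoking")` — four classes (plateaus 8/15/25/22
  cig/day) whose windows emulate constant, recent, long-term and distant
  high-intensity profiles; `icarelike_preset("asbestos")` — four modelled
  classes plus a very-low-exposure class near 0.005 f/mL for the a priori
  partition. Qualitative demonstrations only.
* `generate_association_data()` — stage-2 data with exact Bayes
  posteriors from a Gaussian class-score model (default separation 5,
  relative entropy about 0.97, the discrimination level a well-fitting
  trajectory model attains) and outcomes drawn from known class
  log-odds.

Problem sizes used in the validation suite — chosen as the smallest at
which the checked properties are stable: two-class recovery at $n = 400$,
20 replicates, 10 starts; three-class BIC selection at $n = 600$, ladder
to $G = 4$, 20 replicates, 8 starts; CI coverage at $n = 2000$, 50
replicates. What the generator does *not* emulate: JEM coding error,
calendar-period trends in exposure intensity, recall error in interview
histories, and matched sampling. Passing recovery tests therefore shows
the estimator is correct under its own assumptions, not that real
exposure histories are this clean.

## Numerical choices and degenerate inputs

* Likelihood evaluations at inadmissible parameters (non-finite values,
  $H' \le 0$ at an observation) return $-\infty$ and are rejected by the
  line search rather than raising errors.
* The all-zero link ($w = 0$) makes $H$ flat; `link_inverse()` and
  natural-scale prediction refuse it explicitly.
* `link_inverse()` brackets on the knot span and bisects to 1e-10;
  latent values outside $[H(\min), H(\max)]$ clamp to the boundary
  intensities.
* Natural-scale mean trajectories integrate $H^{-1}$ over
  $u + \epsilon \sim N(0, \sigma_g^2 + 1)$ by 30-node Gauss–Hermite
  quadrature (configurable; 30 vs 60 nodes agree to < 1e-4).
* Ties in modal assignment break to the lowest class index; classes are
  relabelled by decreasing $\hat\pi_g$ after fitting for stable output.
* Aliased (collinear) stage-2 columns keep their coefficient row with NA
  standard errors; separation is flagged when an indicator coefficient
  exceeds 15 in absolute value.

## Known limitations

* Membership covariates, random slopes and autoregressive errors are out
  of scope (the membership sub-model has intercepts only, as in the
  motivating design).
* A dominant point mass at zero must be handled by the a priori
  partition; the likelihood itself does not model a zero spike.
* The multi-start grid makes local maxima unlikely, not impossible;
  refitting with a different seed and comparing log-likelihoods is cheap
  insurance.
* Stage 2 treats posterior weights as fixed; uncertainty in the stage-1
  parameters themselves is not propagated (the sandwich variance covers
  record replication, not estimation error in the weights).

## Worked example

```{r, eval = FALSE}
library(expotraj)

dat <- generate_trajectories(preset_two_class(), 400, seed = 7)
spec <- lcmm_spec(2, link_spline(c(0, 20, 100)),
                  time_basis(boundary_knots = c(0, 50)),
                  n_starts = 10, seed = 11)
fit <- lcmm_fit(dat$series, spec)
fit
predict_trajectory(fit, 1, times = c(5, 15, 25), scale = "natural")

rec <- expand_weighted(dat$subjects, fit$posterior,
                       reference_ids = character(0))
rec$class <- droplevels(rec$class)
weighted_logistic(rec, outcome ~ class)
```
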