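---
title: "Modeling aggregate emotion dynamics with an appraisal-structured VAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling aggregate emotion dynamics with an appraisal-structured VAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Societies express a palette of emotions in online conversations. When an
event pushes one emotion above its usual level — anger after an attack,
joy after a victory — three questions follow: how *much* is each emotion
expressed on an average day (frequency), how *long* does a deviation take
to die out (duration), and which other emotions *rise or fall* as it does
(transition), both the next day and over the following month. **emodyn**
answers these questions from a daily panel of emotion relative
frequencies: for each of N emotions (the motivating design tracks 24),
the share of that day's documents expressing it, obtained by dictionary
matching over lemmatized token lists.

# The model

The panel follows a first-order vector autoregression with exogenous
step dummies (VARX(1)):

$$E_t = \alpha + \Gamma E_{t-1} + B X_t + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \Sigma),$$

where $E_t$ is the N-vector of daily relative frequencies, $X_t$ holds
M permanent 0/1 step dummies (platform-level regime changes such as a
character-limit rollout), and $\Sigma$ is a full innovation covariance:
emotions co-move within a day.

An unrestricted $\Gamma$ would carry $N^2$ free parameters. Instead,
every coefficient is a function of the emotions' positions in a
K-dimensional appraisal space (valence, arousal, dominance when K = 3),
with scores mean-centered across emotions (overbars) and a centered
dictionary-size control $\bar S_i$:

* base level: $\alpha_i = \mu_0 + \sum_k \mu_k \overline{DIM}_{ik} + \mu_S \bar S_i$
* carryover (diagonal): $\gamma_{ii} = \lambda_0 + \sum_k \lambda_k \overline{DIM}_{ik} + \lambda_S \bar S_i$
* transitions (off-diagonal, source j to destination i):
  $\gamma_{ij} = \tau_0 + \sum_k \tau_k^{+} DIST^{k+}_{ij} + \sum_k \tau_k^{-} DIST^{k-}_{ij} + \tau_S \bar S_i$

with one-sided distances $DIST^{k+}_{ij} = \max(DIM_{ik} - DIM_{jk}, 0)$
and $DIST^{k-}_{ij} = \max(DIM_{jk} - DIM_{ik}, 0)$, so that moving *up*
a dimension may transmit differently from moving *down* it. The shared
parameter count is $4K + 6$ (18 at K = 3) plus $N \times M$ free
exogenous coefficients — a drastic, interpretable restriction of the
$N^2 + N + NM$ unrestricted ones.

## Estimation

Substituting the three structural equations into the VARX gives one
stacked regression across all N destination equations
(`build_design()`), estimated by feasible generalized least squares
(`estimate_fgls()`, wrapped by `fit_emotion_var()`):

1. pooled OLS over the stacked system;
2. cross-equation residual covariance $\hat\Sigma$ from the OLS
   residuals, denominator $T-1$ (the observations per equation after
   lagging; no small-sample degrees-of-freedom correction — stated for
   reproducibility);
3. GLS with weight $\hat\Sigma^{-1} \otimes I$, implemented by
   whitening: with $U$ upper-triangular and
   $U'U = \hat\Sigma^{-1}$, the N equations are mixed into N
   uncorrelated pseudo-equations and refit by OLS. Standard errors and
   the joint parameter covariance come from the whitened normal
   equations.

FGLS is two-step by default; `iterate = TRUE` repeats steps 2–3 to
convergence, and a known covariance can be supplied via `sigma` (plain
GLS — with a spherical $\Sigma = cI$ this reproduces pooled OLS
exactly, a useful identity for testing). Equations are stacked
destination-major and the shared-coefficient order is fixed
(`mu_0, mu_<dim>..., mu_dict_size, lambda_0, ..., tau_0, tau_up_<dim>...,
tau_down_<dim>..., tau_dict_size`) so covariance indexing is stable.

Two numerical edge cases are handled explicitly. Noise-free data make
the first-stage fit exact and $\hat\Sigma$ singular; the estimator then
returns the (already exact) OLS solution with a zero covariance rather
than failing. A singular $\hat\Sigma$ with non-trivial residuals —
typically too few days for too many emotions — is an error suggesting
exactly that. Identification also requires more emotions than
base-level regressors (N > K + 2): with N = 4 and K = 3 the
per-equation-constant block $[1, \overline{DIM}, \bar S]$ is exactly
collinear, and the fit refuses with the offending columns named.

## Duration, shocks, and transitions

*Duration.* A deviation with carryover $\lambda$ decays geometrically;
the number of days before P% of its cumulative effect has materialized
is $\ln(1 - P/100)/\ln(\lambda) - 1$ (`duration_interval()`). At the
baseline carryover estimate 0.855983 of an average emotion this gives a
90% interval of 13.8 days. `duration_profiles()` evaluates the same
formula at $\lambda_0 \pm \lambda_k \cdot SD_k$, the carryover of an
emotion one standard deviation above/below average on dimension k, with
$SD_k$ the sample standard deviation of the N emotions' scores.

*Shocks.* Because $\Sigma$ is full, a shock never arrives alone. Under
joint normality, a shock of $\delta$ units to emotion i moves emotion j
by $\delta\,\sigma_{ij}/\sigma_{ii}$ the same day
(`shock_vector()` — the conditional-normal expectation). This day-0
vector is the contemporaneous effect (CE) and measures co-occurrence.

*IRFs.* `compute_irf()` propagates the shock:
$r_0 = \text{shock}$, $r_t = \Gamma r_{t-1}$. Responses are incremental
deviations from the no-shock path, so intercepts and exogenous terms
cancel; the implementation is verified against a brute-force
shocked-minus-unshocked simulation oracle at $10^{-10}$. The long-term
transition measure is the cumulative IRF over days 1–29
(`cumulative_irf()`). `run_all_shocks()` sweeps all N sources with
$\delta_i$ equal to 10% of emotion i's model-implied stationary mean
$(I - \Gamma)^{-1}(\alpha + B\bar x)$ — the base of the percentage is a
package choice, since "10% shock" admits several readings; 10% of the
sample mean is available via `delta_mode = "sample-mean"`.

*Distance regressions.* `distance_regression()` regresses the
$N(N-1)$ off-diagonal CE or CIRF values on a constant, the 2K one-sided
distances, and (by default, toggleable) the destination's centered
dictionary size, by OLS with conventional standard errors. The effects
are themselves estimates, and no generated-regressor correction is
attempted — a deliberate simplification, flagged as a limitation below.

# Pre-estimation diagnostics

`adf_test()` is an augmented Dickey–Fuller regression with constant;
the augmentation order is chosen by information criterion over a common
sample with Schwert's rule bounding the search, and the 5% critical
value follows the MacKinnon (2010) response surface for the
constant-only case. BIC is the default selector: at carryover near 0.9
and T near 800, AIC tends to over-augment and visibly loses power,
while BIC keeps size near nominal (≈3–5% on pure random walks) and
rejects essentially always for the stationary processes this model
generates. `select_lag_order()` fits unrestricted VAR(p) models over a
common sample and reports multivariate AIC/BIC/HQC
($\ln|\hat\Sigma_p|$ plus the usual penalties); BIC is the headline
selector, all three are reported. `granger_tests()` Wald-tests each
cross-lag coefficient of the unrestricted VAR(1), diagonal undefined.
`wald_symmetry()` tests $\tau_k^{+} = \tau_k^{-}$ from the joint GLS
covariance ($\chi^2_1$).

# The appraisal space

`reduce_appraisals()` condenses per-emotion mean ratings on nine
appraisal dimensions (valence, arousal, dominance, motivational state,
time orientation, agency, certainty, attentional activity, effort) to
K = 3 factor scores: principal-axis factoring on the correlation matrix
(iterated communalities, squared-multiple-correlation start, max-|r|
fallback when the correlation matrix is singular), varimax rotation,
regression-method scores (pseudo-inverse when needed). Extraction,
rotation and scoring methods are not dictated by the modeling problem —
these are the most common EFA defaults, and externally supplied score
tables can be used instead, so the choice is not load-bearing. Each
factor is named after the eponymous appraisal loading most strongly on
it and signed so that loading is positive. A factor indicated by a
single variable is unidentifiable on a correlation matrix (its
communality cannot be separated from uniqueness); surveys should give
every expected factor at least two indicators.

# The synthetic-data generator

The raw document corpus behind a study of this kind is typically not
redistributable, so the package ships a generator that emulates the
study conditions end to end and makes every downstream stage testable:

* `sim_config()` — defaults are the study design: N = 24 emotions,
  K = 3 dimensions, T = 790 days, M = 2 step dummies switching on at
  75% and 87% of the sample (late-sample platform events), burn-in 200
  days, innovation scale 0.004 on the frequency scale, target spectral
  radius 0.9.
* `sim_dimension_scores()` — standard-normal scores per dimension;
  dictionary sizes log-uniform on [10, 500] (the spread matters, not
  the law).
* `sim_structured_params()` — draws the 18 shared parameters around
  magnitudes realistic for daily frequency panels (baseline carryover
  near 0.85, weak cross-emotion suppression near −0.01, structural
  slopes of a few 10⁻³), expands them exactly through the structural
  equations, and rescales all carryover/transition parameters uniformly
  until the spectral radius of $\Gamma$ meets the target — uniform
  scaling keeps the expansion exactly consistent, so the returned truth
  re-expands to the simulated matrices bit for bit. The innovation
  covariance has a two-factor correlation structure with per-emotion
  scales around `noise_scale`.
* `simulate_panel()` — iterates the VARX from the deterministic fixed
  point, discards the burn-in, switches the step dummies on at their
  break dates. Frequencies live on the unconstrained Gaussian scale;
  they may leave [0, 1], because the estimation theory is
  linear-Gaussian. Optional clipping (`clip = TRUE`, off by default)
  reports its clip rate.
* `sim_dictionaries()` / `sim_corpus()` — disjoint synthetic term sets
  and dated token-list documents in which each emotion's term is
  planted independently with the day's configured rate, padded with
  filler tokens from a vocabulary disjoint from every dictionary
  (overlap is an error). Bigram terms stay adjacent, and the planted
  indicators are recorded so labeling can be validated against ground
  truth by a binomial oracle.

What the generator does *not* emulate: morphology of any language,
document-length or diurnal structure, heavy tails or
volatility clustering in the innovations, and the empirical marginal
distributions of real frequency series (no public record of them
exists; scales are chosen, not matched). Passing tests therefore show
that the estimator and analytics are correct for the model's own data
generating process — not that real conversations obey a linear-Gaussian
VARX.

# Known limitations

* **Own-lag small-sample bias.** The pooled carryover intercept
  $\lambda_0$ inherits the classic dynamic-regression bias of order
  $-(1+3\lambda)/T$ — about −0.005 at $\lambda \approx 0.86$, T = 790.
  Pooling N = 24 equations shrinks its standard error to a comparable
  size while the bias, common to all equations, does not shrink, so
  nominal 95% intervals for $\lambda_0$ undercover in simulation (the
  replicated-panel test asserts calibration in aggregate across all 18
  shared parameters, where intervals are close to nominal). Estimates
  of $\lambda_0$ should be read with this one-sided O(1/T) caveat;
  duration intervals computed from it are slightly conservative.
* **Generated regressors.** CE/CIRF distance regressions treat
  estimated effects as data; their standard errors are conventional
  OLS.
* **Linear-Gaussian frequencies.** Relative frequencies are modeled on
  an unconstrained scale; the model can predict values outside [0, 1].
* **Two-step FGLS.** $\hat\Sigma$ is estimated once by default;
  standard errors do not account for its sampling variation (iteration
  is available but does not change this).

# Problem sizes used by the test suite

Unit tests run at reduced sizes (5–12 emotions, 30–600 days) chosen so
each property is sharply testable; the study-scale checks use the full
design (N = 24, K = 3, T = 790) with 100 replications for interval
calibration and 200 for test-size simulations, and a 20 000-day panel
for the stationary-mean check. These sizes are the package's own
choices balancing Monte-Carlo resolution against a test suite that runs
in about a minute.

# A short example

```{r, eval = FALSE}
library(emodyn)

cfg   <- sim_config(n_emotions = 12, n_days = 790, seed = 42)
dims  <- sim_dimension_scores(cfg)
truth <- sim_structured_params(dims, cfg)
panel <- simulate_panel(truth$coeffs, cfg)

fit <- fit_emotion_var(panel, dims)
tidy(fit)                       # 18 shared structural coefficients
duration_table(fit, p = 90)     # per-emotion and +/- 1 SD durations

shocks <- run_all_shocks(fit)   # 10%-of-baseline shock to every source
tidy(distance_regression(tidy(shocks), fit$dist, fit$dims, effect = "cirf"))
```
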