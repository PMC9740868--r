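---
title: "Response-surface and neural-surrogate optimization of protein extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface and neural-surrogate optimization of protein extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protexopt)
```

## The problem

Alkaline extraction of a plant protein — here a selenium-enriched rape
(canola) protein — is governed by a handful of process factors: extraction
temperature, extraction time, NaOH concentration, and the liquid-to-material
ratio. The goal is to find the factor settings that maximize the protein
content recovered per gram of powder (mg/g). Running the process at every
candidate setting is infeasible, so the field's standard workflow fits cheap
surrogate models to a designed experiment and optimizes those surrogates
instead. `protexopt` implements the complete workflow:

1. a **Box–Behnken design** (BBD) over the four factors,
2. a **quadratic response-surface model** (RSM) with a full ANOVA,
3. a **back-propagation neural network** (BP-ANN) surrogate,
4. a **real-coded genetic algorithm** (GA) maximizing the surrogate, and
5. the **comparison metrics** used to adjudicate between the two surrogates,
   plus the accompanying assay arithmetic (protein quantitation, yield,
   antioxidant and cytostatic rates, amino-acid summaries).

The packaged study design (`sep_design()`) spans temperature 50–70&nbsp;°C,
time 2–4&nbsp;h, alkali 0.2–0.3&nbsp;mol/L and ratio 50–70&nbsp;mL/g, with
centers (60, 3, 0.25, 60).

## The response-surface model

Factors are rescaled to coded units $x_j = (\xi_j - c_j)/h_j$ with center
$c_j$ and half-range $h_j$, so each design level is $-1$, $0$ or $+1$. The
model is the full second-order polynomial in the four coded factors,

$$ Y = \beta_0 + \sum_j \beta_j x_j + \sum_{j<k} \beta_{jk} x_j x_k
      + \sum_j \beta_{jj} x_j^2 + \varepsilon, $$

15 coefficients fitted by ordinary least squares (`fit_quadratic()`). The
4-factor BBD (24 edge midpoints + replicated centers, `bbd_design()`) makes
the linear and interaction columns mutually orthogonal, which is why each
linear term's partial sum of squares collapses to $12\hat\beta_j^2$ and each
interaction's to $4\hat\beta_{jk}^2$ — a closed form the test suite checks
against brute-force drop-term refits.

```{r}
fit <- fit_quadratic(sep_design())
round(coef(fit), 4)
```

### ANOVA conventions

`rsm_anova()` follows the conventions of the response-surface software this
kind of study is analyzed with:

* **Partial (drop-one-term) sums of squares** for every term: the SSE of the
  model without the term minus the full-model SSE. On this orthogonal design
  partial and sequential SS agree for linear/interaction terms but not for
  the quadratics, and only the partial convention reproduces the published
  per-term values.
* **Lack of fit vs pure error**: the residual SS is split using the
  replicated center runs (4 degrees of freedom from 5 replicates); the
  lack-of-fit F ratio uses the pure-error mean square as denominator.
* **Predicted R²** is PRESS-based: $1 - \mathrm{PRESS}/\mathrm{SST}$ with
  $\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$ from the hat-matrix
  leverages, i.e. exact leave-one-out residuals.
* Normal-probability scores of residuals use Blom plotting positions
  $\Phi^{-1}((i - 0.375)/(n + 0.25))$.

```{r}
rsm_anova(fit, sep_design())
```

### Optimizing the fitted surface

`optimize_surface()` solves the stationary linear system $\nabla Y = 0$ and
refines with multi-start L-BFGS-B over the coded box $[-1,1]^4$ (a
deterministic $3^4$ grid of starts plus the clipped stationary point), so
saddle surfaces and boundary optima are handled. For the packaged design the
fitted Hessian is negative definite and the box maximum is the interior
stationary point, about 56.9&nbsp;mg/g. Note that this is *not* the optimum
printed in such studies' verification tables (56.50&nbsp;mg/g at
62.5&nbsp;°C, 3.0&nbsp;h, 0.25&nbsp;mol/L, 62.2&nbsp;mL/g): desirability
settings of commercial software are rarely published, so the package reports
the true box-constrained maximum and separately *evaluates* the model at any
reported conditions (`predict()`), which is what the reproduction targets
check.

## The neural surrogate

`train_surrogate()` fits a 4-H-1 feed-forward network: tanh hidden layer,
identity output, inputs and targets min-max scaled to $[-1, 1]$. Weights are
initialized uniformly on $[-0.5, 0.5]$ scaled by $1/\sqrt{\text{fan-in}}$,
from a caller-supplied seed; with a fixed seed training is bit-reproducible.
Training is Levenberg–Marquardt: each epoch solves
$(J^\top J + \mu I)\,\delta = -J^\top r$ with the damping factor $\mu$
divided by 10 on an accepted step and multiplied by 10 on rejection
(start $10^{-3}$, abort above $10^{10}$), so the training MSE is
non-increasing by construction. The data are split 70/15/15 into
train/validation/test sets (`split_data()`, largest-remainder sizes — 87
points give 61/13/13); training stops at the epoch cap, the MSE goal, or
after 6 consecutive validation failures, and the best-validation weights are
restored. `sweep_hidden()` repeats this over H = 3..12 and selects the
smallest H attaining the minimum validation MSE.

The 87-point training set is built by exact 3× replication of the 29 design
responses (`replicate_dataset()`): per-replicate raw measurements are not
available, only run means. Two consequences are worth stating plainly:

* **A correlation ceiling.** The five center runs carry five different
  responses at one identical input, so *no* deterministic model can exceed
  the correlation ratio $\eta = \sqrt{1 - SS_{\text{pure}}/SS_{\text{tot}}}
  = 0.9979$ on this set. Trained surrogates reach that ceiling to four
  decimals; published correlations above it (e.g. 0.9998) can only arise
  from true replicate measurements, which are not printed.
* **Interior ambiguity.** 29 distinct support points underdetermine a
  network with 43+ weights, so surrogates that interpolate the design
  perfectly can still deviate by a few mg/g *between* design points. This is
  visible in published studies too, where the ANN+GA optimum exceeds the
  quadratic's box maximum by over 1&nbsp;mg/g. Tests therefore check that
  the GA truly maximizes the surrogate (against a random-search oracle) and
  that the two surrogate optima agree at the mg scale, not at sub-0.2
  precision.

`pooled_replicate_mse()` exposes the pooled within-group variance
$\sum_i (n_i - 1) S_i^2 / (N - r)$ over distinct inputs as a replication
diagnostic; it is kept deliberately distinct from any model's prediction MSE.

## The genetic algorithm

`ga_evolve()` is a real-coded GA with the study's parameters as defaults:
NP = 50 individuals, crossover probability 0.8, mutation probability 0.2,
individual length 4 (one real gene per factor), 100 generations. The
operator set — fitness-proportional roulette selection with a min-shift,
whole-arithmetic crossover, per-gene uniform-reset mutation, one elite —
is the conventional choice where a study names only the probabilities; every
operator parameter is config-swappable. Elitism makes the best-fitness trace
non-decreasing for every seed, which the suite asserts, and "100 epochs"
is implemented as exactly 100 generations with no early stop.
`optimize_extraction()` wires a trained surrogate in as the fitness function
and reports conditions in actual units.

## Comparison metrics

For each model over the 29 design runs, `build_report()` computes

* $R^2 = 1 - \sum(Y_1 - Y_p)^2 / \sum(Y_1 - \bar Y_1)^2$ (the definition
  that coincides with the ANOVA $R^2$ for the least-squares fit; the squared
  Pearson correlation is exposed as an alternative),
* RMSE with divisor $n$,
* SPE = RMSE / $\bar Y_1 \times 100$, and
* two MAD variants. Published MAD formulas in this literature are sometimes
  prediction-free as printed, i.e. $\frac{1}{n}\sum |Y_1 - \bar Y_1|/|Y_1|$,
  which cannot distinguish models; `mad_percent()` implements both that form
  ("printed", 8.67% on the packaged data) and the conventional relative
  prediction error ("conventional", 1.60% for the refit RSM). Because
  neither reproduces published MAD values of ~4%, MAD carries an explicit
  variant label and is excluded from reproduction assertions.

The optimum block reports each model's predicted optimum and, when a
verification measurement is supplied, the relative deviation
$|pred - meas|/meas \times 100$.

## The synthetic-data generator

`simulate_response()` draws $Y_i = x_i^\top \theta + \varepsilon_i$ with
i.i.d. Gaussian noise over any design; `make_study_like()` produces the
29-run + 87-row pair in one call. Defaults are the study conditions: the
published coefficient vector as $\theta$ and
$\sigma = \sqrt{0.6967} \approx 0.835$ mg/g, the pure-error standard
deviation — chosen over the residual standard deviation (1.29) so that the
generating model lies inside the fitted family and lack-of-fit p-values are
uniform, which the suite verifies by a Kolmogorov–Smirnov test over 200
simulated designs. The generator emulates homoscedastic, independent
Gaussian replicate noise around an exactly quadratic surface; it does not
emulate run-order drift, heteroscedasticity, or model bias, so passing
recovery tests demonstrate correctness of the estimation machinery, not that
real extraction data satisfy those assumptions.

## Numerical choices and degenerate inputs

* OLS via QR; a rank-deficient model matrix raises a singular-fit error
  rather than silently dropping terms.
* Designs without replicated runs omit the lack-of-fit rows with a warning.
* Min-max scaling of a constant column maps it to 0 (and back), so constant
  targets are learnable by the output bias alone.
* Hidden-size ties in `sweep_hidden()` break toward the smaller network.
* GA roulette weights are min-shifted; an all-equal-fitness population falls
  back to uniform selection. Non-finite fitness values abort with the
  offending individual.
* Predictions outside the factor box warn (the polynomial extrapolates
  there) instead of failing.

## Problem sizes used in the test suite

The suite's simulation-based checks use 200 replicate designs for parameter
recovery and the lack-of-fit calibration, 500 for the intercept
sampling-variance check, 100 for optimum recovery, 10 training restarts for
the surrogate sweeps and 20 GA seeds for convergence spread — sizes at which
the binomial/Monte-Carlo noise of each check is comfortably below its
assertion margin.

## Limitations

* The package reproduces the printed regression, ANOVA and composition
  arithmetic exactly, but stochastic stages (ANN training, GA) can only be
  checked propertywise: published epoch counts and MSEs depend on unstated
  initializations.
* The 87-point replicated set is means-based; see the correlation ceiling
  above.
* Only the 4-factor BBD is generated; central-composite and general
  k-factor designs are out of scope, as are desirability-based
  multi-response optimization, Box–Cox transforms and stepwise term
  selection.
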