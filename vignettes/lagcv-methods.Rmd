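---
title: "Cross-validation for distributed-lag time series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validation for distributed-lag time series: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcv)
```

## The problem

Daily mortality responds to environmental exposure spread over the
preceding weeks: a hot day raises deaths over the next few days, a cold
spell over the next few weeks.  The distributed-lag nonlinear model (DLNM)
captures this with a Poisson regression on a *cross-basis* -- a tensor
product of a spline in the exposure value and a spline in the lag -- and
when such data are handed to a neural network, every lagged value becomes
an input neuron.  Hyperparameters are then chosen by cross-validation, and
that is where serial data bites: randomly shuffled folds let the model
peek at the future when predicting the past, producing optimistically
biased validation errors.

This package implements and compares three fold constructions over the
training region of a chronological 70/30 split:

* **five-fold CV** -- days shuffled uniformly into five validation sets;
  the conventional baseline.
* **LOBO-CV** (leave-one-block-out) -- the training region is cut into
  five contiguous blocks; each block in turn validates a model trained on
  the other four, both earlier *and* later.  Serial structure inside each
  block is preserved while the whole region is still used.
* **TB-CV** (temporal block) -- forward chaining: the region is cut into
  six contiguous blocks, and fold *i* trains on blocks 1..*i* to validate
  on block *i*+1.  No future datum ever trains a model that predicts the
  past, at the cost of much smaller early training sets.

The CV error of a fold plan is the arithmetic mean of the per-fold
validation mean squared errors, `cv_error()`.

## The permutation ratio

CV errors alone do not say whether a model learned anything.  The
permutation ratio compares the CV error on the observed outcomes with the
CV error of the identical procedure run after shuffling the outcomes over
the training region:

$$PR = \min\!\left(1, \frac{CV_{\text{observed}}}{CV_{\text{permuted}}}\right)$$

Shuffling severs the outcome--predictor association while preserving the
outcome's marginal distribution, so the permuted CV error estimates the
error of a model that can at best predict the mean.  A ratio near 1 means
the model contributed nothing; $(1 - PR) \times 100$ is read as the
percentage of baseline prediction error the model removes -- an
R-squared-like descriptive summary, not a hypothesis test.

Only the outcome vector is permuted.  Lagged-mortality *feature* columns
are left as observed: rebuilding them from the shuffled series would also
destroy the predictors' internal serial structure and change the null
being simulated.  This is the minimal exchange that breaks the
association, and it is worth knowing when interpreting ratios on feature
sets that include outcome lags.  `n_permutations` defaults to 1 -- one
shuffled replicate per cell, matching how permuted grids are usually
tabulated -- but 20 or more gives visibly stabler ratios; replicate seeds
derive deterministically from the base seed.

## The network and its trainer

Grid cells are scored with fully connected networks of one to three
hidden layers (widths drawn from {6, 12, 24, 36, 48, 60}), logistic
hidden activation, and a single linear output neuron predicting deaths on
the raw count scale.  `count_parameters()` counts free parameters as
$\sum_\ell (\text{fan-in}_\ell + 1)\,\text{fan-out}_\ell$.

The training recipe is deliberately simple and fully deterministic given
a seed:

* **full-batch gradient descent** with classical momentum (0.9) on the
  ridge-penalized training MSE;
* a **bold-driver learning rate**: grown by 5% per improving iteration up
  to a cap of 0.03, halved when the penalized loss rises.  This makes
  training insensitive to the outcome scale without per-dataset tuning;
* **output bias initialized at the training outcome mean**, so the first
  iterations start from the constant-mean predictor rather than from zero
  deaths per day;
* Glorot-uniform weight initialization from the cell's derived seed;
* **no early stopping**: every fit spends its full iteration budget, so
  cells compete under budget parity.  The budget default is 50,000
  full-batch updates; the packaged experiments use 2,000, which the
  bold-driver schedule makes sufficient at their problem sizes.

The default weight decay of 0.3 (a quadratic penalty on weights, not
biases) is the one genuinely consequential choice.  Over-parameterized
networks trained without it memorize shuffled outcomes, which inflates
permuted CV errors far above the outcome variance and distorts the
permutation ratio's baseline.  With the penalty, a network fed pure noise
stays close to the constant-mean predictor -- its validation error tracks
the outcome variance, which is exactly the behaviour visible in published
permuted-outcome CV grids, whose errors cluster just below the outcome's
variance.  Ridge decay is also the standard regularizer of classical MLP
regression.  Set `decay = 0` in `network_spec()` for pure MSE
minimization; the unpenalized trainer drives an exactly-linear signal to
under 10% of the outcome variance within a few thousand iterations.

Continuous input columns are standardized per fold with statistics from
the fold's *training* rows only; indicator columns pass through.

## Feature construction

`build_feature_matrix()` turns a validated daily series into the input
matrix: one indicator per calendar year present, twelve month indicators,
weekday/weekend/holiday indicators (holidays from a user-supplied date
list; the three columns are kept even though they are collinear, matching
the conventional presentation), temperature lags 0..30, mortality lags
1..30 (the same-day outcome never enters), and same-day ozone and PM2.5 --
83 columns for a five-year series.  Days lacking a full lag history are
dropped rather than zero-padded, since fabricated exposure would bias the
lag structure.

A `"paper54"` profile reproduces the leaner 54-column variant sometimes
quoted for this design.  Its arithmetic only closes as 24 independent
variables -- the 20 calendar indicators plus four pollutants (O3, PM2.5,
CO, PM10) -- plus 30 temperature lags (1..30) with no mortality lags and
no same-day temperature; the profile therefore pulls in CO and PM10 when
the series carries them.

Fold plans operate on feature-matrix row indices.  Validation rows may
carry lag features computed from earlier observed days; lags are observed
predictors, not fitted values, so this is not leakage of model
information and matches how distributed-lag designs are used in practice.

## The synthetic-data generator

Because the motivating mortality series (Taipei daily all-cause deaths,
2012--2016) is IRB-restricted, the package ships a generator that
implements the DLNM generatively:

$$\log \mu_t = \alpha + s(x_t, l; \beta) + \beta_{O_3} O_{3,t}
  + \beta_{PM_{2.5}} PM_{2.5,t} + f(t; \theta), \qquad
  \text{death}_t \sim \text{Poisson}(\mu_t)$$

* **Cross-basis** $s(x_t, l; \beta)$: quadratic B-spline in temperature
  with internal knots at the 10th/75th/90th percentiles (5 columns, no
  intercept) crossed with a natural cubic spline in lag 0..30 with 5
  degrees of freedom -- three internal knots equally spaced on the
  log-lag scale between lag 1 and lag 30, intercept included.  Row $t$
  holds $\sum_{k=0}^{30} B_x(x_{t-k}) \otimes B_l(k)$, so 25 coefficients
  encode the whole lag--temperature surface.  The construction is checked
  against a brute-force double sum in the tests.
* **Seasonal spline** $f(t;\theta)$: one natural cubic spline over the
  sequential day index with 8 df per year of span (40 columns for five
  years), boundary knots at the series ends.  "Per year" is resolved as
  one spline for the whole period with total df proportional to span,
  rather than separate per-year pieces.
* **Environment**: temperature is an annual sinusoid (mean 23.6 degC,
  amplitude 6.5, peak at day-of-year 205) plus an AR(1) anomaly
  (coefficient 0.8, innovation SD 1.6); ozone (base 28 ppb) couples
  positively and PM2.5 (base 20.5 ug/m3) negatively to the temperature
  anomaly, both truncated at zero.  These defaults steer the simulated
  moments toward the descriptive statistics of the motivating data
  (about 60 deaths/day, temperature SD about 5.5) -- targets, not
  assertions.
* **Coefficients**: $\exp(\alpha) = 60$; the default $\beta$ encodes a
  U-shaped cumulative temperature response (cold and heat excess, heat
  concentrated at short lags) of modest size (about $\pm 0.05$ on the
  log scale); $\theta$ is the least-squares projection of a
  winter-peaking annual cosine (amplitude 0.06) onto the seasonal basis,
  so the generative seasonal term lies exactly in the space an analyst
  would fit.  Cross-basis and seasonal columns are mean-centered over
  valid days, making $\alpha$ the marginal log baseline.

The first `max_lag` days have covariates but no deaths (their lag history
is incomplete); `burn_in = TRUE` simulates a lead-in internally and
returns fully observed days.

What the generator does *not* emulate: day-of-week mortality structure,
holiday effects, influenza epidemics and other outcome autocorrelation
beyond what temperature and season induce, pollutant lag effects, and
measurement error in exposures.  Tests passing on this generator show the
machinery is correct under the stated model, not that any scheme is
superior on real data.

`recovery_study()` closes the loop: simulate, refit the correctly
specified Poisson regression on the true design, and count 95% Wald
interval coverage of $\alpha$, $\beta_{O_3}$, $\beta_{PM_{2.5}}$.  At the
study scale (1,818 days, 100 replicates) coverage sits at the nominal
95% within Monte-Carlo error.

## Reference grids and summary arithmetic

The published two- and three-layer CV-error grids of the motivating
analysis, their permuted counterparts, and the published PR table ship as
transcribed CSVs under `inst/extdata/` (`ref_grid()`, `ref_pr_grid()`).
They are *inputs* to the summary arithmetic -- `best_cell()`,
`row_average()`, `grand_average()`, `winner_counts()`, `pr_table()` --
not outputs the pipeline regenerates, which would require the restricted
data.  Recomputed ratios agree with the published PR table in all 108
cells at its 3-decimal precision.

Two quirks of the source tables, preserved verbatim and worth knowing:

* the running text quotes two-layer grid minima of 61.192 (five-fold, at
  (60,12)) and 54.442 (LOBO, at (24,60)), but the printed grids contain
  smaller cells -- 60.954 and 53.66, both at (36,24).  `best_cell()` does
  honest arithmetic and returns the tabulated minima; the text-quoted
  cells are present with their printed values.
* the three-layer table's first column is headed (12,12,12) where the
  accompanying methods text says (6,6,6); the fixture stores the printed
  label, and all arithmetic is label-agnostic.

Table rendering rounds half away from zero (3 decimals for errors and
ratios, 2 for averages), matching the printed tables; full precision is
kept internally.

## Numerical and design choices

* Indices are 1-based throughout, following R convention.
* The chronological split takes the first `floor(n x 0.70)` rows; any
  rounding convention is defensible, `floor` is reproducible.
* Contiguous blocks that do not divide evenly give their remainder to the
  earlier blocks, deterministically.
* TB-CV uses k+1 blocks so that exactly k validation errors exist and
  the CV error is still "the average of five validation errors" at
  k = 5; a `drop_first` mode (k blocks, k-1 folds) is available but not
  the default.
* Five-fold CV shuffles individual days, the reading most consistent
  with "randomly selected" fold membership; block-shuffling variants
  belong to the other two schemes.
* `best_cell()` breaks exact ties by first occurrence in row-major order
  and says so; published grids report unique minima, so this only
  matters off-grid.
* Every stochastic component takes an explicit integer seed; cell seeds
  and replicate seeds derive linearly from the base seed modulo
  2^31 - 1, so any cell is reproducible in isolation.
* Run configuration lives in `run_config()` and CLI flags; a structured
  configuration file format was considered and dropped as surface
  without users.

## Problem sizes in the packaged experiments

The test suite and `scripts/acceptance.R` run entirely on simulated or
packaged data: parameter recovery uses 100 replicates of 1,818 days; the
strong-signal permutation-ratio experiment uses 1,230 days (840 training
rows), a (12,12) network, and a 2,000-iteration budget; the smoke grid
runs {(6,6), (12,12)} under all three schemes on 400 days at the same
budget.  These sizes are the package's own choices: large enough for the
qualitative behaviour to be stable across seeds, small enough that the
whole suite runs in about a minute.

## Known limitations

* The trainer is plain full-batch gradient descent; it is meant for
  scoring small grids reproducibly, not for state-of-the-art predictive
  accuracy.  No stochastic mini-batching, no adaptive per-weight rates.
* PR is descriptive.  With `n_permutations = 1` its permuted denominator
  carries one replicate's noise; treat 3-decimal differences between
  cells accordingly.
* The generator's pollutants act same-day only; distributed pollutant
  lags are out of scope.
* Holiday effects require a user-supplied holiday list; no national
  calendar is bundled.
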