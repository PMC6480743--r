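---
title: "Modeling intraindividual reaction-time variability with two-level AR(1) DSEMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intraindividual reaction-time variability with two-level AR(1) DSEMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its model, its synthetic
data, and the numerical and design choices a maintainer would want to
know about. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The model and its assumptions

Each person's log reaction times within a 117-trial Go/NoGo block are a
time series. After preprocessing (Section 3), the series is decomposed as

$$RT_{it} = \mu_i + x_{it}, \qquad
  x_{it} = \phi_i\, x_{i,t-1} + \zeta_{it}, \qquad
  \zeta_{it} \sim N(0, \sigma^2_\zeta),$$

with person-specific mean $\mu_i$ and lag-1 autoregression $\phi_i$, and
a common innovation variance. At level 2, the triple
$(\mu_i, \phi_i, iSD_i)$ — where $iSD_i$ is the *observed*
intraindividual SD of the person's log RTs — is jointly multivariate
normal with free covariance matrix, so the amplitude and the temporal
structure of fluctuations may correlate with each other and with mean
speed. Error counts (commission errors per block; prospective omissions
in the prospective block) are continuous-Gaussian level-2 outcomes
regressed on the triple; the two-block models add cross-block paths
(later-block triple on earlier-block triple, later commission count on
the earlier one, omissions on the within-block triple and commission
count) and optionally a working-memory covariate on all three counts.

Assumptions worth making explicit:

* **Person-level stationarity** ($|\phi_i| < 1$) is implicit in the
  normal random-effect specification; the sampler leaves $\phi_i$
  unconstrained and divergent persons would surface in the diagnostics.
* **A common innovation variance** across persons. Together with
  person-varying $\phi_i$, this implies the model's own stationary SD per
  person is $\sigma_\zeta/\sqrt{1-\phi_i^2}$; the observed $iSD_i$ is a
  separate variable correlated with the random effects, not a deterministic
  function of them. Section 2 discusses the consequences.
* **Counts as Gaussian outcomes.** Error counts (0–13) enter linearly
  with Gaussian residuals; no logit/count likelihood is fitted.
* **Missingness at random given the design.** Correct NoGo trials,
  incorrect responses, and trimmed outliers are missing; they remain on
  the time axis as latent states (data augmentation), so AR pairs never
  form across compressed gaps.

## 2. What the generator emulates — and what it does not

`assemble_dataset()` reproduces the study design: 87–100 persons, two
task versions times two blocks of 117 trials (104/13/0 and 91/13/13
Go/NoGo/Prospective), digits 1–9 appearing 13 times per block, digit 3 as
the NoGo stimulus, blue reserved for the prospective cue, and
pseudo-randomized orders with no adjacent special trials. Reaction times
are lognormal AR(1): generated on the log scale with person triples drawn
from the calibrated per-block populations in `default_population()`
(fixed effects and random-effect variances from the published
single-block estimates; iSD variance set to 0.001 because the published
value prints as 0.00 with an upper interval of 0.01, and a strictly
positive value is needed for the phi–iSD correlation of 0.65 to exist).
Error counts follow the level-2 linear model with Gaussian residuals,
rounded to the nearest integer and clipped to [0, 13]; raw regression
weights are backed out of the published standardized weights, block error
means/SDs, and between-level R².

The generator parameterizes a person's fluctuation amplitude as the
stationary SD of their own AR(1) process, with innovation SD
$iSD_i\sqrt{1-\phi_i^2}$. This makes the observed iSD consistent with
the generating `gamma_isd`, but it deliberately differs from the fitted
model's common-innovation-variance assumption: the generated world has
person-specific innovation variances. The practical consequence,
measured during development and visible in any refit of generated data,
is that the fitted model weights persons by the wrong likelihood
precision, which compresses the estimated variance of $\phi$ somewhat
and inflates the phi–iSD correlation, while leaving the fixed effects
essentially unbiased. Fixed-effect recovery is what the acceptance
criteria test; variance-component and correlation point estimates on
generated data should be read with this mismatch in mind.

Other simplifications: prospective-trial RTs behave like Go RTs (a
configurable offset exists but defaults to 0); error counts are decoupled
from the realized RT series (errors are assigned to randomly chosen
NoGo/prospective trials, not to fast trials); stray Go errors default to
a rate of 0; stimulus timing, masks, practice blocks, and feedback are
out of scope. A green test therefore establishes that the estimation
machinery recovers the stated generative structure — not that the
generator reproduces every feature of real RT data (real trim fractions,
for instance, run around 1–2% because real RT tails are heavier than
lognormal-with-3SD-trimming implies).

## 3. Preprocessing and stationarity screening

The pipeline order is fixed and part of the contract: drop the first
trial of each block (consistently inflated RT), trim raw RTs of correct
trials outside mean ± 3 SD (single pass, per person per block), then log
transform, then compute iSD over the observed values. Trimming before
the log transform follows the order in which the source procedure states
the steps; permuting trim and log selects different trials. On Gaussian
raw-scale blocks of 116 trials the single-pass rule trims about 0.21% of
values — slightly below the asymptotic 2(1 − Φ(3)) ≈ 0.27% because the
mean and SD are estimated from the same 116 values (masking); the
acceptance band (±0.15 percentage points around 0.27%) was fixed before
measurement. On lognormal raw RTs the same rule trims more (≈0.4–0.8%),
since the rule operates on the skewed raw scale.

Each person × block series is then classified by augmented Dickey-Fuller
tests in a sequential three-specification scheme (trend, constant, none;
α = 0.05, AIC lag selection over the Schwert bound, MacKinnon
response-surface critical values). Missing values are handled
conservatively: a regression row is used only if every lag it needs is
observed. Persons with any series stationary around *zero* — an
impossible mean for reaction times, indicating corrupt series — are
excluded; trend verdicts flag the series for OLS detrending. The exact
ADF variant, lag rule, and α of the original analysis are unstated; the
package records its own configuration in the verdict output rather than
guessing, and its statistics were verified against an independent
reference implementation (frozen in the test suite).

## 4. Estimation: blocked Gibbs with data augmentation

Each sweep: (a) impute latent deviations at missing trials from their
AR(1) full conditionals (stationary prior at the series head); (b) draw
every $\mu_i$ and then every $\phi_i$ from normal full conditionals
combining the AR likelihood (conditional on the first trial), the
level-2 conditional prior, and any regression where the latent is a
predictor; (c) draw the innovation variance (inverse-gamma); (d) draw
the level-2 mean and covariance (normal / inverse-Wishart); (e) draw
regression coefficients and residual variances (normal /
inverse-gamma). Initial values are deterministic given the data (person
means, lag-1 autocorrelations, method-of-moments variances), so runs are
byte-reproducible under a seed. Default settings follow the reported
estimation protocol (two chains, 50,000 iterations, thinning 10, i.e.
5,000 retained per chain; tests and the acceptance script scale this
down and say so inline). Convergence is summarized by a potential scale
reduction statistic computed as $\sqrt{(W + B/n)/W}$, a conservative
variant that equals 1 exactly for identical chains; parameters above 1.1
are flagged.

### Priors: where the package deviates from "everything vague"

Location priors for fixed effects are the conventional vague
$N(0, 10^{10})$ and the innovation variance keeps inverse-gamma(0.001,
0.001). Two deliberate deviations:

* **Level-2 covariance matrices** use inverse-Wishart with $d+2$ degrees
  of freedom and a *data-scale diagonal* scale matrix (the sample
  variances of the initial person-parameter estimates, worth roughly one
  pseudo-observation). An identity scale — the textbook "vague" choice —
  is catastrophically informative here: random-effect variances are of
  order 0.001–0.02, so identity-scale mass inflates every variance by
  roughly $1/N$ ≈ 0.01, an order of magnitude.
* **Level-2 regressions of counts on latent random effects** use weakly
  informative, data-scaled priors: coefficients
  $N(0, (1.5\,\mathrm{sd}(y)/\mathrm{sd}(x_j))^2)$ and residual
  variances IG(2, var(y)). Fully vague priors make this model class
  bimodal: because $\phi_i$ is weakly determined per person (likelihood
  SD ≈ 0.1 from 116 trials), the chain can drift onto a ridge where the
  latent field bends to fit the counts exactly — residual variance
  collapsing toward zero, coefficients growing without bound, and R²
  approaching 1. A milder symptom persists even away from the ridge: a
  prior-wide coefficient contributes spurious precision
  $\beta^2/\sigma^2_e$ to every person's latent conditional, compressing
  the random-effect variance and narrowing the fixed-effect intervals.
  The 1.5 scale on standardized weights (about twice the largest
  standardized error-regression weight the calibrated world produces)
  removes both symptoms while remaining diffuse on the scale where real
  effects live. Both deviations are reported here as the package's own
  design choices; sensitivity to them is visible by editing the
  constants at the head of `R/dsem-gibbs.R`.

### Numerical choices, tie-breaks, degenerate inputs

* Trial-sequence generation is rejection sampling of uniform
  permutations (capped at 10,000 attempts; acceptance ≈ 0.23 classical,
  ≈ 0.06 prospective), giving near-uniform admissible orders.
* $\phi$ draws outside $(-1, 1)$ in the *generator* are rejected and
  redrawn (count recorded); the *sampler* leaves $\phi_i$ unconstrained.
* iSD draws are floored at $10^{-3}$; series with fewer than 2 observed
  values are flagged, not processed; constant series trim nothing
  (SD = 0 edge) and classify deterministically.
* The quantile convention is R's default (type 7) everywhere;
  significance means the central 95% interval excludes 0.
* Wilcoxon signed-rank tests use Pratt zero handling (zeros ranked,
  dropped from the sum) with tie and continuity corrections —
  conservative for count data with many zero differences — and p-values
  are multiplied by the number of tests (capped at 1); the multiplier
  defaults to the number of contrasts actually computed in a run, since
  the original family of contrasts is unstated.
* The half-block split (`split_block()`) defaults to an even 58/58 cut
  of the 116-trial analyzed axis. The published appendix describes
  trials "1–58 and 59–107", which does not sum to the analyzed length;
  the even split is used and the discrepancy documented rather than
  reproduced.
* Where the source's text and table disagree on a value (a mean log RT
  printed as 6.36 in text but 6.33 in the table, with the table value's
  exponential matching the printed milliseconds), the table is treated
  as authoritative in the calibrated defaults.
* Standardization reports the package's own convention — per-draw
  correlations from covariances, and regression weights multiplied by
  sd(predictor)/sd(outcome) with latent SDs taken from the current draw
  and observed SDs from the data — alongside raw estimates, since the
  original software's exact within-level convention is not knowable.

## 5. Known limitations

* Variance components and correlations refit from generated data carry
  the common-innovation-variance mismatch described in Section 2;
  magnitudes of count-regression weights can also inflate when latents
  partially absorb count noise. Signs and fixed effects are robust (and
  tested); point magnitudes of second-moment parameters are not precise.
* The sampler is single-site for the latent field; long runs of
  consecutive missing trials mix slowly (irrelevant at the design's
  13/117 missingness).
* DIC or other model-comparison criteria are not computed, higher-order
  lags are not supported, and innovation variances are homogeneous by
  design — all declared non-goals.
* Real-data posterior tables from the source study are not reproducible
  without the study data; nothing in the package claims to reproduce
  them beyond printed-arithmetic identities and simulation-based
  recovery of generating values.
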