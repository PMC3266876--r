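---
title: "Gamete-flow kinetics of C. elegans reproduction under chronic heat stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamete-flow kinetics of C. elegans reproduction under chronic heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormrepro)
```

## The model

A self-fertile *C. elegans* hermaphrodite makes a finite cache of
sperm (about 300 in the wild-type) before switching irreversibly to
oocyte production, so the sperm cache caps the self-brood. wormrepro
treats the reproductive system as a pipeline of compartments — gonad,
spermatheca, uterus — through which gametes flow under mass-action
kinetics, with every gamete explicitly accounted for.

The state of one animal is the developed-oocyte pool $O$, the active
sperm $S_a$, the cumulative eggs laid $E$, and the bookkeeping sinks
$S_d$ (dead sperm) and, in one model variant, $O_d$ (dead oocytes).
The full model is

$$
\frac{dO}{dt} = k_g - k_s O - k_o O S_a, \qquad
\frac{dS_a}{dt} = -k_o O S_a - k_d S_a, \qquad
\frac{dE}{dt} = k_o O S_a .
$$

Oocytes are generated at a constant rate $k_g$, relaxed towards the
gonad carrying capacity $k_g/k_s$; ovulation and fertilization are
mass action in oocytes and sperm ($k_o O S_a$), because the
sperm-released signal MSP couples oocyte maturation and ovulation to
sperm presence and each ovulated oocyte consumes one sperm; chronic
heat kills sperm at rate $k_d S_a$. Gamete conservation,
$E + S_a + S_d = S_0$, holds identically, so the terminal brood can
never exceed the sperm cache and equals it exactly when $k_d = 0$.

Because the oocyte pool relaxes much faster than sperm deplete, it is
held at its steady state
$O^\* = k_g / (k_s + k_o S_a)$, giving the quasi-steady-state (QSS)
egg-laying rate

$$
\frac{dE}{dt} = \frac{k^{\max} S_a}{\hat{k} + S_a},
\qquad k^{\max} = k_g,\; \hat{k} = k_s / k_o,
$$

a two-state model in $(S_a, E)$. The sperm equation is separable, and
its implicit closed-form solution (`mean_field_solution()`) serves as
an independent oracle for the numerical integrator throughout the
test suite; the terminal brood has the closed form
$E_\infty = (k^{\max}/k_d)\,\log\!\big(1 + k_d S_0 / (k^{\max} + k_d
\hat{k})\big)$ (`brood_total()`).

An alternative variant adds explicit oocyte death at rate $k_{do} O$.
Its oocyte balance is the parsimonious model with $k_s$ replaced by
$k_s + k_{do}$, so the two are observationally equivalent in eggs and
sperm (`with_oocyte_death()` performs the remapping); the package
keeps the parsimonious form.

### A note on the generation term

The saturating generation term is implemented as the linear
relaxation $k_g - k_s O$. This is the minimal mass-action-consistent
form in which $k_s$ is a carrying-capacity constant, and it is the
unique choice that makes the QSS rate exactly Michaelis–Menten with a
constant $k^{\max}$ and a constant half-saturation $\hat{k}$.

## Temperature laws

Over the narrow physiological range (20–30 °C) each
temperature-sensitive quantity follows a log-linear law
$\theta(T) = e^{a + bT}$: the capacity $k^{\max}$, the sperm death
rate $k_d$, and the non-robust fraction $\delta$ (clipped at 1);
$\hat{k}$ is held fixed at 100 sperm. In the QSS parameterization the
law on $k^{\max}$ is equivalent to a law on $k_o$ at fixed $k_g$.

`default_temperature_law()` is the package's calibration of the
simulator's generating conditions, chosen once from the published
phenomenology and not revisited: $k^{\max}$ = 7.5 eggs/h at 20 °C
rising to ~11 at 29 °C; $k_d$ = 1e-4 /h at 20 °C (negligible — a full
brood loses less than one egg), 0.02 at 25 °C, ~1.4 at 29 °C; and
$\delta$ anchored at 0.25 (28 °C) and 0.6 (29 °C), which leaves it
genuinely negligible (≤ 0.02) at and below 25 °C while clipping to 1
at 30 °C. These values give mean broods of roughly 300, 200, 27, 10
and < 5 eggs at 20, 25, 28, 29 and 30 °C — a full brood at the
cultivation temperature, a strong reduction at 28 °C, and effectively
complete cessation at 30 °C. The $\delta$ law is a smooth exponential
rather than a hard zero below 28 °C, since a hard zero could not be
log-linear.

## The population model and observation protocol

Between-animal heterogeneity has three ingredients
(`population_params()`):

* **A shared latent draw.** One standard-normal $z$ per animal sets
  both its sperm cache $S_0 = \mathrm{round}(\mu_S + \sigma_S z)$ and
  its onset delay $t_0 = \max(0, \mu_{t_0} + \sigma_{t_0} z)$ — both
  are consequences of how long the germline keeps producing sperm
  before the oogenesis switch, so a large cache goes with a late
  onset. Defaults: $\mu_S = 300$, $\sigma_S = 45$ (brood CoV ≈ 15 %
  at 20 °C), $\mu_{t_0} = 4$ h, $\sigma_{t_0} = 1.5$ h.
* **Capacity variation.** $k^{\max}_i \sim N(\mu_{k^{\max}},
  \sigma_{k^{\max}})$, truncated at zero, with
  $\sigma_{k^{\max}} = 0.75$ eggs/h by default. When a cohort is
  simulated at a temperature, $\mu_{k^{\max}}$ is the law's
  $k^{\max}(T)$.
* **The robust/non-robust dichotomy.** Independently of $z$, each
  animal is non-robust with probability $\delta(T)$; non-robust
  animals draw their capacity around a reduced mean
  ($0.25\,\mu_{k^{\max}}$ by default). This produces the
  two-component brood-size mixtures seen at stressful temperatures
  while broods at 20–25 °C stay normal.

Counts carry no noise beyond rounding — egg counting is exact in this
assay; all variability is biological plus protocol structure.

The observation protocol (`observation_protocol()`) mirrors the
study design: destructive cross-sectional scoring every 2 h for the
first 12 h (fresh animals at every time point, so these records carry
no individual linkage) and longitudinal transfers counted every 12 h
until egg-laying ceases (240 h by default, long enough for a 20 °C
brood to complete). `brood_sizes()` accepts a longitudinal animal as
ceased when its last two counts agree and excludes the rest with a
warning.

## Likelihood and fitting

The observation model for `fit_mle()` is Gaussian with
heterogeneity-derived moments: at each time the mean and variance of
the cumulative count are computed by Gauss–Hermite quadrature over
the shared latent $z$ (5 nodes) and the capacity draw (5 nodes),
mixed over the two classes with weight $\delta$. Cross-sectional
records enter as independent draws of the count at their time;
longitudinal records contribute their first count plus increments
between consecutive counts, treated as independent between intervals
(a composite-likelihood simplification — within-animal increments
share the latent draw, so the variance weighting is approximate but
the means are exact). A variance floor of 1/3 egg² absorbs count
rounding and keeps the likelihood finite in the zero-heterogeneity
limit. Free parameters — $\mu_{k^{\max}}$, $k_d$ and (at ≥ 28 °C)
$\delta$ — are optimized by Nelder–Mead on smooth log/logit-bounded
transforms from multiple starts (one deterministic, the rest seeded
random); $\delta$ is fixed at zero at permissive temperatures, where
it is indistinguishable from zero. The sperm hyper-parameters are not
fit from time courses: at 20 °C sperm death is negligible, so each
brood equals its animal's cache and `infer_sperm_from_brood()` reads
$(\mu_S, \sigma_S)$ off the permissive-temperature brood
distribution — the same reasoning that converts the printed mutant
brood summaries (437 ± 40 for *tra-3*, 238 ± 115 for *cdc-48.1*) into
sperm caches for mutant predictions.

`fit_temperature_law()` then puts least-squares lines through
$(T, \log \theta)$. Estimates that are non-positive or pinned to an
optimization bound are excluded with a warning: a parameter at its
box edge carries no information (the prime example is $k_d$ at 20 °C,
whose entire effect on a brood is under one egg). $\delta$'s law is
anchored on the temperatures where it is nonzero.

### Identifiability

Two facts about this design are worth knowing and are verified by the
test suite. First, $k_d$ is unidentifiable at 20 °C (above). Second,
at 29 °C egg-laying finishes within ~6 h of onset — on the same scale
as the onset-delay spread — so $(k^{\max}, k_d)$ are only jointly
identified along a likelihood ridge: very fast kinetics with matched
terminal brood fit almost equally well. The ridge-invariant
quantities are recovered reliably (the class fraction $\delta$, the
robust-class terminal brood, and law-implied held-out predictions);
the individual rate constants at 29 °C are not, and the package makes
no claim that they are. This mirrors the familiar "sloppy model"
situation: predictions are far better determined than parameters.

## Brood-size statistics

* `coef_variation()` — sample s.d. over mean, the scale-free
  variability measure; with $k_d \approx 0$ broods equal caches, so
  cohorts differing only in capacity share the same CoV.
* `permutation_test_cov()` — two-sided test of
  $d = |\mathrm{CoV}_A - \mathrm{CoV}_B|$ by pooled relabeling
  (default 10⁶ resamples, computed in bounded-memory chunks), with
  the $+1$ small-sample correction. Two-sided because no direction is
  privileged a priori.
* `ks_normality_test()` — Kolmogorov–Smirnov distance to a normal
  with estimated parameters, calibrated by parametric bootstrap
  (Lilliefors-style), since the naive test with estimated parameters
  is anti-conservative.
* `fit_brood_mixture()` — EM for normal+normal (two reproductive
  strategies) or normal+exponential (waiting time to a failure
  event), with 10 restarts including one at the single-normal
  solution, which guarantees the nesting inequality. The family
  choice is reported, not auto-decided — the data cannot distinguish
  the two interpretations. Degenerate EM runs (vanishing weight or
  collapsing component s.d.) are discarded and restarted; if all runs
  degenerate the single normal is reported. Model *order* (one vs two
  components) is judged by BIC: the unequal-variance mixture
  likelihood is unbounded, and spurious near-degenerate components
  routinely beat the AIC penalty on single-component data (measured:
  AIC prefers a spurious second component on ~40 % of normal
  samples at n = 200, BIC on ~1 %). AIC is still reported.

## Numerical choices

* Integration: `deSolve::lsoda`, rtol = atol = 1e-8, with the sperm
  state clamped at zero inside the right-hand side. Equivalence
  checks between model variants are asserted at 1e-5 eggs, the
  achievable agreement at these tolerances on counts of order 300.
* Cessation: the QSS horizon doubles until the egg-laying rate falls
  below 1e-9 eggs/h.
* Whole cohorts are integrated as one stacked ODE system on the union
  of shifted observation grids, which keeps likelihood evaluations at
  a single solver call.
* The closed-form sperm trajectory is solved by bracketed root
  finding (`uniroot`, tolerance 1e-13·S₀) on the separable implicit
  relation.
* Quadrature: 5×5 Gauss–Hermite nodes; degenerate dimensions
  (zero sigmas) collapse to single nodes automatically.

## What the simulator does and does not emulate

The generator reproduces the study's statistical structure: the
destructive/longitudinal protocol, coupled cache/onset heterogeneity,
capacity variation, the temperature-dependent class dichotomy, exact
integer counts, and per-animal conservation. It does not emulate
egg-retention/bagging at high production rates (the known failure
mode of sperm-limited prediction for *tra-3* at 25 °C), laying of
unfertilized oocytes after sperm exhaustion, oocyte-quality
senescence beyond sperm depletion, or within-day bursts of egg-laying
(minutes-scale, far below the 2 h counting grid). Passing tests
therefore validate the inference machinery against this structure,
not against those unmodelled phenomena.

## Problem sizes used by the tests

The suite fits cohorts of 78 animals at 20 and 25 °C and ~300 at
29 °C (the stressful-temperature fit needs the larger design, as in
the original study's sample sizes), runs 100-replicate calibration
loops for the normality and mixture checks, and 1000 replicates of
1000 resamples for the permutation-test calibration; the end-to-end
pipeline in the tests uses reduced cohort sizes. These sizes were
chosen to keep the estimator properties measurable while the full
suite completes in minutes.
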