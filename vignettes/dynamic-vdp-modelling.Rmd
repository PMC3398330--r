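---
title: "Dynamic van der Pol modelling of circadian temperature rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic van der Pol modelling of circadian temperature rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdprhythm)
```

## The scientific problem

In the ovariectomized (OVX) rat model of menopausal thermoregulatory
dysfunction, estrogen deprivation flattens the circadian oscillation of
tail skin temperature; an effective treatment restores it. Telemetry
yields long, noisy series (one record every 3 minutes, phases of 6-10
days), and the scientifically interesting quantity is not the mean
temperature but the *amplitude dynamics*: how large the circadian
oscillation is at the start of a phase, how fast it adapts under a
treatment, and at what level it settles. `vdprhythm` models these
dynamics explicitly and turns the fitted amplitudes into group-level
treatment-effect statistics.

## The observation model

An observed series in one phase is

$$ y_n = x(n\Delta t) + c(n\Delta t) + e_n, $$

with sampling interval $\Delta t = 3$ min, a linear baseline trend
$c(t) = c_0 + c_1 t$, and independent normal errors $e_n$ whose variance
depends on the time of day (three regimes: 06:00-12:00 with husbandry and
treatment disturbances, a quiet 12:00-18:00 afternoon, and an active
18:00-06:00 night). The circadian component $x(t)$ is the second-order
perturbation solution of the van der Pol oscillator

$$ \ddot x + \varepsilon\omega\left(\frac{4x^2}{\gamma^2} - 1\right)\dot x
   + \omega^2 x = 0, \qquad \omega = 2\pi/\tau, $$

namely

$$ x(t) = a(t)\cos(\omega t + \psi)
   - \frac{\varepsilon\, a(t)^3}{8\gamma^2}\sin(3\omega t + 3\psi), $$

with the closed-form dynamic amplitude

$$ a(t) = \left[\frac{1}{4k}e^{-\varepsilon\omega t}
   + \frac{1}{\gamma^2}\right]^{-1/2},
   \qquad \frac{1}{4k} = \frac{1}{a_0^2} - \frac{1}{\gamma^2}. $$

$a(t)$ interpolates monotonically from the start amplitude $a_0$ towards
the limit-cycle amplitude $\gamma$ at a pace set by the flexibility
$\varepsilon$; $a_0 = \gamma$ (infinite $k$, handled as a sentinel)
yields a constant amplitude. The leading cosine carries the *dynamic*
amplitude $a(t)$, consistent with the cubed $a(t)$ in the harmonic
correction; the literal constant-amplitude reading is available via
`circadian_component(..., dynamic_amplitude = FALSE)` but is not the
default. The order-$\varepsilon^2$ remainder is dropped. Validity of this
approximation is checked against a fixed-step Runge-Kutta integration of
the exact equation (`integrate_vdp_ode()`, step 0.02 h): over 10 periods
the sup-norm gap shrinks about fourfold when $\varepsilon$ is halved, the
expected second-order behaviour, and stays useful for
$\varepsilon \le 1$ — which is why fitting constrains $\varepsilon$ to
$[0.2, 1]$.

## Parameters and their meaning

| Parameter | Unit | Meaning | Constraint in fitting |
|---|---|---|---|
| $a_0$ | °C | amplitude at phase start | $[0.05,\ \mathrm{span}_1/2]$ |
| $\gamma$ | °C | limit-cycle amplitude (endpoint of interest) | $[0.05,\ \mathrm{span}_L/2]$ |
| $\varepsilon$ | — | adaptation speed / anharmonicity | $[0.2, 1]$ |
| $\psi$ | rad | phase shift | $[-\pi, \pi]$ |
| $\tau$ | h | circadian period | fixed at 24 |
| $c_0, c_1$ | °C, °C/h | baseline and trend | least squares, then fixed |
| $\sigma^2_{d1}, \sigma^2_{d2}, \sigma^2_{n}$ | °C² | regime noise variances | profiled from residuals |

$\mathrm{span}_1$ and $\mathrm{span}_L$ are the ranges of raw
temperatures over the first and last day of the phase: half of a day's
span is a natural ceiling for an amplitude. The $\varepsilon$ lower bound
of 0.2 exists because an unbounded fit can inflate $\gamma$ arbitrarily
while sending $\varepsilon \to 0$; the upper bound of 1 keeps the
perturbation solution close to the exact oscillator. The period is fixed
at 24 h because the animals are entrained to a strict 12:12 light-dark
cycle.

## Pseudo-maximum-likelihood fitting

`fit_phase()` maximises the diagonal multivariate-normal likelihood in
stages rather than jointly over all 10 parameters:

1. $c_0, c_1$ by ordinary least squares on the phase, then fixed;
2. $\tau$ fixed at 24 h;
3. $(a_0, \gamma, \varepsilon, \psi)$ by L-BFGS-B inside the boxes above,
   where **at every objective evaluation** the three regime variances are
   replaced by the mean squared residuals of the current fit (profile
   likelihood, the strictest reading of re-profiling "at each step"; an
   alternate outer-loop mode that re-profiles once per optimisation round
   is available via `fit_config(profile_every_eval = FALSE)` and agrees
   closely in practice).

Starting values: a one-day harmonic regression
$A_1\cos\omega t + A_2\sin\omega t$ on the detrended first day gives
$a_0^{(0)} = \sqrt{A_1^2+A_2^2}$ and $\psi^{(0)} = -\mathrm{atan2}(A_2,
A_1)$; the same regression on the last day seeds $\gamma$. In the first
experimental phase the start amplitude is instead initialised at 0.5 °C,
because post-surgical artifacts make the first day unreliable.
$\varepsilon$ starts at 0.5, the box midpoint (the procedure is
empirically insensitive to perturbed initial values on smooth synthetic
data). Harmonic initialisation is applied to *detrended* data since the
trend is already fixed at that point; variances are profiled with the
maximum-likelihood divisor $n$ (at $n \approx 2880$ the $n$ vs $n-1$
distinction is negligible) and floored at $10^{-6}$ °C². Convergence uses
a relative-objective tolerance of $10^{-8}$ with at most 500 iterations;
a non-converged fit is flagged and the best iterate returned, and the
returned objective is never worse than at the starting values. AIC is
reported with $p = 9$ free parameters (four optimised, two trend, three
variances; $\tau$ fixed) — `aic(fit, p = 10)` counts the period too.

## The synthetic-data generator

`default_scenario()` + `simulate_study()` emulate the OVX experiment: 20
animals in two groups of 10, phases P1 (estrogen reference, 6 d), P2
(vehicle washout, 6 d), P3 (treatment, 10 d), 480 samples/day, recording
starting at 06:00. Per-animal truths are independent normal draws around
group-by-phase central values typical of fitted animals (reference-group
$\gamma$: 3.97 → 1.58 → 2.70 °C across phases; test group 3.55 → 1.61 →
3.29 °C; baselines ≈ 30 °C; regime variances ≈ 3.5-15 °C²), with the
between-animal spreads used as standard deviations — the conservative
reading of a "mean ± spread" table that does not say whether the spread
is an SD or an SEM. Draws are clipped to valid ranges. Published slopes
of order $10^{-4}$ are read as °C per 3-minute sample and converted to
°C/hour.

The generator samples noise from the fitted-model form (perturbation
solution + regime-wise normal errors), *not* from the raw differential
equation: the likelihood being fitted is defined on the perturbation
solution, so this is the matching data-generating process. The exact-ODE
integrator exists purely as a validation oracle. Real telemetry features
the simulator does **not** reproduce: husbandry/injection artifacts as
structured transients (represented only through the inflated morning
variance), short-term autocorrelation from vasodilatation episodes
(errors here are independent; real residuals show short-range
dependence), ambient-temperature excursions, and missing records.
Passing tests therefore demonstrate correctness of the estimator under
its own assumptions, not robustness to every artifact of real data.

## Group-level inference

The endpoint is the limit-cycle amplitude $\gamma$ per animal and phase.
Two analyses mirror the study logic:

* **Amplitude restoration.** Within-animal differences
  $\hat\gamma_{P2} - \hat\gamma_{P3}$ per group; `bootstrap_mean_ci()`
  resamples the 10 animals (B = 1000) and reports the one-sided 95%
  percentile interval $(-\infty, q_{0.95}]$ of the bootstrap means.
  Restoration is established when the interval lies below zero.
* **Similar recovery between compounds.** Reconstruction ratios
  $Q = \hat\gamma_{P3}/\hat\gamma_{P1}$ per animal;
  `ratio_noninferiority_test()` tests
  $H_0: \theta_\mathrm{ref} - \theta_\mathrm{test} \ge 0.2$ against
  $H_1: < 0.2$ on the difference of group medians, resampling each group
  independently (B = 1000, $\alpha = 0.05$), with p-value
  $P^*(d^* \ge 0.2)$. $H_0$ is rejected when the one-sided 95% upper
  percentile bound of the bootstrap differences falls below the margin.

Conventions chosen where the method family leaves room: the statistic is
the difference of group medians (not the median of cross-pair
differences); intervals are plain percentile (not BCa); ties in medians
use the standard midpoint definition; p-value and CI decisions agree
under this convention in ≈99% of simulated cases (exact agreement is not
guaranteed by percentile bootstrap). Two calibration caveats, both
verified by simulation in the test suite: (1) the one-sided percentile
interval for a mean of n = 10 values is slightly anti-conservative —
true coverage ≈ 92.5% rather than 95%, the classical normal-vs-$t_9$
gap inherent to the percentile method at this sample size; (2) at the
$H_0$ boundary the non-inferiority test's rejection rate stays below
$\alpha$ (≈ 3-4%), i.e. it is conservative.

## Numerical choices and degenerate inputs

* Time unit: hours, $t = 0$ at each phase's first sample; clock time is
  carried per sample so regimes are assigned correctly for any start
  time (default 06:00). Regime intervals are half-open and left-closed
  ([06:00, 12:00) etc.).
* $a_0 = \gamma$ is represented through $1/(4k) = 0$, avoiding the
  infinite integration constant in arithmetic.
* A phase whose first or last day is constant has amplitude bound 0 and
  is rejected with an informative error, as are series shorter than one
  day, empty noise regimes, and non-positive variances.
* Noise-free simulations reproduce the model mean to machine precision;
  simulated regime variances are verified against chi-square
  Monte-Carlo bounds.
* RK4 uses a fixed 0.02 h step (≈ 1/1200 of a period), ample for the
  stiffness-free circadian regime.

### Identifiability near the constant-amplitude ridge

When $a_0 \approx \gamma$ the likelihood is nearly flat in
$(a_0, \varepsilon)$: with no amplitude transient, $a_0$ is informed
only by the first ~1-2 days and $\varepsilon$ only by the small third
harmonic. Fits remain unbiased (no spurious amplitude growth is induced
by the $\varepsilon \ge 0.2$ bound; the median fitted $\gamma$ matches
the truth) but the *spread* of $\hat a_0 - \hat\gamma$ under realistic
noise (variances ≈ 10/3.5/10 °C²) has a median magnitude near 0.3 °C.
This is a property of the model, not of the optimiser, and is documented
rather than hidden: comparisons of start-vs-final amplitudes should not
be over-interpreted in phases without dynamics.

## Problem sizes used in the shipped experiments

The package's simulation experiments use the study-sized default
scenario (60 series of 2880-4800 samples; fitting the whole study takes
a few seconds), 50-replicate recovery runs for the single-phase
estimator, 500-replicate calibration runs for the bootstrap procedures,
and 20-replicate runs for constraint behaviour — sizes chosen to make
Monte-Carlo error small relative to the effects being checked.

## Known limitations

* Independent-error likelihood: real residuals are short-range
  correlated; an ARMA error extension would sharpen (and slightly widen)
  the stated uncertainties.
* Per-(animal, phase) fits only — no joint hierarchical model across
  animals.
* No global-optimisation guarantee: L-BFGS-B finds a local optimum of a
  noisy-surfaced objective; robustness to starting values is verified
  empirically, not proven.
* The non-inferiority margin 0.2 is on the ratio scale and
  pre-specified; no multiplicity correction is applied since a single
  contrast is tested.
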