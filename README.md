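# vdprhythm

Dynamic van der Pol modelling of circadian rhythms in telemetry
temperature series.

## What it is for

In the ovariectomized (OVX) rat model of menopausal thermoregulatory
dysfunction, the circadian oscillation of tail skin temperature flattens
under estrogen deprivation and is restored by effective treatment.
Telemetry produces one temperature record every 3 minutes over phases of
6–10 days. `vdprhythm` is for pharmacology/biostatistics workflows that
need to quantify, per animal and phase, how the oscillation's amplitude
adapts — and then decide, at the group level, whether a test compound
restores amplitudes as well as a reference compound.

## The model

Observations are `y_n = x(nΔt) + c(nΔt) + e_n` with a linear baseline
trend `c(t) = c0 + c1·t` and independent normal noise whose variance
depends on the time of day (06–12 h, 12–18 h, 18–06 h regimes). The
circadian component is the second-order perturbation solution of the van
der Pol oscillator `ẍ + εω(4x²/γ² − 1)ẋ + ω²x = 0` (ω = 2π/τ, τ fixed at
24 h):

    x(t) = a(t)·cos(ωt + ψ) − ε·a(t)³/(8γ²)·sin(3ωt + 3ψ)

with the closed-form dynamic amplitude

    a(t) = [ (1/(4k))·e^(−εωt) + 1/γ² ]^(−1/2),
    1/(4k) = 1/a0² − 1/γ²

which runs monotonically from the start amplitude `a0` to the limit-cycle
amplitude `γ` at a pace set by the flexibility `ε`. Estimation is by
pseudo-maximum likelihood: trend fixed from least squares, variances
profiled from residuals at every objective evaluation, and
`(a0, γ, ε, ψ)` optimised by box-constrained L-BFGS-B (`ε ∈ [0.2, 1]`,
`ψ ∈ [−π, π]`, amplitudes bounded by half the first/last-day span).
Group inference bootstraps within-animal amplitude differences
(P2 − P3) and tests non-inferiority of amplitude-reconstruction ratios
`Q = γ_P3/γ_P1` via a one-sided bootstrap test on the difference of
group medians (margin 0.2, B = 1000, α = 0.05).

## Worked example

Simulate one treatment-like phase and fit it:

```r
library(vdprhythm)
truth <- full_model_params(vdp_params(a0 = 1.4, gamma = 2.7,
                                      epsilon = 0.3, psi = 0.15),
                           trend_params(30.7, -2.9e-3),
                           noise_params(10, 3.5, 9.8))
s <- simulate_phase(truth, study_design(), "P2", seed = 7)
fit_phase(s)
#> van der Pol phase fit: animal A1, phase P2 (n = 2880)
#>   a0 = 1.6927, gamma = 2.7652, epsilon = 0.2000, psi = 0.1175
#>   a(T) = 2.7640 degC at T = 144 h
#>   NLL = 6996.58, AIC = 14011.15, converged: TRUE
```

The limit-cycle amplitude `γ` (truth 2.7 °C) is recovered to 0.07 °C
from a series whose noise variances (10/3.5/9.8 °C²) dwarf the signal;
`a(T)` is the amplitude reached at the end of the 6-day phase and
essentially equals `γ̂`, showing the limit cycle has been attained. The
full study-level pipeline (20 animals × 3 phases, fit and compare):

```r
res <- run_default_pipeline(seed = 1)
cat(format_comparison_report(res$report), sep = "\n")
#> Mean differences between vehicle and treatment phase (P2 - P3)
#>   E2         estimate  -0.9345   CI (-Inf,  -0.5911]
#>   Tibolone   estimate  -1.4516   CI (-Inf,  -0.5880]
#>
#> Amplitude reconstruction (Q = gamma_P3 / gamma_P1), difference of group medians
#>   E2 - Tibolone: estimate -0.3014   CI (-Inf, 0.0493]   p_0.2 = 0.0040   similar recovery (H0 rejected)
```

Both groups' intervals lie entirely below zero — amplitudes rose
significantly from the vehicle to the treatment phase — and the ratio
test's upper confidence bound (0.049) is far below the 0.2 margin, so
the test compound's recovery is statistically similar to the reference's.

A thin command-line wrapper covers the same pipeline from a shell:

```sh
Rscript inst/cli/vdprhythm.R simulate --seed 1 --out study.csv
Rscript inst/cli/vdprhythm.R fit --in study.csv --out fits.json --summary fits.csv
Rscript inst/cli/vdprhythm.R compare --in fits.csv --out report.json
```

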