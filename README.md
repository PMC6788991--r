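# flankSCR

Bayesian spatially explicit capture–recapture (SCR) for single-camera
photo-identification surveys of bilaterally asymmetric animals — the
situation of leopard camera-trap studies where a left-flank photo series and
a right-flank photo series cannot always be linked to the same individual.
The package is aimed at wildlife statisticians and field ecologists who need
population density from flank-coded encounter histories without discarding
one side's data or double-counting animals.

## The model

Encounter histories are coded 0–4 per (occasion, station): absence, left
flank, right flank, both flanks non-simultaneously, both flanks in one photo
(the single-camera "sometimes" data type, where simultaneous events resolve
identity). Detection follows a half-normal hazard on the cloglog scale,

    p = 1 − exp(−exp(η)),   η = β(t) + c·1[prev capture] + w·1[water]
                                + θ·t̃ − d²/(2σ²),

with a trap-specific behavioural response `c`, a camera-placement contrast
`w` (water vs trail), an optional temporal trend, and spatial scale `σ` (km)
from the animal's latent activity centre to the trap. Conditional on
detection the flank outcome is multinomial: single-flank probability `δ` per
side (δ₁ = δ₂ = δ ≤ 0.5), simultaneous both-flank `α(1−2δ)`,
non-simultaneous `(1−α)(1−2δ)`. Activity centres live on a discretized
habitat mask; inference uses the semi-complete-data likelihood

    log L = log N!/(N−n)! + (N−n)·log p₀ + Σᵢ log ∫ [history i | s] ds,

sampled by Metropolis-within-Gibbs over the detection/flank parameters, the
latent matching of left-only to right-only histories, activity centres, and
abundance N (exact categorical Gibbs). Candidate detection models are
compared by Barker–Link posterior model probabilities with moment-matched
pseudo-priors, and reported as model-averaged posterior summaries. A full
account is in `vignettes/bilateral-scr-methods.Rmd`.

## Worked example

Simulate a reference survey (density 6 / 100 km², σ = 1.5 km, δ = 0.4,
α = 0.8, an 8×8 camera grid at 1.25-km spacing, 11 five-day occasions) and
fit the constant-detection model:

```r
library(flankSCR)
sim <- simulateSurvey(simulationConfig(), seed = 11)
sim$data
#> EncounterArray ('sometimes'): 9 histories (2 left-only, 2 right-only,
#>   5 known-both), 11 occasions x 64 traps, 33 detections
fit <- fitScr(sim$data, sim$mask, scrModel("~1"),
              chainConfig(n_chains = 3, seed = 11))
posteriorSummary(fit, c("D", "sigma_km", "delta", "alpha", "psi"))
#>  parameter     mean       sd    lower    upper
#>          D    3.785   1.0925    2.160    6.481
#>   sigma_km    1.385   0.2364    1.027    1.961
#>      delta    0.458   0.0228    0.403    0.491
#>      alpha    0.748   0.1982    0.287    0.992
#>        psi    0.789   0.0344    0.778    0.889
#>    sigma_m 1385.498 236.3676 1027.311 1961.285
```

`D` is density per 100 km² (this realization drew 16 animals on a 324-km²
mask, i.e. a realized density of 4.9; the 95% credible interval 2.2–6.5
covers it), `sigma_km` the movement scale, `delta`/`alpha` the
flank-observation parameters, and `psi` the share of observed histories
attributed to the current latent individuals. `convergenceDiagnostics(fit)`
reports Gelman–Rubin–Brooks factors and effective sample sizes; the
desk-scale schedule above mixes well (mpsrf ≈ 1.01) but deliberately stays
far below the publication-grade ESS ≥ 4000 criterion — scale
`chainConfig(sample_iters = ...)` up for real analyses.

Model sets, averaging and summaries:

```r
fits <- fitModelSet(sim$data, sim$mask, list("~1", "~c"), chainConfig(seed = 1))
pmp  <- multimodelProbabilities(fits, sim$data, sim$mask)
modelAverage(fits, as.numeric(pmp))
```

A YAML-driven pipeline (`cmdSimulate`, `cmdFit`, `cmdAverage`,
`cmdSummarize`; thin dispatcher in `inst/cli/flankscr.R`) covers
simulate → fit → average → summarize for whole survey areas.

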