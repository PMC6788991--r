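---
title: "Spatial capture-recapture with bilateral photo-identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial capture-recapture with bilateral photo-identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankSCR)
```

## The problem

Camera-trap surveys of individually patterned animals (leopards, tigers,
hyaenas) usually identify individuals from their pelage. When stations carry a
single camera, each photo shows one flank, and because natural marks are
bilaterally asymmetric a left-flank photo series and a right-flank photo
series of the same animal cannot in general be linked. Treating each flank as
a separate individual inflates abundance; discarding one flank wastes data.
flankSCR implements a spatially explicit capture-recapture (SCR) model in
which the left-right linkage is a latent variable: left-sided and right-sided
encounter histories are probabilistically matched while the uncertainty about
the true number of distinct animals propagates into the abundance estimate.

Occasionally a single photo (or external information such as a capture event)
shows both flanks at once. These events resolve an animal's identity
completely; the package's data type is therefore the single-camera
"sometimes" configuration: simultaneous both-flank encounters are possible
but not guaranteed.

## Data model

The observed data are flank-coded encounter histories over occasions `t = 1..T`
(five-day intervals in the motivating surveys) and stations `j = 1..J`, with
codes

* 0 — no detection,
* 1 — left-flank detection,
* 2 — right-flank detection,
* 3 — both flanks detected in the interval, never in one photo,
* 4 — simultaneous both-flank detection (one photo event).

Records of the same individual at the same station closer than 0.5 h are
collapsed to one detection before coding (`collapseDetections`), and within
each (individual, occasion, station) cell only the most informative code is
kept (4 over 3 over 1/2). Observed histories are of three kinds: left-only
(codes 0/1), right-only (codes 0/2), and known-both (any code, for bilaterally
known animals). Dependent cubs are excluded from the encounter array — the
density target is independent animals — but retained in the survey summaries.

## Detection and flank-observation model

An individual's activity centre `s` lives on a habitat mask: a regular lattice
(1-km^2 cells by default) covering the trap bounding box expanded by a buffer,
with non-habitat cells excluded. Detection at station `j`, occasion `t`
follows a complementary log-log (hazard) half-normal model:

    p = 1 - exp(-exp(eta)),
    eta = beta(t) + c * prevCapture + w * water + cw * prevCapture * water
          + trend * tTilde - d(s, x_j)^2 / (2 sigma^2)

where `beta(t)` is either a single intercept, one intercept per occasion
(`~time`), or a linear trend on the occasion index standardized to
[-0.5, 0.5] (`~Time`); `c` is a trap-specific behavioural response that
switches on permanently after the first capture at that trap; `w` contrasts
water-placed against trail-placed cameras; and `sigma` (km) is the spatial
scale of the half-normal. The hazard form factorizes as
`h = exp(eta0) * exp(-d^2/(2 sigma^2))`, which both the compiled sampler and
the R reference implementation exploit: non-detection cells contribute
`-sum(h)` on the log scale, so per-history likelihoods over all mask cells
reduce to matrix-vector products.

Conditional on a detection, the encounter type is multinomial with
single-flank probability `delta` for each side (constrained
`delta1 = delta2 = delta <= 0.5`, since the two flanks arise from a very
similar photographic process), simultaneous both-flank probability
`alpha * (1 - 2 delta)` and non-simultaneous both-flank probability
`(1 - alpha) * (1 - 2 delta)`.

A key simplification follows from the deterministic mapping between true and
observed histories given a matching: the observed-code mass rule is the same
for every history kind. An unmerged left-only history's `1` is a true code 1
(mass `p * delta`) and its `0` a true non-detection, because any right-flank
event would have surfaced as a right-only history owned by the same latent
individual. The uncertainty about unseen right-flank activity is carried
entirely by the sum over matchings, not by the per-cell masses.

## Likelihood and priors

With `n` latent detected individuals (after matching) and abundance `N`, the
semi-complete-data likelihood integrates undetected individuals' centres over
the mask:

    log L = log N!/(N-n)! + (N - n) log p0 + sum_i log integral_i

where `p0` is the mask-average probability of never being detected and
`integral_i` is the mask-cell average (midpoint rule, uniform centre prior) of
the per-history likelihood. Priors are deliberately diffuse: Normal(0, 10) on
cloglog intercepts and effects, Normal(log(mask diameter / 10), 2) on
`log sigma`, Uniform(0, 0.5) on `delta`, Uniform(0, 1) on `alpha`, and a scale
prior `p(N) ~ 1/N` (uniform optional) truncated at 50 times the number of
observed histories. The N prior is defined on `[1, N_max]`; the restriction
`N >= n` enters through the likelihood's falling factorial rather than a
latent-state-dependent prior normalizer, so matching moves need no prior
correction term.

Under the "sometimes" data type no (left-only, right-only) merge is
structurally infeasible: a shared (occasion, station) cell simply implies a
true code 3, and a true code 4 cannot occur in an unknown individual because
it would have resolved the identity. The feasibility hook in the sampler
exists for other deployment types but marks all pairs feasible here.

## The sampler

`fitScr` runs Metropolis-within-Gibbs chains (compiled core) over four blocks:

* **Parameters** — random-walk proposals per coordinate; `sigma` on the log
  scale, `delta` and `alpha` on logit scales. Proposal scales adapt toward
  0.44 acceptance during a dedicated adaptive phase, then freeze. Two exact
  fast paths keep the cost low: flank parameters touch only the multinomial
  code factors, and a single cloglog intercept rescales every hazard by a
  common factor.
* **Activity centres** — per-individual Normal displacements snapped to the
  containing lattice cell (a symmetric proposal, because cells are congruent
  squares); proposals on excluded or out-of-range cells are rejected.
* **Latent matching** — merge/split Metropolis moves on the partition of
  single-flank histories, drawn uniformly among feasible moves. Acceptance
  uses per-history likelihoods with centres integrated over the mask, and the
  affected individuals' centres are then redrawn from their exact cell
  conditional (a collapsed, marginalize-then-sample move that avoids
  reversible-jump bookkeeping).
* **Abundance** — an exact categorical Gibbs draw of `N` over
  `[n, N_max]` using precomputed log-factorial tables.

Initial values are drawn from the priors; matchings start fully unmerged and
centres at the detection-weighted mean trap location of each history, snapped
to the nearest included cell. A chain whose initial log posterior is not
finite is re-initialized (at most 100 attempts). Reported quantities per
retained draw include density `D = N / area * 100` (exact for every draw),
`sigma`, `delta`, `alpha`, derived capture (`p`) and recapture (`c`)
probabilities at distance zero via the cloglog link — at the first/last
occasion, or per placement class when the model carries a placement term —
and `psi`, defined in this implementation as `n / M_obs`, the share of
observed histories attributable to the current latent individuals.

Numerical care: all per-cell non-detection sums use the hazard factorization;
`log(1 - exp(-h))` switches between `log(-expm1(-h))` and `log1p(-exp(-h))`;
per-history integrals use log-sum-exp over cells.

## Multimodel inference

The candidate set mirrors the motivating study: `~1`, `~time`, `~Time`, `~c`,
plus `~Placement`, `~c+Placement` and `~c*Placement` where the design carries
a placement covariate (`candidateModels`). Posterior model probabilities come
from a product-space Gibbs sampler over the model indicator
(`barkerLinkProbabilities`): each model's parameters are refreshed from its
stored single-model posterior draws when current, and from moment-matched
independent Normal pseudo-priors (on the sampling scales) otherwise; the
discrete latent component — the matching encoding together with `N` — uses an
empirical categorical pseudo-prior over the stored latent draws. The per-model
observed-data likelihood is the semi-complete likelihood with centres
marginalized over the mask, evaluated by the same compiled kernel the sampler
uses. Model-averaged summaries pool raw draws by weighted resampling rather
than a Normal approximation. Sex effects are examined by refitting the
per-area best model to the male and female history subsets and comparing 95%
credible intervals (`fitBySex`).

## Convergence diagnostics

`convergenceDiagnostics` reports univariate Gelman-Rubin factors, the
Brooks-Gelman multivariate factor and Geyer initial-monotone-sequence
effective sample sizes, with default adequacy thresholds mpsrf <= 1.1 and
ESS >= 4000 (the chain-length criteria used in the motivating study). The
PSRF here omits the `(n-1)/n` shrinkage of the pooled variance, so chains
that are exact copies report exactly 1 and the factor is never below 1;
near convergence it agrees with the classical estimator to the third decimal.
Rank normalization is not applied, matching the coda-era workflow. `N` is
excluded from the default multivariate set because it is exactly proportional
to `D`.

## The simulator and what the tests show

`simulateSurvey` generates the full data-producing process: a Poisson
population over the mask (uniform activity centres), Bernoulli detections
with the behavioural state updated as captures accrue, multinomial flank
realization, identity resolution (a priori known individuals plus anyone with
a simultaneous both-flank event), and the split of unknown individuals into
single-flank observed histories. `makeFixture` writes the corresponding photo
record, station, occasion, mask and known-pair files, including same-flank
duplicate photos inside the 0.5-h window and two-photo non-simultaneous
both-flank events, so the ingestion path is exercised end to end.

The default configuration is the package's reference validation condition:
density 6 individuals / 100 km^2, sigma 1.5 km, delta 0.4, alpha 0.8, an
8 x 8 single-camera grid at 1.25-km spacing (the motivating surveys spaced
cameras at 1.2-1.4 km), 11 five-day occasions, half the population
bilaterally known, and a 4.5-km mask buffer. The buffer is 3 sigma — the
standard SCR rule for a mask wide enough that the omitted detection hazard is
negligible; the motivating study's 40-100 km buffers reflect collar-measured
movements of its study species and are equally valid inputs to `buildMask`.
The validation suite fits 30 replicate surveys at this condition with 3
chains of 20,000 iterations each and checks 95% credible-interval coverage
for density and relative error in sigma; smaller enumerable instances
validate the likelihood against exhaustive complete-data enumeration and the
matching sampler against the enumerated partition posterior.

What the simulator does not emulate: territoriality or any interaction
between activity centres (the point process is homogeneous Poisson),
within-survey movement of centres (demographic and geographic closure),
misidentification of flanks, heterogeneous per-camera failure (operation
flags exist but fixtures keep cameras on), and inhomogeneous density
surfaces. Passing tests therefore demonstrate correctness of the estimator
under the stated model, not robustness to these violations.

## Reporting conventions and known limitations

* `sigma` is carried in km internally; summaries print both km and m because
  published tables in this literature are inconsistent about the unit.
* `psi` is this implementation's definition (`n / M_obs` per draw); partial
  identity software differs in the exact internal parameterization of the
  observed-history augmentation.
* The behavioural response is permanent after first capture at a trap
  (standard "b"-type behaviour); a Markovian variant is not implemented.
* Detection functions other than the half-normal, covariates on `sigma`, and
  habitat covariates on density are out of scope.
* With very sparse both-flank information (`delta` near 0.5, few known
  individuals) the matching posterior is diffuse and abundance intervals
  widen accordingly; this is a property of the design, not the estimator.
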