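---
title: "Staging-ground population viability under illegal offtake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging-ground population viability under illegal offtake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goosepva)
```

## The model

`goosepva` simulates the yearly dynamics of a migratory goose population
at a staging area — the case it is parameterised for is the Lesser
White-fronted Goose (*Anser erythropus*, LWfG) in northern Kazakhstan,
a red-listed species that passes through a region of intense legal
waterfowl hunting and is easily confused with huntable congeners. The
question the model answers is: how much yearly illegal or accidental
offtake can the staging population absorb before growth turns negative
or extinction becomes likely, and how does the answer depend on survival
along the rest of the flyway?

One year of the model is the composition of four processes. Writing
$N_t$ for the population present at the staging area in year $t$:

1. **Survival and return.** Each bird independently survives the rest of
   the flyway and returns with probability $\phi$ (the *return rate*,
   conflating true survival and site fidelity):
   $N_{a,t+1} \sim \mathrm{Binomial}(N_t, \phi)$.
2. **Recruitment.** Half the returning birds are assumed female and a
   proportion $p$ of females breed successfully; the number of breeding
   females is floored to a natural number,
   $F = \lfloor \tfrac12\, p\, N_{a,t+1} \rfloor$, and recruits are
   $N_{j,t+1} \sim \mathrm{Poisson}(rF)$ with $r$ the mean brood size.
   $p$ is redrawn every year from $\mathrm{Normal}(\bar p, \sigma_p)$,
   clamped to $[0,1]$.
3. **Offtake.** $H$ birds are removed from the combined returned pool
   (adults and juveniles, without age bias), clamped at zero. Harvest
   happens after all birds have returned, so flyway mortality and
   hunting mortality are additive.
4. **Density dependence.** Above the carrying capacity $K$ the
   per-capita mortality probability rises linearly,
   $\psi = \min\!\big(\max\!\big(0, \tfrac{N-K}{K}\big), 1\big)$, and
   the year closes with
   $N_{t+1} \sim \mathrm{Binomial}(N^{(H)}, 1 - \psi)$ where $N^{(H)}$
   is the post-offtake pool. Extinction is absorbing.

Default parameters: $\bar p = 0.5$, $\sigma_p = 0.05$, $r = 1.26$,
$K = 250{,}000$ (the species' historical abundance), $N_0 = 32{,}000$
(the Western main subpopulation estimate), a 20-year management horizon,
and $\phi$ varied over $[0.60, 0.84]$, the plausible range for
waterfowl under reduced harvest pressure.

A useful closed form below carrying capacity is the expected yearly
multiplier
$\lambda = \phi\,(1 + \tfrac12 \bar p\, r) = 1.315\,\phi$: growth
requires $\phi > 1/1.315 \approx 0.76$, and the deterministic recursion
$N \leftarrow \lambda N - H$ crosses zero growth at
$H^\* = N_0(\lambda - 1)$. These closed forms are used throughout the
test suite as independent oracles for the stochastic engine.

## Scenario sweeps and metrics

```{r sweep}
params <- demographic_params(phi = 0.6)
rec <- run_scenario(params, offtake = 0, replicates = 100, seed = 1)
mean(rec$growth_total)
```

`run_grid()` sweeps offtake $\times$ return rate (default: offtake 0 to
10,000 in steps of 100, $\phi$ from 0.60 to 0.84, 100 replicates per
scenario — 131,300 twenty-year trajectories, a few seconds on one CPU)
and records three per-replicate metrics:

* total growth $(N_T - N_0)/N_0$, which equals $-1$ exactly at
  extinction;
* the mean annual growth rate
  $\mathrm{mean}_t\{(N_{t+1}-N_t)/N_t\}$, where years with $N_t = 0$
  are excluded (the rate is undefined there; the crash year itself
  contributes $-1$);
* an extinction flag, aggregated per scenario into the fraction of
  replicates reaching zero.

The $\phi$ step of 0.02 (13 levels) is a package choice balancing the
axis densities; only the range is fixed by the study design.
Reproducibility is by construction: scenario $i$ of a grid uses seed
`base_seed + (i - 1) * seed_stride` (offtake varying fastest), so a grid
is bit-reproducible and individual scenarios can be re-run in isolation.

Two behavioural switches are deliberately exposed rather than decided
silently, because the yearly update can be read two ways:

* `p_redraw`: the breeding proportion is redrawn every replicate-year
  (default; interannual variation is the natural reading of a yearly
  stochastic model) or once per replicate;
* `psi_timing`: density mortality is evaluated on the pool after
  offtake removal (default — density acts on the birds actually
  present) or before. At default parameters the two are
  indistinguishable, since $\psi > 0$ only near $K$, far above where
  harvested scenarios ever sit.

## Response surfaces and thresholds

The metric surfaces over (offtake, $\phi$) are fitted with `mgcv` GAMs:
Gaussian family for growth (per-replicate observations), binomial for
extinction (per-scenario counts). The default smoother is an isotropic
thin-plate spline on *standardized* covariates. Isotropy on the raw
scales would be meaningless — the offtake axis spans 10,000 birds and
the $\phi$ axis 0.24, so a raw-scale thin-plate smooth effectively
ignores the return-rate direction (we measured its no-harvest corner
prediction collapsing to the $\phi$-averaged value). Standardizing both
axes before the smooth restores a meaningful isotropy; a tensor-product
smooth on the raw scales (`smoother = "tensor"`), which is scale
invariant by construction, is the exposed alternative. The basis
dimension defaults to `mgcv`'s own; the effective complexity is chosen
by GCV.

Thresholds are read off the fitted surfaces by linear interpolation
between adjacent prediction-grid points (no root polishing beyond the
grid resolution):

* `zero_growth_frontier()`: per $\phi$, the smallest offtake where
  predicted growth crosses zero; the global frontier is the maximum
  over $\phi$ — the offtake above which growth is negative regardless
  of return rate.
* `probability_contour()`: per $\phi$, the offtake where the predicted
  extinction probability first rises through a level (0.1 and 0.9 are
  the conventional pair).

Two caveats are intrinsic and therefore surfaced in the API rather than
hidden. First, smoothed and raw thresholds diverge where the surface is
steep — the extinction surface shifts from 0 to 1 within a few grid
steps — so `empirical_thresholds()` always offers the raw replicate-mean
counterpart, and every threshold object carries its smoother
specification as provenance. Second, a penalized smooth of a
cliff-shaped surface overshoots: fitted growth dips slightly below the
attainable minimum of $-1$ near the collapse cliff (about $-1.2$ at
worst on the full grid). Predictions are reported raw, not clipped, so
this artefact stays visible.

`k_sensitivity()` re-runs a grid at several carrying capacities and
compares the extracted thresholds. Declining trajectories never
approach $K$, so the frontier and contours barely move across a
four-fold range of $K$ (less than one offtake grid step in our runs) —
which is why the headline thresholds can be trusted despite $K$ being
the least-known parameter.

## From hunting quotas to population risk

`expected_accidental_offtake(quota, misid_rate)` converts a legal goose
quota and a misidentification rate into an expected yearly accidental
kill of the protected species. With the 2017 regional quota of 71,240
and field rates of one LWfG per 100 legally huntable geese (up to one
per 20–30 in the worst area), this is about 700, and about 3,500 in the
extreme; the extreme endpoint is encoded as 1/20, the value consistent
with that rounding, with the 1/30 end available by just passing it.
`offtake_risk_report()` places such an estimate on a simulated grid:
per return rate it reports the sign of mean growth and the extinction
probability at the nearest simulated offtake, classifying the scenario
as growing, declining, or extinction risk (extinction probability at or
above 0.5, i.e. the majority of replicates), and reports the smallest
return rate that still sustains growth.

## The synthetic survey generator

No raw survey data ship with the package (the original survey archive is
restricted), so the survey-side tools run on a synthetic generator that
emulates the *structure* of the hunter survey: ~166 male respondents
scattered over 46 sites; licence ownership near 42% with goose-and-duck
licences the most common type; a latent goose-hunting indicator whose
probability depends on licence type; a five-species protection-status
quiz (LWfG, Red-breasted Goose and Mute Swan protected; Greylag Goose
and Goldeneye Duck not); and an unmatched-count design with four
non-sensitive activities (farming/herding, taxi driving, construction,
milking) shared by both lists and goose hunting as the treatment list's
fifth item, asked for four reference periods. Control and treatment
assignment follows the realised 80:109 split.

Non-sensitive endorsement probabilities were never published; the
defaults (0.35, 0.10, 0.15, 0.30) are plausible for the activities and
only calibrate the generator — estimator correctness does not depend on
them. By default the sensitive item counts toward the past-year and
autumn/winter questions but not spring/summer or for-cash, emulating
compliance with the spring ban and non-monetary motivation; both are
configurable to simulate non-compliance.

What the generator does *not* emulate: respondent covariates are
mutually independent given licence type (no realistic collinearity
structure), site effects on responses are absent, and item endorsements
are independent across questions and items. Tests passing on this
generator therefore validate the estimators and the machinery around
them, not claims about the real survey population.

```{r uct}
pr <- generate_respondents(166, seed = 5)
uct <- generate_uct_responses(pr, seed = 6)
uct_prevalence(uct)
```

The prevalence estimator is the list-experiment difference in means
with a two-sample standard error. `design_effect_check()` screens for
the design assumption (that adding the sensitive item leaves the
non-sensitive answers unchanged): under the null, treatment counts are
the control-count distribution convolved with an independent Bernoulli
at the estimated prevalence; the statistic is the largest absolute CDF
difference between observed treatment counts and that convolution, and
its null distribution comes from a parametric bootstrap that resimulates
*both* groups and re-estimates the prevalence each time, so estimation
uncertainty is propagated. This is a deliberately simple screen, named
and documented as such — it is not a re-implementation of published
likelihood-based design tests. Its level is accurate (measured type-I
error 0.059 at nominal 0.05 over 1,000 null simulations), but its power
against design effects that merely shift an item's endorsement
probability is modest, because the induced mean shift is absorbed into
the estimated prevalence and only the residual change of distributional
shape is detectable; the power test therefore asserts detection well
above the false-positive rate rather than near-certain detection.

## Model selection and averaging

Candidate models (fitted by any engine — `lm`, `glm`, `lme4`; the
package deliberately does not own the likelihood machinery) enter as
`model_summary` objects holding an AICc and named coefficients.
`aicc_top_set()` keeps models strictly within 4 AICc of the best;
`natural_model_average()` computes Akaike weights
$w_i \propto e^{-\Delta_i/2}$ over the set and averages each term only
over the models containing it, with the weights renormalized over that
subset — the *natural* method, which does not shrink a term toward zero
for being absent elsewhere. A term in one model keeps that model's
estimate; a term in every model gets the ordinary weighted average.

## Numerical choices and test scale

* Breeding females are floored before the Poisson draw, so three or
  fewer returning adults at $p = 0.5$ recruit nothing; the induced
  downward bias on expected recruits is at most $r/2$ birds per year.
* Clamping of $p$ to $[0,1]$ and of offtake at zero keeps all states
  valid; extinction is absorbing by construction since binomial and
  Poisson draws on zero counts stay zero.
* All randomness flows through R's generator via explicit seeds;
  per-scenario seeds are an affine map of the grid's base seed.
* The test suite exercises reduced designs (e.g. offtake steps of
  250–1,000, 20–40 replicates) chosen so the whole suite and the
  full-grid headline checks run in well under a minute, with
  Monte-Carlo tolerances stated as multiples of the relevant standard
  errors; the full 131,300-trajectory study grid itself is used where
  the check is about the study-scale surface.

## Limitations

The model is unstructured beyond the adult/juvenile split within a
year: no age classes, sexes, spatial structure, or flyway-segment
mortality decomposition, and offtake is a fixed yearly count, not a
rate or a policy. Threshold readings from fitted surfaces are
smoother-dependent wherever the underlying surface is steep; treat the
raw and smoothed values as a pair. The survey tools estimate and screen
— they do not attempt inference about the real respondent population,
whose data are not available.
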