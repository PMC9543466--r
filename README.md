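# goosepva

Stochastic population viability analysis for a migratory goose
population at its staging grounds under illegal or accidental hunting
offtake — parameterised for the Lesser White-fronted Goose (*Anser
erythropus*, LWfG) staging in northern Kazakhstan — plus the
survey-side toolkit used to study hunter behaviour around it: a
synthetic unmatched-count (list experiment) generator and estimator, a
design-effect screen, species protection knowledge scoring, and AICc
top-set selection with natural model averaging.

It is intended for conservation ecologists asking harvest-sustainability
questions of the form: *how much yearly offtake can a staging population
absorb before growth turns negative or extinction becomes likely, and
how does the answer depend on survival along the rest of the flyway?*

## The model

One year of population dynamics composes four stochastic processes.
With $N_t$ birds present in year $t$, return rate $\phi$, breeding
proportion $p \sim \mathrm{Normal}(\bar p, \sigma_p)$ clamped to
$[0,1]$, mean brood size $r$, yearly offtake $H$ and carrying capacity
$K$:

$$N_{a,t+1} \sim \mathrm{Binomial}(N_t,\ \phi)$$

$$N_{j,t+1} \sim \mathrm{Poisson}(rF), \qquad
  F = \big\lfloor \tfrac12\, p\, N_{a,t+1} \big\rfloor$$

$$N^{(H)} = \max\!\big(0,\ N_{a,t+1} + N_{j,t+1} - H\big)$$

$$N_{t+1} \sim \mathrm{Binomial}\!\big(N^{(H)},\ 1 - \psi\big), \qquad
  \psi = \min\!\Big(\max\!\Big(0, \tfrac{N^{(H)} - K}{K}\Big),\ 1\Big)$$

Extinction is absorbing. Defaults: $N_0 = 32{,}000$, $K = 250{,}000$,
$\bar p = 0.5$, $\sigma_p = 0.05$, $r = 1.26$, a 20-year horizon, and
$\phi \in [0.60, 0.84]$. Scenario sweeps over offtake $\times$ return
rate yield three metrics per replicate — total growth
$(N_T - N_0)/N_0$, mean annual growth rate, and extinction — which are
smoothed with `mgcv` GAMs (Gaussian for growth, binomial for
extinction) to extract zero-growth frontiers and
extinction-probability contours.

## Worked example

Sweep a reduced grid, fit the growth surface, and extract the harvest
frontier:

```r
library(goosepva)

g <- scenario_grid(offtake_values = seq(0, 5000, by = 500),
                   phi_values = seq(0.60, 0.84, by = 0.04),
                   replicates = 50, base_seed = 42)
recs <- run_grid(g, demographic_params())
fit  <- fit_metric_surface(recs, "growth_total")
fr   <- zero_growth_frontier(fit)
fr$per_phi
#>    phi offtake_threshold
#> 1 0.60                NA
#> 2 0.64                NA
#> 3 0.68                NA
#> 4 0.72                NA
#> 5 0.76                NA
#> 6 0.80          1647.844
#> 7 0.84          3341.358
```

Below a return rate of about 0.76 the expected yearly multiplier
$\lambda = 1.315\,\phi$ is under 1, so the population declines at *any*
offtake (threshold `NA`); above it, the frontier rises to ~3,340 birds
per year at $\phi = 0.84$ — closely matching the closed-form
$H^* = N_0(\lambda - 1) \approx 3{,}347$.

Classify an accidental-offtake estimate (the 2017 regional quota of
71,240 times a 1-per-100 misidentification rate is
`expected_accidental_offtake(71240, 1/100)` = 712.4 birds/year)
against the grid:

```r
offtake_risk_report(700, recs)
#> Risk classification at offtake 700 (nearest simulated: 500)
#>   phi mean_growth extinction_probability           class
#>  0.60      -1.000                      1 extinction-risk
#>  0.64      -1.000                      1 extinction-risk
#>  0.68      -1.000                      1 extinction-risk
#>  0.72      -0.859                      0       declining
#>  0.76      -0.310                      0       declining
#>  0.80       1.177                      0         growing
#>  0.84       5.156                      0         growing
#> Smallest return rate with positive mean growth: 0.80
```

An offtake of ~700 birds/year is survivable only if flyway survival is
high: at return rates below ~0.7 it combines with the baseline decline
to make extinction within 20 years near-certain.

On the survey side:

```r
pr  <- generate_respondents(166, seed = 5)
uct <- generate_uct_responses(pr, seed = 6)
uct_prevalence(uct)
#> List-experiment prevalence, question 'past_year'
#>   estimate 0.370 (SE 0.124), 95% CI [0.126, 0.613]
#>   treatment mean 1.301 (n = 93), control mean 0.932 (n = 73)
```

See `vignette("population-viability")` for the full methods account:
model assumptions, smoother choice, threshold extraction, the
design-effect screen, and what the synthetic survey generator does and
does not emulate.

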