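Package: goosepva
Title: Stochastic Population Viability Analysis for Staging Goose
    Populations Under Illegal Offtake
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the annual dynamics of a migratory goose population
    at a staging ground under varying levels of illegal or accidental
    hunting offtake and flyway return rates, using a stochastic model with
    binomial survival, Poisson recruitment and linear density-dependent
    mortality above carrying capacity. Sweeps offtake-by-return-rate
    scenario grids, computes total growth, mean annual growth rate and
    extinction probability, fits generalised additive response surfaces
    and extracts zero-growth frontiers and extinction-probability
    contours, and links hunting quotas and misidentification rates to
    expected accidental offtake. Also provides survey-side tools: a
    synthetic generator for unmatched count technique (list experiment)
    data, the difference-in-means prevalence estimator, a bootstrap
    design-effect check, species protection knowledge scoring, and AICc
    top-set selection with natural model averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    stats
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
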