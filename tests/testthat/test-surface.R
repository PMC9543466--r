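test_that("a noiseless plane is recovered exactly by the gaussian smooth", {
  rec <- synthetic_records(function(off, phi) 2 + 0.001 * off)
  fit <- fit_metric_surface(rec, "growth_total")
  inner <- fit$grid[fit$grid$offtake > 0 & fit$grid$offtake < 5000, ]
  expect_lt(max(abs(inner$predicted - (2 + 0.001 * inner$offtake))), 1e-3)
  expect_equal(fit$family, "gaussian")
})

test_that("an all-extinct table yields a near-one probability surface", {
  rec <- synthetic_records(function(off, phi) -1)
  expect_true(all(rec$extinct))
  fit <- suppressWarnings(fit_metric_surface(rec, "extinct"))
  expect_true(all(fit$grid$predicted >= 0.99))
  expect_true(all(fit$grid$predicted <= 1))
})

test_that("grid predictions stay near replicate means in smooth regions", {
  rec <- reduced_grid_records()
  # the collapse region (low phi) is flat: growth is near -1 throughout
  low <- rec[rec$phi <= 0.68, ]
  fit <- fit_metric_surface(low, "growth_total")
  summ <- summarize_scenarios(low)
  m <- merge(fit$grid, summ, by = c("offtake", "phi"))
  interior <- m$offtake > 0 & m$offtake < 5000 &
    m$phi > 0.6 & m$phi < 0.68
  dev <- abs(m$predicted - m$mean_growth)[interior]
  tol <- pmax(2 * m$se_growth[interior], 0.02)
  expect_true(all(dev <= tol))
})

test_that("surface fitting rejects degenerate grids", {
  rec <- synthetic_records(function(off, phi) off, phi_values = 0.7)
  expect_error(fit_metric_surface(rec, "growth_total"), "distinct values")
})

test_that("the zero-growth frontier interpolates the sign change", {
  # negative everywhere: no frontier
  neg <- synthetic_records(function(off, phi) -0.5)
  fneg <- zero_growth_frontier(fit_metric_surface(neg, "growth_total"))
  expect_true(all(is.na(fneg$per_phi$offtake_threshold)))
  expect_equal(fneg$global, 0)

  # deterministic harvest recursion N <- lambda * N - H: growth crosses
  # zero exactly at H* = N0 * (lambda - 1), about 3,347 at phi = 0.84
  det_growth <- function(off, phi) {
    lam <- 1.315 * phi
    n <- rep(32000, length(off))
    for (t in 1:20) n <- pmax(lam * n - off, 0)
    (n - 32000) / 32000
  }
  det <- synthetic_records(det_growth,
                           offtake_values = seq(0, 5000, by = 100),
                           phi_values = seq(0.6, 0.84, by = 0.02))
  fr <- zero_growth_frontier(fit_metric_surface(det, "growth_total"))
  h84 <- fr$per_phi$offtake_threshold[abs(fr$per_phi$phi - 0.84) < 1e-9]
  expect_lt(abs(h84 - 32000 * (1.315 * 0.84 - 1)), 250)
  # frontier is non-decreasing in phi where defined
  thr <- fr$per_phi$offtake_threshold
  expect_true(all(diff(thr[!is.na(thr)]) >= -1e-6))
  expect_error(zero_growth_frontier(fit_metric_surface(det, "extinct")),
               "Gaussian")
})

test_that("probability contours cross where the surface does", {
  # constant-zero surface never crosses
  none <- synthetic_records(function(off, phi) 0)
  none$extinct <- FALSE
  fit0 <- suppressWarnings(fit_metric_surface(none, "extinct"))
  c0 <- probability_contour(fit0, 0.5)
  expect_true(all(is.na(c0$offtake_threshold)))

  # synthetic step from 0 to 1 at offtake 5,000
  step <- synthetic_records(function(off, phi) ifelse(off >= 5000, -1, 1),
                            offtake_values = seq(0, 10000, by = 500))
  fit_s <- suppressWarnings(fit_metric_surface(step, "extinct"))
  cs <- probability_contour(fit_s, 0.5)
  expect_true(all(abs(cs$offtake_threshold - 5000) < 500))

  expect_error(probability_contour(fit_s, 1.5), "strictly between")
  expect_error(probability_contour(fit_s, 0), "strictly between")
})

test_that("fitted extinction contours are ordered and bounded", {
  rec <- reduced_grid_records()
  efit <- suppressWarnings(fit_metric_surface(rec, "extinct"))
  expect_true(all(efit$grid$predicted >= 0 & efit$grid$predicted <= 1))
  c10 <- probability_contour(efit, 0.1)
  c90 <- probability_contour(efit, 0.9)
  both <- !is.na(c10$offtake_threshold) & !is.na(c90$offtake_threshold)
  expect_true(all(c10$offtake_threshold[both] <=
                    c90$offtake_threshold[both] + 1e-6))
  # gaussian growth surface never undershoots total loss by more than the
  # smoother overshoot tolerance at the collapse cliff
  gfit <- fit_metric_surface(rec, "growth_total")
  expect_true(all(gfit$grid$predicted >= -1 - 0.25))
})

test_that("predictions outside the fitted hull are refused", {
  rec <- reduced_grid_records()
  fit <- fit_metric_surface(rec, "growth_total")
  expect_error(predict(fit, data.frame(offtake = 20000, phi = 0.7)),
               "outside")
  expect_error(predict(fit, data.frame(offtake = 100, phi = 0.5)),
               "outside")
  ok <- predict(fit, data.frame(offtake = c(0, 2500), phi = c(0.84, 0.7)))
  expect_length(ok, 2)
})

test_that("raw-grid thresholds accompany the smoothed ones", {
  rec <- reduced_grid_records()
  emp <- empirical_thresholds(rec, level = 0.9)
  expect_named(emp, c("phi", "zero_growth_offtake", "extinction_offtake"))
  # at the lowest return rate the population declines at any offtake
  expect_true(is.na(emp$zero_growth_offtake[1]))
  # at the highest return rate a positive-growth region exists
  h84 <- emp$zero_growth_offtake[abs(emp$phi - 0.84) < 1e-9]
  expect_true(is.finite(h84) && h84 > 2000 && h84 < 5000)
})

test_that("carrying-capacity sensitivity requires several K and reports shifts", {
  params <- demographic_params()
  g <- scenario_grid(offtake_values = seq(0, 4000, by = 1000),
                     phi_values = c(0.6, 0.72, 0.84),
                     replicates = 20, base_seed = 12)
  expect_error(k_sensitivity(params, 250000, g), "at least two")
  ks <- suppressWarnings(k_sensitivity(params, c(125000, 500000), g))
  expect_s3_class(ks, "k_sensitivity")
  expect_equal(sort(unique(ks$thresholds$K)), c(125000, 500000))
  expect_true(all(c("zero_growth_offtake", "p10_offtake", "p90_offtake")
                  %in% names(ks$thresholds)))
  expect_true(is.finite(ks$max_shift[["zero_growth_offtake"]]))
})

test_that("a population starting at carrying capacity cannot grow", {
  pK <- demographic_params(K = 32000)
  rec <- run_scenario(pK, offtake = 0, replicates = 40, seed = 77)
  expect_lt(abs(mean(rec$growth_total)), 0.05)
})
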