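test_that("breeding proportion draws follow the clamped normal contract", {
  # degenerate distribution
  expect_equal(draw_breeding_proportion(0.5, 0, n = 20), rep(0.5, 20))
  # Monte-Carlo check against the stated normal moments
  set.seed(101)
  draws <- draw_breeding_proportion(0.5, 0.05, n = 10000)
  expect_lt(abs(mean(draws) - 0.5), 0.002)
  expect_lt(abs(sd(draws) - 0.05), 0.003)
  # clamping keeps even an absurd spread inside [0, 1]
  wild <- draw_breeding_proportion(0.5, 5.0, n = 2000)
  expect_true(all(wild >= 0 & wild <= 1))
  expect_error(draw_breeding_proportion(0.5, -0.1), "non-negative")
})

test_that("survival-and-return is binomial with the right moments", {
  expect_identical(survive_and_return(0, 0.84), 0L)
  expect_identical(survive_and_return(500, 1.0), 500L)
  set.seed(102)
  draws <- replicate(2000, survive_and_return(10000, 0.6))
  expect_lt(abs(mean(draws) - 6000), 5)      # ~4.5 SE of the mean
  expect_lt(abs(var(draws) - 2400) / 2400, 0.15)
  expect_error(survive_and_return(100, 1.2), "probability")
})

test_that("recruitment floors breeding females and is Poisson in mean", {
  expect_identical(recruit(0, 0.5, 1.26), 0L)
  # F = floor(0.5 * 0.5 * 3) = 0, so never any recruits
  set.seed(103)
  expect_true(all(replicate(50, recruit(3, 0.5, 1.26)) == 0))
  draws <- replicate(2000, recruit(100, 0.5, 1.26))
  expect_lt(abs(mean(draws) - 31.5), 0.6)    # ~4.8 SE of Poisson(31.5) mean
})

test_that("offtake removal clamps at zero", {
  expect_equal(apply_offtake(100, 0), 100)
  expect_equal(apply_offtake(100, 150), 0)
  expect_equal(apply_offtake(42000, 7300), 34700)
})

test_that("density mortality is zero below K and capped at one", {
  expect_equal(density_mortality(100000, 50000, 250000), 0)
  expect_equal(density_mortality(200000, 100000, 250000), 0.2)
  expect_equal(density_mortality(600000, 0, 250000), 1.0)
  expect_error(density_mortality(10, 10, 0), "carrying capacity")
})

test_that("a single year composes the processes correctly", {
  params <- demographic_params()
  # absorbing state
  st0 <- step_year(0, params, offtake = 1000)
  expect_equal(st0$n_end, 0L)
  # identity year: perfect return, no breeding, no harvest, K unbinding
  ident <- demographic_params(phi = 1, p_mean = 0, p_sd = 0, K = 10^7)
  set.seed(104)
  st <- step_year(5000, ident, offtake = 0)
  expect_equal(st$n_end, 5000L)
  expect_equal(st$n_juveniles, 0L)
  expect_equal(st$psi, 0)
  # closed-form one-year multiplier: lambda = phi * (1 + 0.5 * p * r)
  set.seed(105)
  ratios <- replicate(1000, step_year(32000, params, offtake = 0)$n_end / 32000)
  expect_lt(abs(mean(ratios) - 0.84 * (1 + 0.5 * 0.5 * 1.26)), 0.002)
})

test_that("density timing switch changes when psi is evaluated", {
  # n = 1400, K = 1000, offtake 500: post-offtake pool 900 < K so psi = 0
  # and thinning is a sure event; pre-offtake psi = 0.4 thins the pool.
  p <- demographic_params(phi = 1, p_mean = 0, p_sd = 0, K = 1000,
                          N0 = 1400, T = 1)
  set.seed(106)
  post <- step_year(1400, p, offtake = 500, psi_timing = "post_offtake")
  expect_equal(post$n_end, 900L)
  set.seed(106)
  pre_draws <- replicate(300, step_year(1400, p, offtake = 500,
                                        psi_timing = "pre_offtake")$n_end)
  expect_lt(abs(mean(pre_draws) - 900 * 0.6), 15)
})

test_that("trajectories start at N0, are reproducible and absorb extinction", {
  p0 <- demographic_params(T = 0)
  tr0 <- simulate_trajectory(p0, seed = 1)
  expect_equal(tr0$sizes, 32000)
  expect_false(tr0$extinct)

  params <- demographic_params(phi = 0.6)
  t1 <- simulate_trajectory(params, offtake = 300, seed = 7)
  t2 <- simulate_trajectory(params, offtake = 300, seed = 7)
  expect_identical(t1$sizes, t2$sizes)
  expect_equal(t1$sizes[1], 32000)

  # once zero, always zero; counts are non-negative integers
  sizes <- simulate_replicates(demographic_params(phi = 0.6), offtake = 300,
                               replicates = 50, seed = 8)
  expect_true(all(sizes >= 0))
  expect_true(all(sizes == floor(sizes)))
  for (i in seq_len(nrow(sizes))) {
    z <- which(sizes[i, ] == 0)
    if (length(z)) expect_true(all(sizes[i, z[1]:ncol(sizes)] == 0))
  }
})

test_that("long-run decline matches the geometric oracle at low return rate", {
  # lambda = 1.315 * 0.6 = 0.789; 32,000 * 0.789^20 is about 280
  params <- demographic_params(phi = 0.6)
  sizes <- simulate_replicates(params, offtake = 0, replicates = 200,
                               seed = 109)
  expect_gt(mean(sizes[, 21]), 100)
  expect_lt(mean(sizes[, 21]), 600)
})

test_that("heavy harvest at high return rate extinguishes within the horizon", {
  # deterministic recursion N <- 1.1046 N - 7,300 reaches zero near year 7
  params <- demographic_params(phi = 0.84)
  sizes <- simulate_replicates(params, offtake = 7300, replicates = 200,
                               seed = 110)
  extinct <- apply(sizes == 0, 1, any)
  expect_gte(mean(extinct), 0.99)
  first_zero <- apply(sizes[extinct, , drop = FALSE] == 0, 1,
                      function(z) which(z)[1]) - 1
  expect_true(median(first_zero) >= 5 && median(first_zero) <= 9)
})

test_that("one-year expectation matches the closed form below K", {
  # E[N'] ~ phi * n * (1 + 0.5 * pbar * r) - H when psi = 0; the floor on
  # breeding females biases this down by at most r/2 birds.
  for (n0 in c(1000, 32000)) {
    params <- demographic_params(N0 = n0, T = 1)
    H <- 100
    sizes <- simulate_replicates(params, offtake = H, replicates = 1000,
                                 seed = 200 + n0 %% 97)
    final <- sizes[, 2]
    oracle <- 0.84 * n0 * (1 + 0.5 * 0.5 * 1.26) - H
    tol <- 3 * sd(final) / sqrt(length(final)) + 1.26 / 2
    expect_lt(abs(mean(final) - oracle), tol)
  }
})

test_that("per-replicate breeding draws are held constant within a replicate", {
  params <- demographic_params(T = 5)
  a <- simulate_replicates(params, replicates = 10, seed = 31,
                           p_redraw = "per_replicate")
  b <- simulate_replicates(params, replicates = 10, seed = 31,
                           p_redraw = "per_replicate")
  expect_identical(a, b)
  c <- simulate_replicates(params, replicates = 10, seed = 31,
                           p_redraw = "per_year")
  expect_false(identical(a, c))
})

test_that("parameter validation rejects invalid demography", {
  expect_error(demographic_params(phi = 1.2), "phi")
  expect_error(demographic_params(p_sd = -1), "p_sd")
  expect_error(demographic_params(K = 0), "K")
  expect_error(demographic_params(T = -1), "T")
  expect_error(demographic_params(N0 = 10.5), "N0")
})
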