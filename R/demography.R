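#' Draw a yearly breeding proportion
#'
#' The proportion `p` of returning females that successfully breed is
#' drawn from a normal distribution and clamped to `[0, 1]` so that it is
#' always a valid probability. At the default Normal(0.5, 0.05) the clamp
#' is a < 1e-23 event and has no practical effect on results.
#'
#' @param p_mean Mean of the normal distribution.
#' @param p_sd Standard deviation (>= 0); `p_sd = 0` returns `p_mean`
#'   exactly.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, each entry in `[0, 1]`.
#' @export
draw_breeding_proportion <- function(p_mean, p_sd, n = 1) {
  if (!is.numeric(p_sd) || length(p_sd) != 1 || p_sd < 0) {
    stop("`p_sd` must be a single non-negative number", call. = FALSE)
  }
  pmin(pmax(stats::rnorm(n, p_mean, p_sd), 0), 1)
}

#' Binomial survival-and-return of a cohort
#'
#' The number of birds that survive the rest of the flyway and return the
#' following year is a Binomial(`n`, `phi`) draw: mortality is assumed
#' independent across individuals.
#'
#' @param n Cohort size (non-negative count).
#' @param phi Return rate, a probability in `[0, 1]`.
#' @return A single count in `[0, n]`.
#' @export
survive_and_return <- function(n, phi) {
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi > 1) {
    stop("`phi` must be a probability in [0, 1]", call. = FALSE)
  }
  stopifnot("`n` must be a non-negative count" = n >= 0)
  stats::rbinom(1, n, phi)
}

#' Poisson recruitment of juveniles
#'
#' Half the returning adults are assumed female; a proportion `p` of
#' females breed. The number of breeding females `F = floor(0.5 * p *
#' n_adults)` is floored to a natural number, and the juveniles recruited
#' are a Poisson draw with mean `r` times `F`. `F = 0` gives exactly
#' zero recruits.
#'
#' @param n_adults Returning adults (non-negative count).
#' @param p Realised breeding proportion.
#' @param r Mean brood size.
#' @return A single non-negative count.
#' @export
recruit <- function(n_adults, p, r) {
  stopifnot(
    "`n_adults` must be a non-negative count" = n_adults >= 0,
    "`r` must be non-negative" = r >= 0
  )
  f <- floor(0.5 * p * n_adults)
  if (f == 0) return(0L)
  stats::rpois(1, r * f)
}

#' Remove harvested birds from the returned pool
#'
#' Offtake is removed once all individuals (adults and accompanying
#' juveniles) have returned to the staging area, clamped so the count
#' never goes negative.
#'
#' @param pool Birds present after return and recruitment.
#' @param offtake Birds removed by hunting.
#' @return `max(0, pool - offtake)`.
#' @export
apply_offtake <- function(pool, offtake) {
  stopifnot(pool >= 0, offtake >= 0)
  pmax(pool - offtake, 0)
}

#' Density-dependent mortality probability
#'
#' Below carrying capacity every individual survives the density stage;
#' above it the per-capita mortality probability increases linearly,
#' `psi = (N - K) / K`, capped at 1 (complete mortality at `N >= 2K`).
#'
#' @param n_adults Returning adults.
#' @param n_juveniles Recruited juveniles.
#' @param K Carrying capacity (>= 1).
#' @return A probability in `[0, 1]`.
#' @export
density_mortality <- function(n_adults, n_juveniles, K) {
  if (!is.numeric(K) || length(K) != 1 || K < 1) {
    stop("`K` must be a positive carrying capacity", call. = FALSE)
  }
  pmin(pmax((n_adults + n_juveniles - K) / K, 0), 1)
}

#' One year of the stochastic population update
#'
#' Composes the annual processes: binomial survival-and-return of the
#' whole population, Poisson recruitment from the returned adults,
#' removal of `offtake` birds from the combined returned pool (adults and
#' juveniles, without age bias), and binomial density thinning with
#' probability `1 - psi`. Extinction is absorbing: `n = 0` yields 0.
#'
#' By default `psi` is evaluated on the pool after offtake removal (the
#' birds density acts on); set `psi_timing = "pre_offtake"` to evaluate
#' it on the full returned pool as in the plain update equations. At
#' default parameters the two are indistinguishable because `psi > 0`
#' only near carrying capacity.
#'
#' @param n Population size at the start of the year.
#' @param params A [demographic_params()] object.
#' @param offtake Birds removed by hunting this year.
#' @param p Optional fixed breeding proportion; if `NULL` a fresh draw is
#'   taken via [draw_breeding_proportion()].
#' @param psi_timing Whether density mortality is computed on the pool
#'   after (`"post_offtake"`, default) or before (`"pre_offtake"`)
#'   harvest removal.
#' @return A list of class `year_state` with elements `n_adults`,
#'   `n_juveniles`, `p_draw`, `psi` and `n_end`.
#' @export
step_year <- function(n, params, offtake = 0, p = NULL,
                      psi_timing = c("post_offtake", "pre_offtake")) {
  psi_timing <- match.arg(psi_timing)
  stopifnot("`n` must be a non-negative count" = n >= 0)
  if (n == 0) {
    return(structure(list(n_adults = 0L, n_juveniles = 0L,
                          p_draw = NA_real_, psi = 0, n_end = 0L),
                     class = "year_state"))
  }
  na <- survive_and_return(n, params$phi)
  if (is.null(p)) p <- draw_breeding_proportion(params$p_mean, params$p_sd)
  nj <- recruit(na, p, params$r)
  pool <- apply_offtake(na + nj, offtake)
  psi <- if (psi_timing == "post_offtake") {
    density_mortality(pool, 0, params$K)
  } else {
    density_mortality(na, nj, params$K)
  }
  n_end <- stats::rbinom(1, pool, 1 - psi)
  structure(list(n_adults = na, n_juveniles = nj, p_draw = p,
                 psi = psi, n_end = n_end),
            class = "year_state")
}

#' Simulate one population trajectory
#'
#' Runs the annual update for `params$T` years from `params$N0` under a
#' constant yearly offtake. Identical seeds give bit-identical
#' trajectories.
#'
#' @param params A [demographic_params()] object.
#' @param offtake Yearly harvest (birds removed per year).
#' @param seed Optional integer seed for reproducibility.
#' @param p_redraw Whether the breeding proportion is redrawn every year
#'   (`"per_year"`, default) or drawn once and held for the whole
#'   replicate (`"per_replicate"`).
#' @param psi_timing Passed to the yearly update; see [step_year()].
#' @return A list of class `trajectory` with `sizes` (length `T + 1`,
#'   year 0 first) and `extinct` (whether any entry is zero).
#' @export
simulate_trajectory <- function(params, offtake = 0, seed = NULL,
                                p_redraw = c("per_year", "per_replicate"),
                                psi_timing = c("post_offtake", "pre_offtake")) {
  sizes <- simulate_replicates(params, offtake, replicates = 1, seed = seed,
                               p_redraw = p_redraw, psi_timing = psi_timing)
  trajectory(drop(sizes))
}

#' Construct a trajectory object from yearly sizes
#'
#' @param sizes Non-negative yearly population sizes, year 0 first.
#' @return A list of class `trajectory` with `sizes` and `extinct`.
#' @export
trajectory <- function(sizes) {
  stopifnot("sizes must be non-negative" = all(sizes >= 0))
  structure(list(sizes = as.numeric(sizes), extinct = any(sizes == 0)),
            class = "trajectory")
}

#' Simulate many replicate trajectories at once
#'
#' Vectorised engine behind [simulate_trajectory()] and the scenario
#' sweep: all replicates advance together through the yearly update, so a
#' full scenario costs `T` vectorised draws rather than `T * replicates`
#' scalar ones. Extinction is absorbing by construction (binomial and
#' Poisson draws on zero counts stay zero).
#'
#' @inheritParams simulate_trajectory
#' @param replicates Number of independent trajectories.
#' @return A numeric matrix with `replicates` rows and `T + 1` columns
#'   (column 1 is year 0 at `N0`).
#' @export
simulate_replicates <- function(params, offtake = 0, replicates = 1,
                                seed = NULL,
                                p_redraw = c("per_year", "per_replicate"),
                                psi_timing = c("post_offtake", "pre_offtake")) {
  p_redraw <- match.arg(p_redraw)
  psi_timing <- match.arg(psi_timing)
  stopifnot(
    "`offtake` must be a single non-negative count" =
      is.numeric(offtake) && length(offtake) == 1 && offtake >= 0,
    "`replicates` must be >= 1" =
      is.numeric(replicates) && length(replicates) == 1 && replicates >= 1
  )
  if (!is.null(seed)) set.seed(seed)
  R <- as.integer(replicates)
  N <- matrix(0, nrow = R, ncol = params$T + 1)
  N[, 1] <- params$N0
  p_fixed <- if (p_redraw == "per_replicate") {
    draw_breeding_proportion(params$p_mean, params$p_sd, R)
  }
  if (params$T == 0) return(N)
  for (t in seq_len(params$T)) {
    n <- N[, t]
    na <- stats::rbinom(R, n, params$phi)
    p <- if (p_redraw == "per_year") {
      draw_breeding_proportion(params$p_mean, params$p_sd, R)
    } else {
      p_fixed
    }
    f <- floor(0.5 * p * na)
    nj <- stats::rpois(R, params$r * f)
    pool <- pmax(na + nj - offtake, 0)
    psi <- if (psi_timing == "post_offtake") {
      pmin(pmax((pool - params$K) / params$K, 0), 1)
    } else {
      pmin(pmax((na + nj - params$K) / params$K, 0), 1)
    }
    N[, t + 1] <- stats::rbinom(R, pool, 1 - psi)
  }
  N
}

#' @export
print.trajectory <- function(x, ...) {
  T <- length(x$sizes) - 1
  cat(sprintf("Population trajectory over %d years: N0 = %s, NT = %s%s\n",
              T, format(x$sizes[1], big.mark = ","),
              format(x$sizes[T + 1], big.mark = ","),
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}
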