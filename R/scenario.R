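#' Total growth over the management period
#'
#' Proportional change over the whole horizon, `(N_T - N_0) / N_0`.
#' Equals -1 exactly when the population is extinct at the final year.
#'
#' @param traj A [trajectory()] object or a numeric vector of yearly
#'   sizes (year 0 first).
#' @return A single number >= -1.
#' @export
growth_total <- function(traj) {
  sizes <- traj_sizes(traj)
  if (sizes[1] <= 0) {
    stop("total growth is undefined for an initially empty population",
         call. = FALSE)
  }
  (sizes[length(sizes)] - sizes[1]) / sizes[1]
}

#' Mean annual growth rate
#'
#' Mean of the yearly proportional changes `(N_{t+1} - N_t) / N_t` over
#' the years with `N_t > 0`. The rate is undefined once the population is
#' extinct, so post-extinction years are excluded from the mean; the
#' extinction year itself contributes a rate of -1.
#'
#' @inheritParams growth_total
#' @return Mean yearly rate, or `NA` if no year has `N_t > 0`.
#' @export
mean_annual_growth <- function(traj) {
  sizes <- traj_sizes(traj)
  if (sizes[1] <= 0) {
    stop("annual growth is undefined for an initially empty population",
         call. = FALSE)
  }
  if (length(sizes) < 2) return(NA_real_)
  from <- sizes[-length(sizes)]
  to <- sizes[-1]
  rates <- (to - from)[from > 0] / from[from > 0]
  if (length(rates) == 0) return(NA_real_)
  mean(rates)
}

traj_sizes <- function(traj) {
  if (inherits(traj, "trajectory")) traj$sizes else as.numeric(traj)
}

#' Extinction probability of a scenario
#'
#' Fraction of replicates in which the population reaches zero abundance
#' within the horizon.
#'
#' @param x Either a logical vector of per-replicate extinction flags or
#'   a metrics data.frame with an `extinct` column (e.g. from
#'   [run_scenario()]).
#' @return A probability in `[0, 1]`.
#' @export
extinction_probability <- function(x) {
  flags <- if (is.data.frame(x)) x$extinct else x
  if (is.null(flags) || length(flags) == 0) {
    stop("no replicates supplied", call. = FALSE)
  }
  mean(as.logical(flags))
}

#' Run one offtake-by-return-rate scenario
#'
#' Simulates `replicates` independent trajectories at fixed `offtake` and
#' the return rate in `params`, and computes the three population metrics
#' per replicate.
#'
#' @param params A [demographic_params()] object.
#' @param offtake Yearly harvest level.
#' @param replicates Number of replicate trajectories (>= 1).
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_replicates()] (`p_redraw`,
#'   `psi_timing`).
#' @return A data.frame with one row per replicate and columns `offtake`,
#'   `phi`, `replicate`, `growth_total`, `mean_annual_growth`, `extinct`.
#' @export
run_scenario <- function(params, offtake = 0, replicates = 100,
                         seed = NULL, ...) {
  if (!is.numeric(replicates) || length(replicates) != 1 || replicates < 1) {
    stop("`replicates` must be at least 1", call. = FALSE)
  }
  sizes <- simulate_replicates(params, offtake, replicates, seed = seed, ...)
  metrics_from_sizes(sizes, offtake = offtake, phi = params$phi)
}

metrics_from_sizes <- function(sizes, offtake, phi) {
  n0 <- sizes[, 1]
  nT <- sizes[, ncol(sizes)]
  growth <- (nT - n0) / n0
  if (ncol(sizes) >= 2) {
    from <- sizes[, -ncol(sizes), drop = FALSE]
    to <- sizes[, -1, drop = FALSE]
    rates <- (to - from) / from
    rates[from <= 0] <- NA_real_
    annual <- rowMeans(rates, na.rm = TRUE)
    annual[is.nan(annual)] <- NA_real_
  } else {
    annual <- rep(NA_real_, nrow(sizes))
  }
  data.frame(
    offtake = offtake,
    phi = phi,
    replicate = seq_len(nrow(sizes)),
    growth_total = growth,
    mean_annual_growth = annual,
    extinct = apply(sizes == 0, 1, any)
  )
}

#' Define an offtake-by-return-rate scenario grid
#'
#' The default grid matches the study design: yearly offtake from 0 to
#' 10,000 birds in steps of 100, return rate from 0.60 to 0.84, 100
#' replicates per scenario. The return-rate step of 0.02 (13 levels) is a
#' package choice; only the range is fixed by the design.
#'
#' @param offtake_values Strictly increasing non-negative offtake levels.
#' @param phi_values Strictly increasing return rates in `[0, 1]`.
#' @param replicates Replicates per scenario (>= 1).
#' @param base_seed Integer seed from which per-scenario seeds are
#'   derived.
#' @param seed_stride Gap between consecutive scenario seeds; scenario
#'   `i` (offtake varying fastest) uses `base_seed + (i - 1) *
#'   seed_stride`.
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(offtake_values = seq(0, 10000, by = 100),
                          phi_values = seq(0.60, 0.84, by = 0.02),
                          replicates = 100,
                          base_seed = 1L,
                          seed_stride = 1000L) {
  stopifnot(
    "offtake values must be non-empty and strictly increasing" =
      length(offtake_values) > 0 && all(diff(offtake_values) > 0) &&
      all(offtake_values >= 0),
    "phi values must be non-empty, strictly increasing probabilities" =
      length(phi_values) > 0 && all(diff(phi_values) > 0) &&
      all(phi_values >= 0 & phi_values <= 1),
    "`replicates` must be >= 1" = replicates >= 1
  )
  structure(
    list(offtake_values = offtake_values, phi_values = phi_values,
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         seed_stride = as.integer(seed_stride)),
    class = "scenario_grid"
  )
}

#' Sweep the full scenario grid
#'
#' Runs every offtake-by-return-rate combination of the grid with
#' replicated simulations. Row order is deterministic (offtake varying
#' fastest within return rate) and scenario seeds, derived from the
#' grid's `base_seed`, are attached as the `"seeds"` attribute, so the
#' same grid always reproduces the same table.
#'
#' @param grid A [scenario_grid()] object.
#' @param params A [demographic_params()] object; its `phi` is overridden
#'   by each grid value.
#' @param ... Passed to [simulate_replicates()].
#' @return A data.frame of per-replicate metrics
#'   (`|offtake| * |phi| * replicates` rows) with columns as in
#'   [run_scenario()].
#' @export
run_grid <- function(grid, params = demographic_params(), ...) {
  stopifnot(inherits(grid, "scenario_grid"))
  scen <- expand.grid(offtake = grid$offtake_values, phi = grid$phi_values,
                      KEEP.OUT.ATTRS = FALSE)
  scen$seed <- grid$base_seed +
    (seq_len(nrow(scen)) - 1) * as.numeric(grid$seed_stride)
  out <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    p_i <- params
    p_i$phi <- scen$phi[i]
    out[[i]] <- run_scenario(p_i, offtake = scen$offtake[i],
                             replicates = grid$replicates,
                             seed = scen$seed[i], ...)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seeds") <- scen
  res
}

#' Summarise a metrics table per scenario
#'
#' Collapses per-replicate metrics to one row per scenario: mean and
#' Monte-Carlo standard error of each growth metric, and the extinction
#' probability.
#'
#' @param records A per-replicate metrics data.frame from [run_grid()] or
#'   [run_scenario()].
#' @return A data.frame with one row per (offtake, phi) scenario.
#' @export
summarize_scenarios <- function(records) {
  key <- interaction(records$offtake, records$phi, drop = TRUE)
  splits <- split(records, key)
  rows <- lapply(splits, function(d) {
    n <- nrow(d)
    data.frame(
      offtake = d$offtake[1],
      phi = d$phi[1],
      n = n,
      mean_growth = mean(d$growth_total),
      se_growth = stats::sd(d$growth_total) / sqrt(n),
      mean_annual_growth = mean(d$mean_annual_growth, na.rm = TRUE),
      se_annual_growth = stats::sd(d$mean_annual_growth, na.rm = TRUE) /
        sqrt(sum(!is.na(d$mean_annual_growth))),
      extinction_probability = mean(d$extinct)
    )
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$phi, res$offtake), ]
  rownames(res) <- NULL
  res
}
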