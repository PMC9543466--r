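#' Demographic parameters for the staging-ground population model
#'
#' Bundles the parameters of the annual stochastic update: the flyway
#' return rate, the breeding-proportion distribution, mean brood size,
#' carrying capacity, initial abundance and the management horizon.
#' Defaults are the Lesser White-fronted Goose staging-ground values:
#' the Western main subpopulation estimate of 32,000 birds, a carrying
#' capacity of 250,000 reflecting historical abundance, mean brood size
#' 1.26, breeding proportion Normal(0.5, 0.05), and a 20-year horizon.
#'
#' @param phi Mean individual return rate: the probability that a bird
#'   present at the staging area in year `t` survives the rest of the
#'   flyway and returns in year `t + 1`. Must lie in `[0, 1]`.
#' @param p_mean Mean of the breeding proportion `p`, the fraction of
#'   returning females accompanied by recruited offspring.
#' @param p_sd Standard deviation of the breeding proportion; draws are
#'   clamped to `[0, 1]`.
#' @param r Mean brood size (juveniles per successfully breeding female).
#' @param K Carrying capacity: above this population size the per-capita
#'   mortality probability rises linearly.
#' @param N0 Initial population size (individuals, year 0).
#' @param T Horizon in years.
#'
#' @return An object of class `demographic_params`.
#' @examples
#' demographic_params(phi = 0.6)
#' @export
demographic_params <- function(phi = 0.84, p_mean = 0.5, p_sd = 0.05,
                               r = 1.26, K = 250000, N0 = 32000, T = 20) {
  stopifnot(
    "`phi` must lie in [0, 1]" = is.numeric(phi) && length(phi) == 1 &&
      phi >= 0 && phi <= 1,
    "`p_mean` must lie in [0, 1]" = is.numeric(p_mean) && length(p_mean) == 1 &&
      p_mean >= 0 && p_mean <= 1,
    "`p_sd` must be non-negative" = is.numeric(p_sd) && length(p_sd) == 1 &&
      p_sd >= 0,
    "`r` must be non-negative" = is.numeric(r) && length(r) == 1 && r >= 0,
    "`K` must be a count >= 1" = is.numeric(K) && length(K) == 1 &&
      K >= 1 && K == floor(K),
    "`N0` must be a non-negative count" = is.numeric(N0) && length(N0) == 1 &&
      N0 >= 0 && N0 == floor(N0),
    "`T` must be a non-negative integer" = is.numeric(T) && length(T) == 1 &&
      T >= 0 && T == floor(T)
  )
  structure(
    list(phi = phi, p_mean = p_mean, p_sd = p_sd, r = r,
         K = K, N0 = N0, T = T),
    class = "demographic_params"
  )
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Staging-ground demographic parameters\n")
  cat(sprintf("  return rate (phi):      %.3f\n", x$phi))
  cat(sprintf("  breeding proportion p:  Normal(%.2f, %.2f), clamped to [0, 1]\n",
              x$p_mean, x$p_sd))
  cat(sprintf("  mean brood size (r):    %.2f\n", x$r))
  cat(sprintf("  carrying capacity (K):  %s\n", format(x$K, big.mark = ",")))
  cat(sprintf("  initial size (N0):      %s\n", format(x$N0, big.mark = ",")))
  cat(sprintf("  horizon (T):            %d years\n", x$T))
  invisible(x)
}
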