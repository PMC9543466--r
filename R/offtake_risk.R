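#' Expected accidental offtake from a hunting quota
#'
#' Links the licensed goose-hunting quota to the protected species:
#' `quota * misid_rate`, where the misidentification rate is the number
#' of protected birds shot per legally hunted goose. With the 2017
#' northern-Kazakhstan quota of 71,240 and field misidentification rates
#' of 1 per 100 (up to 1 per 20 in the worst-affected area), this gives
#' roughly 700 (up to ~3,500) protected geese killed accidentally per
#' season.
#'
#' @param quota Licensed goose offtake limit (birds per season).
#' @param misid_rate Protected birds per legally hunted goose, in
#'   `[0, 1]`.
#' @return Expected accidental offtake (birds per season).
#' @examples
#' expected_accidental_offtake(71240, 1 / 100) # ~700
#' expected_accidental_offtake(71240, 1 / 20)  # extreme: ~3,500
#' @export
expected_accidental_offtake <- function(quota, misid_rate) {
  stopifnot("`quota` must be non-negative" = all(quota >= 0))
  if (any(misid_rate < 0 | misid_rate > 1)) {
    stop("`misid_rate` must lie in [0, 1]", call. = FALSE)
  }
  quota * misid_rate
}

#' Classify an offtake level against the simulated scenario grid
#'
#' Looks up an offtake estimate on a simulated metrics table and reports,
#' for each return rate, whether the population is growing, declining, or
#' at extinction risk at the nearest simulated offtake level, together
#' with the smallest return rate that still yields positive mean growth.
#'
#' Classification per return rate: `"extinction-risk"` when the
#' replicate extinction probability is at least `risk_level`, otherwise
#' `"declining"` when mean total growth is negative, otherwise
#' `"growing"`.
#'
#' @param offtake Offtake estimate (birds per year); must lie within the
#'   simulated offtake range.
#' @param records Per-replicate metrics data.frame from [run_grid()].
#' @param risk_level Extinction probability at or above which a scenario
#'   is classed as extinction risk.
#' @return A list of class `offtake_risk_report`: `offtake` (requested),
#'   `offtake_used` (nearest simulated level), `by_phi` (data.frame
#'   `phi, mean_growth, extinction_probability, class`), and
#'   `min_phi_growing` (`NA` if no return rate sustains growth).
#' @export
offtake_risk_report <- function(offtake, records, risk_level = 0.5) {
  lv <- sort(unique(records$offtake))
  if (offtake < min(lv) || offtake > max(lv)) {
    stop("`offtake` lies outside the simulated grid range", call. = FALSE)
  }
  used <- lv[which.min(abs(lv - offtake))]
  summ <- summarize_scenarios(records[records$offtake == used, ])
  cls <- ifelse(summ$extinction_probability >= risk_level, "extinction-risk",
                ifelse(summ$mean_growth < 0, "declining", "growing"))
  by_phi <- data.frame(phi = summ$phi,
                       mean_growth = summ$mean_growth,
                       extinction_probability = summ$extinction_probability,
                       class = cls)
  growing <- by_phi$phi[by_phi$class == "growing"]
  structure(list(offtake = offtake, offtake_used = used, by_phi = by_phi,
                 min_phi_growing = if (length(growing)) min(growing)
                                   else NA_real_),
            class = "offtake_risk_report")
}

#' @export
print.offtake_risk_report <- function(x, ...) {
  cat(sprintf("Risk classification at offtake %s (nearest simulated: %s)\n",
              format(x$offtake, big.mark = ","),
              format(x$offtake_used, big.mark = ",")))
  print(x$by_phi, row.names = FALSE, digits = 3)
  if (is.na(x$min_phi_growing)) {
    cat("No simulated return rate sustains positive growth at this offtake.\n")
  } else {
    cat(sprintf("Smallest return rate with positive mean growth: %.2f\n",
                x$min_phi_growing))
  }
  invisible(x)
}
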