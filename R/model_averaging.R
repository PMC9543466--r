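#' Summarise a candidate model for selection and averaging
#'
#' A lightweight container for what selection and averaging need from a
#' fitted candidate model: its AICc and its per-term coefficient
#' estimates (optionally with standard errors). Model fitting itself is
#' left to whichever engine produced the candidates (lm/glm, mixed-model
#' packages, ...); see [model_summary_from_fit()] for a convenience
#' extractor.
#'
#' @param aicc Small-sample-corrected AIC of the model.
#' @param coefficients Named numeric vector of term estimates.
#' @param se Optional named numeric vector of standard errors covering
#'   the same terms.
#' @param label Optional model label.
#' @return Object of class `model_summary`.
#' @export
model_summary <- function(aicc, coefficients, se = NULL, label = NULL) {
  stopifnot(
    "`aicc` must be a single finite number" =
      is.numeric(aicc) && length(aicc) == 1 && is.finite(aicc),
    "`coefficients` must be a named numeric vector" =
      is.numeric(coefficients) && !is.null(names(coefficients)) &&
      all(nzchar(names(coefficients)))
  )
  if (!is.null(se)) {
    stopifnot("`se` must cover the same terms as `coefficients`" =
                setequal(names(se), names(coefficients)))
    se <- se[names(coefficients)]
  }
  structure(list(aicc = aicc, coefficients = coefficients, se = se,
                 terms = names(coefficients), label = label),
            class = "model_summary")
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)` with `k` the number of
#' estimated parameters and `n` the number of observations; infinite when
#' `n <= k + 1`.
#'
#' @param fit A fitted model with `logLik()` and `nobs()` methods.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Build a model summary from a fitted model
#'
#' Extracts AICc and fixed-effect coefficients from a fitted `lm`/`glm`
#' (or, when the `lme4` package is available, a mixed model) into a
#' [model_summary()].
#'
#' @param fit The fitted model.
#' @param label Optional model label.
#' @return A `model_summary`.
#' @export
model_summary_from_fit <- function(fit, label = NULL) {
  coefs <- if (inherits(fit, "merMod") &&
               requireNamespace("lme4", quietly = TRUE)) {
    lme4::fixef(fit)
  } else {
    stats::coef(fit)
  }
  model_summary(aicc(fit), coefs, label = label)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with `delta_i`
#' the AICc difference from the best model.
#'
#' @param aicc_values Numeric vector of AICc scores.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Top model set by AICc difference
#'
#' Retains the candidates strictly within `delta` AICc of the best model
#' (ties at exactly `delta` are excluded), sorted by ascending AICc.
#'
#' @param candidates List of [model_summary()] objects.
#' @param delta AICc difference cut-off (default 4).
#' @return The retained candidates, a list of class `model_set` with the
#'   AICc differences attached as attribute `"delta_aicc"`.
#' @export
aicc_top_set <- function(candidates, delta = 4) {
  if (length(candidates) == 0) {
    stop("no candidate models supplied", call. = FALSE)
  }
  stopifnot(all(vapply(candidates, inherits, logical(1), "model_summary")))
  scores <- vapply(candidates, `[[`, numeric(1), "aicc")
  keep <- which(scores - min(scores) < delta)
  keep <- keep[order(scores[keep])]
  out <- candidates[keep]
  attr(out, "delta_aicc") <- scores[keep] - min(scores)
  class(out) <- c("model_set", "list")
  out
}

#' Natural model averaging over a top model set
#'
#' Computes Akaike weights over the set and averages each term only over
#' the models that contain it, renormalizing the weights within that
#' subset (the "natural" averaging method, as opposed to full averaging
#' which shrinks absent terms towards zero). A term appearing in a single
#' model keeps that model's estimate unchanged; a term present in every
#' model gets the ordinary Akaike-weighted average.
#'
#' @param top_set A `model_set` from [aicc_top_set()], or a list of
#'   [model_summary()] objects.
#' @return data.frame with one row per term: `term`, `estimate`
#'   (natural-averaged coefficient), `n_models` (models containing the
#'   term) and `weight` (summed unrenormalized Akaike weight of those
#'   models).
#' @export
natural_model_average <- function(top_set) {
  if (length(top_set) == 0) {
    stop("the top model set is empty", call. = FALSE)
  }
  scores <- vapply(top_set, `[[`, numeric(1), "aicc")
  w <- akaike_weights(scores)
  terms <- unique(unlist(lapply(top_set, `[[`, "terms")))
  rows <- lapply(terms, function(tm) {
    has <- vapply(top_set, function(m) tm %in% m$terms, logical(1))
    wi <- w[has] / sum(w[has])
    est <- sum(wi * vapply(top_set[has], function(m) m$coefficients[[tm]],
                           numeric(1)))
    data.frame(term = tm, estimate = est, n_models = sum(has),
               weight = sum(w[has]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
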