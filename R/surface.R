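#' Fit a smooth response surface of a population metric
#'
#' Fits a generalised additive model of a metric over the (offtake,
#' return rate) plane: a Gaussian-family smooth of per-replicate growth,
#' or a binomial-family smooth of per-scenario extinction counts. The
#' default smoother is an isotropic thin-plate regression spline on
#' standardized covariates — the two axes differ by several orders of
#' magnitude, so isotropy is only meaningful after rescaling — with the
#' basis dimension left to `mgcv`'s default and the effective complexity
#' chosen by GCV. A tensor-product smooth on the raw scales is available
#' as `smoother = "tensor"`. Because the fitted surface is smooth, grid
#' predictions can differ visibly from raw replicate means where the
#' response is steep; thresholds extracted from fits therefore carry the
#' smoother specification as provenance.
#'
#' @param records Per-replicate metrics data.frame from [run_grid()].
#' @param metric One of `"growth_total"`, `"mean_annual_growth"`,
#'   `"extinct"`. The extinction metric is fitted with a binomial family
#'   on per-scenario counts; the growth metrics with a Gaussian family on
#'   per-replicate values.
#' @param smoother `"isotropic"` (thin-plate on standardized axes,
#'   default) or `"tensor"` (tensor product on raw axes).
#' @param k Optional basis dimension passed to the smooth; `NULL` uses
#'   the `mgcv` default.
#' @return An object of class `surface_fit` with elements `metric`,
#'   `family`, `model` (the `gam` fit), `grid` (data.frame `offtake,
#'   phi, predicted` over the training scenarios), and `smoother_spec`.
#' @export
fit_metric_surface <- function(records,
                               metric = c("growth_total",
                                          "mean_annual_growth",
                                          "extinct"),
                               smoother = c("isotropic", "tensor"),
                               k = NULL) {
  metric <- match.arg(metric)
  smoother <- match.arg(smoother)
  if (length(unique(records$offtake)) < 2 || length(unique(records$phi)) < 2) {
    stop("surface fitting needs at least 2 distinct values on each axis",
         call. = FALSE)
  }
  family <- if (metric == "extinct") stats::binomial() else stats::gaussian()
  scaling <- list(
    off_center = mean(records$offtake), off_scale = stats::sd(records$offtake),
    phi_center = mean(records$phi), phi_scale = stats::sd(records$phi)
  )

  if (metric == "extinct") {
    agg <- stats::aggregate(extinct ~ offtake + phi, records,
                            function(z) c(sum(z), length(z)))
    dat <- data.frame(offtake = agg$offtake, phi = agg$phi,
                      n_ext = agg$extinct[, 1], n = agg$extinct[, 2])
    dat$y <- cbind(dat$n_ext, dat$n - dat$n_ext)
  } else {
    dat <- records[!is.na(records[[metric]]),
                   c("offtake", "phi", metric)]
    names(dat)[3] <- "y"
  }
  dat$off_s <- (dat$offtake - scaling$off_center) / scaling$off_scale
  dat$phi_s <- (dat$phi - scaling$phi_center) / scaling$phi_scale

  n_pts <- nrow(unique(records[, c("offtake", "phi")]))
  kk <- if (is.null(k)) min(30, n_pts - 1) else k
  form <- if (smoother == "isotropic") {
    y ~ s(off_s, phi_s, k = kk)
  } else {
    kt <- if (is.null(k)) {
      pmin(5, c(length(unique(records$offtake)),
                length(unique(records$phi))))
    } else {
      k
    }
    y ~ te(offtake, phi, k = kt)
  }
  environment(form) <- environment()
  model <- mgcv::gam(form, family = family, data = dat)

  pts <- unique(records[, c("offtake", "phi")])
  pts <- pts[order(pts$phi, pts$offtake), ]
  rownames(pts) <- NULL
  fit <- structure(
    list(metric = metric,
         family = family$family,
         model = model,
         smoother_spec = paste0(
           if (smoother == "isotropic") {
             "thin-plate s(offtake, phi) on standardized covariates"
           } else {
             "tensor product te(offtake, phi)"
           },
           ", k = ", if (is.null(k)) "mgcv default" else k,
           ", family = ", family$family),
         scaling = scaling,
         train_range = list(offtake = range(records$offtake),
                            phi = range(records$phi))),
    class = "surface_fit"
  )
  pts$predicted <- predict(fit, pts)
  fit$grid <- pts
  fit
}

#' Predict from a fitted metric surface
#'
#' Predictions are restricted to the hull of the training grid: requests
#' outside the fitted offtake or return-rate range are an error, never an
#' extrapolation. Binomial-family predictions are on the probability
#' scale.
#'
#' @param object A `surface_fit`.
#' @param newdata data.frame with columns `offtake` and `phi`.
#' @param ... Unused.
#' @return Numeric vector of predicted metric values.
#' @export
predict.surface_fit <- function(object, newdata, ...) {
  rng <- object$train_range
  if (any(newdata$offtake < rng$offtake[1] | newdata$offtake > rng$offtake[2]) ||
      any(newdata$phi < rng$phi[1] | newdata$phi > rng$phi[2])) {
    stop("prediction outside the fitted grid is not supported",
         call. = FALSE)
  }
  nd <- newdata
  nd$off_s <- (nd$offtake - object$scaling$off_center) / object$scaling$off_scale
  nd$phi_s <- (nd$phi - object$scaling$phi_center) / object$scaling$phi_scale
  as.numeric(mgcv::predict.gam(object$model, nd, type = "response"))
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("Smooth surface of %s over (offtake, phi)\n", x$metric))
  cat(sprintf("  smoother: %s\n", x$smoother_spec))
  cat(sprintf("  grid: %d points, offtake %g-%g, phi %g-%g\n",
              nrow(x$grid), x$train_range$offtake[1], x$train_range$offtake[2],
              x$train_range$phi[1], x$train_range$phi[2]))
  invisible(x)
}

# Linear interpolation of the x position where y crosses `level` between
# grid points, scanning upward in x; direction = "down" finds the first
# descent through the level, "up" the first ascent. NA when no crossing.
.first_crossing <- function(x, y, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (direction == "down") {
    above <- y >= level
    if (!above[1]) return(list(x = NA_real_, state = "below"))
    i <- which(!above)[1]
    if (is.na(i)) return(list(x = NA_real_, state = "above"))
  } else {
    above <- y >= level
    if (above[1]) return(list(x = x[1], state = "at_start"))
    i <- which(above)[1]
    if (is.na(i)) return(list(x = NA_real_, state = "below"))
  }
  x0 <- x[i - 1]; x1 <- x[i]
  y0 <- y[i - 1]; y1 <- y[i]
  list(x = x0 + (x1 - x0) * (level - y0) / (y1 - y0), state = "crossing")
}

#' Zero-growth frontier of a fitted growth surface
#'
#' For each return rate, the smallest offtake at which the predicted
#' growth surface crosses zero (linear interpolation between adjacent
#' prediction-grid offtakes), or `NA` where predicted growth is negative
#' at every offtake. The global frontier is the maximum per-phi
#' threshold: the offtake above which growth is negative regardless of
#' return rate.
#'
#' @param fit A Gaussian-family `surface_fit` of a growth metric.
#' @return A list of class `growth_frontier`: `per_phi` (data.frame
#'   `phi, offtake_threshold`), `global` (0 when the surface is negative
#'   everywhere), and `smoother_spec`.
#' @export
zero_growth_frontier <- function(fit) {
  stopifnot(inherits(fit, "surface_fit"))
  if (fit$family != "gaussian") {
    stop("the zero-growth frontier needs a Gaussian-family growth surface",
         call. = FALSE)
  }
  per_phi <- lapply(split(fit$grid, fit$grid$phi), function(d) {
    d <- d[order(d$offtake), ]
    cr <- .first_crossing(d$offtake, d$predicted, 0, "down")
    data.frame(phi = d$phi[1], offtake_threshold = cr$x)
  })
  per_phi <- do.call(rbind, per_phi)
  rownames(per_phi) <- NULL
  global <- if (all(is.na(per_phi$offtake_threshold))) 0 else {
    max(per_phi$offtake_threshold, na.rm = TRUE)
  }
  structure(list(per_phi = per_phi, global = global,
                 smoother_spec = fit$smoother_spec),
            class = "growth_frontier")
}

#' Extinction-probability contour of a fitted surface
#'
#' For each return rate, the interpolated offtake at which the predicted
#' extinction probability first rises through `level`; `NA` where it
#' never reaches the level, and the smallest grid offtake where the
#' surface already exceeds it there.
#'
#' @param fit A binomial-family `surface_fit` of the extinction metric.
#' @param level A probability strictly between 0 and 1.
#' @return data.frame with columns `phi` and `offtake_threshold`.
#' @export
probability_contour <- function(fit, level) {
  stopifnot(inherits(fit, "surface_fit"))
  if (fit$family != "binomial") {
    stop("probability contours need a binomial-family extinction surface",
         call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  out <- lapply(split(fit$grid, fit$grid$phi), function(d) {
    d <- d[order(d$offtake), ]
    cr <- .first_crossing(d$offtake, d$predicted, level, "up")
    data.frame(phi = d$phi[1], offtake_threshold = cr$x)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Raw-grid (unsmoothed) thresholds
#'
#' Empirical counterpart of the smoothed frontier and contours, computed
#' directly on per-scenario replicate means: for each return rate, the
#' interpolated offtake where mean growth crosses zero and where the
#' empirical extinction probability rises through `level`. Reported
#' alongside the smoothed thresholds because the two diverge where the
#' surface is steep.
#'
#' @param records Per-replicate metrics data.frame from [run_grid()].
#' @param level Extinction-probability level for the empirical contour.
#' @return data.frame with columns `phi`, `zero_growth_offtake`,
#'   `extinction_offtake`.
#' @export
empirical_thresholds <- function(records, level = 0.9) {
  summ <- summarize_scenarios(records)
  out <- lapply(split(summ, summ$phi), function(d) {
    d <- d[order(d$offtake), ]
    g <- .first_crossing(d$offtake, d$mean_growth, 0, "down")
    e <- .first_crossing(d$offtake, d$extinction_probability, level, "up")
    data.frame(phi = d$phi[1], zero_growth_offtake = g$x,
               extinction_offtake = e$x)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sensitivity of harvest thresholds to carrying capacity
#'
#' Re-runs a scenario grid at each supplied carrying capacity, refits the
#' growth and extinction surfaces, and compares the extracted thresholds
#' across `K` values. Declining trajectories never approach carrying
#' capacity, so thresholds are expected to be insensitive to `K`.
#'
#' @param params Baseline [demographic_params()]; `K` is overridden.
#' @param K_values At least two carrying capacities.
#' @param grid A [scenario_grid()]; a reduced grid keeps this affordable.
#' @param levels Extinction-probability contour levels.
#' @param ... Passed to [run_grid()].
#' @return A list of class `k_sensitivity`: `thresholds` (per K and phi),
#'   `global_frontiers` (per K), and `max_shift` (largest absolute
#'   threshold difference across K, per quantity).
#' @export
k_sensitivity <- function(params, K_values, grid, levels = c(0.1, 0.9), ...) {
  if (length(K_values) < 2) {
    stop("carrying-capacity sensitivity needs at least two K values",
         call. = FALSE)
  }
  res <- list(); globals <- numeric(length(K_values))
  for (i in seq_along(K_values)) {
    p_i <- params
    p_i$K <- K_values[i]
    rec <- run_grid(grid, p_i, ...)
    gfit <- fit_metric_surface(rec, "growth_total")
    efit <- fit_metric_surface(rec, "extinct")
    fr <- zero_growth_frontier(gfit)
    tab <- fr$per_phi
    names(tab)[2] <- "zero_growth_offtake"
    for (lv in levels) {
      ct <- probability_contour(efit, lv)
      tab[[sprintf("p%02.0f_offtake", 100 * lv)]] <- ct$offtake_threshold
    }
    tab$K <- K_values[i]
    res[[i]] <- tab
    globals[i] <- fr$global
  }
  thr <- do.call(rbind, res)
  qty <- setdiff(names(thr), c("phi", "K"))
  max_shift <- vapply(qty, function(col) {
    wide <- stats::reshape(thr[, c("phi", "K", col)], direction = "wide",
                           idvar = "phi", timevar = "K")
    vals <- as.matrix(wide[, -1, drop = FALSE])
    keep <- stats::complete.cases(vals)
    if (!any(keep)) return(NA_real_)
    max(apply(vals[keep, , drop = FALSE], 1, function(z) diff(range(z))))
  }, numeric(1))
  structure(list(thresholds = thr,
                 global_frontiers = data.frame(K = K_values,
                                               zero_growth_global = globals),
                 max_shift = max_shift),
            class = "k_sensitivity")
}

#' @export
print.k_sensitivity <- function(x, ...) {
  cat("Carrying-capacity sensitivity of harvest thresholds\n")
  print(x$global_frontiers, row.names = FALSE)
  cat("Largest threshold shift across K (per quantity):\n")
  print(round(x$max_shift, 1))
  invisible(x)
}
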