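#' Resampling configuration for the bias-correction fit
#'
#' The MAT systematically under-predicts dense forest because modern
#' Europe retains little of it; the correction curve is estimated from the
#' two-fold cross-validation pairs after a window resampling step that
#' counters the predominance of low-cover samples: per iteration, a number
#' of 5-percentage-point-wide windows are placed uniformly at random along
#' the modeled axis and the quartiles of the pairs inside each window are
#' extracted as support points.
#'
#' @param width window width (percentage points).
#' @param windows windows placed per iteration.
#' @param iterations resampling iterations.
#' @param grid percentile grid for the quantile-quantile reduction (odd
#'   percentiles 1, 3, ..., 99 -- every second percentile between 1 and 100).
#' @param spar optional `smooth.spline` smoothing parameter; `NULL` =
#'   generalized cross-validation.
#' @param min_pairs minimum pairs for a window to be used.
#' @param seed RNG seed.
#' @export
resample_config <- function(width = 5, windows = 10, iterations = 99,
                            grid = seq(1, 99, by = 2), spar = NULL,
                            min_pairs = 4, seed = NULL) {
  stopifnot(width > 0, all(diff(grid) > 0), all(grid > 0 & grid < 100))
  list(width = width, windows = windows, iterations = iterations,
       grid = grid, spar = spar, min_pairs = min_pairs, seed = seed)
}

#' Fit the quantile-mapping calibration curve
#'
#' Estimates a monotone mapping from raw MAT predictions to bias-corrected
#' forest cover. Robust empirical quantiles of modeled vs. observed cover
#' are built from window-resampled quartiles (see [resample_config()]),
#' reduced to paired quantiles on the percentile grid, fitted with a smooth
#' regression spline, and projected onto the monotone cone (isotonic
#' regression on a dense grid) so the calibration is order-preserving.
#' Outputs are clamped to `[0, 100]`.
#'
#' @param modeled,observed paired cover values (percent), e.g. the pooled
#'   two-fold cross-validation pairs; at least 100 pairs.
#' @param config a [resample_config()].
#' @return an object of class `"calibration_curve"`: the fitted evaluator
#'   plus the quantile-quantile support points and diagnostics (median
#'   residual per 10-point observed class before and after correction).
#' @export
fit_curve <- function(modeled, observed, config = resample_config()) {
  ok <- !is.na(modeled) & !is.na(observed)
  modeled <- modeled[ok]; observed <- observed[ok]
  if (length(modeled) < 100) stop("need at least 100 (modeled, observed) pairs")
  if (!is.null(config$seed)) set.seed(config$seed)
  qm <- qo <- vector("list", config$iterations)
  used <- 0L
  for (it in seq_len(config$iterations)) {
    starts <- stats::runif(config$windows, 0, 100 - config$width)
    pm <- po <- numeric(0)
    for (s in starts) {
      inw <- modeled >= s & modeled < s + config$width
      if (sum(inw) < config$min_pairs) next  # skipped, too few pairs
      pm <- c(pm, stats::quantile(modeled[inw], c(0.25, 0.5, 0.75), names = FALSE))
      po <- c(po, stats::quantile(observed[inw], c(0.25, 0.5, 0.75), names = FALSE))
      used <- used + 1L
    }
    qm[[it]] <- pm; qo[[it]] <- po
  }
  pm <- unlist(qm); po <- unlist(qo)
  if (!length(pm)) stop("all resampling windows were empty; cannot fit curve")
  qx <- stats::quantile(pm, config$grid / 100, names = FALSE)
  qy <- stats::quantile(po, config$grid / 100, names = FALSE)
  fitfun <- if (length(unique(qx)) >= 4) {
    sp <- if (is.null(config$spar)) stats::smooth.spline(qx, qy)
          else stats::smooth.spline(qx, qy, spar = config$spar)
    function(x) stats::predict(sp, x)$y
  } else {
    stop("degenerate quantile-quantile support (fewer than 4 distinct modeled quantiles)")
  }
  xg <- seq(0, 100, by = 0.25)
  yg <- fitfun(xg)
  yg <- stats::isoreg(xg, yg)$yf        # enforce monotonicity
  yg <- pmin(100, pmax(0, yg))
  evaluator <- stats::approxfun(xg, yg, rule = 2)
  corrected <- evaluator(modeled)
  diag_pre <- residual_class_medians(list(residuals = modeled - observed, obs = observed))
  diag_post <- residual_class_medians(list(residuals = corrected - observed, obs = observed))
  structure(list(qq = data.frame(modeled = qx, observed = qy),
                 grid_x = xg, grid_y = yg, fun = evaluator,
                 n_windows_used = used, config = config,
                 diagnostics = data.frame(class = seq(0, 90, 10),
                                          median_resid_pre = as.numeric(diag_pre),
                                          median_resid_post = as.numeric(diag_post))),
            class = "calibration_curve")
}

#' Apply a calibration curve to MAT predictions
#'
#' Element-wise evaluation of the monotone curve; missing predictions
#' (no-analog samples) stay missing; outputs are clamped to `[0, 100]`.
#' Applied mechanically to all samples regardless of age, composition or
#' location.
#'
#' @param curve a [fit_curve()] result.
#' @param predictions raw predictions (percent) or a `"mat_predict"` table,
#'   in which case the corrected values are added as column `fit_cal`.
#' @export
apply_curve <- function(curve, predictions) {
  if (inherits(predictions, "mat_predict")) {
    predictions$fit_cal <- apply_curve(curve, predictions$fit)
    return(predictions)
  }
  out <- rep(NA_real_, length(predictions))
  ok <- !is.na(predictions)
  out[ok] <- pmin(100, pmax(0, curve$fun(predictions[ok])))
  out
}

#' @export
predict.calibration_curve <- function(object, newdata, ...) apply_curve(object, newdata)

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("quantile-mapping calibration curve (%d windows used, %d qq points)\n",
              x$n_windows_used, nrow(x$qq)))
  cat(sprintf("  corrected(0) = %.1f, corrected(50) = %.1f, corrected(100) = %.1f\n",
              x$fun(0), x$fun(50), x$fun(100)))
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  plot(x$qq$modeled, x$qq$observed, pch = 1, col = "orange",
       xlab = "modeled forest cover (%)", ylab = "observed forest cover (%)",
       xlim = c(0, 100), ylim = c(0, 100), ...)
  graphics::lines(x$grid_x, x$grid_y, col = "red", lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
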