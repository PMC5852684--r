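#' Squared-chord dissimilarity
#'
#' `d(p, q) = sum_k (sqrt(p_k) - sqrt(q_k))^2` between two proportion
#' vectors; ranges over `[0, 2]`, symmetric, and sensitive to differences
#' in minor components -- the standard dissimilarity for pollen data.
#'
#' @param p,q non-negative vectors, each summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @export
squared_chord <- function(p, q, tol = 1e-6) {
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("inputs must be normalized proportion vectors (sum to 1)")
  sum((sqrt(p) - sqrt(q))^2)
}

# pairwise squared-chord distances between row-normalized matrices:
# d_ij = |sx_i|^2 + |sy_j|^2 - 2 sx_i . sy_j = 2 - 2 sx_i . sy_j
chord_dist_matrix <- function(x, y) {
  sx <- sqrt(x)
  sy <- sqrt(y)
  d <- 2 - 2 * tcrossprod(sx, sy)
  d[d < 1e-12] <- 0   # exact self-matches stay exactly zero
  d
}

.normalize_rows <- function(x, what = "assemblage") {
  x <- as.matrix(x)
  if (any(x < 0)) stop(what, " values must be non-negative")
  s <- rowSums(x)
  if (any(s <= 0)) stop("all-zero ", what, " vector")
  x / s
}

#' Fit a Modern Analog Technique transfer function
#'
#' Builds the MAT model: the calibration set of modern assemblage vectors
#' (PFT scores or taxon proportions) paired with their forest-cover values.
#' Prediction for a fossil assemblage takes the `k` compositionally closest
#' calibration entries under the squared-chord distance, discards those
#' beyond the dissimilarity threshold `T`, and returns the
#' inverse-distance-weighted mean of their cover values. A fossil sample
#' whose closest analog exceeds `T` is a no-analog situation.
#'
#' @param x matrix of calibration assemblages (one row per sample; rows are
#'   normalized internally).
#' @param y forest-cover values (percent) paired with the rows of `x`.
#' @param k maximum number of analogs (default 8).
#' @param T squared-chord dissimilarity threshold (default 0.3).
#' @param eps zero-distance guard in the analog weights `1/max(d, eps)`.
#' @param ids optional sample identifiers (default rownames of `x`).
#' @return an object of class `"mat"` with `predict`, `print`, `summary`,
#'   `fitted`, `residuals` and `plot` methods. `fitted` and `residuals` are
#'   leave-one-out quantities (each calibration sample predicted from all
#'   the others).
#' @seealso [loo_cv()], [twofold_cv()], [no_analog_rates()], [fit_curve()]
#' @export
mat <- function(x, y, k = 8, T = 0.3, eps = 1e-9, ids = NULL) {
  x <- .normalize_rows(x, "calibration")
  stopifnot(k >= 1, T > 0, length(y) == nrow(x))
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = as.numeric(y), k = k, T = T, eps = eps,
                 ids = as.character(ids), call = match.call()),
            class = "mat")
}

# analog selection for one row of a distance matrix: the k nearest entries
# (all entries tied with the k-th kept), then the threshold T. Ties in d are
# broken by stable id order, so permuting the calibration never changes the
# result.
.select_analogs <- function(d, k, T) {
  ord <- order(d, seq_along(d))
  if (length(d) > k) {
    dk <- d[ord[k]]
    kk <- sum(d <= dk)        # include distance ties at the k-th rank
  } else kk <- length(d)
  sel <- ord[seq_len(kk)]
  sel[d[sel] <= T]
}

.predict_rows <- function(dmat, y, ids, k, T, eps) {
  n <- nrow(dmat)
  fit <- se <- dmin <- rep(NA_real_, n)
  n_used <- integer(n)
  analogs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    dmin[i] <- min(d)
    sel <- .select_analogs(d, k, T)
    n_used[i] <- length(sel)
    if (length(sel)) {
      w <- 1 / pmax(d[sel], eps)
      fit[i] <- sum(w * y[sel]) / sum(w)
      if (length(sel) > 1) se[i] <- stats::sd(y[sel]) / sqrt(length(sel))
      analogs[[i]] <- data.frame(analog = ids[sel], d = d[sel],
                                 cover = y[sel], stringsAsFactors = FALSE)
    }
  }
  list(fit = fit, se = se, n_used = n_used, dmin = dmin, analogs = analogs)
}

#' Predict forest cover for fossil assemblages
#'
#' @param object a fitted [mat()] model.
#' @param newdata matrix of fossil assemblage vectors (rows normalized
#'   internally; columns must match the calibration assemblage space).
#' @param ids optional fossil sample identifiers.
#' @param ... unused.
#' @return a data frame of class `"mat_predict"` with one row per fossil
#'   sample: `id`, `fit` (percent, uncalibrated; `NA` for no-analog),
#'   `se` (standard deviation of the retained analog covers divided by
#'   `sqrt(n_used)`; `NA` when `n_used <= 1`), `n_used`, `d_min`,
#'   `no_analog`. The per-sample analog tables (analog id, squared-chord
#'   distance, cover) are in attribute `"analogs"`.
#' @export
predict.mat <- function(object, newdata, ids = NULL, ...) {
  newdata <- .normalize_rows(newdata, "fossil")
  if (ncol(newdata) != ncol(object$x))
    stop("fossil assemblages must live in the calibration assemblage space")
  if (is.null(ids)) ids <- rownames(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  dmat <- chord_dist_matrix(newdata, object$x)
  r <- .predict_rows(dmat, object$y, object$ids, object$k, object$T, object$eps)
  out <- data.frame(id = as.character(ids), fit = r$fit, se = r$se,
                    n_used = r$n_used, d_min = r$dmin,
                    no_analog = r$n_used == 0, stringsAsFactors = FALSE)
  attr(out, "analogs") <- r$analogs
  class(out) <- c("mat_predict", class(out))
  out
}

#' @export
print.mat <- function(x, ...) {
  cat("Modern Analog Technique transfer function\n")
  cat(sprintf("  calibration: %d samples, %d assemblage components\n",
              nrow(x$x), ncol(x$x)))
  cat(sprintf("  k = %d analogs, squared-chord threshold T = %g\n", x$k, x$T))
  cat(sprintf("  cover range: [%.1f, %.1f] %%\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
fitted.mat <- function(object, ...) loo_cv(object)$pred

#' @export
residuals.mat <- function(object, ...) {
  cv <- loo_cv(object)
  cv$pred - cv$obs
}

#' @export
summary.mat <- function(object, ...) {
  cv <- loo_cv(object)
  structure(list(model = object, loo = cv), class = "summary.mat")
}

#' @export
print.summary.mat <- function(x, ...) {
  print(x$model)
  cat(sprintf("Leave-one-out cross-validation: r^2 = %.3f, RMSEP = %.2f%%\n",
              x$loo$r2, x$loo$rmsep))
  cat(sprintf("  no-analog calibration samples: %d\n", sum(is.na(x$loo$pred))))
  invisible(x)
}

#' @export
plot.mat <- function(x, ...) {
  cv <- loo_cv(x)
  plot(cv$obs, cv$pred, xlab = "observed forest cover (%)",
       ylab = "LOO-predicted forest cover (%)",
       xlim = c(0, 100), ylim = c(0, 100), pch = 16,
       col = grDevices::adjustcolor("forestgreen", 0.6), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
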