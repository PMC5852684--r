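#' Thin-plate spline interpolant in scaled coordinates
#'
#' Polyharmonic radial-basis spline with kernel `eta(r) = r^2 log(r)` and an
#' affine polynomial part, fitted in user-scaled coordinates (the scaling
#' sets the anisotropy of the space-time metric; see
#' [interpolation_config()]). With smoothing `lambda = 0` the evaluator
#' interpolates the data exactly and reproduces affine functions of the
#' scaled coordinates; positive `lambda` smooths. `lambda = NULL` selects
#' smoothing by generalized cross-validation. Duplicate locations (after
#' scaling) are averaged before fitting.
#'
#' @param x numeric matrix of coordinates, one row per point (2- to 4-D).
#' @param y values at the points.
#' @param lambda smoothing parameter (`NULL` = GCV over a log grid, `0` =
#'   exact interpolation).
#' @param scale positive scale factor per coordinate (default all 1).
#' @return an object of class `"tps"` with a `predict` method.
#' @export
tps <- function(x, y, lambda = NULL, scale = NULL) {
  x <- as.matrix(x)
  n0 <- nrow(x)
  d <- ncol(x)
  stopifnot(length(y) == n0)
  if (is.null(scale)) scale <- rep(1, d)
  stopifnot(length(scale) == d, all(scale > 0))
  xs <- sweep(x, 2, scale, `*`)
  # average duplicates
  key <- apply(round(xs, 10), 1, paste, collapse = "_")
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    xs <- apply(xs, 2, function(col) tapply(col, grp, mean))
    if (is.null(dim(xs))) xs <- matrix(xs, ncol = d)
    y <- as.numeric(tapply(y, grp, mean))
  }
  n <- nrow(xs)
  if (n < d + 2) stop("need at least ", d + 2, " distinct points")
  P <- cbind(1, xs)
  if (qr(P)$rank < d + 1)
    stop("degenerate point configuration: polynomial part rank-deficient ",
         "(points affinely dependent in scaled space)")
  K <- .tps_kernel_matrix(xs, xs)
  if (is.null(lambda)) {
    lgrid <- 10^seq(-8, 3, length.out = 23)
    gcvs <- vapply(lgrid, function(l) .tps_gcv(K, P, y, l), 0)
    lambda <- lgrid[which.min(gcvs)]
  }
  coefs <- .tps_solve(K, P, y, lambda)
  structure(list(xs = xs, scale = scale, c = coefs$c, d = coefs$d,
                 lambda = lambda, y = y),
            class = "tps")
}

.tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

.tps_kernel_matrix <- function(a, b) {
  # squared Euclidean distances via the expansion trick
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- pmax(outer(aa, bb, `+`) - 2 * tcrossprod(a, b), 0)
  .tps_eta(sqrt(d2))
}

.tps_solve <- function(K, P, y, lambda) {
  n <- nrow(K)
  p <- ncol(P)
  M <- rbind(cbind(K + n * lambda * diag(n), P),
             cbind(t(P), matrix(0, p, p)))
  sol <- solve(M, c(y, rep(0, p)))
  list(c = sol[seq_len(n)], d = sol[n + seq_len(p)])
}

.tps_gcv <- function(K, P, y, lambda) {
  n <- nrow(K)
  p <- ncol(P)
  M <- rbind(cbind(K + n * lambda * diag(n), P),
             cbind(t(P), matrix(0, p, p)))
  Minv_y <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv_y)) return(Inf)
  # influence matrix: fitted = [K P] M^{-1}[, 1:n] y
  A <- cbind(K, P) %*% Minv_y[, seq_len(n), drop = FALSE]
  fitted <- as.numeric(A %*% y)
  tr <- sum(diag(A))
  denom <- (1 - tr / n)^2
  if (denom <= 0) return(Inf)
  mean((y - fitted)^2) / denom
}

#' @rdname tps
#' @param object a fitted `"tps"`.
#' @param newx matrix of prediction coordinates (unscaled).
#' @param ... unused.
#' @export
predict.tps <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  xs <- sweep(newx, 2, object$scale, `*`)
  K <- .tps_kernel_matrix(xs, object$xs)
  as.numeric(K %*% object$c + cbind(1, xs) %*% object$d)
}

#' @export
print.tps <- function(x, ...) {
  cat(sprintf("thin-plate spline: %d points, %d-D, lambda = %.3g\n",
              nrow(x$xs), ncol(x$xs), x$lambda))
  invisible(x)
}

#' Delete-one-site jackknife standard error of a TPS prediction
#'
#' Refits the spline `n` times, each time deleting one site, and returns
#' the jackknife standard error of the prediction at each query point --
#' the resampling estimate of the uncertainty contributed by the
#' interpolation itself.
#'
#' @param x,y,lambda,scale as in [tps()] (`lambda` fixed across refits; if
#'   `NULL` it is first selected once by GCV on the full data).
#' @param newx matrix of query coordinates.
#' @export
tps_jackknife_se <- function(x, y, newx, lambda = NULL, scale = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  full <- tps(x, y, lambda = lambda, scale = scale)
  lambda <- full$lambda
  preds <- matrix(NA_real_, n, nrow(as.matrix(newx)))
  for (i in seq_len(n)) {
    fit_i <- tryCatch(tps(x[-i, , drop = FALSE], y[-i], lambda = lambda, scale = scale),
                      error = function(e) NULL)
    if (!is.null(fit_i)) preds[i, ] <- predict(fit_i, newx)
  }
  ok <- stats::complete.cases(preds)
  preds <- preds[ok, , drop = FALSE]
  m <- nrow(preds)
  if (m < 3) return(rep(NA_real_, ncol(preds)))
  centers <- colMeans(preds)
  sqrt((m - 1) / m * colSums(sweep(preds, 2, centers)^2))
}
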