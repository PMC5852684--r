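# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they check the optimized paths from the outside.

# squared-chord distance, element by element
oracle_chord <- function(p, q) {
  s <- 0
  for (k in seq_along(p)) s <- s + (sqrt(p[k]) - sqrt(q[k]))^2
  s
}

# Gaussian-weighted extraction by an explicit double loop over all pixels
oracle_extract <- function(raster, lon, lat, sigma, R = 50000) {
  num <- den <- 0
  ny <- nrow(raster$values); nx <- ncol(raster$values)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    v <- raster$values[i, j]
    if (v == raster$nodata || v == raster$water) next
    clon <- raster$xll + (j - 0.5) * raster$cellsize
    clat <- raster$yll + (ny - i + 0.5) * raster$cellsize
    r <- gc_distance(lon, lat, clon, clat)
    if (r > R) next
    w <- exp(-r^2 / (2 * sigma^2))
    num <- num + w * v
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

# MAT prediction for one fossil vector by exhaustive sort
oracle_mat_predict <- function(fossil, cal_x, cal_y, k, T, eps = 1e-9) {
  d <- apply(cal_x, 1, function(row) oracle_chord(fossil, row))
  ord <- order(d)
  kk <- min(k, length(d))
  sel <- ord[seq_len(kk)]
  if (kk < length(d)) {
    ties <- setdiff(which(d == d[ord[kk]]), sel)
    sel <- c(sel, ties)
  }
  sel <- sel[d[sel] <= T]
  if (!length(sel)) return(list(fit = NA_real_, se = NA_real_, n = 0L))
  w <- 1 / pmax(d[sel], eps)
  fit <- sum(w * cal_y[sel]) / sum(w)
  se <- if (length(sel) > 1) sd(cal_y[sel]) / sqrt(length(sel)) else NA_real_
  list(fit = fit, se = se, n = length(sel))
}

# naive thin-plate spline: dense system assembled with loops
oracle_tps_fit <- function(x, y, lambda = 0, scale = rep(1, ncol(x))) {
  xs <- x
  for (j in seq_len(ncol(x))) xs[, j] <- x[, j] * scale[j]
  n <- nrow(xs); d <- ncol(xs)
  eta <- function(r) if (r > 0) r^2 * log(r) else 0
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- eta(sqrt(sum((xs[i, ] - xs[j, ])^2)))
  P <- cbind(1, xs)
  M <- rbind(cbind(K + n * lambda * diag(n), P),
             cbind(t(P), matrix(0, d + 1, d + 1)))
  sol <- solve(M, c(y, rep(0, d + 1)))
  list(xs = xs, scale = scale, cc = sol[1:n], dd = sol[(n + 1):(n + d + 1)],
       eta = eta)
}

oracle_tps_predict <- function(fit, newx) {
  xs <- newx
  for (j in seq_len(ncol(newx))) xs[, j] <- newx[, j] * fit$scale[j]
  out <- numeric(nrow(xs))
  for (i in seq_len(nrow(xs))) {
    s <- fit$dd[1] + sum(fit$dd[-1] * xs[i, ])
    for (j in seq_len(nrow(fit$xs)))
      s <- s + fit$cc[j] * fit$eta(sqrt(sum((xs[i, ] - fit$xs[j, ])^2)))
    out[i] <- s
  }
  out
}

# cosine-latitude area-weighted regional mean by an explicit cell loop
oracle_region_mean <- function(field, poly) {
  ny <- nrow(field$values); nx <- ncol(field$values)
  num <- den <- 0
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    v <- field$values[i, j]
    if (is.na(v)) next
    clon <- field$xll + (j - 0.5) * field$cellsize
    clat <- field$yll + (ny - i + 0.5) * field$cellsize
    if (!mgcv::in.out(rbind(poly, poly[1, ]), cbind(clon, clat))) next
    w <- cos(clat * pi / 180)
    num <- num + w * v
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}
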