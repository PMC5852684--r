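#' Leave-one-out cross-validation of a MAT model
#'
#' Each calibration sample is predicted from all the others. Skill is
#' summarized as `r^2` (squared Pearson correlation between predicted and
#' observed, the transfer-function convention) and RMSEP (root mean square
#' error of prediction, in percent cover). No-analog samples are excluded
#' from the skill statistics but reported.
#'
#' @param object a fitted [mat()] model.
#' @return an object of class `"mat_cv"`: list with `pred`, `obs`, `r2`,
#'   `rmsep`, `residuals` (predicted minus observed) and `classes`
#'   (observed-cover class of each sample in 10-percentage-point bins).
#' @export
loo_cv <- function(object) {
  n <- nrow(object$x)
  if (n < object$k + 1) stop("need at least k + 1 calibration entries")
  dmat <- chord_dist_matrix(object$x, object$x)
  diag(dmat) <- Inf
  r <- .predict_rows(dmat, object$y, object$ids, object$k, object$T, object$eps)
  .cv_result(r$fit, object$y, iterations = 1L)
}

#' Sweep the analog count k by leave-one-out RMSEP
#'
#' @param object a fitted [mat()] model.
#' @param ks candidate `k` values.
#' @return data frame with columns `k`, `rmsep`, `r2`; the RMSEP-minimizing
#'   `k` in attribute `"best_k"`.
#' @export
loo_k_sweep <- function(object, ks = 1:15) {
  res <- do.call(rbind, lapply(ks, function(k) {
    m <- object
    m$k <- k
    cv <- loo_cv(m)
    data.frame(k = k, rmsep = cv$rmsep, r2 = cv$r2)
  }))
  attr(res, "best_k") <- res$k[which.min(res$rmsep)]
  res
}

.cv_result <- function(pred, obs, iterations, per_iter = NULL) {
  ok <- !is.na(pred)
  r2 <- if (sum(ok) >= 3 && stats::sd(obs[ok]) > 0 && stats::sd(pred[ok]) > 0)
    stats::cor(pred[ok], obs[ok])^2 else NA_real_
  rmsep <- sqrt(mean((pred[ok] - obs[ok])^2))
  structure(list(pred = pred, obs = obs, r2 = r2, rmsep = rmsep,
                 residuals = pred - obs,
                 classes = cover_class(obs),
                 iterations = iterations, per_iter = per_iter),
            class = "mat_cv")
}

#' @export
print.mat_cv <- function(x, ...) {
  cat(sprintf("MAT cross-validation (%d iteration%s): r^2 = %s, RMSEP = %.2f%%\n",
              x$iterations, if (x$iterations > 1) "s" else "",
              if (is.na(x$r2)) "undefined" else sprintf("%.3f", x$r2), x$rmsep))
  invisible(x)
}

#' Observed-cover class in 10-percentage-point bins
#'
#' Bins `[0,10), [10,20), ..., [90,100]` partition the cover range; the
#' label is the bin's lower edge.
#' @param x cover values (percent).
#' @export
cover_class <- function(x) {
  cls <- pmin(floor(x / 10), 9) * 10
  factor(cls, levels = seq(0, 90, 10))
}

#' Repeated two-fold cross-validation of a MAT model
#'
#' The calibration set is randomly split into two halves (the first half
#' larger by one for odd sizes); each half predicts the other, and the
#' process is repeated. Per-iteration skill plus the pooled
#' (predicted, observed) pairs -- the input to the bias-correction fit --
#' are returned. Seeded and reproducible. When all observed covers are
#' equal, `r^2` is undefined and flagged `NA`.
#'
#' @param object a fitted [mat()] model.
#' @param iterations number of random splits (999 matches the full
#'   experiment; smaller values give the same contract at less cost).
#' @param seed RNG seed.
#' @return an object of class `"mat_cv"`; `pred`/`obs` are the pooled pairs
#'   across iterations, `per_iter` holds per-iteration `r2` and `rmsep`.
#' @export
twofold_cv <- function(object, iterations = 999, seed = NULL) {
  n <- nrow(object$x)
  if (n < 2 * (object$k + 1)) stop("need at least 2(k + 1) calibration entries")
  if (!is.null(seed)) set.seed(seed)
  dmat <- chord_dist_matrix(object$x, object$x)  # reused across iterations
  n1 <- ceiling(n / 2)
  pred_all <- obs_all <- vector("list", iterations)
  per_iter <- data.frame(iteration = seq_len(iterations), r2 = NA_real_,
                         rmsep = NA_real_)
  for (it in seq_len(iterations)) {
    a <- sort(sample.int(n, n1))
    b <- setdiff(seq_len(n), a)
    pa <- .predict_rows(dmat[a, b, drop = FALSE], object$y[b], object$ids[b],
                        object$k, object$T, object$eps)
    pb <- .predict_rows(dmat[b, a, drop = FALSE], object$y[a], object$ids[a],
                        object$k, object$T, object$eps)
    pred <- c(pa$fit, pb$fit)
    obs <- c(object$y[a], object$y[b])
    ok <- !is.na(pred)
    per_iter$rmsep[it] <- sqrt(mean((pred[ok] - obs[ok])^2))
    if (sum(ok) >= 3 && stats::sd(obs[ok]) > 0 && stats::sd(pred[ok]) > 0)
      per_iter$r2[it] <- stats::cor(pred[ok], obs[ok])^2
    pred_all[[it]] <- pred
    obs_all[[it]] <- obs
  }
  .cv_result(unlist(pred_all), unlist(obs_all), iterations, per_iter)
}

#' Median residual per observed-cover class
#'
#' @param cv a `"mat_cv"` object (or any list with `residuals` and `obs`).
#' @return named vector of median residuals (predicted minus observed) for
#'   the ten 10-point observed-cover classes (`NA` for empty classes).
#' @export
residual_class_medians <- function(cv) {
  cls <- cover_class(cv$obs)
  tapply(cv$residuals, cls, stats::median, na.rm = TRUE)
}

#' Per-timeslice no-analog rates
#'
#' For each timeslice, the percentage of fossil samples whose nearest
#' calibration entry exceeds the dissimilarity threshold. Running this once
#' on taxon proportions and once on PFT scores quantifies how much the PFT
#' transformation alleviates no-analog situations.
#'
#' @param object a fitted [mat()] model in the chosen assemblage space.
#' @param newdata fossil assemblage matrix in the same space.
#' @param slices timeslice labels (one per fossil sample); `NA` = unassigned.
#' @param T dissimilarity threshold (defaults to the model's).
#' @return data frame with `slice`, `n`, `no_analog_pct` (`NA` for slices
#'   with no samples).
#' @export
no_analog_rates <- function(object, newdata, slices, T = object$T) {
  newdata <- .normalize_rows(newdata, "fossil")
  dmin <- apply(chord_dist_matrix(newdata, object$x), 1, min)
  lv <- sort(unique(slices[!is.na(slices)]), decreasing = TRUE)
  do.call(rbind, lapply(lv, function(s) {
    sel <- !is.na(slices) & slices == s
    data.frame(slice = s, n = sum(sel),
               no_analog_pct = if (any(sel)) 100 * mean(dmin[sel] > T) else NA_real_)
  }))
}
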