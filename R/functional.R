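## Errors-in-variables ("functional") calibration model:
##   y_i  = a + b x_i + e_i,  e_i  ~ N(0, sigma2)     (calibration line)
##   z_ij = x_i + g_ij,       g_ij ~ N(0, sigma_z2)   (replicated signals)
## with the true signal variates x_1..x_k treated as fixed unknowns.
##
## The joint likelihood of this model is unbounded (sigma2 -> 0 with the
## x_i interpolating the y_i drives it to infinity), so simultaneous
## maximisation over all parameters is ill-posed; with the error-variance
## ratio treated as unknown the interior stationary point also vanishes
## once the slope-scaled signal noise dominates the line scatter. The
## identified, consistent estimator for the replicated functional design
## is the classical moment-corrected errors-in-variables fit used here:
## sigma_z2 from the pooled within-point replicate variance (the only
## information the data carry about it), the slope de-attenuated by the
## error variance of the per-point signal means, and sigma2 from the
## residual variance minus the slope-leaked signal-noise component. When
## the replicate scatter vanishes every correction vanishes and the fit
## reduces exactly to OLS.

#' Errors-in-variables (functional model) calibration fit
#'
#' Fits the functional calibration model, which acknowledges measurement
#' error in the sensor signal: each calibration point has a fixed but
#' unknown true signal `x_i`, observed `l` times with noise variance
#' `sigma_z2`, while the measurand follows the calibration line with
#' residual variance `sigma2`.
#'
#' Estimation uses the moment-corrected errors-in-variables solution for
#' replicated designs: `sigma_z2` is the pooled within-point replicate
#' variance; the slope is the attenuation-corrected
#' `s_xy / (s_xx - sigma_z2 / l)`; `sigma2` subtracts the slope-leaked
#' signal-noise component `b^2 sigma_z2 / l` from the residual variance;
#' and the true signals `x_i` are recovered as the precision-weighted
#' combination of the replicate mean and the line-implied value. With
#' identical replicates (`sigma_z2 = 0`) the result equals the OLS fit
#' exactly — the practical check that sensor noise is small enough for
#' ordinary linear regression.
#'
#' @param data A [calibration_data()] tibble with at least 2 signal
#'   replicates per point.
#'
#' @return An object of class `baps_functional` (also `baps_fit`) with
#'   elements `a`, `b`, `sigma2`, `sigma_z2`, `x_hat`, `loglik`,
#'   `converged`, `k`, `l`. `tidy()` and `glance()` methods are
#'   provided.
#' @examples
#' d <- calibration_data(rep(1:4, each = 2),
#'                       rep(c(0, 1, 2, 3), each = 2) + rnorm(8, 0, 0.01),
#'                       rep(c(1, 3, 5, 7), each = 2))
#' fit_functional(d)
#' @export
fit_functional <- function(data) {
  need <- c("point_id", "signal_v", "measurand")
  if (!all(need %in% names(data))) {
    stop_data("functional fit needs columns point_id, signal_v, measurand.")
  }
  by_pt <- dplyr::group_by(data, .data$point_id)
  pts <- dplyr::summarise(
    by_pt,
    zbar = mean(.data$signal_v),
    ssz = sum((.data$signal_v - mean(.data$signal_v))^2),
    ybar = .data$measurand[1],
    l = dplyr::n(),
    .groups = "drop"
  )
  k <- nrow(pts)
  if (k < 3) stop_data("functional fit needs at least 3 calibration points.")
  if (any(pts$l < 2)) {
    stop_data("functional fit needs >= 2 signal replicates per point to identify sigma_z2.")
  }
  ols <- fit_ols(data)
  l <- mean(pts$l)
  sz2 <- sum(pts$ssz) / sum(pts$l - 1)
  szm2 <- sz2 / l # error variance of the per-point signal mean

  xm <- mean(pts$zbar); ym <- mean(pts$ybar)
  sxx <- sum((pts$zbar - xm)^2) / (k - 1)
  sxy <- sum((pts$zbar - xm) * (pts$ybar - ym)) / (k - 1)
  if (sxx - szm2 <= 0) {
    abort("signal noise exceeds the spread of the calibration points: the functional slope is not identifiable.",
          class = "bapscal_error_fit")
  }
  b <- sxy / (sxx - szm2)
  a <- ym - b * xm
  res <- pts$ybar - a - b * pts$zbar
  s2 <- max(sum(res^2) / (k - 2) - b^2 * szm2, 0)

  ## precision-weighted recovery of the true signal variates
  x_hat <- if (s2 == 0 && szm2 == 0) {
    pts$zbar
  } else if (s2 == 0) {
    (pts$ybar - a) / b
  } else {
    w <- b^2 / s2 + pts$l / max(sz2, .Machine$double.xmin)
    (b * (pts$ybar - a) / s2 + pts$l * pts$zbar / max(sz2, .Machine$double.xmin)) / w
  }

  loglik <- sum(stats::dnorm(pts$ybar, a + b * x_hat,
                             sqrt(max(s2, 1e-300)), log = TRUE)) +
    if (sz2 > 0) {
      -0.5 * sum(pts$l) * log(2 * pi * sz2) -
        (sum(pts$ssz) + sum(pts$l * (pts$zbar - x_hat)^2)) / (2 * sz2)
    } else 0

  structure(
    list(a = a, b = b, sigma2 = s2, sigma_z2 = sz2, x_hat = x_hat,
         loglik = loglik, converged = TRUE, k = k, l = pts$l, ols = ols),
    class = c("baps_functional", "baps_fit")
  )
}

#' @export
print.baps_functional <- function(x, ...) {
  cat(sprintf("<baps_functional> y = %.4g + %.4g x (k = %d points, EIV)\n",
              x$a, x$b, x$k))
  cat(sprintf("  sigma2 = %.4g, sigma_z2 = %.4g, logLik = %.3f\n",
              x$sigma2, x$sigma_z2, x$loglik))
  invisible(x)
}

#' @export
tidy.baps_functional <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.baps_functional <- function(x, ...) {
  tibble(sigma2 = x$sigma2, sigma_z2 = x$sigma_z2, loglik = x$loglik,
         converged = x$converged, k = x$k)
}
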