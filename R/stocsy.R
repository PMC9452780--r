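#' Statistical total correlation spectroscopy (STOCSY)
#'
#' Pearson correlation and covariance of one spectral variable (the driver)
#' against all variables across the cohort. Peaks of the same molecule share
#' a concentration factor and therefore correlate strongly, which aids peak
#' assignment.
#'
#' @param m a [spectral_matrix()] of normalized (unscaled) spectra.
#' @param driver_ppm chemical shift of the driver peak; the nearest grid
#'   variable is used.
#' @return An object of class `nmr_stocsy`: `driver_ppm` (as matched),
#'   `ppm`, `correlation`, `covariance`.
#' @export
stocsy <- function(m, driver_ppm) {
  stopifnot(inherits(m, "spectral_matrix"))
  j <- which.min(abs(m$ppm - driver_ppm))
  d <- m$X[, j]
  if (stats::sd(d) == 0) stop("zero-variance driver variable at ",
                              signif(m$ppm[j], 5), " ppm")
  sds <- apply(m$X, 2, stats::sd)
  covv <- as.vector(crossprod(d - mean(d), sweep(m$X, 2, colMeans(m$X)))) /
    (nrow(m$X) - 1)
  corr <- ifelse(sds > 0, covv / (stats::sd(d) * sds), NA_real_)
  structure(list(driver_ppm = m$ppm[j], ppm = m$ppm,
                 correlation = corr, covariance = covv),
            class = "nmr_stocsy")
}

#' @export
print.nmr_stocsy <- function(x, ...) {
  top <- order(-abs(x$correlation))[1:5]
  cat(sprintf("STOCSY driver %.3f ppm; strongest correlations:\n",
              x$driver_ppm))
  for (i in top)
    cat(sprintf("  %.3f ppm  r = %+.3f\n", x$ppm[i], x$correlation[i]))
  invisible(x)
}

#' @export
plot.nmr_stocsy <- function(x, ...) {
  cols <- grDevices::colorRampPalette(c("blue", "grey", "red"))(101)
  ci <- cols[round(50 * (x$correlation + 1)) + 1]
  plot(x$ppm, x$covariance, type = "h", col = ci, xlim = rev(range(x$ppm)),
       xlab = "ppm", ylab = "covariance", ...)
  invisible(x)
}
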