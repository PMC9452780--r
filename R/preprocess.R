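#' Interpolate spectra onto a common grid
#'
#' Linear interpolation of each spectrum onto the target grid. Grid points
#' outside a spectrum's ppm range are set to zero and their count recorded
#' in the `extrapolated` attribute.
#'
#' @param spectra a list of [nmr_spectrum()] objects, or an existing
#'   [spectral_matrix()] (re-gridded).
#' @param grid target ppm grid (any monotone orientation; stored
#'   descending).
#' @return A [spectral_matrix()].
#' @export
to_common_grid <- function(spectra, grid) {
  if (inherits(spectra, "spectral_matrix")) {
    samples <- spectra$samples
    spectra <- lapply(seq_len(nrow(spectra$X)), function(i)
      nmr_spectrum(samples$sample_id[i], spectra$ppm, spectra$X[i, ],
                   samples$group[i]))
  } else {
    samples <- data.frame(
      sample_id = vapply(spectra, `[[`, "", "sample_id"),
      group = vapply(spectra, function(s)
        if (is.null(s$group)) NA_character_ else s$group, ""),
      stringsAsFactors = FALSE)
  }
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  n_extrap <- 0L
  X <- t(vapply(spectra, function(s) {
    if (min(s$ppm) > max(grid) || max(s$ppm) < min(grid))
      stop("spectrum ", s$sample_id, " does not overlap the target grid")
    y <- stats::approx(s$ppm, s$intensity, xout = grid, rule = 1)$y
    out <- is.na(y)
    n_extrap <<- n_extrap + sum(out)
    y[out] <- 0
    y
  }, numeric(length(grid))))
  m <- spectral_matrix(grid, X, samples)
  attr(m, "extrapolated") <- n_extrap
  m
}

#' Exclude a chemical-shift region
#'
#' Removes all grid points with `lo <= ppm <= hi` (default: the residual
#' water band at 4.7-5.0 ppm). The removed interval is recorded in the
#' matrix's `excluded` list for reporting. A region outside the grid is a
#' no-op with a warning.
#'
#' @param m a [spectral_matrix()].
#' @param lo,hi region bounds in ppm (`lo < hi`).
#' @return The matrix without the in-band variables.
#' @export
exclude_region <- function(m, lo = 4.7, hi = 5.0) {
  stopifnot(inherits(m, "spectral_matrix"), lo < hi)
  inband <- m$ppm >= lo & m$ppm <= hi
  if (!any(inband)) {
    warning(sprintf("region [%g, %g] outside grid; nothing excluded",
                    lo, hi))
    return(m)
  }
  m$X <- m$X[, !inband, drop = FALSE]
  m$ppm <- m$ppm[!inband]
  m$excluded <- c(m$excluded, list(c(lo, hi)))
  m
}

# integer-lag shift with boundary-value padding
.shift_vec <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(rep(x[1], lag), x[seq_len(n - lag)])
  else c(x[(-lag + 1):n], rep(x[n], -lag))
}

# best integer lag (|lag| <= max_shift) maximizing the cross-correlation
# with the reference (FFT-based); ties resolved toward the smallest |lag|
.best_lag <- function(x, ref, max_shift) {
  n <- length(x)
  max_shift <- min(max_shift, n - 1L)
  n2 <- stats::nextn(2L * n, 2)
  fx <- stats::fft(c(x, numeric(n2 - n)))
  fr <- stats::fft(c(ref, numeric(n2 - n)))
  cc <- Re(stats::fft(fr * Conj(fx), inverse = TRUE)) / n2
  # cc[m + 1] = sum_k ref[k] * x[k - m] for m >= 0; negative m wrap around
  lags <- (-max_shift):max_shift
  idx <- ifelse(lags >= 0, lags + 1L, n2 + lags + 1L)
  score <- cc[idx]
  top <- max(score)
  cand <- lags[score >= top - 1e-9 * max(abs(top), 1e-300)]
  as.integer(cand[which.min(abs(cand))])
}

.rspa_rec <- function(x, ref, min_segment, max_shift_frac, depth,
                      max_depth) {
  n <- length(x)
  max_shift <- max(1L, floor(max_shift_frac * n))
  max_shift <- min(max_shift, n - 1L)
  lag <- .best_lag(x, ref, max_shift)
  x <- .shift_vec(x, lag)
  if (n >= 2 * min_segment && depth < max_depth) {
    # split at the least-intense point of the reference near the middle,
    # so the cut avoids peaks
    mid <- seq(floor(n / 3), ceiling(2 * n / 3))
    k <- mid[which.min(ref[mid])]
    x <- c(.rspa_rec(x[1:k], ref[1:k], min_segment, max_shift_frac,
                     depth + 1, max_depth),
           .rspa_rec(x[(k + 1):n], ref[(k + 1):n], min_segment,
                     max_shift_frac, depth + 1, max_depth))
  }
  x
}

#' Recursive segment-wise peak alignment (RSPA)
#'
#' Aligns every spectrum to a reference (default: the point-wise median
#' spectrum of the cohort) by recursively segmenting the spectrum and
#' shifting each segment by the bounded integer lag that maximizes its
#' cross-correlation with the corresponding reference segment. Segment
#' boundaries are placed at low-intensity points of the reference so peaks
#' are not cut. A sample's aligned spectrum is kept only if its Pearson
#' correlation to the reference does not decrease, so the cohort-average
#' correlation to the reference is non-decreasing by construction.
#'
#' @param m a [spectral_matrix()] on a common grid.
#' @param reference reference spectrum (length `ncol`); default median.
#' @param min_segment minimum segment length in grid points.
#' @param max_shift_frac maximum shift as a fraction of segment length.
#' @param max_depth maximum recursion depth.
#' @return The aligned matrix, with per-sample whole-spectrum lags (grid
#'   points, positive = moved toward the first/most-downfield point) in the
#'   `shifts` attribute.
#' @export
rspa_align <- function(m, reference = NULL, min_segment = 128,
                       max_shift_frac = 0.1, max_depth = 5) {
  stopifnot(inherits(m, "spectral_matrix"))
  n <- ncol(m$X)
  if (max_shift_frac >= 1)
    stop("max_shift must be smaller than the segment length")
  if (is.null(reference)) reference <- apply(m$X, 2, stats::median)
  shifts <- integer(nrow(m$X))
  for (i in seq_len(nrow(m$X))) {
    x <- m$X[i, ]
    lag0 <- .best_lag(x, reference, max(1L, floor(max_shift_frac * n)))
    aligned <- .rspa_rec(x, reference, min_segment, max_shift_frac,
                         0L, max_depth)
    if (stats::cor(aligned, reference) >= stats::cor(x, reference)) {
      m$X[i, ] <- aligned
      shifts[i] <- lag0
    }
  }
  m$aligned <- TRUE
  attr(m, "shifts") <- shifts
  m
}

#' Normalize spectra
#'
#' `total_area`: each spectrum is divided by its summed intensity, so rows
#' sum to 1 (the water band, and any other nuisance region such as the TSP
#' resonance, should be excluded beforehand with [exclude_region()]).
#' `cell_count`: total-area normalization rescaled per group by the
#' group-average cell count relative to the reference group, i.e. each row
#' is divided by (row sum x group_cells / ref_cells). This approximates
#' per-cell (intracellular) concentrations using group-average cellularity.
#'
#' @param m a [spectral_matrix()].
#' @param mode `"total_area"` or `"cell_count"`.
#' @param design for `"cell_count"`: data.frame with `group` and
#'   `avg_cell_count`.
#' @param ref_group reference group for cell-count rescaling (default: the
#'   first row of `design`).
#' @return The normalized matrix.
#' @export
normalize_spectra <- function(m, mode = c("total_area", "cell_count"),
                              design = NULL, ref_group = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "spectral_matrix"))
  areas <- rowSums(m$X)
  if (any(areas == 0)) stop("zero total area in sample(s) ",
                            paste(m$samples$sample_id[areas == 0],
                                  collapse = ", "))
  if (mode == "total_area") {
    m$X <- m$X / areas
  } else {
    if (is.null(design) || !all(c("group", "avg_cell_count") %in%
                                names(design)))
      stop("cell_count normalization needs a design with group and ",
           "avg_cell_count")
    if (is.null(ref_group)) ref_group <- design$group[1]
    unknown <- setdiff(unique(m$samples$group), design$group)
    if (length(unknown))
      stop("unknown group: ", paste(unknown, collapse = ", "))
    cells <- design$avg_cell_count[match(m$samples$group, design$group)]
    ref <- design$avg_cell_count[match(ref_group, design$group)]
    m$X <- m$X / (areas * cells / ref)
  }
  m$normalization <- mode
  m
}

#' Unit-variance (auto) scaling
#'
#' Mean-centres each variable and divides by its standard deviation.
#' Zero-variance columns are dropped (their count is stored in the
#' `dropped` attribute); column means and SDs are retained on the object
#' for back-transformation of loadings and for [uv_unscale()].
#'
#' @param m a [spectral_matrix()] with at least two samples.
#' @return The scaled matrix (`scaled = TRUE`, `scale_center`/`scale_sd`
#'   filled in).
#' @export
uv_scale <- function(m) {
  stopifnot(inherits(m, "spectral_matrix"))
  if (nrow(m$X) < 2) stop("UV scaling needs at least 2 samples")
  mu <- colMeans(m$X)
  sd <- apply(m$X, 2, stats::sd)
  keep <- sd > 0
  n_drop <- sum(!keep)
  m$X <- sweep(sweep(m$X[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep],
               "/")
  m$ppm <- m$ppm[keep]
  m$scale_center <- mu[keep]
  m$scale_sd <- sd[keep]
  m$scaled <- TRUE
  attr(m, "dropped") <- n_drop
  m
}

#' Invert unit-variance scaling
#'
#' @param m a UV-scaled [spectral_matrix()].
#' @return The matrix on its original scale (retained columns only).
#' @export
uv_unscale <- function(m) {
  stopifnot(inherits(m, "spectral_matrix"), isTRUE(m$scaled))
  m$X <- sweep(sweep(m$X, 2, m$scale_sd, "*"), 2, m$scale_center, "+")
  m$scaled <- FALSE
  m$scale_center <- NULL
  m$scale_sd <- NULL
  m
}
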