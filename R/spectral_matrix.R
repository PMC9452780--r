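#' Spectral matrix container
#'
#' A `spectral_matrix` holds a cohort of 1D NMR spectra interpolated onto a
#' common chemical-shift grid, together with sample metadata and provenance
#' flags that record which preprocessing stages have been applied. The ppm
#' grid is stored in descending order (NMR plotting convention).
#'
#' @param ppm numeric vector of chemical shifts (ppm), strictly monotone.
#' @param X numeric matrix, one row per sample, one column per grid point.
#' @param samples data.frame with at least `sample_id` and `group`; an
#'   optional `cell_count` column carries per-sample cell counts.
#' @param normalization one of `"none"`, `"total_area"`, `"cell_count"`.
#' @param aligned logical; has RSPA been applied?
#' @param scaled logical; has unit-variance scaling been applied?
#'
#' @return An object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(ppm, X, samples,
                            normalization = "none",
                            aligned = FALSE, scaled = FALSE) {
  ppm <- as.numeric(ppm)
  X <- as.matrix(X)
  if (length(ppm) != ncol(X))
    stop("length(ppm) must equal ncol(X)")
  if (any(!is.finite(X)))
    stop("intensities must be finite")
  d <- diff(ppm)
  if (all(d > 0)) {
    # normalize to the canonical descending orientation
    ppm <- rev(ppm)
    X <- X[, rev(seq_along(ppm)), drop = FALSE]
  } else if (!all(d < 0)) {
    stop("ppm grid must be strictly monotone")
  }
  samples <- as.data.frame(samples)
  if (is.null(samples$sample_id))
    samples$sample_id <- paste0("S", seq_len(nrow(X)))
  if (nrow(samples) != nrow(X))
    stop("samples metadata must have one row per spectrum")
  rownames(X) <- samples$sample_id
  structure(list(ppm = ppm, X = X, samples = samples,
                 normalization = normalization,
                 aligned = aligned, scaled = scaled,
                 scale_center = NULL, scale_sd = NULL,
                 excluded = list()),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("spectral_matrix: %d spectra x %d variables\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  ppm range: %.3f .. %.3f (descending)\n",
              x$ppm[1], x$ppm[length(x$ppm)]))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(grp), grp),
                         collapse = ", "), "\n")
  cat(sprintf("  normalization: %s | aligned: %s | scaled: %s\n",
              x$normalization, x$aligned, x$scaled))
  if (length(x$excluded))
    cat("  excluded regions:",
        paste(vapply(x$excluded, function(r)
          sprintf("[%.2f, %.2f]", r[1], r[2]), ""), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$X)

#' Grid step of a spectral matrix
#' @param m a `spectral_matrix`.
#' @return Positive grid spacing in ppm (median absolute step).
#' @export
grid_step <- function(m) stats::median(abs(diff(m$ppm)))

#' A single 1D spectrum
#'
#' Lightweight container for one spectrum before interpolation onto a
#' common grid.
#'
#' @param sample_id sample identifier.
#' @param ppm strictly monotone chemical-shift vector (ppm).
#' @param intensity intensity vector of the same length.
#' @param group optional group label.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(sample_id, ppm, intensity, group = NA_character_) {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm grid must be strictly monotone")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  structure(list(sample_id = sample_id, ppm = as.numeric(ppm),
                 intensity = as.numeric(intensity), group = group),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("nmr_spectrum '%s' (group %s): %d points, %.3f .. %.3f ppm\n",
              x$sample_id, x$group, length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}
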