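#' Principal component analysis of a spectral matrix
#'
#' Thin wrapper around the singular value decomposition of the
#' column-centred intensity matrix, with a deterministic sign convention:
#' each component is flipped so that its largest-magnitude loading is
#' positive.
#'
#' @param m a [spectral_matrix()] (typically UV-scaled) or a plain matrix.
#' @param n_components number of components to retain.
#' @return An object of class `nmr_pca`: `scores` (samples x components),
#'   `loadings` (variables x components), `explained_variance` (fractions,
#'   non-increasing), `center`, `ppm`.
#' @export
fit_pca <- function(m, n_components = 2) {
  X <- if (inherits(m, "spectral_matrix")) m$X else as.matrix(m)
  ppm <- if (inherits(m, "spectral_matrix")) m$ppm else NULL
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds min(samples - 1, variables)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)],
                          n_components, n_components)
  for (a in seq_len(n_components)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(n_components)],
                 center = mu, ppm = ppm,
                 groups = if (inherits(m, "spectral_matrix"))
                   m$samples$group else NULL),
            class = "nmr_pca")
}

#' @export
print.nmr_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, explained variance %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = " + ")))
  invisible(x)
}

#' @export
plot.nmr_pca <- function(x, comps = c(1, 2), ...) {
  g <- if (is.null(x$groups)) factor(rep(1, nrow(x$scores)))
       else factor(x$groups)
  plot(x$scores[, comps[1]], x$scores[, comps[2]],
       col = as.integer(g), pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", comps[1],
                      100 * x$explained_variance[comps[1]]),
       ylab = sprintf("PC%d (%.1f%%)", comps[2],
                      100 * x$explained_variance[comps[2]]), ...)
  if (nlevels(g) > 1)
    legend("topright", legend = levels(g), col = seq_len(nlevels(g)),
           pch = 19, bty = "n")
  invisible(x)
}
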