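#' Integrate assigned peak windows
#'
#' Trapezoidal integration of each assignment window
#' `[center - halfwidth, center + halfwidth]` for every sample, on the
#' normalized (unscaled) spectra. Overlapping windows are flagged with a
#' warning (stored in the `overlaps` attribute) but are not an error; a
#' window with no grid point inside is.
#'
#' @param m a normalized, unscaled [spectral_matrix()].
#' @param assignments data.frame with `metabolite`, `center`, `halfwidth`.
#' @return An object of class `integral_table`: `values`
#'   (samples x metabolites), `samples`, `windows`, `normalization`.
#' @export
integrate_windows <- function(m, assignments) {
  stopifnot(inherits(m, "spectral_matrix"),
            all(c("metabolite", "center", "halfwidth") %in%
                names(assignments)))
  ppm <- m$ppm
  vals <- matrix(NA_real_, nrow(m$X), nrow(assignments),
                 dimnames = list(m$samples$sample_id,
                                 assignments$metabolite))
  cover <- vector("list", nrow(assignments))
  for (k in seq_len(nrow(assignments))) {
    lo <- assignments$center[k] - assignments$halfwidth[k]
    hi <- assignments$center[k] + assignments$halfwidth[k]
    j <- which(ppm >= lo & ppm <= hi)
    if (!length(j))
      stop("window for ", assignments$metabolite[k],
           " contains no grid point")
    cover[[k]] <- j
    # ppm is descending: integrate on the ascending axis
    xx <- rev(ppm[j])
    Y <- m$X[, rev(j), drop = FALSE]
    if (length(j) == 1) {
      vals[, k] <- Y[, 1] * 2 * assignments$halfwidth[k]
    } else {
      w <- diff(xx)
      vals[, k] <- as.vector(
        (Y[, -length(j), drop = FALSE] + Y[, -1, drop = FALSE]) %*% w) / 2
    }
  }
  ov <- character(0)
  if (nrow(assignments) > 1) {
    for (k in 2:nrow(assignments))
      for (l in 1:(k - 1))
        if (length(intersect(cover[[k]], cover[[l]])))
          ov <- c(ov, paste(assignments$metabolite[l],
                            assignments$metabolite[k], sep = "/"))
    if (length(ov))
      warning("overlapping integration windows: ",
              paste(ov, collapse = ", "))
  }
  structure(list(values = vals, samples = m$samples,
                 windows = assignments,
                 normalization = m$normalization,
                 overlaps = ov),
            class = "integral_table")
}

#' @export
print.integral_table <- function(x, ...) {
  cat(sprintf("integral_table: %d samples x %d windows (%s-normalized)\n",
              nrow(x$values), ncol(x$values), x$normalization))
  if (length(x$overlaps))
    cat("  overlapping windows:", length(x$overlaps), "\n")
  invisible(x)
}

#' Normality-routed two-group test
#'
#' Shapiro-Wilk normality screening in each group: if both groups are
#' compatible with normality (p >= 0.05) a two-sided Welch t-test is used,
#' otherwise a two-sided Wilcoxon rank-sum test. Groups smaller than 3
#' (Shapiro-Wilk undefined) take the nonparametric route with a warning.
#'
#' @param x,y numeric vectors of the two groups' values.
#' @param alpha normality-screen level.
#' @return list with `p_value` and `test_used` (`"t"` or `"wilcoxon"`).
#' @export
route_and_test <- function(x, y, alpha = 0.05) {
  sw_p <- function(v) {
    if (length(unique(v)) == 1) return(0)  # degenerate: not normal
    stats::shapiro.test(v)$p.value
  }
  if (length(x) < 3 || length(y) < 3) {
    warning("group with n < 3: Shapiro-Wilk undefined, using Wilcoxon")
    normal <- FALSE
  } else {
    normal <- sw_p(x) >= alpha && sw_p(y) >= alpha
  }
  if (normal) {
    p <- stats::t.test(x, y, var.equal = FALSE)$p.value
    list(p_value = p, test_used = "t")
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))$p.value
    list(p_value = p, test_used = "wilcoxon")
  }
}

#' Standardized effect size (Hedges' g) with standard error
#'
#' `ES = J * (mean(x) - mean(y)) / s_pooled` with the small-sample
#' correction `J = 1 - 3 / (4 df - 1)`, `df = n_x + n_y - 2`; its standard
#' error is `sqrt((n_x + n_y) / (n_x n_y) + ES^2 / (2 (n_x + n_y - 2)))`.
#' Positive values mean higher levels in the first group.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `es` and `es_error`.
#' @export
effect_size <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  df <- nx + ny - 2
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df)
  if (sp == 0) {
    if (mean(x) == mean(y)) return(list(es = 0, es_error = 0))
    stop("zero pooled SD with unequal means")
  }
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(x) - mean(y)) / sp
  se <- sqrt((nx + ny) / (nx * ny) + g^2 / (2 * df))
  list(es = g, es_error = se)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone after sorting, capped at
#' 1), computed with `stats::p.adjust(method = "BH")` after validating the
#' inputs.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Univariate screen of one pairwise group comparison
#'
#' For every integrated window: normality-routed test
#' ([route_and_test()]), Hedges' g with standard error ([effect_size()],
#' first group minus second), and BH-FDR adjustment across the full window
#' family of this comparison. A window is `significant` when
#' `|ES| > ES_error` and `p < alpha`, and `fdr_significant` when its
#' adjusted p-value is below `alpha`.
#'
#' @param tab an [integrate_windows()] result.
#' @param group_a,group_b group labels; ES > 0 means higher in `group_a`.
#' @param alpha significance level.
#' @return A `comparison_result` data.frame, one row per window.
#' @export
compare_groups <- function(tab, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(tab, "integral_table"))
  g <- tab$samples$group
  if (!group_a %in% g) stop("group missing: ", group_a)
  if (!group_b %in% g) stop("group missing: ", group_b)
  A <- tab$values[g == group_a, , drop = FALSE]
  B <- tab$values[g == group_b, , drop = FALSE]
  k <- ncol(tab$values)
  es <- se <- p <- numeric(k)
  used <- character(k)
  for (j in seq_len(k)) {
    rt <- suppressWarnings(route_and_test(A[, j], B[, j], alpha))
    ef <- effect_size(A[, j], B[, j])
    es[j] <- ef$es; se[j] <- ef$es_error
    p[j] <- rt$p_value; used[j] <- rt$test_used
  }
  padj <- bh_adjust(p)
  out <- data.frame(
    metabolite = colnames(tab$values),
    ppm = tab$windows$center,
    group_a = group_a, group_b = group_b,
    n_a = nrow(A), n_b = nrow(B),
    normalization = tab$normalization,
    es = es, es_error = se,
    p_value = p, p_adjusted = padj,
    test_used = used,
    direction = sign(es),
    significant = abs(es) > se & p < alpha,
    fdr_significant = padj < alpha,
    identified = !grepl("^U[0-9]", colnames(tab$values)),
    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", class(out))
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  if (all(c("group_a", "group_b", "significant") %in% names(x))) {
    cat(sprintf("%s vs %s (%s): %d windows, %d significant (%d after FDR)\n",
                x$group_a[1], x$group_b[1],
                if (is.null(x$normalization)) "?" else x$normalization[1],
                nrow(x), sum(x$significant),
                sum(x$significant & x$fdr_significant)))
  }
  NextMethod()
}

#' Volcano-plot coordinates of a comparison
#'
#' @param cmp a `comparison_result`.
#' @return data.frame with `metabolite`, `es` and `neg_log10_p`.
#' @export
volcano_data <- function(cmp) {
  stopifnot(inherits(cmp, "comparison_result"))
  data.frame(metabolite = cmp$metabolite, es = cmp$es,
             neg_log10_p = -log10(cmp$p_value),
             significant = cmp$significant,
             stringsAsFactors = FALSE)
}
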