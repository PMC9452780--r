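#' Monte Carlo cross-validation of a two-class PLS-DA model
#'
#' Repeated stratified random hold-out: in each run, 1/`n_blocks` of the
#' samples of each class (at least one per class) is held out, a PLS-DA
#' model is fitted on the remainder and the held-out class responses are
#' predicted. Per run, `Q2 = 1 - PRESS/TSS` on the held-out responses
#' (TSS about the training-response mean); held-out class predictions
#' (thresholded at the midpoint of the class codes) are pooled over all
#' runs into a confusion matrix, from which the classification rate,
#' sensitivity and specificity are computed (in percent; the first class
#' level is the positive class).
#'
#' If the input matrix is not UV-scaled, scaling is performed inside each
#' training fold (training-fold means and SDs, applied to the held-out
#' samples) so that no held-out information enters the model.
#'
#' @param m a [spectral_matrix()] or plain matrix (normalized spectra).
#' @param labels two-class labels; defaults to the matrix's groups.
#' @param n_blocks hold-out granularity: 1/`n_blocks` of each class held
#'   out per run.
#' @param n_runs number of Monte Carlo runs.
#' @param n_components number of PLS components per run.
#' @param seed integer seed; results are deterministic given the seed.
#' @return An object of class `nmr_mccv`: `q2_values`, `q2_median`,
#'   `confusion` (TP/FP/TN/FN), `cr`, `sensitivity`, `specificity` (in %).
#' @export
mccv <- function(m, labels = NULL, n_blocks = 7, n_runs = 500,
                 n_components = 2, seed = 1) {
  X <- if (inherits(m, "spectral_matrix")) m$X else as.matrix(m)
  prescaled <- inherits(m, "spectral_matrix") && isTRUE(m$scaled)
  if (is.null(labels) && inherits(m, "spectral_matrix"))
    labels <- m$samples$group
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("MCCV requires exactly two classes")
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
  pos <- levels(labels)[1]
  y <- ifelse(labels == pos, 1, -1)
  # canonical class order for the stratified draws, so results do not
  # depend on which class is coded positive
  idx_by_class <- split(seq_along(labels), labels)
  idx_by_class <- idx_by_class[sort(names(idx_by_class))]
  n_out <- vapply(idx_by_class, function(i)
    max(1L, as.integer(round(length(i) / n_blocks))), integer(1))
  if (any(vapply(idx_by_class, length, integer(1)) - n_out < 2))
    stop("hold-out would leave fewer than 2 training samples in a class")
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  q2 <- numeric(n_runs)
  tp <- fp <- tn <- fn <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    test <- unlist(lapply(seq_along(idx_by_class), function(k)
      sample(idx_by_class[[k]], n_out[k])))
    train <- setdiff(seq_along(labels), test)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (!prescaled) {
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2, stats::sd)
      keep <- sd > 0
      Xtr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sd[keep], "/")
      Xte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sd[keep], "/")
    }
    a <- min(n_components, length(train) - 1)
    fit <- fit_plsda(Xtr, labels[train], a)
    yhat <- predict(fit, Xte)[, 1]
    if (fit$levels[1] != pos) yhat <- -yhat
    press <- sum((y[test] - yhat)^2)
    tss <- sum((y[test] - mean(y[train]))^2)
    q2[r] <- 1 - press / tss
    pred_pos <- yhat >= 0
    true_pos <- y[test] == 1
    tp <- tp + sum(pred_pos & true_pos)
    fp <- fp + sum(pred_pos & !true_pos)
    tn <- tn + sum(!pred_pos & !true_pos)
    fn <- fn + sum(!pred_pos & true_pos)
  }
  structure(list(q2_values = q2, q2_median = stats::median(q2),
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 cr = 100 * (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 positive_class = pos, n_blocks = n_blocks,
                 n_runs = n_runs, n_components = n_components,
                 seed = seed),
            class = "nmr_mccv")
}

#' @export
print.nmr_mccv <- function(x, ...) {
  cat(sprintf(
    "MCCV (%d blocks, %d runs): Q2median = %.3f | CR = %.1f%% | sens = %.1f%% | spec = %.1f%% (positive: %s)\n",
    x$n_blocks, x$n_runs, x$q2_median, x$cr, x$sensitivity,
    x$specificity, x$positive_class))
  invisible(x)
}
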