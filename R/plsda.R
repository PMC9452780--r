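#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS-DA model by sequential NIPALS extraction. The class response
#' is coded as a centred indicator: for two classes a single +1/-1 column,
#' for more classes a centred one-hot matrix. Per component, the X-weight
#' is the (normalized) covariance direction `X'u`, scores are `X w`, and X
#' and Y are deflated by the score. Components use the same deterministic
#' sign convention as [fit_pca()] (largest-|loading| positive).
#'
#' @param m a UV-scaled [spectral_matrix()] or a plain matrix.
#' @param labels class labels (length = number of samples); defaults to the
#'   matrix's `group` column.
#' @param n_components number of latent variables.
#' @return An object of class `nmr_plsda` with weights `W`, X-loadings
#'   `P`, Y-loadings `Q`, scores `T`, regression matrix `B`, `r2y`,
#'   per-component explained Y-variance `ssy`, class coding and centring
#'   metadata.
#' @export
fit_plsda <- function(m, labels = NULL, n_components = 2) {
  X <- if (inherits(m, "spectral_matrix")) m$X else as.matrix(m)
  if (is.null(labels) && inherits(m, "spectral_matrix"))
    labels <- m$samples$group
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds the data rank bound")
  # class coding
  if (nlevels(labels) == 2) {
    Y0 <- matrix(ifelse(labels == levels(labels)[1], 1, -1), ncol = 1)
  } else {
    Y0 <- stats::model.matrix(~ labels - 1)
    colnames(Y0) <- levels(labels)
  }
  x_center <- colMeans(X)
  y_center <- colMeans(Y0)
  Xd <- sweep(X, 2, x_center)
  Yd <- sweep(Y0, 2, y_center)
  n <- nrow(Xd); p <- ncol(Xd); q <- ncol(Yd)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components); Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    for (it in 1:500) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("zero X-weight: no residual X-Y covariance")
      w <- w / nw
      tt <- Xd %*% w
      qv <- crossprod(Yd, tt) / sum(tt^2)
      u_new <- Yd %*% qv / sum(qv^2)
      if (q == 1 || sum((u_new - u)^2) < 1e-12 * sum(u_new^2)) {
        u <- u_new; break
      }
      u <- u_new
    }
    pv <- crossprod(Xd, tt) / sum(tt^2)
    # sign convention: largest-|x-loading| element positive
    j <- which.max(abs(pv))
    if (pv[j] < 0) { w <- -w; tt <- -tt; pv <- -pv; qv <- -qv }
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(qv^2)
    Xd <- Xd - tt %*% t(pv)
    Yd <- Yd - tt %*% t(qv)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  fitted <- sweep(sweep(X, 2, x_center) %*% B, 2, y_center, "+")
  Yc <- sweep(Y0, 2, y_center)
  r2y <- 1 - sum((Y0 - fitted)^2) / sum(Yc^2)
  structure(list(W = W, P = P, Q = Q, T = Tm, B = B,
                 ssy = ssy, r2y = r2y,
                 x_center = x_center, y_center = y_center,
                 levels = levels(labels), labels = labels,
                 n_components = n_components,
                 ppm = if (inherits(m, "spectral_matrix")) m$ppm else NULL,
                 scale_sd = if (inherits(m, "spectral_matrix"))
                   m$scale_sd else NULL),
            class = "nmr_plsda")
}

#' @export
print.nmr_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d component(s), classes %s, R2Y = %.3f\n",
              x$n_components, paste(x$levels, collapse = " vs "), x$r2y))
  invisible(x)
}

#' Predict class responses from a PLS-DA model
#'
#' @param object an `nmr_plsda` model.
#' @param newdata matrix (or [spectral_matrix()]) on the same variable
#'   scale as the training data.
#' @param type `"response"` for the continuous indicator prediction,
#'   `"class"` for hard labels (two classes: thresholded at the midpoint of
#'   the class codes; multi-class: arg-max column).
#' @param ... unused.
#' @return Matrix of responses, or a character vector of class labels.
#' @export
predict.nmr_plsda <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectral_matrix")) newdata$X
       else as.matrix(newdata)
  yhat <- sweep(sweep(X, 2, object$x_center) %*% object$B, 2,
                object$y_center, "+")
  if (type == "response") return(yhat)
  if (length(object$levels) == 2) {
    # class codes +1 (first level) and -1: midpoint 0
    ifelse(yhat[, 1] >= 0, object$levels[1], object$levels[2])
  } else {
    object$levels[max.col(yhat)]
  }
}

#' Variable importance in projection (VIP)
#'
#' `vip_j = sqrt( p * sum_a[ SSY_a * (w_ja / ||w_a||)^2 ] / sum_a SSY_a )`,
#' where `SSY_a` is the Y-variance explained by component `a` and `p` the
#' number of variables; the mean of the squared VIP scores is exactly 1.
#'
#' @param model an `nmr_plsda` model.
#' @return Numeric vector of per-variable VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "nmr_plsda"))
  if (sum(model$ssy) <= 0) stop("zero explained Y-variance")
  p <- nrow(model$W)
  W2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  sqrt(p * as.vector(W2 %*% model$ssy) / sum(model$ssy))
}

#' Back-transformed loadings with VIP colouring
#'
#' Multiplies each variable's loading by the standard deviation stored at
#' UV-scaling time, recovering a loadings profile on the original intensity
#' scale (a pseudo-spectrum), paired with the per-variable VIP score used
#' to colour it.
#'
#' @param model an `nmr_plsda` or `nmr_pca` model fitted on a UV-scaled
#'   [spectral_matrix()] (or supply `sds` explicitly).
#' @param sds per-variable standard deviations; defaults to the scaling
#'   metadata captured at fit time.
#' @param component which component's loadings to back-transform.
#' @return data.frame with `ppm` (if available), `loading`,
#'   `backtransformed` and `vip` (PLS-DA only).
#' @export
backtransform_loadings <- function(model, sds = NULL, component = 1) {
  if (is.null(sds)) sds <- model$scale_sd
  if (is.null(sds)) stop("no scaling metadata: supply column SDs")
  ld <- if (inherits(model, "nmr_plsda")) model$P[, component]
        else model$loadings[, component]
  if (length(sds) != length(ld))
    stop("SD vector length does not match the number of variables")
  out <- data.frame(loading = ld, backtransformed = ld * sds)
  if (!is.null(model$ppm)) out <- cbind(ppm = model$ppm, out)
  if (inherits(model, "nmr_plsda")) out$vip <- vip(model)
  out
}

#' Choose the number of PLS components by cross-validated Q2
#'
#' Adds components while the K-fold cross-validated Q2 improves by more
#' than `delta`, up to `max_components`.
#'
#' @param m UV-scaled [spectral_matrix()] or matrix.
#' @param labels class labels.
#' @param max_components cap on the number of components.
#' @param folds number of CV folds.
#' @param delta minimum Q2 improvement to accept another component.
#' @param seed RNG seed for the fold split.
#' @return Integer number of components (>= 1).
#' @export
choose_ncomp <- function(m, labels = NULL, max_components = 5, folds = 7,
                         delta = 0.01, seed = 1) {
  X <- if (inherits(m, "spectral_matrix")) m$X else as.matrix(m)
  if (is.null(labels) && inherits(m, "spectral_matrix"))
    labels <- m$samples$group
  labels <- factor(labels)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(min(folds, n)), n))
  q2 <- function(a) {
    press <- 0; tss <- 0
    for (f in unique(fold)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2 || any(table(labels[tr]) < 2))
        next
      fit <- fit_plsda(X[tr, , drop = FALSE], labels[tr],
                       min(a, sum(tr) - 1))
      y <- ifelse(labels == levels(labels)[1], 1, -1)
      yhat <- predict(fit, X[!tr, , drop = FALSE])[, 1]
      press <- press + sum((y[!tr] - yhat)^2)
      tss <- tss + sum((y[!tr] - mean(y[tr]))^2)
    }
    1 - press / tss
  }
  best <- 1; best_q2 <- q2(1)
  for (a in seq(2, max_components)) {
    qa <- q2(a)
    if (qa > best_q2 + delta) { best <- a; best_q2 <- qa } else break
  }
  best
}
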