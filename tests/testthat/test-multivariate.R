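test_that("PCA matches a dense SVD oracle and explains rank-1 data fully", {
  set.seed(31)
  # rank-1 matrix plus tiny noise
  u <- rnorm(10); v <- rnorm(50)
  X1 <- outer(u, v)
  p1 <- fit_pca(X1, 2)
  expect_gte(p1$explained_variance[1], 0.999)
  # oracle: full decomposition of the centred matrix
  X <- matrix(rnorm(10 * 50), 10, 50)
  p <- fit_pca(X, 3)
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  for (a in 1:3) {
    sc_oracle <- sv$u[, a] * sv$d[a]
    ld_oracle <- sv$v[, a]
    j <- which.max(abs(ld_oracle))
    if (ld_oracle[j] < 0) { ld_oracle <- -ld_oracle; sc_oracle <- -sc_oracle }
    expect_lt(max(abs(p$scores[, a] - sc_oracle)), 1e-8)
    expect_lt(max(abs(p$loadings[, a] - ld_oracle)), 1e-8)
  }
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_lt(max(abs(crossprod(p$loadings) - diag(3))), 1e-8)
  expect_error(fit_pca(X, 20), "n_components")
})

test_that("PCA separates well-separated synthetic classes on PC1", {
  co <- simulate_cohort(small_config(
    effects = plant(resolved_mets, c(1.5, -1.5)), seed = 32))
  sc <- uv_scale(prep_matrix(co))
  p <- fit_pca(sc, 2)
  g <- sc$samples$group
  expect_true(max(p$scores[g == "Pt", 1]) < min(p$scores[g == "N", 1]) ||
                min(p$scores[g == "Pt", 1]) > max(p$scores[g == "N", 1]))
})

test_that("PLS-DA component 1 matches the eigen-decomposition oracle", {
  set.seed(33)
  X <- matrix(rnorm(10 * 50), 10, 50)
  y <- rep(c("A", "B"), each = 5)
  fit <- fit_plsda(X, y, 1)
  # oracle: first weight is the dominant eigenvector of X'yy'X, i.e. the
  # normalized X'y direction; scores follow directly
  Xc <- scale(X, scale = FALSE)
  yv <- ifelse(y == "A", 1, -1); yv <- yv - mean(yv)
  M <- crossprod(Xc, yv) %*% crossprod(yv, Xc)
  w_oracle <- eigen(M, symmetric = TRUE)$vectors[, 1]
  # align sign with the fitted convention
  if (sum(w_oracle * fit$W[, 1]) < 0) w_oracle <- -w_oracle
  expect_lt(max(abs(fit$W[, 1] - w_oracle)), 1e-8)
  expect_lt(max(abs(fit$T[, 1] - Xc %*% w_oracle)), 1e-8)
  expect_lt(max(abs(colMeans(fit$T))), 1e-10)
})

test_that("a variable collinear with the response dominates a 1-component fit", {
  set.seed(34)
  X <- matrix(rnorm(20 * 30, sd = 0.05), 20, 30)
  y <- rep(c("A", "B"), each = 10)
  X[, 7] <- ifelse(y == "A", 1, -1) + rnorm(20, sd = 0.01)
  fit <- fit_plsda(X, y, 1)
  expect_equal(which.max(abs(fit$W[, 1])), 7)
  expect_gt(fit$r2y, 0.99)
  v <- vip(fit)
  expect_equal(which.max(v), 7)
  expect_gt(v[7], 1)
})

test_that("VIP has unit mean square and is 1 under weight symmetry", {
  set.seed(35)
  X <- matrix(rnorm(12 * 40), 12, 40)
  y <- rep(c("A", "B"), 6)
  fit <- fit_plsda(X, y, 3)
  expect_equal(mean(vip(fit)^2), 1, tolerance = 1e-8)
  # equal weights: duplicate one informative variable everywhere
  s <- ifelse(y == "A", 1, -1)
  Xeq <- matrix(rep(s, 5), ncol = 5) + matrix(rnorm(60, sd = 1e-6), 12, 5)
  feq <- fit_plsda(Xeq, y, 1)
  expect_equal(unname(vip(feq)), rep(1, 5), tolerance = 1e-3)
})

test_that("permuted labels collapse the training fit toward chance", {
  co <- simulate_cohort(small_config(
    effects = plant(resolved_mets, c(1, -1)), seed = 36))
  sc <- uv_scale(prep_matrix(co))
  r2_true <- fit_plsda(sc, n_components = 1)$r2y
  set.seed(361)
  r2_perm <- replicate(30, {
    fit_plsda(sc$X, sample(sc$samples$group), 1)$r2y
  })
  expect_gt(r2_true, quantile(r2_perm, 0.95))
})

test_that("back-transformed loadings rescale by the stored SDs", {
  co <- simulate_cohort(small_config(
    effects = plant(c("Alanine", "ATP"), c(-1.2, 1.2)), seed = 37))
  sc <- uv_scale(prep_matrix(co))
  fit <- fit_plsda(sc, n_components = 1)
  bt <- backtransform_loadings(fit)
  expect_equal(bt$backtransformed, bt$loading * sc$scale_sd,
               ignore_attr = TRUE)
  # SDs of 1 leave loadings unchanged; doubling one SD doubles the value
  bt1 <- backtransform_loadings(fit, sds = rep(1, nrow(fit$P)))
  expect_equal(bt1$backtransformed, bt1$loading)
  sds2 <- rep(1, nrow(fit$P)); sds2[5] <- 2
  bt2 <- backtransform_loadings(fit, sds = sds2)
  expect_equal(bt2$backtransformed[5], 2 * bt2$loading[5])
  # the strongest back-transformed windows sit on the planted metabolites
  top_ppm <- bt$ppm[order(-abs(bt$backtransformed))[1:40]]
  expect_true(any(abs(top_ppm - 1.48) < 0.03))  # alanine doublet
  expect_true(any(abs(top_ppm - 6.14) < 0.03))  # ATP doublet
  expect_error(backtransform_loadings(fit_plsda(sc$X, sc$samples$group, 1)),
               "scaling metadata")
})

test_that("model statistics are invariant to variable reordering", {
  set.seed(38)
  X <- matrix(rnorm(14 * 25), 14, 25)
  y <- rep(c("A", "B"), 7)
  fit <- fit_plsda(X, y, 2)
  perm <- sample(25)
  fitp <- fit_plsda(X[, perm], y, 2)
  expect_equal(vip(fitp), vip(fit)[perm], tolerance = 1e-8)
  expect_equal(fitp$r2y, fit$r2y, tolerance = 1e-10)
  expect_equal(abs(fitp$W[, 1]), abs(fit$W[perm, 1]), tolerance = 1e-8)
})

test_that("STOCSY links peaks of the same metabolite and not independent ones", {
  # single group: no between-group structure, correlations driven purely
  # by the shared per-metabolite concentration factors
  des <- data.frame(group = "A", n = 30L, avg_cell_count = 1000,
                    cell_count_rel_error = 0)
  co <- simulate_cohort(small_config(groups = des, seed = 39,
                                     noise_sd = 0.2, shift_jitter_sd = 0))
  m <- prep_matrix(co)
  st <- stocsy(m, 6.14)  # ATP doublet; its partner singlet is at 8.52
  expect_equal(st$correlation[which.min(abs(st$ppm - st$driver_ppm))], 1,
               tolerance = 1e-12)
  expect_true(all(abs(st$correlation) <= 1 + 1e-12, na.rm = TRUE))
  r_partner <- st$correlation[which.min(abs(st$ppm - 8.52))]
  expect_gte(r_partner, 0.95)
  # independent metabolite (formate, 8.46): below the 95% null quantile
  # for n = 30 (|r| < qt-based bound ~0.36)
  r_indep <- st$correlation[which.min(abs(st$ppm - 8.46))]
  null_q <- sqrt(qt(0.975, 28)^2 / (qt(0.975, 28)^2 + 28))
  expect_lt(abs(r_indep), null_q)
  expect_error(stocsy_zero <- {
    mz <- m; mz$X[, 5] <- 1; stocsy(mz, mz$ppm[5])
  }, "zero-variance")
})
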