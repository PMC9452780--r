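test_that("default panel contains the assigned resonances with valid structure", {
  panel <- default_panel()
  expect_true(all(tapply(panel$rel_intensity, panel$metabolite,
                         function(x) abs(sum(x) - 1) < 1e-9)))
  has <- function(met, ppm, mult)
    any(panel$metabolite == met & abs(panel$center - ppm) < 1e-9 &
          panel$multiplicity == mult)
  expect_true(has("Alanine", 1.48, "d"))
  expect_true(has("UMP", 8.10, "d"))
  expect_true(has("Lactate", 1.33, "d"))
  expect_true(has("PC", 3.22, "s"))
  expect_true(has("UDP-GlcNAc", 5.52, "dd"))
  expect_true(has("TSP", 0.0, "s"))
  # at least the ~40-compound assignment list
  expect_gte(length(unique(panel$metabolite)), 40)
  # no multiplet centre inside the water band
  expect_false(any(panel$center >= 4.7 & panel$center <= 5.0))
  # line expansion conserves weight per metabolite
  lines <- peak_lines(panel)
  expect_true(all(abs(tapply(lines$weight, lines$metabolite, sum) - 1)
                  < 1e-9))
})

test_that("cohort size and structure follow the design", {
  co <- simulate_cohort(small_config(groups = cohort_design(), seed = 2))
  expect_equal(nrow(co$matrix$X), 40)  # 7+6+5+7+6+9
  expect_equal(as.vector(table(co$matrix$samples$group)[cohort_design()$group]),
               cohort_design()$n)
  expect_s3_class(co$matrix, "spectral_matrix")
})

test_that("all-deterministic configuration gives identical within-group spectra", {
  cfg <- small_config(seed = 3, shift_jitter_sd = 0, noise_sd = 0,
                      between_sample_cv = 0, reference_peak_cv = 0,
                      cell_count_cv = 0)
  co <- simulate_cohort(cfg)
  g <- co$matrix$samples$group
  for (grp in unique(g)) {
    X <- co$matrix$X[g == grp, , drop = FALSE]
    expect_equal(max(abs(sweep(X, 2, X[1, ]))), 0)
  }
})

test_that("with no baseline or noise, spectral area matches the analytic line areas", {
  cfg <- small_config(groups = cohort_design()[1, , drop = FALSE],
                      seed = 4, shift_jitter_sd = 0, noise_sd = 0,
                      between_sample_cv = 0, reference_peak_cv = 0,
                      cell_count_cv = 0, baseline_amplitude = 0,
                      water_amplitude = 0, n_points = 8192)
  co <- simulate_cohort(cfg)
  ppm <- co$matrix$ppm
  x <- rev(ppm); y <- rev(co$matrix$X[1, ])
  trap <- sum(diff(x) * (y[-1] + y[-length(y)])) / 2
  lines <- peak_lines(cfg$panel)
  w <- ifelse(lines$metabolite == "TSP", cfg$tsp_area, 1) * lines$weight
  analytic <- sum(w * lorentzian_area(lines$position, cfg$peak_width,
                                      min(ppm), max(ppm)))
  expect_lt(abs(trap - analytic) / analytic, 1e-6)
})

test_that("planted log-fold changes the window integral by the expected factor", {
  # one group of n = 20 vs reference, lactate raised by e^0.7
  des <- data.frame(group = c("A", "B"), n = c(20L, 20L),
                    avg_cell_count = c(1000, 1000),
                    cell_count_rel_error = c(0, 0))
  panel <- default_panel()
  panel <- panel[panel$metabolite %in% c("Lactate", "TSP"), ]
  cfg <- small_config(groups = des, panel = panel,
                      effects = data.frame(metabolite = "Lactate",
                                           group = "B", log_fold = 0.7),
                      seed = 5, baseline_amplitude = 0, noise_sd = 0.05,
                      shift_jitter_sd = 0)
  co <- simulate_cohort(cfg)
  m <- co$matrix
  win <- data.frame(metabolite = "Lactate", center = 1.33,
                    halfwidth = 0.03)
  it <- integrate_windows(m, win)
  a <- it$values[m$samples$group == "A", 1]
  b <- it$values[m$samples$group == "B", 1]
  ratio <- mean(b) / mean(a)
  # lognormal mean is exp(log_fold); 3 Monte-Carlo SEs at CV 0.25, n = 20
  se <- exp(0.7) * cfg$between_sample_cv * sqrt(2 / 20)
  expect_lt(abs(ratio - exp(0.7)), 3 * se)
})

test_that("regeneration is deterministic in the seed and stable across seeds", {
  cfg <- small_config(seed = 6)
  m1 <- regenerate(cfg, 42)
  m2 <- regenerate(cfg, 42)
  expect_identical(m1$X, m2$X)
  m3 <- regenerate(cfg, 43)
  expect_false(identical(m1$X, m3$X))
  # different seeds: equal expected signal within 3 SE of the difference
  win <- which(m1$ppm > 1.30 & m1$ppm < 1.36)
  w1 <- rowMeans(m1$X[, win]); w3 <- rowMeans(m3$X[, win])
  se_diff <- sqrt(var(w1) / length(w1) + var(w3) / length(w3))
  expect_lt(abs(mean(w1) - mean(w3)), 3 * se_diff)
})

test_that("residual noise scales linearly with noise_sd", {
  cfg1 <- small_config(seed = 7, noise_sd = 0.5)
  cfg2 <- small_config(seed = 7, noise_sd = 1.0)
  m1 <- simulate_cohort(cfg1)$matrix
  m2 <- simulate_cohort(cfg2)$matrix
  # signal-free region: 9.6..9.9 ppm holds no multiplet
  j <- which(m1$ppm > 9.6 & m1$ppm < 9.9)
  r1 <- sd(m1$X[1, j] - mean(m1$X[1, j]))
  r2 <- sd(m2$X[1, j] - mean(m2$X[1, j]))
  expect_lt(abs(r2 / r1 - 2), 0.1)
})

test_that("window integral mean increases monotonically with log_fold", {
  des <- data.frame(group = c("A", "B"), n = c(8L, 8L),
                    avg_cell_count = c(1000, 1000),
                    cell_count_rel_error = c(0, 0))
  means <- vapply(c(0, 0.5, 1.0), function(lf) {
    cfg <- small_config(groups = des, seed = 8, noise_sd = 0,
                        between_sample_cv = 0, shift_jitter_sd = 0,
                        cell_count_cv = 0,
                        effects = if (lf > 0)
                          data.frame(metabolite = "Formate", group = "B",
                                     log_fold = lf) else NULL)
    co <- simulate_cohort(cfg)
    it <- integrate_windows(co$matrix,
                            data.frame(metabolite = "Formate",
                                       center = 8.46, halfwidth = 0.03))
    mean(it$values[co$matrix$samples$group == "B", 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("invalid configurations are rejected", {
  des <- two_group_design()
  expect_error(simulation_config(groups = des, n_points = 512),
               "1024")
  des2 <- des; des2$group <- c("N", "N")
  expect_error(simulation_config(groups = des2), "duplicate")
  expect_error(simulation_config(groups = des, ppm_range = c(10, -0.5)),
               "grid")
  expect_error(
    simulation_config(groups = des,
                      effects = data.frame(metabolite = "Alanine",
                                           group = "N", log_fold = 0.5)),
    "reference")
})
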