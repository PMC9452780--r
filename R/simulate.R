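#' Study design of the murine pancreatic cohort
#'
#' The six experimental groups with their sample sizes and group-average
#' pancreatic cell counts (with relative errors from microscopic counting):
#' normal tissue (N), caerulein-induced acute pancreatitis (Pt), low-grade
#' PanIN lesions (LG), high-grade PanIN lesions (HG), pancreatic ductal
#' adenocarcinoma (PDA) and sarcomatoid carcinoma (Sarc).
#'
#' @return data.frame with columns `group`, `n`, `avg_cell_count`,
#'   `cell_count_rel_error`.
#' @export
cohort_design <- function() {
  data.frame(
    group = c("N", "Pt", "LG", "HG", "PDA", "Sarc"),
    n = c(7L, 6L, 5L, 7L, 6L, 9L),
    avg_cell_count = c(1761, 4454, 2794, 2422, 2318, 2958),
    cell_count_rel_error = c(0.19, 0.08, 0.19, 0.07, 0.29, 0.19),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic spectral-cohort
#' generator. Defaults emulate the study conditions: the six groups of
#' [cohort_design()], the assigned-metabolite panel of [default_panel()],
#' Lorentzian lineshapes, per-sample chemical-shift jitter, a slowly varying
#' baseline, Gaussian noise, a residual water hump at 4.7-5.0 ppm, and a
#' 0.0 ppm reference peak whose intensity varies between samples
#' (lognormal, CV `reference_peak_cv`) and is therefore unusable for
#' quantitation.
#'
#' @param groups design data.frame (`group`, `n`, `avg_cell_count`,
#'   `cell_count_rel_error`); first row is the reference group.
#' @param panel metabolite peak panel, see [default_panel()].
#' @param effects data.frame of planted effects (`metabolite`, `group`,
#'   `log_fold`): natural-log concentration multipliers relative to the
#'   reference group. `NULL` means no planted effects.
#' @param ppm_range grid limits in ppm.
#' @param n_points number of grid points (>= 1024).
#' @param peak_width Lorentzian half-width at half-maximum (ppm).
#' @param shift_jitter_sd per-sample, per-multiplet Gaussian chemical-shift
#'   jitter SD (ppm), truncated at +/- 3 SD.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param baseline_amplitude amplitude of the (deterministic, slowly
#'   varying) baseline.
#' @param between_sample_cv lognormal CV of metabolite concentrations
#'   within a group.
#' @param reference_peak_cv lognormal CV of the TSP reference-peak area.
#' @param water_amplitude area of the residual water hump.
#' @param extracellular character vector of metabolites whose signal does
#'   NOT scale with cell count (default: none, i.e. all scale).
#' @param cell_count_cv per-sample cell-count CV; `NULL` uses each group's
#'   `cell_count_rel_error`.
#' @param base_concentration named vector of baseline concentrations;
#'   unnamed metabolites default to 1.
#' @param tsp_area mean area of the TSP reference peak.
#' @param seed integer RNG seed.
#'
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(groups = cohort_design(),
                              panel = default_panel(),
                              effects = NULL,
                              ppm_range = c(-0.5, 10),
                              n_points = 32768,
                              peak_width = 0.0015,
                              shift_jitter_sd = 0.003,
                              noise_sd = 0.5,
                              baseline_amplitude = 0.2,
                              between_sample_cv = 0.25,
                              reference_peak_cv = 0.3,
                              water_amplitude = 10,
                              extracellular = character(),
                              cell_count_cv = NULL,
                              base_concentration = NULL,
                              tsp_area = 5,
                              seed = 1L) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1,
            all(c("group", "n", "avg_cell_count") %in% names(groups)))
  if (anyDuplicated(groups$group)) stop("duplicate group labels")
  if (any(groups$n < 2)) stop("all group sizes must be >= 2")
  if (n_points < 1024) stop("n_points must be >= 1024")
  if (diff(ppm_range) <= 0) stop("non-positive grid spacing")
  stopifnot(shift_jitter_sd >= 0, noise_sd >= 0, between_sample_cv >= 0,
            reference_peak_cv >= 0)
  validate_panel(panel)
  if (!is.null(effects)) {
    stopifnot(all(c("metabolite", "group", "log_fold") %in% names(effects)))
    bad <- setdiff(effects$metabolite, panel$metabolite)
    if (length(bad)) stop("effects name metabolites absent from panel: ",
                          paste(bad, collapse = ", "))
    if (any(effects$group == groups$group[1] & effects$log_fold != 0))
      stop("reference group must have log_fold = 0")
  }
  structure(list(groups = groups, panel = panel, effects = effects,
                 ppm_range = ppm_range, n_points = as.integer(n_points),
                 peak_width = peak_width, shift_jitter_sd = shift_jitter_sd,
                 noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
                 between_sample_cv = between_sample_cv,
                 reference_peak_cv = reference_peak_cv,
                 water_amplitude = water_amplitude,
                 water_region = c(4.7, 5.0),
                 extracellular = extracellular,
                 cell_count_cv = cell_count_cv,
                 base_concentration = base_concentration,
                 tsp_area = tsp_area,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lognormal draw with mean `m` and coefficient of variation `cv`
.rlnorm_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# truncated normal (+/- 3 SD), sd may be zero
.rnorm_trunc3 <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -3 * sd), 3 * sd)
}

#' Simulate a synthetic spectral cohort
#'
#' Generates one spectrum per sample on a common ppm grid. Each metabolite's
#' concentration is drawn log-normally around its group mean (reference mean
#' times `exp(log_fold)`); each multiplet is rendered as a sum of Lorentzian
#' lines (unit analytic area, scaled by concentration and line weight) with
#' per-sample chemical-shift jitter. A deterministic slowly-varying
#' baseline, Gaussian noise, a residual water hump in the 4.7-5.0 ppm band
#' and a variable-intensity TSP reference peak at 0.0 ppm are added.
#' Metabolite signal scales linearly with the sample's cell-count draw
#' (relative to the reference-group average) unless the metabolite is listed
#' as extracellular, so that cell-count normalization is meaningful.
#'
#' @param config a `sim_config`, see [simulation_config()].
#' @return A list of class `nmr_cohort` with elements `matrix` (a
#'   [spectral_matrix()]), `design` (per-group design), `ground_truth`
#'   (planted effects), `concentrations` (samples x metabolites) and
#'   `cell_counts`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- seq(config$ppm_range[2], config$ppm_range[1],
              length.out = config$n_points)   # descending
  groups <- config$groups
  mets <- unique(config$panel$metabolite)
  mets <- setdiff(mets, "TSP")
  base <- rep(1, length(mets)); names(base) <- mets
  if (!is.null(config$base_concentration)) {
    keep <- intersect(names(config$base_concentration), mets)
    base[keep] <- config$base_concentration[keep]
  }
  # per-group concentration means
  mean_conc <- matrix(base, nrow = nrow(groups), ncol = length(mets),
                      byrow = TRUE, dimnames = list(groups$group, mets))
  if (!is.null(config$effects)) {
    for (i in seq_len(nrow(config$effects))) {
      e <- config$effects[i, ]
      if (e$metabolite %in% mets && e$group %in% groups$group)
        mean_conc[e$group, e$metabolite] <-
          mean_conc[e$group, e$metabolite] * exp(e$log_fold)
    }
  }
  n_total <- sum(groups$n)
  sample_group <- rep(groups$group, groups$n)
  sample_id <- paste0(sample_group, "_",
                      unlist(lapply(groups$n, seq_len)))
  lines <- peak_lines(config$panel)
  tsp_lines <- lines[lines$metabolite == "TSP", , drop = FALSE]
  met_lines <- lines[lines$metabolite != "TSP", , drop = FALSE]
  # multiplets get one jitter value each: map lines -> multiplet index
  mult_id <- interaction(config$panel$metabolite, config$panel$center,
                         drop = TRUE)
  line_mult <- integer(nrow(lines))
  k <- 0
  for (i in seq_len(nrow(config$panel))) {
    nl <- config$panel$n_lines[i]
    line_mult[k + seq_len(nl)] <- i
    k <- k + nl
  }
  met_line_mult <- line_mult[lines$metabolite != "TSP"]
  tsp_line_mult <- line_mult[lines$metabolite == "TSP"]

  ref_cells <- groups$avg_cell_count[1]
  gamma <- config$peak_width
  X <- matrix(0, n_total, config$n_points)
  conc_mat <- matrix(NA_real_, n_total, length(mets),
                     dimnames = list(sample_id, mets))
  cells <- numeric(n_total)
  # deterministic slowly-varying baseline, identical for all samples
  baseline <- config$baseline_amplitude *
    (1 + 0.5 * sin(2 * pi * grid / 7) + 0.3 * cos(2 * pi * grid / 3.1))
  water <- config$water_amplitude *
    (gammaw <- 0.04) / (pi * ((grid - 4.85)^2 + gammaw^2))

  for (s in seq_len(n_total)) {
    g <- sample_group[s]
    gi <- match(g, groups$group)
    cv_cells <- if (is.null(config$cell_count_cv))
      groups$cell_count_rel_error[gi] else config$cell_count_cv
    cells[s] <- .rlnorm_cv(1, groups$avg_cell_count[gi], cv_cells)
    conc <- .rlnorm_cv(length(mets), 1, config$between_sample_cv) *
      as.numeric(mean_conc[g, ])
    names(conc) <- mets
    conc_mat[s, ] <- conc
    cell_scale <- cells[s] / ref_cells
    scale_per_met <- ifelse(mets %in% config$extracellular, 1, cell_scale)
    names(scale_per_met) <- mets
    amp <- conc[met_lines$metabolite] *
      scale_per_met[met_lines$metabolite] * met_lines$weight
    jit_mult <- .rnorm_trunc3(nrow(config$panel), config$shift_jitter_sd)
    pos <- met_lines$position + jit_mult[met_line_mult]
    spec <- lorentzian_sum(grid, pos, amp, gamma)
    # TSP reference: variable area, independent of cell count
    tsp_amp <- .rlnorm_cv(1, config$tsp_area, config$reference_peak_cv) *
      tsp_lines$weight
    tsp_pos <- tsp_lines$position + jit_mult[tsp_line_mult]
    spec <- spec + lorentzian_sum(grid, tsp_pos, tsp_amp, gamma)
    spec <- spec + baseline + water
    if (config$noise_sd > 0)
      spec <- spec + stats::rnorm(config$n_points, 0, config$noise_sd)
    X[s, ] <- spec
  }
  samples <- data.frame(sample_id = sample_id, group = sample_group,
                        cell_count = cells, stringsAsFactors = FALSE)
  mat <- spectral_matrix(grid, X, samples)
  structure(list(matrix = mat, design = groups,
                 ground_truth = config$effects,
                 concentrations = conc_mat,
                 cell_counts = cells,
                 config = config),
            class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat("Synthetic NMR cohort\n")
  print(x$matrix)
  if (!is.null(x$ground_truth))
    cat(sprintf("  planted effects: %d\n", nrow(x$ground_truth)))
  invisible(x)
}

# sum of unit-area Lorentzians evaluated on `grid`
lorentzian_sum <- function(grid, positions, amplitudes, gamma) {
  out <- numeric(length(grid))
  for (i in seq_along(positions)) {
    out <- out + amplitudes[i] * gamma /
      (pi * ((grid - positions[i])^2 + gamma^2))
  }
  out
}

#' Analytic area of a Lorentzian line over a finite ppm interval
#'
#' @param position line centre (ppm).
#' @param gamma half-width at half-maximum (ppm).
#' @param lo,hi integration limits.
#' @return Area fraction of a unit-area line inside `[lo, hi]`.
#' @export
lorentzian_area <- function(position, gamma, lo, hi) {
  (atan((hi - position) / gamma) - atan((lo - position) / gamma)) / pi
}

#' Regenerate a cohort's spectral matrix under a given seed
#'
#' Re-runs the generator with the same configuration but the given seed.
#' Identical seeds give byte-identical matrices; different seeds change the
#' stochastic draws (noise, jitter, concentrations) only.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return A [spectral_matrix()].
#' @export
regenerate <- function(config, seed) {
  config$seed <- as.integer(seed)
  simulate_cohort(config)$matrix
}
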