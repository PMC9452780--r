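# Shared builders for synthetic test cohorts. Grids are kept modest
# (2048 points over -0.5..10 ppm) so the suite stays fast; the generator
# itself defaults to the acquisition-sized grid.

two_group_design <- function() cohort_design()[1:2, ]  # N (7), Pt (6)

# metabolites with well-separated primary windows, used for planted-effect
# tests (no overlap with neighbouring multiplets at halfwidth 0.03)
resolved_mets <- c("Alanine", "ATP", "AMP", "ADP", "Formate", "UMP",
                   "Niacinamide", "GSH", "Histidine", "Fumarate")

# peak_width is widened in proportion to the coarser grid so that peaks
# stay resolved by several grid points, as on the acquisition-sized grid
small_config <- function(effects = NULL, seed = 1, groups = two_group_design(),
                         ...) {
  args <- list(...)
  if (is.null(args$peak_width)) args$peak_width <- 0.006
  if (is.null(args$n_points)) args$n_points <- 2048
  do.call(simulation_config,
          c(list(groups = groups, effects = effects, seed = seed), args))
}

# exclusion + alignment-free normalized matrix for quick tests
prep_matrix <- function(cohort, mode = "total_area", align = FALSE) {
  m <- exclude_region(cohort$matrix, 4.7, 5.0)
  m <- exclude_region(m, -0.03, 0.03)
  if (align) m <- rspa_align(m, min_segment = 64)
  normalize_spectra(m, mode, design = cohort$design)
}

plant <- function(mets, log_fold, group = "Pt") {
  data.frame(metabolite = mets, group = group,
             log_fold = rep_len(log_fold, length(mets)),
             stringsAsFactors = FALSE)
}
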