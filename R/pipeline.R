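#' End-to-end pipeline run
#'
#' Orchestrates simulate (or load) -> common grid -> water/TSP exclusion ->
#' RSPA alignment -> dual normalization -> UV scaling -> PCA/PLS-DA/MCCV ->
#' window integration -> univariate screen -> signature derivation, writing
#' plain-text artifacts (TSV/JSON) plus a manifest with checksums. The
#' exclusion step precedes normalization so that neither the water band nor
#' the variable-intensity TSP resonance enters the total area.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{simulation}{a [simulation_config()] (or supply `spectra_file`
#'       and `design` to read data instead).}
#'     \item{comparisons}{list of `c(group_a, group_b)` pairs.}
#'     \item{normalizations}{subset of `c("total_area", "cell_count")`.}
#'     \item{mccv}{list(blocks, runs, n_components) or `NULL` to skip.}
#'     \item{align}{logical, run RSPA (default `TRUE`).}
#'     \item{assignments}{integration windows; default
#'       [assignment_table()].}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed, recorded in the manifest.}
#'   }
#' @return Invisibly, a list with the computed objects (`cohort`,
#'   `matrices`, `comparisons`, `signatures`, `mccv`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  normalizations <- config$normalizations %||% c("total_area", "cell_count")
  comparisons <- config$comparisons %||% list(c("Pt", "N"))
  align <- config$align %||% TRUE

  # --- input stage ---------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- seed
    cohort <- simulate_cohort(sim)
    mat <- cohort$matrix
    design <- cohort$design
  } else if (!is.null(config$spectra_file)) {
    spectra <- read_spectra(config$spectra_file, design = config$design)
    grid <- config$grid %||% spectra[[1]]$ppm
    mat <- to_common_grid(spectra, grid)
    mat$samples$group <- vapply(spectra, `[[`, "", "group")
    cohort <- NULL
    design <- config$design
  } else stop("config needs either a simulation or a spectra_file")
  groups_named <- unique(unlist(comparisons))
  missing_groups <- setdiff(groups_named, mat$samples$group)
  if (length(missing_groups))
    stop("comparison names absent group(s): ",
         paste(missing_groups, collapse = ", "))

  # --- preprocessing -------------------------------------------------
  mat <- exclude_region(mat, 4.7, 5.0)            # residual water
  mat <- exclude_region(mat, -0.03, 0.03)         # TSP reference
  if (align) mat <- rspa_align(mat)
  assignments <- config$assignments %||%
    (if (!is.null(config$simulation))
      assignment_table(config$simulation$panel) else assignment_table())
  norm_mats <- list()
  for (nm in normalizations)
    norm_mats[[nm]] <- normalize_spectra(mat, nm, design = design)

  # --- multivariate + univariate per comparison ----------------------
  mccv_cfg <- config$mccv %||% list(blocks = 7, runs = 500,
                                    n_components = 2)
  results <- list(); mccv_out <- list(); pairs <- list()
  scaled_all <- uv_scale(norm_mats[[1]])
  pca_all <- fit_pca(scaled_all, 2)
  for (cmpv in comparisons) {
    key <- paste(cmpv, collapse = "_vs_")
    keep <- mat$samples$group %in% cmpv
    per_norm <- list()
    for (nm in names(norm_mats)) {
      sub <- norm_mats[[nm]]
      sub$X <- sub$X[keep, , drop = FALSE]
      sub$samples <- sub$samples[keep, , drop = FALSE]
      tabi <- suppressWarnings(integrate_windows(sub, assignments))
      per_norm[[nm]] <- compare_groups(tabi, cmpv[1], cmpv[2])
      if (nm == "total_area" && !is.null(mccv_cfg)) {
        mccv_out[[key]] <- mccv(sub,
                                factor(sub$samples$group,
                                       levels = cmpv),
                                n_blocks = mccv_cfg$blocks,
                                n_runs = mccv_cfg$runs,
                                n_components = mccv_cfg$n_components,
                                seed = seed)
      }
    }
    results[[key]] <- per_norm
    if (all(c("total_area", "cell_count") %in% names(per_norm)))
      pairs[[key]] <- build_signature_pair(per_norm$total_area,
                                           per_norm$cell_count)
  }

  # --- artifacts -----------------------------------------------------
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    files <<- c(files, name)
  }
  for (key in names(results))
    for (nm in names(results[[key]]))
      wr(as.data.frame(results[[key]][[nm]]),
         sprintf("compare_%s_%s.tsv", key, nm))
  for (key in names(mccv_out)) {
    mm <- mccv_out[[key]]
    wr(list(q2_median = mm$q2_median, cr = mm$cr,
            sensitivity = mm$sensitivity, specificity = mm$specificity,
            confusion = as.list(mm$confusion)),
       sprintf("mccv_%s.json", key))
  }
  wr(data.frame(ppm = pca_all$ppm,
                pc1 = pca_all$loadings[, 1],
                pc2 = pca_all$loadings[, 2]), "pca_loadings.tsv")
  if (!is.null(cohort) && !is.null(cohort$ground_truth))
    wr(cohort$ground_truth, "ground_truth.tsv")
  manifest <- list(
    seed = seed,
    normalizations = normalizations,
    comparisons = lapply(comparisons, paste, collapse = "_vs_"),
    aligned = align,
    n_samples = nrow(mat$X), n_variables = ncol(mat$X),
    artifacts = lapply(files, function(f)
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, matrix = mat, matrices = norm_mats,
                 pca = pca_all, comparisons = results,
                 signature_pairs = pairs, mccv = mccv_out,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
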