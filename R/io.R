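#' Read 1D spectra
#'
#' Reads a cohort of spectra either from a delimited matrix file (first
#' column the ppm axis, one column per sample) or from Bruker processed-data
#' directories (one `pdata/<procno>` directory per sample, containing the
#' binary `1r` vector and its `procs` parameter file).
#'
#' @param path for `format = "matrix"`, a TSV/CSV file; for
#'   `format = "bruker"`, a character vector of processed-data directories
#'   (each containing `1r` and `procs`).
#' @param format `"matrix"` or `"bruker"`.
#' @param design optional data.frame (`sample_id`, `group`, optionally
#'   `cell_count`) attaching group labels; every sample must appear in it.
#' @return A list of [nmr_spectrum()] objects.
#' @export
read_spectra <- function(path, format = c("matrix", "bruker"),
                         design = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("matrix file needs a ppm column plus samples")
    ppm <- tab[[1]]
    d <- diff(ppm)
    if (!(all(d > 0) || all(d < 0)))
      stop("non-monotone ppm axis in ", path)
    spectra <- lapply(2:ncol(tab), function(j) {
      v <- tab[[j]]
      if (any(is.na(v))) stop("ragged matrix: missing values in column ",
                              names(tab)[j])
      nmr_spectrum(names(tab)[j], ppm, v)
    })
  } else {
    spectra <- lapply(path, read_bruker_1r)
  }
  if (!is.null(design)) {
    ids <- vapply(spectra, `[[`, "", "sample_id")
    miss <- setdiff(ids, design$sample_id)
    if (length(miss))
      stop("unknown sample id in design: ", paste(miss, collapse = ", "))
    for (i in seq_along(spectra))
      spectra[[i]]$group <-
        design$group[match(ids[i], design$sample_id)]
  }
  spectra
}

#' Write a spectral matrix as a delimited file
#'
#' First column `ppm`, one column per sample; readable by [read_spectra()].
#'
#' @param m a [spectral_matrix()].
#' @param path output file (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(ppm = m$ppm, t(m$X), check.names = FALSE)
  names(tab) <- c("ppm", m$samples$sample_id)
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Bruker processed 1D data: pdata/<procno>/{1r, procs}. `1r` is a vector of
# 32-bit integers scaled by 2^NC_proc; OFFSET is the ppm of the first point
# and SW_p/SF the spectral width in ppm.
read_bruker_1r <- function(dir, sample_id = basename(dir)) {
  procs <- file.path(dir, "procs")
  oner <- file.path(dir, "1r")
  if (!file.exists(procs) || !file.exists(oner))
    stop("not a Bruker processed-data directory: ", dir)
  txt <- readLines(procs, warn = FALSE)
  getpar <- function(name) {
    ln <- grep(sprintf("^##\\$%s=", name), txt, value = TRUE)
    if (!length(ln)) stop("missing parameter ", name, " in ", procs)
    as.numeric(sub(".*=\\s*", "", ln[1]))
  }
  si <- as.integer(getpar("SI"))
  offset <- getpar("OFFSET")
  swp <- getpar("SW_p")
  sf <- getpar("SF")
  nc <- getpar("NC_proc")
  byt <- getpar("BYTORDP")
  endian <- if (byt == 0) "little" else "big"
  raw <- readBin(oner, what = "integer", n = si, size = 4, endian = endian)
  if (length(raw) != si) stop("1r file shorter than SI in ", dir)
  intensity <- raw * 2^nc
  sw_ppm <- swp / sf
  ppm <- offset - sw_ppm * (seq_len(si) - 1) / (si - 1)  # descending
  nmr_spectrum(sample_id, ppm, intensity)
}

#' Write a spectrum as a synthetic Bruker processed-data directory
#'
#' Creates `1r` (32-bit integers) and a minimal `procs` file so that
#' [read_spectra()] with `format = "bruker"` can read it back. Intended for
#' round-trip testing and interoperability checks; intensities are stored
#' with an integer scaling chosen to preserve relative precision.
#'
#' @param spectrum an [nmr_spectrum()] (descending ppm).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bruker_1r <- function(spectrum, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ppm <- spectrum$ppm
  if (diff(ppm)[1] > 0) {
    ppm <- rev(ppm); spectrum$intensity <- rev(spectrum$intensity)
  }
  si <- length(ppm)
  sf <- 600
  sw_ppm <- ppm[1] - ppm[si]
  # pick NC_proc so the largest magnitude fits comfortably in int32
  mx <- max(abs(spectrum$intensity), 1e-12)
  nc <- ceiling(log2(mx / 2^30))
  ints <- as.integer(round(spectrum$intensity / 2^nc))
  writeLines(c("##TITLE=synthetic processed data",
               sprintf("##$SI= %d", si),
               sprintf("##$OFFSET= %.10g", ppm[1]),
               sprintf("##$SW_p= %.10g", sw_ppm * sf),
               sprintf("##$SF= %.10g", sf),
               sprintf("##$NC_proc= %d", nc),
               "##$BYTORDP= 0"),
             file.path(dir, "procs"))
  writeBin(ints, file.path(dir, "1r"), size = 4, endian = "little")
  invisible(dir)
}

#' Load a packaged reference table
#'
#' Machine-readable versions of the study's printed tables: `"T1"` the
#' group design (sample sizes, strains, ages, average cell counts), `"T2"`
#' the pancreatitis comparisons (Pt vs N and Pt vs LG, tissue and cell
#' signatures), `"T3"` the disease-progression comparisons (LG vs N,
#' HG vs LG, PDA vs HG, Sarc vs PDA; tissue signature only). Absent table
#' cells are absent rows, not zeros: the tables report only variations
#' passing the significance filter (|ES| > error and p <= 0.05).
#'
#' @param table_id one of `"T1"`, `"T2"`, `"T3"`.
#' @return For `"T1"` a design data.frame; otherwise a data.frame of
#'   reported effect sizes with per-row flags (`fdr_ns`: significance lost
#'   after FDR correction; `pt_signature_member`; `cell_maintained`).
#' @export
load_fixture <- function(table_id = c("T1", "T2", "T3")) {
  table_id <- match.arg(table_id)
  f <- switch(table_id,
              T1 = "table1_design.tsv",
              T2 = "table2_signatures.tsv",
              T3 = "table3_progression.tsv")
  path <- system.file("extdata", f, package = "nmrmetab", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (table_id == "T1") {
    class(tab) <- c("sample_design", class(tab))
  } else {
    audit_fixture(tab)
  }
  tab
}

#' Audit a reference table against its inclusion rule
#'
#' Every reported variation must satisfy |ES| > error and p <= 0.05.
#'
#' @param fix a fixture data.frame from [load_fixture()].
#' @return The fixture, invisibly; errors if a row violates the rule.
#' @export
audit_fixture <- function(fix) {
  stopifnot(all(c("es", "es_error", "p_value") %in% names(fix)))
  bad <- abs(fix$es) <= fix$es_error | fix$p_value > 0.05
  if (any(bad))
    stop("fixture rows violate |ES| > error & p <= 0.05: ",
         paste(fix$metabolite[bad], collapse = ", "))
  invisible(fix)
}

#' Reference-table rows as comparison results
#'
#' Reshapes one comparison of a packaged reference table into the
#' `comparison_result` data.frame produced by [compare_groups()], so the
#' signature operations run identically on packaged and computed results.
#'
#' @param fix fixture from [load_fixture()] (`"T2"` or `"T3"`).
#' @param comparison e.g. `"Pt_vs_N"`; must appear in the fixture.
#' @param signature `"tissue"` or `"cell"` (ignored for `"T3"`, which is
#'   tissue-only).
#' @return A `comparison_result` data.frame (all rows significant by
#'   construction; `fdr_significant` from the table flags).
#' @export
fixture_comparison <- function(fix, comparison,
                               signature = c("tissue", "cell")) {
  signature <- match.arg(signature)
  if (!comparison %in% fix$comparison)
    stop("comparison not in fixture: ", comparison)
  rows <- fix[fix$comparison == comparison, , drop = FALSE]
  if ("signature" %in% names(rows))
    rows <- rows[rows$signature == signature, , drop = FALSE]
  ab <- strsplit(comparison, "_vs_")[[1]]
  out <- data.frame(
    metabolite = rows$metabolite,
    ppm = rows$ppm,
    group_a = ab[1], group_b = ab[2],
    normalization = if (signature == "tissue") "total_area" else "cell_count",
    es = rows$es, es_error = rows$es_error,
    p_value = rows$p_value, p_adjusted = NA_real_,
    test_used = NA_character_,
    direction = sign(rows$es),
    significant = TRUE,
    fdr_significant = !rows$fdr_ns,
    identified = rows$identified,
    stringsAsFactors = FALSE)
  for (fl in intersect(c("age_flag", "dietary"), names(rows)))
    out[[fl]] <- rows[[fl]]
  class(out) <- c("comparison_result", class(out))
  out
}
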