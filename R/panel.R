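#' Built-in metabolite peak panel
#'
#' Returns the default panel of assigned polar-metabolite resonances used by
#' the synthetic cohort generator: the compounds observed in murine
#' pancreatic polar extracts (amino acids, organic acids, nucleotides and
#' sugar phosphates) plus the TSP chemical-shift reference at 0.0 ppm. Each
#' row describes one multiplet: its centre (ppm), multiplicity, number of
#' lines, line spacing (a J-coupling surrogate, ppm at 600 MHz) and the
#' fraction of the metabolite's total signal carried by that multiplet
#' (`rel_intensity`; the fractions of one metabolite sum to 1).
#'
#' Multiplicity is rendered as s/d/t/dd = 1/2/3/4 lines with binomial
#' intensity ratios, and "m" as 5 equal lines.
#'
#' @return A data.frame with columns `metabolite`, `center`, `multiplicity`,
#'   `n_lines`, `line_spacing`, `rel_intensity`.
#' @export
default_panel <- function() {
  J <- 0.012  # ~7 Hz at 600 MHz
  rows <- list(
    # metabolite, center, mult, rel_intensity
    c("TSP",               0.00, "s", 1),
    c("Leucine",           0.96, "t", 1),
    c("Isoleucine",        1.01, "d", 1),
    c("Valine",            1.05, "d", 1),
    c("3-HIBA",            1.08, "d", 1),
    c("3-HBA",             1.20, "d", 1),
    c("3-HIVA",            1.25, "s", 1),
    c("Threonine",         1.32, "d", 1),
    c("Lactate",           1.33, "d", 0.8),
    c("Lactate",           4.11, "m", 0.2),
    c("Alanine",           1.48, "d", 0.75),
    c("Alanine",           3.78, "m", 0.25),
    c("Lysine",            1.70, "m", 1),
    c("Acetate",           1.92, "s", 1),
    c("Proline",           1.99, "m", 1),
    c("Glutamate",         2.35, "m", 1),
    c("Succinate",         2.41, "s", 1),
    c("Glutamine",         2.45, "m", 1),
    c("Aspartate",         2.80, "d", 1),
    c("Creatine",          3.04, "s", 0.7),
    c("Creatine",          3.93, "s", 0.3),
    c("Creatinine",        3.05, "s", 1),
    c("Choline",           3.20, "s", 1),
    c("PC",                3.22, "s", 0.7),
    c("PC",                4.17, "m", 0.3),
    c("GPC",               3.23, "s", 1),
    c("Taurine",           3.26, "t", 1),
    c("TMAO",              3.27, "s", 1),
    c("Methanol",          3.36, "s", 1),
    c("Glucose",           3.47, "m", 0.65),
    c("Glucose",           5.23, "d", 0.35),
    c("Glycine",           3.56, "s", 1),
    c("m-Inositol",        4.06, "t", 1),
    c("PE",                3.98, "m", 1),
    c("2-Phosphoglycerate", 4.43, "m", 1),
    c("Ascorbate",         4.51, "d", 1),
    c("GSH",               4.57, "m", 1),
    c("Sucrose",           5.42, "d", 1),
    c("UDP-GlcNAc",        5.52, "dd", 1),
    c("Uridine",           5.90, "d", 1),
    c("UDP",               5.98, "d", 1),
    c("UTP",               6.04, "d", 1),
    c("ATP",               6.14, "d", 0.5),
    c("ATP",               8.52, "s", 0.5),
    c("Fumarate",          6.52, "s", 1),
    c("Tyrosine",          6.90, "d", 0.4),
    c("Tyrosine",          7.20, "d", 0.6),
    c("Histidine",         7.08, "s", 0.6),
    c("Histidine",         7.80, "s", 0.4),
    c("Phenylacetate",     7.26, "t", 1),
    c("Phenylalanine",     7.42, "t", 1),
    c("UDP-Glc/GlcA",      7.95, "d", 1),
    c("3-Methylxanthine",  8.03, "s", 1),
    c("UMP",               8.10, "d", 1),
    c("ADP",               8.28, "s", 1),
    c("Formate",           8.46, "s", 1),
    c("AMP",               8.60, "s", 1),
    c("Niacinamide",       8.94, "d", 1),
    c("NAD+",              9.34, "s", 1)
  )
  panel <- data.frame(
    metabolite   = vapply(rows, `[`, "", 1),
    center       = as.numeric(vapply(rows, `[`, "", 2)),
    multiplicity = vapply(rows, `[`, "", 3),
    rel_intensity = as.numeric(vapply(rows, `[`, "", 4)),
    stringsAsFactors = FALSE)
  panel$n_lines <- multiplicity_lines(panel$multiplicity)
  panel$line_spacing <- J
  validate_panel(panel)
  panel[, c("metabolite", "center", "multiplicity", "n_lines",
            "line_spacing", "rel_intensity")]
}

#' @keywords internal
multiplicity_lines <- function(m) {
  map <- c(s = 1L, d = 2L, t = 3L, dd = 4L, m = 5L)
  out <- map[m]
  if (any(is.na(out))) stop("unknown multiplicity: ",
                            paste(unique(m[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @keywords internal
validate_panel <- function(panel) {
  stopifnot(all(panel$center >= 0), all(panel$center <= 10),
            all(panel$n_lines >= 1), all(panel$rel_intensity > 0))
  sums <- tapply(panel$rel_intensity, panel$metabolite, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("per-metabolite rel_intensities must sum to 1: ",
         paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", "))
  invisible(panel)
}

#' Expand a panel into individual Lorentzian lines
#'
#' Each multiplet becomes `n_lines` lines centred on the multiplet centre,
#' spaced by `line_spacing`, with binomial weights (s/d/t/dd) or equal
#' weights (m). Line weights of one metabolite sum to 1.
#'
#' @param panel a panel data.frame as returned by [default_panel()].
#' @return data.frame with columns `metabolite`, `position`, `weight`.
#' @export
peak_lines <- function(panel) {
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    k <- panel$n_lines[i]
    if (panel$multiplicity[i] == "m") {
      w <- rep(1 / k, k)
    } else {
      w <- choose(k - 1, 0:(k - 1))
      w <- w / sum(w)
    }
    pos <- panel$center[i] + (seq_len(k) - (k + 1) / 2) * panel$line_spacing[i]
    out[[i]] <- data.frame(metabolite = panel$metabolite[i],
                           position = pos,
                           weight = w * panel$rel_intensity[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default integration windows for a panel
#'
#' One window per metabolite, centred on the metabolite's first (primary)
#' multiplet. TSP is excluded: its intensity tracks the reference compound,
#' not the tissue.
#'
#' @param panel a panel data.frame; defaults to [default_panel()].
#' @param halfwidth window half-width in ppm.
#' @return data.frame with columns `metabolite`, `center`, `halfwidth`,
#'   `multiplicity`.
#' @export
assignment_table <- function(panel = default_panel(), halfwidth = 0.03) {
  first <- !duplicated(panel$metabolite)
  a <- panel[first & panel$metabolite != "TSP",
             c("metabolite", "center", "multiplicity")]
  a$halfwidth <- halfwidth
  rownames(a) <- NULL
  a[, c("metabolite", "center", "halfwidth", "multiplicity")]
}
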