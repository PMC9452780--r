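#' Pair tissue- and cell-normalized comparison results
#'
#' Bundles the two screens of the same pairwise group comparison computed
#' under total-area normalization (the tissue metabolic signature) and
#' cell-count normalization (the cellular metabolic signature). Members of
#' either signature are the rows with `significant = TRUE`.
#'
#' @param tissue,cell `comparison_result` data.frames for the same
#'   (group_a, group_b) pair.
#' @return An object of class `signature_pair`.
#' @export
build_signature_pair <- function(tissue, cell) {
  stopifnot(inherits(tissue, "comparison_result"),
            inherits(cell, "comparison_result"))
  if (nrow(tissue) && nrow(cell) &&
      (tissue$group_a[1] != cell$group_a[1] ||
       tissue$group_b[1] != cell$group_b[1]))
    stop("tissue and cell results compare different group pairs")
  structure(list(
    comparison = if (nrow(tissue))
      c(tissue$group_a[1], tissue$group_b[1]) else c(NA, NA),
    tissue = tissue, cell = cell),
    class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("signature_pair %s vs %s: %d tissue / %d cell members\n",
              x$comparison[1], x$comparison[2],
              sum(x$tissue$significant), sum(x$cell$significant)))
  invisible(x)
}

.sig_members <- function(cmp) cmp[cmp$significant, , drop = FALSE]

#' Condition-specific signature by intersection
#'
#' Intersects the tissue signatures of several pairwise comparisons that
#' share a condition group: members are the identified (named, non-Ui)
#' metabolites significant in the tissue signature of every pair with the
#' same effect direction relative to the condition. The exclusion rule
#' then removes members whose variation does not survive FDR correction:
#' `"fdr_all"` (default) drops a metabolite only when it is
#' FDR-nonsignificant in every contributing comparison, `"fdr_any"` when
#' it is FDR-nonsignificant in at least one, `"none"` never.
#'
#' @param pairs list of [build_signature_pair()] objects sharing the
#'   condition group.
#' @param condition the shared group label.
#' @param exclusion_rule `"fdr_all"`, `"fdr_any"` or `"none"`.
#' @return An object of class `condition_signature`: `members`
#'   (metabolite, direction), `exclusions` (metabolite, reason),
#'   `provenance`.
#' @export
intersect_condition_signature <- function(pairs, condition,
                                          exclusion_rule = c("fdr_all",
                                                             "fdr_any",
                                                             "none")) {
  exclusion_rule <- match.arg(exclusion_rule)
  stopifnot(length(pairs) >= 2)
  per_pair <- lapply(pairs, function(p) {
    stopifnot(inherits(p, "signature_pair"))
    if (!condition %in% p$comparison)
      stop("pair ", paste(p$comparison, collapse = " vs "),
           " does not involve condition ", condition)
    m <- .sig_members(p$tissue)
    m <- m[m$identified, , drop = FALSE]
    # direction relative to the condition group
    flip <- p$comparison[2] == condition
    m$direction_cond <- if (flip) -m$direction else m$direction
    m
  })
  common <- Reduce(intersect, lapply(per_pair, function(m) m$metabolite))
  members <- character(0); directions <- integer(0)
  excl <- data.frame(metabolite = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (met in common) {
    dirs <- vapply(per_pair, function(m)
      m$direction_cond[match(met, m$metabolite)], numeric(1))
    fdr <- vapply(per_pair, function(m)
      m$fdr_significant[match(met, m$metabolite)], logical(1))
    if (length(unique(dirs)) > 1) {
      excl <- rbind(excl, data.frame(metabolite = met,
                                     reason = "direction conflict"))
      next
    }
    drop_fdr <- switch(exclusion_rule,
                       fdr_all = all(!fdr),
                       fdr_any = any(!fdr),
                       none = FALSE)
    if (drop_fdr) {
      excl <- rbind(excl, data.frame(metabolite = met,
                                     reason = "FDR-nonsignificant"))
      next
    }
    members <- c(members, met)
    directions <- c(directions, dirs[1])
  }
  structure(list(
    condition = condition,
    members = data.frame(metabolite = members, direction = directions,
                         stringsAsFactors = FALSE),
    exclusions = excl,
    provenance = lapply(pairs, `[[`, "comparison"),
    exclusion_rule = exclusion_rule),
    class = "condition_signature")
}

#' @export
print.condition_signature <- function(x, ...) {
  cat(sprintf("%s-specific signature: %d members\n", x$condition,
              nrow(x$members)))
  if (nrow(x$members)) {
    up <- x$members$metabolite[x$members$direction > 0]
    dn <- x$members$metabolite[x$members$direction < 0]
    if (length(up)) cat("  up:  ", paste(sort(up), collapse = ", "), "\n")
    if (length(dn)) cat("  down:", paste(sort(dn), collapse = ", "), "\n")
  }
  if (nrow(x$exclusions))
    cat("  excluded:",
        paste(sprintf("%s (%s)", x$exclusions$metabolite,
                      x$exclusions$reason), collapse = "; "), "\n")
  invisible(x)
}

#' Classify metabolites by cellularity dependence
#'
#' Compares a pair's tissue and cell signatures per metabolite:
#' `cell-independent` when significant in both with the same direction
#' (the change persists after correcting for cellularity, so it reflects
#' altered intracellular metabolism); `cellularity-driven` when
#' tissue-significant only (the tissue-level change is attributable, at
#' least in part, to the different cell density); `ambiguous` otherwise
#' (cell-only, or conflicting directions).
#'
#' @param pair a [build_signature_pair()].
#' @return data.frame with `metabolite` and `class`, one row per
#'   metabolite significant in either signature.
#' @export
classify_cellularity <- function(pair) {
  stopifnot(inherits(pair, "signature_pair"))
  tis <- .sig_members(pair$tissue)
  cel <- .sig_members(pair$cell)
  mets <- union(tis$metabolite, cel$metabolite)
  cls <- vapply(mets, function(met) {
    in_t <- met %in% tis$metabolite
    in_c <- met %in% cel$metabolite
    if (in_t && in_c) {
      same <- tis$direction[match(met, tis$metabolite)] ==
        cel$direction[match(met, cel$metabolite)]
      if (same) "cell-independent" else "ambiguous"
    } else if (in_t) "cellularity-driven" else "ambiguous"
  }, character(1))
  data.frame(metabolite = mets, class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Per-metabolite trajectory across disease stages
#'
#' Collapses the successive pairwise comparisons of a staged progression
#' (e.g. N to LG to HG to PDA to Sarc under total-area normalization) into
#' a long table of the signed significant steps per metabolite - the
#' machine-readable form of a stage-trajectory figure. Optional per-row
#' flags (e.g. `age_flag`, `dietary`) present in the comparison results
#' are carried through.
#'
#' @param results named list of `comparison_result` data.frames in stage
#'   order (names like `"LG_vs_N"`).
#' @return An object of class `progression_profile`: a data.frame with
#'   `metabolite`, `step`, `step_index`, `es`, `es_error`, `direction`
#'   plus any carried flags; only significant steps appear.
#' @export
progression_profile <- function(results) {
  stopifnot(is.list(results), length(results) >= 1,
            !is.null(names(results)))
  chunks <- list()
  for (i in seq_along(results)) {
    cmp <- results[[i]]
    stopifnot(inherits(cmp, "comparison_result"))
    m <- .sig_members(cmp)
    if (!nrow(m)) next
    row <- data.frame(metabolite = m$metabolite,
                      step = names(results)[i],
                      step_index = i,
                      es = m$es, es_error = m$es_error,
                      direction = m$direction,
                      stringsAsFactors = FALSE)
    for (fl in intersect(c("age_flag", "dietary", "fdr_significant"),
                         names(m)))
      row[[fl]] <- m[[fl]]
    chunks[[length(chunks) + 1]] <- row
  }
  out <- NULL
  if (length(chunks)) {
    cols <- Reduce(union, lapply(chunks, names))
    chunks <- lapply(chunks, function(ch) {
      for (cn in setdiff(cols, names(ch))) ch[[cn]] <- NA
      ch[, cols, drop = FALSE]
    })
    out <- do.call(rbind, chunks)
  }
  if (is.null(out))
    out <- data.frame(metabolite = character(0), step = character(0),
                      step_index = integer(0), es = numeric(0),
                      es_error = numeric(0), direction = numeric(0))
  out <- out[order(out$metabolite, out$step_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("progression_profile", class(out))
  out
}

#' @export
print.progression_profile <- function(x, ...) {
  cat(sprintf("progression profile: %d significant steps, %d metabolites\n",
              nrow(x), length(unique(x$metabolite))))
  NextMethod()
}
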