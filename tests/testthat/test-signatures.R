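# The packaged reference tables drive most signature tests: they are the
# published end state of the univariate screen, so the set operations can
# be checked against the printed membership exactly.

t2_pairs <- function() {
  t2 <- load_fixture("T2")
  list(
    PtN = build_signature_pair(fixture_comparison(t2, "Pt_vs_N", "tissue"),
                               fixture_comparison(t2, "Pt_vs_N", "cell")),
    PtLG = build_signature_pair(fixture_comparison(t2, "Pt_vs_LG", "tissue"),
                                fixture_comparison(t2, "Pt_vs_LG", "cell")))
}

test_that("significance-filtered counts match the published tables", {
  t2 <- load_fixture("T2")
  tn <- fixture_comparison(t2, "Pt_vs_N", "tissue")
  expect_equal(sum(tn$identified), 22)
  expect_equal(sum(!tn$identified), 8)
  tl <- fixture_comparison(t2, "Pt_vs_LG", "tissue")
  expect_equal(sum(tl$identified), 20)
  expect_equal(sum(!tl$identified), 6)
  t3 <- load_fixture("T3")
  expect_equal(sum(fixture_comparison(t3, "LG_vs_N")$identified), 15)
  hg <- fixture_comparison(t3, "HG_vs_LG")
  strong <- c("3-Methylxanthine", "Glutamate", "UMP")
  expect_equal(sum(hg$identified & !hg$metabolite %in% strong), 9)
})

test_that("signature membership follows the Table rule on each side", {
  pairs <- t2_pairs()
  tis <- pairs$PtN$tissue
  expect_true("ATP" %in% tis$metabolite[tis$significant])
  expect_equal(tis$es[tis$metabolite == "ATP"], 5.2)
  expect_false("Lactate" %in% tis$metabolite)   # tissue-absent cell-member
  cel <- pairs$PtN$cell
  expect_true("Lactate" %in% cel$metabolite[cel$significant])
  expect_equal(cel$es[cel$metabolite == "Lactate"], -2.0)
  # empty inputs give empty signatures
  empty <- pairs$PtN$tissue[0, ]
  p0 <- build_signature_pair(empty, empty)
  expect_equal(sum(p0$tissue$significant), 0)
})

test_that("the condition signature has exactly the ten published members", {
  pairs <- t2_pairs()
  sig <- intersect_condition_signature(pairs, "Pt")
  up <- sort(sig$members$metabolite[sig$members$direction > 0])
  dn <- sort(sig$members$metabolite[sig$members$direction < 0])
  expect_equal(up, c("ADP", "ATP", "GSH", "Phenylacetate"))
  expect_equal(dn, sort(c("Alanine", "AMP", "Formate", "Niacinamide",
                          "TMAO", "UMP")))
  expect_equal(nrow(sig$members), 10)
  # GPC leaves via the FDR rule, PC via the direction-consistency rule
  expect_true("GPC" %in%
                sig$exclusions$metabolite[sig$exclusions$reason ==
                                            "FDR-nonsignificant"])
  expect_true("PC" %in%
                sig$exclusions$metabolite[sig$exclusions$reason ==
                                            "direction conflict"])
})

test_that("intersection honours its exclusion-rule variants and monotonicity", {
  pairs <- t2_pairs()
  none <- intersect_condition_signature(pairs, "Pt", "none")
  expect_true("GPC" %in% none$members$metabolite)
  any_rule <- intersect_condition_signature(pairs, "Pt", "fdr_any")
  # alanine and phenylacetate lose FDR significance in one comparison only
  expect_false("Alanine" %in% any_rule$members$metabolite)
  expect_true(all(any_rule$members$metabolite %in%
                    none$members$metabolite))
  # adding a contributing comparison never enlarges the signature
  tis <- pairs$PtN$tissue
  solo <- tis$metabolite[tis$significant & tis$identified]
  sig2 <- intersect_condition_signature(pairs, "Pt")
  expect_true(all(sig2$members$metabolite %in% solo))
  # disjoint signatures yield nothing
  alt <- pairs
  alt$PtLG$tissue <- alt$PtLG$tissue[alt$PtLG$tissue$metabolite ==
                                       "Creatinine", ]
  sig3 <- intersect_condition_signature(alt, "Pt")
  expect_equal(nrow(sig3$members), 0)
})

test_that("cellularity classification matches the published reading", {
  pairs <- t2_pairs()
  cls <- classify_cellularity(pairs$PtN)
  got <- function(met) cls$class[cls$metabolite == met]
  for (met in c("Alanine", "AMP", "Niacinamide", "UMP"))
    expect_equal(got(met), "cell-independent")
  # tissue-significant with no cell entry: attributable to cell density
  for (met in c("ATP", "ADP", "GSH", "Phenylacetate", "Glucose"))
    expect_equal(got(met), "cellularity-driven")
  # opposite directions in the two signatures
  expect_equal(got("Glutamate"), "ambiguous")
  # every tissue- or cell-significant metabolite gets exactly one class
  t2 <- load_fixture("T2")
  universe <- unique(t2$metabolite[t2$comparison == "Pt_vs_N"])
  expect_setequal(cls$metabolite, universe)
  expect_false(any(duplicated(cls$metabolite)))
  expect_true(all(cls$class %in% c("cell-independent",
                                   "cellularity-driven", "ambiguous")))
})

test_that("progression profiles list the published stage steps", {
  t3 <- load_fixture("T3")
  res <- list(LG_vs_N = fixture_comparison(t3, "LG_vs_N"),
              HG_vs_LG = fixture_comparison(t3, "HG_vs_LG"),
              PDA_vs_HG = fixture_comparison(t3, "PDA_vs_HG"),
              Sarc_vs_PDA = fixture_comparison(t3, "Sarc_vs_PDA"))
  pp <- progression_profile(res)
  lac <- pp[pp$metabolite == "Lactate", ]
  expect_equal(lac$step, "PDA_vs_HG")
  expect_equal(lac$es, 1.9)
  sarc <- pp[pp$step == "Sarc_vs_PDA", ]
  expect_equal(sarc$metabolite, "UDP-Glc/GlcA")
  expect_equal(sarc$es, 1.4)
  # age-confound flags ride along
  expect_true(pp$age_flag[pp$metabolite == "Proline"])
  # all-null input gives an empty table
  empty <- res$LG_vs_N[0, ]
  pp0 <- progression_profile(list(LG_vs_N = empty))
  expect_equal(nrow(pp0), 0)
})

test_that("a purely cellularity-scaled metabolite separates the two normalizations", {
  # one intracellular metabolite (formate, scaling with cell count) in an
  # otherwise cell-count-independent background: its tissue-level signal
  # tracks cellularity (Pt has ~2.5x the cells of N), so it shows a
  # tissue-signature change with no planted concentration effect, while
  # cell-count normalization removes most of the apparent change.
  cfg <- small_config(seed = 57, between_sample_cv = 0.1,
                      extracellular = setdiff(
                        unique(default_panel()$metabolite),
                        c("Formate", "TSP")))
  co <- simulate_cohort(cfg)
  win <- assignment_table(cfg$panel)
  cmp_ta <- compare_groups(
    suppressWarnings(integrate_windows(prep_matrix(co, "total_area"), win)),
    "Pt", "N")
  cmp_cc <- compare_groups(
    suppressWarnings(integrate_windows(prep_matrix(co, "cell_count"), win)),
    "Pt", "N")
  es_ta <- cmp_ta$es[cmp_ta$metabolite == "Formate"]
  es_cc <- cmp_cc$es[cmp_cc$metabolite == "Formate"]
  expect_gt(es_ta, 0)
  expect_true(cmp_ta$significant[cmp_ta$metabolite == "Formate"])
  expect_lt(abs(es_cc), abs(es_ta))
  pair <- build_signature_pair(cmp_ta, cmp_cc)
  cls <- classify_cellularity(pair)
  expect_equal(cls$class[cls$metabolite == "Formate"],
               "cellularity-driven")
})
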