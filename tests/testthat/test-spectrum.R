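test_that("substitution classification follows purine/pyrimidine identity", {
  expect_identical(classify_substitution("U", "C"), "transition")
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("G", "C"), "transversion")
  expect_identical(classify_substitution(c("A", "C"), c("U", "A")),
                   c("transversion", "transversion"))
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("mispair inference complements the template strand and round-trips", {
  expect_identical(infer_mispair("U", "C"), "A.C")
  expect_identical(infer_mispair("A", "G"), "U.G")
  expect_identical(infer_mispair("C", "G"), "G.G")
  expect_identical(infer_mispair("U", "C", round = "first"), "U.G")
  # complementing the inferred template recovers the wild-type base
  bases <- c("A", "C", "G", "U")
  for (wt in bases) for (mut in setdiff(bases, wt)) {
    template <- substr(infer_mispair(wt, mut), 1, 1)
    expect_identical(chartr("ACGU", "UGCA", template), wt)
  }
})

test_that("coding effects are classified from the affected codon", {
  tgt <- mutation_target("UGGGGUCUU")  # Trp, Gly, Leu
  rec <- data.frame(
    isolate = c("a", "b", "c", "d"),
    position = c(2L, 6L, 7L, 4L),
    kind = c("substitution", "substitution", "substitution", "insertion"),
    wt = c("G", "U", "C", NA), mut = c("A", "C", "A", NA),
    indel_seq = c(NA, NA, NA, "G"),
    rank = "primary")
  expect_identical(mutation_effects(rec, tgt),
                   c("nonsense",     # UGG -> UAG
                     "synonymous",   # GGU -> GGC
                     "missense",     # CUU -> AUU (Leu -> Ile)
                     "frameshift"))
  # records beyond the target are rejected
  rec$position[1] <- 10L
  expect_error(mutation_effects(rec, tgt), "beyond")
})

test_that("the packaged mutation catalogue reproduces the published spectrum", {
  tgt <- rt_fixture_target()
  catalog <- rt_mutation_catalog()
  expect_identical(nrow(catalog), 45L)
  expect_identical(sum(catalog$rank == "primary"), 32L)
  expect_identical(sum(catalog$rank == "secondary"), 13L)

  ss <- spectrum_summary(catalog, tgt)
  counts <- setNames(ss$classes$count, ss$classes$class)
  published <- c("A>G" = 8L, "G>A" = 10L, "U>C" = 16L, "C>U" = 5L,
                 "A>U" = 1L, "A>C" = 0L, "G>U" = 2L, "G>C" = 0L,
                 "U>A" = 0L, "U>G" = 1L, "C>A" = 0L, "C>G" = 0L)
  expect_identical(counts[names(published)], published)
  expect_identical(ss$transitions, 39L)
  expect_identical(ss$transversions, 4L)
  expect_equal(ss$ts_tv_ratio, 9.75)
  expect_identical(ss$n_indels, 2L)
  expect_identical(sum(ss$classes$count), ss$n_substitutions)

  # mispairs of the four transition classes, second-round attribution
  mp <- setNames(ss$classes$mispair, ss$classes$class)
  expect_identical(unname(mp[c("U>C", "G>A", "A>G", "C>U")]),
                   c("A.C", "C.A", "U.G", "G.U"))

  # mutability normalised to target base content; U>C leads at 16/175
  norm <- setNames(ss$classes$normalized, ss$classes$class)
  expect_equal(unname(norm["U>C"]), 16 / 175, tolerance = 1e-12)
  expect_equal(unname(norm["U>C"]), 0.091, tolerance = 0.01)
  expect_equal(unname(norm["G>A"]), 10 / 147, tolerance = 1e-12)
  expect_true(all(ss$classes$normalized >= 0 & ss$classes$normalized <= 1))

  # coding-effect tallies: the read-through codon change is reported
  # apart from the two true nonsense mutations
  eff <- ss$effects
  expect_identical(unname(eff["missense"]), 31L)
  expect_identical(unname(eff["synonymous"]), 9L)
  expect_identical(unname(eff["nonsense"]), 2L)
  expect_identical(unname(eff["stop_to_stop"]), 1L)
  expect_identical(unname(eff["frameshift"]), 2L)

  # per-record effects match the catalogued impact annotations
  parse_impact <- function(impact, kind) {
    if (kind != "substitution") return("frameshift")
    aa <- strsplit(impact, ">", fixed = TRUE)[[1]]
    if (aa[1] == "Stop" && aa[2] == "Stop") "stop_to_stop"
    else if (aa[2] == "Stop") "nonsense"
    else if (aa[1] == aa[2]) "synonymous"
    else "missense"
  }
  expected <- mapply(parse_impact, catalog$impact, catalog$kind)
  expect_identical(mutation_effects(catalog, tgt), unname(expected))
})

test_that("an empty record list yields an all-zero summary", {
  empty <- rt_mutation_catalog()[0, ]
  ss <- spectrum_summary(empty, rt_fixture_target())
  expect_identical(sum(ss$classes$count), 0L)
  expect_identical(ss$n_records, 0L)
  expect_true(is.na(ss$ts_tv_ratio))
})

test_that("missense deficit probabilities are exact binomial values", {
  res <- missense_deficit_test(6, 13, 0.75)
  # direct pmf: choose(13,6) 0.75^6 0.25^7
  expect_equal(res$p_point, choose(13, 6) * 0.75^6 * 0.25^7,
               tolerance = 1e-12)
  expect_equal(res$p_point, 0.018642, tolerance = 1e-4)
  expect_equal(missense_deficit_test(13, 13, 0.5)$p_point, 0.5^13)
  expect_equal(missense_deficit_test(0, 5, 0.5)$p_le, 0.03125)
  expect_error(missense_deficit_test(7, 5, 0.5), "n_total")
})

test_that("codon-table missense fraction lies near three-quarters", {
  f <- expected_missense_fraction(rt_fixture_target())
  expect_gt(f, 0.6)
  expect_lt(f, 0.85)
})

test_that("upstream G/C context test partitions G additively", {
  tgt <- rt_fixture_target()
  catalog <- rt_mutation_catalog()
  for (w in c(6, 7)) {
    res <- gc_context_test(catalog, tgt, width = w)
    expect_identical(res$n_used + res$n_excluded, 43L)
    # the substitution at target position 2 has no full upstream window
    expect_identical(res$n_excluded, 1L)
    expect_equal(res$total$statistic,
                 res$pooled$statistic + res$heterogeneity$statistic,
                 tolerance = 1e-10)
    expect_identical(res$pooled$df, 1L)
    expect_identical(res$total$df, as.integer(w))
  }
})
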