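test_that("Shannon entropy matches closed forms and hand evaluations", {
  expect_equal(shannon_index(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_index(c(1, 1, 1, 1), base = 2), 2)
  expect_equal(shannon_index(c(5)), 0)
  expect_equal(shannon_index(c(2, 1, 1)), 1.0397207708, tolerance = 1e-9)
  # bounded by log(S) in the stated base
  expect_lte(shannon_index(c(5, 3, 1), base = 2), log2(3))
})

test_that("Pielou evenness is 1 when even, NA for one clone, correct otherwise", {
  for (S in c(2, 7, 100))
    expect_equal(pielou_index(rep(13, S)), 1)
  expect_equal(pielou_index(c(2, 1, 1)), 0.9463946304, tolerance = 1e-9)
  expect_equal(pielou_index(c(9999, 1)), 0.0014730335283282, tolerance = 1e-9)
  expect_identical(pielou_index(c(5)), NA_real_)
})

test_that("Simpson diversity matches its formula", {
  expect_equal(simpson_index(c(1, 1)), 0.5)
  expect_equal(simpson_index(c(5)), 0)
  expect_equal(simpson_index(c(2, 1, 1)), 0.625)
})

test_that("Gini via Brown's formula on ascending ranks", {
  expect_equal(gini_brown(rep(4, 25)), 0)
  expect_equal(gini_brown(c(1, 1, 1, 97)), 0.72)
  expect_equal(gini_brown(c(5)), 0)
  # rank order is ascending: a permuted input gives the same value
  expect_equal(gini_brown(c(97, 1, 1, 1)), 0.72)
})

test_that("Chao1 uses singletons/doubletons, with the f2 = 0 substitution", {
  # S = 10, f1 = 4, f2 = 2 -> 10 + 4*3/4 = 13
  x <- c(1, 1, 1, 1, 2, 2, 3, 3, 3, 4)
  expect_equal(chao1_richness(x), 13)
  expect_equal(chao1_richness(clone_frequencies(x)), 13)
  # no singletons -> estimate equals observed richness
  expect_equal(chao1_richness(c(2, 2, 3)), 3)
  # f2 = 0: denominator uses f2 + 1 -> 5 + 2*1/2 = 6
  expect_equal(chao1_richness(c(1, 1, 3, 3, 3)), 6)
  expect_gte(chao1_richness(c(1, 1, 1, 2)), 4)
  expect_error(chao1_richness(c(1.5, 2)), "integer")
})

test_that("UC50 counts top clones reaching half the abundance", {
  expect_identical(uc50(c(6, 2, 2)), 1L)
  expect_identical(uc50(c(5)), 1L)
  expect_identical(uc50(c(1, 1, 1, 1)), 2L)
  # exactly-50% dominance yields 1
  expect_identical(uc50(c(5, 3, 2)), 1L)
  expect_identical(uc50(rep(1, 10)), 5L)
})

test_that("coverage-corrected Shannon evaluates both dialects", {
  expect_equal(shannon_corrected(c(5)), 0)
  expect_equal(shannon_corrected(c(2, 1, 1), "printed"),
               2.5114806049, tolerance = 1e-9)
  expect_equal(shannon_corrected(c(2, 1, 1), "chao-shen"),
               1.7632402413, tolerance = 1e-9)
  # all singletons: coverage <= 0, undefined sentinel
  expect_identical(shannon_corrected(c(1, 1, 1)), NA_real_)
  expect_identical(shannon_corrected(c(1, 1, 1), "chao-shen"), NA_real_)
  expect_error(shannon_corrected(c(2.5, 1)), "integer")
})

test_that("diversity_panel composes all indices and carries sentinels", {
  p <- diversity_panel(c(1, 1, 1, 1))
  expect_equal(p$pielou, 1)
  expect_equal(p$gini, 0)
  expect_identical(p$uc50, 2L)

  p <- diversity_panel(c(6, 2, 2))
  expect_identical(p$uc50, 1L)
  expect_equal(p$dominant_fraction, 0.6)

  p <- diversity_panel(c(5))
  expect_identical(p$pielou, NA_real_)
  expect_equal(p$shannon, 0)

  # fractional abundances: integer-only indices become sentinels,
  # the rest of the panel is still computed
  p <- diversity_panel(c(2.5, 1.5))
  expect_identical(p$chao1, NA_real_)
  expect_identical(p$shannon_corrected, NA_real_)
  expect_equal(p$simpson, 1 - (0.625^2 + 0.375^2))
})

test_that("invalid samples are rejected with informative errors", {
  expect_error(as_abundance(numeric(0)))
  expect_error(as_abundance(c(0, 0)), "empty")
  expect_error(as_abundance(c(-1, 2)), "negative")
  expect_error(as_abundance(c(NA, 2)), "NA")
  expect_error(shannon_index(c(1, 2), base = 1))
  # zero counts are dropped before any index computation
  expect_equal(shannon_index(c(2, 1, 1, 0, 0)), shannon_index(c(2, 1, 1)))
  expect_identical(attr(as_abundance(c(1, 0, 2)), "n_dropped"), 1L)
})
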