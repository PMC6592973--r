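test_that("gamete repertoires follow mode and ploidy", {
  g <- gametes(taxon("sex2", "sexual", 2, "D"))
  expect_true(any(g$mechanism == "reduced_meiotic" & g$gamete_ploidy == 1))

  g <- gametes(taxon("apo3", "apogamous", 3, "B"))
  expect_true(any(g$mechanism == "unreduced_diplospore" & g$gamete_ploidy == 3))
  expect_true(any(g$mechanism == "irregular_meiosis_reduced" &
                    g$gamete_ploidy == 2))

  g <- gametes(taxon("apo2", "apogamous", 2, "B"))
  expect_equal(g$mechanism, "unreduced_diplospore")
  expect_equal(g$gamete_ploidy, 2L)

  # sexual triploid: no reduced gamete; without the unreduced option the
  # repertoire is empty
  cfg <- default_config(allow_unreduced_sexual = FALSE)
  expect_warning(g <- gametes(taxon("sex3", "sexual", 3, "A"), cfg),
                 "no available gamete mechanism")
  expect_equal(nrow(g), 0)
  g <- gametes(taxon("sex3", "sexual", 3, "A"))
  expect_false(any(g$mechanism == "reduced_meiotic"))

  cfg <- default_config(allow_irregular_meiosis = FALSE)
  g <- gametes(taxon("apo3", "apogamous", 3, "B"), cfg)
  expect_false(any(g$mechanism == "irregular_meiosis_reduced"))
})

test_that("unknown mode or ploidy expands over the plausible assumptions", {
  g <- gametes(taxon("mystery", NA, NA, "A"))
  expect_setequal(unique(g$assumed_mode), c("sexual", "apogamous"))
  expect_true(all(g$assumed_ploidy %in% 2:4))
  g2 <- gametes(taxon("apo?", "apogamous", NA, "A"))
  expect_setequal(unique(g2$assumed_mode), "apogamous")
})

test_that("crosses reproduce the four canonical hybridization patterns", {
  apo3 <- taxon("apo3", "apogamous", 3, "B")
  apo2 <- taxon("apo2", "apogamous", 2, "B")
  sex2 <- taxon("sex2", "sexual", 2, "D")
  sex4 <- taxon("sex4", "sexual", 4, "D")

  cr <- cross_taxa(apo3, sex2)
  expect_true(any(cr$pattern == "P1" & cr$hybrid_ploidy == 4))
  expect_true(any(cr$pattern == "P3" & cr$hybrid_ploidy == 3))
  expect_true(all(cr$offspring_mode[cr$pattern %in% c("P1", "P3")] == "apogamous"))

  cr <- cross_taxa(apo2, sex2)
  expect_true(any(cr$pattern == "P2" & cr$hybrid_ploidy == 3))

  cr <- cross_taxa(apo3, sex4)
  expect_true(any(cr$pattern == "P4" & cr$hybrid_ploidy == 4))

  # two sexual diploids with the unreduced option: allopolyploid 4x
  sex2b <- taxon("sex2b", "sexual", 2, "J")
  cr <- cross_taxa(sex2, sex2b)
  expect_true(any(cr$pattern == "allopolyploid" & cr$hybrid_ploidy == 4))
  expect_true(all(cr$offspring_mode[cr$pattern == "allopolyploid"] == "sexual"))

  # self-cross is autopolyploidization
  cr <- cross_taxa(sex2, sex2)
  expect_true(all(cr$pattern == "autopolyploid"))
  expect_true(any(cr$hybrid_ploidy == 4))
})

test_that("patterns are mutually exclusive and ploidy is conserved", {
  modes <- c("sexual", "apogamous")
  for (pm in 2:4) for (pp in 2:4) for (mm in modes) for (mp in modes) {
    a <- taxon("a", mm, pm, "A")
    b <- taxon("b", mp, pp, "B")
    cr <- cross_taxa(a, b)
    if (nrow(cr) == 0) next
    expect_true(all(cr$hybrid_ploidy ==
                      cr$maternal_gamete_ploidy + cr$paternal_gamete_ploidy))
    # each row carries exactly one pattern label
    expect_true(all(cr$pattern %in% c("P1", "P2", "P3", "P4",
                                      "allopolyploid", "other")))
  }
})

test_that("gamete enumeration is deterministic", {
  a <- taxon("a", NA, NA, c("A", "B"))
  expect_identical(gametes(a), gametes(a))
  b <- taxon("b", "sexual", 2, "D")
  expect_identical(cross_taxa(a, b), cross_taxa(a, b))
})
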