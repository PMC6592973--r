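alpha <- "\u03b1"; beta <- "\u03b2"; delta <- "\u03b4"; eps <- "\u03b5"

test_that("orphan alleles are those never seen as a sole constitution", {
  s <- summarize_taxa(diplazium_complex())
  expect_equal(orphan_types(s), c("E", "F", "G", "H", "J", "K"))

  # only single-type taxa: no orphans
  pool <- rbind(taxon("a", "sexual", 2, "A", alpha),
                taxon("b", "apogamous", 3, "B", beta))
  expect_equal(orphan_types(pool), character(0))

  # removing the sole B carrier makes B an orphan too
  spc <- diplazium_complex()
  s2 <- summarize_taxa(spc[spc$species != "D. takii", , drop = FALSE])
  expect_equal(orphan_types(s2), c("B", "E", "F", "G", "H", "J", "K"))
})

test_that("the packaged complex reproduces the published reticulate origins", {
  inf <- infer_parentage(diplazium_complex())
  th <- top_hypotheses(inf)
  exp <- expected_complex_origins()
  key <- function(d) paste(d$species, d$specimen_group, d$maternal, d$paternal)
  expect_setequal(key(th), key(exp))

  expect_setequal(inf$progenitors,
                  c("D. amamianum", "D. dilatatum", "D. doederleinii",
                    "D. takii"))

  # the backcross origin of D. okinawaense requires one allele loss
  oki <- th[th$species == "D. okinawaense", ]
  expect_equal(oki$n_loss, 1L)
  expect_equal(oki$pattern, "P3")

  # the allopolyploid origin of the tetraploid sexual: its private
  # plastid type matches no sampled taxon, so the maternal constraint
  # is uninformative and flagged
  nip <- th[th$species == "D. nipponicum", ]
  expect_equal(nip$pattern, "allopolyploid")
  expect_true(nip$plastid_unmatched)
  expect_equal(nip$hybrid_ploidy, 4L)
})

test_that("hypothesized lineages are registered once, H as a triploid apomict", {
  inf <- infer_parentage(diplazium_complex())
  expect_equal(nrow(inf$registry), 6)
  expect_equal(inf$registry$lineage,
               paste("D. sp.", c("E", "F", "G", "H", "J", "K")))
  h <- inf$registry[inf$registry$type == "H", ]
  expect_equal(h$mode, "apogamous")
  expect_equal(h$ploidy, 3L)
  expect_true(all(inf$registry$mode[inf$registry$type != "H"] == "sexual"))
})

test_that("every emitted hypothesis re-checks against the three constraints", {
  inf <- infer_parentage(diplazium_complex())
  s <- inf$summaries
  pool_types <- setNames(c(s$nuclear_types, inf$registry$type),
                         c(s$species, inf$registry$lineage))
  pool_plastid <- setNames(c(s$plastid_types,
                             rep(list(character(0)), nrow(inf$registry))),
                           c(s$species, inf$registry$lineage))
  for (res in inf$results) {
    h <- res$hypotheses
    for (i in seq_len(nrow(h))) {
      # (i) maternal plastid (unless waived)
      if (!res$plastid_unmatched) {
        expect_true(res$focal$plastid_type %in% pool_plastid[[h$maternal[i]]])
      }
      # (ii) payloads union to the focal constitution and are legal subsets
      pm <- if (nzchar(h$maternal_payload[i]))
        parse_allele_string(h$maternal_payload[i]) else character(0)
      pp <- if (nzchar(h$paternal_payload[i]))
        parse_allele_string(h$paternal_payload[i]) else character(0)
      expect_setequal(union(pm, pp), res$focal$nuclear_types)
      expect_true(all(pm %in% unlist(pool_types[[h$maternal[i]]])))
      expect_true(all(pp %in% unlist(pool_types[[h$paternal[i]]])))
      # (iii) ploidy arithmetic and offspring mode
      expect_equal(h$hybrid_ploidy[i],
                   h$maternal_gamete_ploidy[i] + h$paternal_gamete_ploidy[i])
      if (!is.na(res$focal$ploidy)) {
        expect_equal(h$hybrid_ploidy[i], res$focal$ploidy)
      }
      if (!is.na(res$focal$mode)) {
        expect_equal(h$offspring_mode[i], res$focal$mode)
      }
      expect_false(h$maternal[i] == res$species)
      expect_false(h$paternal[i] == res$species)
      expect_false(h$maternal[i] == h$paternal[i])
    }
  }
})

test_that("a constitution no parent pair can deliver is flagged unexplained", {
  pool <- rbind(taxon("a", "sexual", 2, "A", alpha),
                taxon("b", "sexual", 2, "B", beta))
  focal <- list(species = "focal", mode = "apogamous", ploidy = 3L,
                plastid_type = alpha, nuclear_types = c("A", "B"))
  # neither sexual diploid can contribute an apomictic gamete
  res <- candidate_parents(focal, pool)
  expect_true(res$unexplained)
  expect_error(candidate_parents(focal, pool[0, ]), "empty")
})

test_that("enumeration equals the exhaustive brute-force oracle", {
  set.seed(99)
  cfg <- default_config()
  for (i in 1:30) {
    ds <- random_dataset()
    res <- candidate_parents(ds$focal, ds$pool, cfg)
    expect_identical(impl_parentage_keys(res),
                     oracle_parentage_keys(ds$focal, ds$pool, cfg),
                     info = sprintf("dataset %d", i))
  }
})

test_that("inference output order is deterministic", {
  a <- infer_parentage(diplazium_complex())
  b <- infer_parentage(diplazium_complex())
  expect_identical(top_hypotheses(a), top_hypotheses(b))
  expect_identical(lapply(a$results, `[[`, "hypotheses"),
                   lapply(b$results, `[[`, "hypotheses"))
})
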