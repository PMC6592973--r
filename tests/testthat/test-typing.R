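test_that("newick trees with support labels round-trip", {
  gt <- read_genetree("((a:1,b:1)0.99/95:1,c:1);")
  expect_equal(sort(gt$phylo$tip.label), c("a", "b", "c"))
  expect_equal(gt$support$pp[!is.na(gt$support$pp)], 0.99)
  expect_equal(gt$support$bp[!is.na(gt$support$bp)], 95)

  txt <- write_genetree(gt)
  gt2 <- read_genetree(txt)
  expect_equal(gt2$phylo$tip.label, gt$phylo$tip.label)
  expect_equal(gt2$support, gt$support)

  # single-value labels are posterior probabilities
  gt3 <- read_genetree("((a,b)0.97,c);")
  expect_equal(gt3$support$pp[!is.na(gt3$support$pp)], 0.97)
  expect_true(all(is.na(gt3$support$bp)))
})

test_that("malformed or duplicated newick input is rejected", {
  expect_error(read_genetree("((a,b)),c;"), "malformed")
  expect_error(read_genetree("((a,b,c);"), "unbalanced")
  expect_error(read_genetree("((a:1,b:1):1,a:1);"), "duplicate leaf")
})

test_that("support thresholds follow the pp/bp decision rule", {
  expect_true(is_supported(pp = 0.99, bp = 80))
  expect_true(is_supported(pp = 0.90, bp = 95))   # either suffices
  expect_false(is_supported(pp = 0.90, bp = 95,
                            config = default_config(strict_support = TRUE)))
  expect_true(is_supported(pp = NA, bp = 71))
  expect_false(is_supported(pp = NA, bp = 70))    # strictly greater
  expect_false(is_supported(pp = 0.95, bp = NA))
  expect_false(is_supported(pp = NA, bp = NA))
  expect_false(is_supported(pp = NA, bp = NA,
                            config = default_config(strict_support = TRUE)))
})

test_that("queries are typed from the smallest supported clade with references", {
  # hachijoense-like allele grouping with takii references
  nwk <- paste0("(((Dtakii__B2,Dtakii__B3)0.99/98,Dhachijoense__B2x)0.97/85,",
                "((Damamianum__D1,Dhachijoense__D2x)0.99/91,out__o));")
  gt <- read_genetree(nwk)
  refs <- c(Dtakii = "B", Damamianum = "D")
  got <- assign_type(gt, "Dhachijoense__B2x", refs)
  expect_equal(got$type, "B")
  expect_true("Dtakii__B2" %in% got$evidence$clade)
  expect_equal(assign_type(gt, "Dhachijoense__D2x", refs)$type, "D")
  # a reference leaf types as itself
  expect_equal(assign_type(gt, "Dtakii__B2", refs)$type, "B")
  # an unsupported placement stays unassigned
  expect_equal(assign_type(gt, "out__o", refs)$type, "unassigned")
  expect_error(assign_type(gt, "missing__x", refs), "not in the tree")
})

test_that("mixed reference types in the decisive clade leave queries unassigned", {
  nwk <- "((RefA__A1,RefB__B1,Query__q)0.99/99,RefC__C1);"
  gt <- read_genetree(nwk)
  refs <- c(RefA = "A", RefB = "B", RefC = "C")
  expect_equal(assign_type(gt, "Query__q", refs)$type, "unassigned")
})

test_that("noise-free simulated trees are typed with perfect recovery", {
  sim <- simulate_complex(sim_config(support_noise = 0), seed = 11)
  gt <- sim$trees$nuclear
  out <- assign_types(gt, sim$references)
  covered <- base_types(out$allele) %in% unname(sim$references)
  for (i in seq_len(nrow(out))) {
    truth <- parse_label(out$allele[i])$base
    if (truth %in% unname(sim$references)) {
      expect_equal(out$type[i], truth)
    }
  }
  expect_gt(sum(out$type != "unassigned"), 0)
})

test_that("raising thresholds never increases the number of assigned leaves", {
  set.seed(5)
  for (i in 1:10) {
    rt <- random_support_tree()
    loose <- default_config(pp_threshold = 0.5, bp_threshold = 40)
    tight <- default_config(pp_threshold = 0.95, bp_threshold = 80)
    n_loose <- sum(assign_types(rt$tree, rt$references, loose)$type != "unassigned")
    n_tight <- sum(assign_types(rt$tree, rt$references, tight)$type != "unassigned")
    expect_lte(n_tight, n_loose)
  }
})

test_that("count_types counts distinct assigned types excluding outgroups", {
  sim <- simulate_complex(sim_config(), seed = 3)
  out <- assign_types(sim$trees$nuclear, sim$references)
  expect_equal(count_types(out),
               length(unique(out$type[out$type != "unassigned"])))
  expect_equal(count_types(out[0, ]), 0L)
  all_sp <- unique(out$species)
  expect_equal(count_types(out, exclude_species = all_sp), 0L)
})
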