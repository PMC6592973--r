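test_that("simulation requires an explicit seed", {
  expect_error(simulate_complex(sim_config()), "seed")
})

test_that("the same seed reproduces byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_complex(sim_config(dropout = 0.3, support_noise = 0.2),
                         seed = 5, dir = d1)
  s2 <- simulate_complex(sim_config(dropout = 0.3, support_noise = 0.2),
                         seed = 5, dir = d2)
  expect_identical(s1$specimens, s2$specimens)
  expect_identical(s1$sequences, s2$sequences)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  s3 <- simulate_complex(sim_config(dropout = 0.3, support_noise = 0.2),
                         seed = 6)
  expect_false(identical(s1$sequences, s3$sequences))
})

test_that("simulated hybrids obey maternal plastid and ploidy invariants", {
  for (seed in 1:5) {
    sim <- simulate_complex(sim_config(n_hybrids = 3, n_backcrosses = 2,
                                       dropout = 0.4), seed = seed)
    taxa <- sim$network$taxa
    ev <- sim$network$events
    for (i in seq_len(nrow(ev))) {
      off <- taxa[taxa$species == ev$offspring[i], ]
      mat <- taxa[taxa$species == ev$maternal[i], ]
      pat <- taxa[taxa$species == ev$paternal[i], ]
      expect_equal(off$plastid, mat$plastid)
      gm <- if (ev$maternal_mechanism[i] == "reduced_meiotic")
        mat$ploidy / 2 else if (ev$maternal_mechanism[i] ==
                                  "irregular_meiosis_reduced") 2 else mat$ploidy
      gp <- if (ev$paternal_mechanism[i] == "reduced_meiotic")
        pat$ploidy / 2 else if (ev$paternal_mechanism[i] ==
                                  "irregular_meiosis_reduced") 2 else pat$ploidy
      expect_equal(off$ploidy, as.integer(gm + gp))
      expect_setequal(off$types[[1]],
                      union(ev$maternal_payload[[i]], ev$paternal_payload[[i]]))
    }
  }
})

test_that("infeasible events fail at construction", {
  net <- list()
  net$taxa <- rbind(
    data.frame(species = "odd", mode = "sexual", ploidy = 3L, plastid = "\u03b1",
               sampled = TRUE, types = I(list("A"))),
    data.frame(species = "sex2", mode = "sexual", ploidy = 2L, plastid = "\u03b2",
               sampled = TRUE, types = I(list("B"))))
  net$events <- data.frame(offspring = "x", maternal = "odd",
                           paternal = "sex2",
                           maternal_mechanism = "reduced_meiotic",
                           paternal_mechanism = "reduced_meiotic",
                           stringsAsFactors = FALSE)
  net$events$maternal_payload <- list(NULL)
  net$events$paternal_payload <- list(NULL)
  expect_error(simulate_complex(network = net, seed = 1), "odd ploidy")

  net$events$maternal_mechanism <- "irregular_meiosis_reduced"
  expect_error(simulate_complex(network = net, seed = 1), "apogamous")
})

test_that("noise-free simulations are recovered perfectly", {
  sim <- simulate_complex(sim_config(), seed = 21)
  rr <- recovery_report(infer_parentage(sim$specimens), sim$truth)
  expect_equal(rr$precision, 1)
  expect_equal(rr$recall, 1)

  simc <- simulate_complex(network = hachijoense_network(), seed = 22)
  rrc <- recovery_report(infer_parentage(simc$specimens), simc$truth)
  expect_equal(rrc$recall, 1)
  expect_true(all(rrc$per_taxon$recovered))
})

test_that("recovery_report follows its stated conventions", {
  truth <- data.frame(maternal = "a", paternal = "b", offspring = "c")
  perfect <- data.frame(maternal = "a", paternal = "b", species = "c")
  rr <- recovery_report(perfect, truth)
  expect_equal(rr$precision, 1)
  expect_equal(rr$recall, 1)

  rr0 <- recovery_report(perfect[0, ], truth)
  expect_equal(rr0$precision, 1)  # by convention
  expect_equal(rr0$recall, 0)

  sim <- simulate_complex(sim_config(), seed = 31)
  truth_bad <- sim$truth
  truth_bad$offspring[1] <- "never sampled"
  expect_error(recovery_report(infer_parentage(sim$specimens), truth_bad),
               "not present")
})

test_that("specimen tables written by the simulator reload identically", {
  d <- withr::local_tempdir()
  sim <- simulate_complex(sim_config(), seed = 13, dir = d)
  spc <- load_specimens(file.path(d, "specimens.tsv"))
  expect_equal(spc$species, sim$specimens$species)
  expect_equal(spc$ploidy, sim$specimens$ploidy)
  expect_identical(spc$nuclear, sim$specimens$nuclear)
  # simulated trees round-trip through the newick dialect
  gt <- read_genetree(file.path(d, "nuclear.nwk"))
  expect_setequal(gt$phylo$tip.label, sim$trees$nuclear$phylo$tip.label)
})
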