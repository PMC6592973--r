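test_that("the complex reticulogram has the expected shape", {
  inf <- infer_parentage(diplazium_complex())
  g <- build_reticulogram(inf)
  # 10 named + 4 unnamed sampled taxa + 6 hypothesized lineages
  expect_equal(igraph::gorder(g), 20)
  # one maternal + one paternal edge per origin; the reciprocal taxon
  # contributes two origins
  expect_equal(igraph::gsize(g), 22)
  expect_true(igraph::is_dag(g))

  e <- igraph::as_data_frame(g, what = "edges")
  expect_true(any(e$from == "D. amamianum" & e$to == "D. hachijoense" &
                    e$type == "maternal"))
  expect_true(any(e$from == "D. hachijoense" & e$to == "D. okinawaense" &
                    e$type == "maternal"))
  tai <- e[e$to == "D. taiwanense", ]
  expect_equal(sum(tai$type == "maternal"), 2)
  expect_setequal(tai$from[tai$type == "maternal"],
                  c("D. dilatatum", "D. takii"))

  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(sum(!v$sampled), 6)
})

test_that("an inference without hybrids yields an edgeless graph", {
  spc <- diplazium_complex()
  prog <- spc[spc$species %in% c("D. amamianum", "D. takii"), , drop = FALSE]
  g <- build_reticulogram(infer_parentage(prog))
  expect_equal(igraph::gsize(g), 0)
  expect_equal(igraph::gorder(g), 2)
})

test_that("cyclic parent assignments are rejected by name", {
  fake <- structure(list(
    summaries = rbind(taxon("a", "apogamous", 3, c("A", "B"), "α"),
                      taxon("b", "apogamous", 3, c("A", "B"), "α")),
    registry = data.frame(lineage = character(0), type = character(0),
                          mode = character(0), ploidy = integer(0)),
    results = list(
      structure(list(species = "a", specimen_group = NA_character_,
                     focal = list(), plastid_unmatched = FALSE,
                     unexplained = FALSE,
                     hypotheses = data.frame(maternal = "b", paternal = "b",
                                             pattern = "P3")),
                class = "parentage_result"),
      structure(list(species = "b", specimen_group = NA_character_,
                     focal = list(), plastid_unmatched = FALSE,
                     unexplained = FALSE,
                     hypotheses = data.frame(maternal = "a", paternal = "a",
                                             pattern = "P3")),
                class = "parentage_result"))),
    class = "parentage_inference")
  expect_error(build_reticulogram(fake), "cycle through: a, b")
})

test_that("DOT export is well-formed and byte-stable", {
  inf <- infer_parentage(diplazium_complex())
  g <- build_reticulogram(inf)
  d1 <- export_dot(g)
  d2 <- export_dot(build_reticulogram(infer_parentage(diplazium_complex())))
  expect_identical(d1, d2)

  lines <- strsplit(d1, "\n")[[1]]
  expect_equal(lines[1], "digraph reticulogram {")
  expect_equal(lines[length(lines)], "}")
  body <- lines[-c(1, length(lines))]
  node_or_edge <- grepl("^\\s+\"[^\"]+\" \\[.*\\];$", body) |
    grepl("^\\s+\"[^\"]+\" -> \"[^\"]+\" \\[.*\\];$", body) |
    grepl("^\\s+(rankdir|node)", body)
  expect_true(all(node_or_edge))
  # maternal edges solid, paternal dashed
  expect_true(any(grepl("style=solid.*maternal", body)))
  expect_true(any(grepl("style=dashed.*paternal", body)))
})

test_that("a two-node toy network exports one solid maternal edge", {
  spc <- diplazium_complex()
  sub <- spc[spc$species %in% c("D. amamianum", "D. takii",
                                "D. hachijoense"), , drop = FALSE]
  g <- build_reticulogram(infer_parentage(sub))
  d <- export_dot(g)
  expect_equal(length(grep("style=solid", strsplit(d, "\n")[[1]])), 1)
})

test_that("GraphML round-trips nodes, edge types and annotations", {
  inf <- infer_parentage(diplazium_complex())
  g <- build_reticulogram(inf)
  xml <- export_graphml(g)
  expect_identical(xml, export_graphml(g))  # stable

  g2 <- read_graphml(xml)
  expect_equal(igraph::gorder(g2), igraph::gorder(g))
  expect_equal(igraph::gsize(g2), igraph::gsize(g))
  e1 <- igraph::as_data_frame(g, what = "edges")
  e2 <- igraph::as_data_frame(g2, what = "edges")
  key <- function(e) sort(paste(e$from, e$to, e$type))
  expect_equal(key(e2), key(e1))
  v2 <- igraph::as_data_frame(g2, what = "vertices")
  expect_equal(sum(!v2$sampled), 6)
})
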