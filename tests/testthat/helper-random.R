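# Random small datasets and trees for property-style and oracle tests.

greek5 <- c("\u03b1", "\u03b2", "\u03b3", "\u03b4", "\u03b5")

# A random <=8-taxon pool plus one focal hybrid, structured like the
# datasets the inference consumes: single-type progenitors with their
# own plastid types, optional multi-type (hybrid-derived) taxa,
# optional hypothesized lineages, and a focal with random constitution
# and possibly undetermined mode/ploidy.
random_dataset <- function() {
  n_prog <- sample(2:4, 1)
  types <- LETTERS[seq_len(n_prog)]
  pool <- NULL
  for (i in seq_len(n_prog)) {
    if (i %% 2 == 1) {
      pool <- rbind(pool, taxon(paste0("prog", i), "sexual", 2,
                                types[i], greek5[i]))
    } else {
      pool <- rbind(pool, taxon(paste0("prog", i), "apogamous", 3,
                                types[i], greek5[i]))
    }
  }
  n_hyb <- sample(0:2, 1)
  for (h in seq_len(n_hyb)) {
    tt <- sample(types, sample(2:min(3, n_prog), 1))
    pool <- rbind(pool, taxon(
      paste0("hyb", h),
      mode = sample(c("apogamous", NA), 1),
      ploidy = sample(c(3L, NA), 1),
      nuclear_types = tt,
      plastid_types = sample(greek5[seq_len(n_prog)], 1)))
  }
  n_unk <- sample(0:2, 1)
  extra <- setdiff(LETTERS[1:6], types)
  for (u in seq_len(min(n_unk, length(extra)))) {
    pool <- rbind(pool, taxon(paste0("unk", u), NA, NA,
                              nuclear_types = extra[u], sampled = FALSE))
  }
  avail <- unique(unlist(pool$nuclear_types))
  focal <- list(
    species = "focal",
    mode = sample(c("apogamous", "sexual", NA), 1),
    ploidy = sample(c(2L, 3L, 4L, NA), 1),
    plastid_type = sample(c(greek5[seq_len(n_prog)], greek5[5]), 1),
    nuclear_types = sort(sample(avail, sample(1:min(3, length(avail)), 1)))
  )
  list(focal = focal, pool = pool)
}

# A random rooted 12-leaf tree with reference and query leaves and
# randomly present/absent node supports.
random_support_tree <- function() {
  phy <- ape::rtree(12, br = NULL)
  ref_species <- paste0("Ref", LETTERS[1:4])
  labs <- c(sprintf("Ref%s__%s1", LETTERS[1:4], LETTERS[1:4]),
            sprintf("Ref%s__%s2", LETTERS[1:4], LETTERS[1:4]),
            sprintf("Query%d__q%d", 1:4, 1:4))
  phy$tip.label <- sample(labs)
  nl <- character(phy$Nnode)
  for (k in seq_len(phy$Nnode)) {
    r <- runif(1)
    nl[k] <- if (r < 0.3) "" else if (r < 0.5) {
      sprintf("%.2f", runif(1))
    } else {
      sprintf("%.2f/%.0f", runif(1), runif(1) * 100)
    }
  }
  phy$node.label <- nl
  gt <- read_genetree(ape::write.tree(phy))
  refs <- setNames(LETTERS[1:4], ref_species)
  list(tree = gt, references = refs)
}

# Expected top-ranked origins of the packaged complex (used by several
# tests): maternal parent, paternal parent per hybrid taxon/group.
expected_complex_origins <- function() {
  df <- rbind(
    c("D. conterminum", NA, "D. takii", "D. sp. F"),
    c("D. hachijoense", NA, "D. amamianum", "D. takii"),
    c("D. nipponicum", NA, "D. amamianum", "D. sp. J"),
    c("D. okinawaense", NA, "D. hachijoense", "D. dilatatum"),
    c("D. sp. 1", NA, "D. dilatatum", "D. sp. G"),
    c("D. sp. 2", NA, "D. doederleinii", "D. sp. K"),
    c("D. sp. 3", NA, "D. amamianum", "D. doederleinii"),
    c("D. sp. 4", NA, "D. amamianum", "D. sp. H"),
    c("D. taiwanense", "\u03b1", "D. dilatatum", "D. takii"),
    c("D. taiwanense", "\u03b2", "D. takii", "D. dilatatum"),
    c("D. virescens", NA, "D. takii", "D. sp. E"))
  data.frame(species = df[, 1], specimen_group = df[, 2],
             maternal = df[, 3], paternal = df[, 4],
             stringsAsFactors = FALSE)
}
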