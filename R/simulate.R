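#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The generator emulates
#' the genealogical structure the parentage inference assumes: a small
#' set of progenitor taxa (diploid sexuals, autotriploid apomicts, and
#' optionally an autotriploid cytotype twin of a sexual species, a
#' situation observed in real complexes), hybridization-cycle events
#' producing triploid apomictic hybrids, optional backcross events with
#' a hybrid as the maternal parent, per-type reference sequences
#' evolved under an equal-rates substitution model, and SSCP-style
#' dosage masking (allele sets, never counts).
#'
#' @param n_sexual_diploid Number of diploid sexual progenitors.
#' @param n_apo_triploid Number of autotriploid apogamous progenitors.
#' @param twin_autotriploid Add an apogamous triploid cytotype of the
#'   first sexual progenitor, sharing its nuclear type and plastid.
#' @param n_hybrids Number of first-generation hybridization-cycle
#'   events (triploid apomict x diploid sexual).
#' @param n_backcrosses Number of second-generation events using the
#'   first hybrid as maternal parent.
#' @param specimens_per_taxon Vouchers generated per sampled taxon.
#' @param seq_length Reference sequence length in bp (default 600, the
#'   scale of a short low-copy nuclear intron alignment).
#' @param divergence Substitutions separating each base type's
#'   reference sequence from the ancestral sequence.
#' @param subtype_mutations Substitutions separating a subtype variant
#'   from its type reference.
#' @param n_subtypes Subtype variants segregating per base type.
#' @param support_noise Fraction of support lost at gene-tree nodes:
#'   node supports are drawn as pp = 1 - noise*U, bp = 100*(1 -
#'   noise*U) with U uniform on \[0, 1\].
#' @param dropout Per-type probability that a segregating
#'   (`subset_allowed`) gamete payload loses a type (models allele loss
#'   through segregation with recombination); at least one type is
#'   always transmitted.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_sexual_diploid = 3, n_apo_triploid = 1,
                       twin_autotriploid = TRUE, n_hybrids = 2,
                       n_backcrosses = 2, specimens_per_taxon = 2,
                       seq_length = 600, divergence = 25,
                       subtype_mutations = 2, n_subtypes = 2,
                       support_noise = 0, dropout = 0) {
  stopifnot(n_sexual_diploid >= 1, n_apo_triploid >= 0,
            n_hybrids >= 1, n_backcrosses >= 0,
            specimens_per_taxon >= 2, seq_length > 0,
            support_noise >= 0, support_noise <= 1,
            dropout >= 0, dropout <= 1)
  structure(as.list(environment()), class = "sim_config")
}

compact_name <- function(x) gsub("[^A-Za-z0-9]", "", x)

sim_taxon_row <- function(species, mode, ploidy, plastid, types,
                          sampled = TRUE) {
  out <- data.frame(species = species, mode = mode,
                    ploidy = as.integer(ploidy), plastid = plastid,
                    sampled = sampled, stringsAsFactors = FALSE)
  out$types <- list(sort(types, method = "radix"))
  out
}

sim_event_row <- function(offspring, maternal, paternal,
                          maternal_mechanism, paternal_mechanism,
                          maternal_payload = NULL, paternal_payload = NULL) {
  out <- data.frame(offspring = offspring, maternal = maternal,
                    paternal = paternal,
                    maternal_mechanism = maternal_mechanism,
                    paternal_mechanism = paternal_mechanism,
                    stringsAsFactors = FALSE)
  out$maternal_payload <- list(maternal_payload)
  out$paternal_payload <- list(paternal_payload)
  out
}

#' Truth network of the simulator's default study system
#'
#' A deterministic truth network shaped like the *D. hachijoense*
#' complex: four core progenitors (plus the apogamous triploid cytotype
#' of *D. dilatatum*), six unsampled orphan lineages (E, F, G, J, K
#' diploid sexual; H triploid apogamous), and eleven hybridization
#' events \u2014 nine hybridization-cycle (P3) crosses including a
#' reciprocal pair and a backcross with intrinsic allele loss, one
#' cross with the apomictic orphan lineage H, and one allopolyploid
#' origin of a tetraploid sexual.  Reciprocal origins are represented
#' as two offspring taxa so each event has its own voucher series.
#'
#' @return A list with `taxa` and `events` data.frames, consumable by
#'   [simulate_complex()].
#' @export
hachijoense_network <- function() {
  taxa <- rbind(
    sim_taxon_row("D. amamianum", "sexual", 2, "\u03b4", "D"),
    sim_taxon_row("D. dilatatum", "sexual", 2, "\u03b1", "A"),
    sim_taxon_row("D. dilatatum-apo", "apogamous", 3, "\u03b1", "A"),
    sim_taxon_row("D. takii", "apogamous", 3, "\u03b2", "B"),
    sim_taxon_row("D. doederleinii", "apogamous", 3, "\u03b3", "C"),
    sim_taxon_row("D. sp. E", "sexual", 2, NA, "E", sampled = FALSE),
    sim_taxon_row("D. sp. F", "sexual", 2, NA, "F", sampled = FALSE),
    sim_taxon_row("D. sp. G", "sexual", 2, NA, "G", sampled = FALSE),
    sim_taxon_row("D. sp. H", "apogamous", 3, NA, "H", sampled = FALSE),
    sim_taxon_row("D. sp. J", "sexual", 2, NA, "J", sampled = FALSE),
    sim_taxon_row("D. sp. K", "sexual", 2, NA, "K", sampled = FALSE))
  events <- rbind(
    sim_event_row("D. hachijoense", "D. amamianum", "D. takii",
                  "reduced_meiotic", "irregular_meiosis_reduced"),
    sim_event_row("D. okinawaense", "D. hachijoense", "D. dilatatum",
                  "irregular_meiosis_reduced", "reduced_meiotic",
                  maternal_payload = "B"),
    sim_event_row("D. taiwanense-a", "D. dilatatum", "D. takii",
                  "reduced_meiotic", "irregular_meiosis_reduced"),
    sim_event_row("D. taiwanense-b", "D. takii", "D. dilatatum",
                  "irregular_meiosis_reduced", "reduced_meiotic"),
    sim_event_row("D. conterminum", "D. takii", "D. sp. F",
                  "irregular_meiosis_reduced", "reduced_meiotic"),
    sim_event_row("D. virescens", "D. takii", "D. sp. E",
                  "irregular_meiosis_reduced", "reduced_meiotic"),
    sim_event_row("D. sp. 1", "D. dilatatum-apo", "D. sp. G",
                  "irregular_meiosis_reduced", "reduced_meiotic"),
    sim_event_row("D. sp. 2", "D. doederleinii", "D. sp. K",
                  "irregular_meiosis_reduced", "reduced_meiotic"),
    sim_event_row("D. sp. 3", "D. amamianum", "D. doederleinii",
                  "reduced_meiotic", "irregular_meiosis_reduced"),
    sim_event_row("D. sp. 4", "D. amamianum", "D. sp. H",
                  "reduced_meiotic", "irregular_meiosis_reduced"),
    sim_event_row("D. nipponicum", "D. amamianum", "D. sp. J",
                  "unreduced_sexual", "unreduced_sexual"))
  list(taxa = taxa, events = events)
}

# Deterministic truth-network topology from a sim_config: progenitors
# with distinct plastid types, hybridization-cycle events over distinct
# ordered parent pairs, and backcrosses using the first hybrid as
# maternal parent.  These constraints (no repeated ordered pair, and
# the two parents of an event never share a plastid base type) are the
# identifiability conditions under which noise-free recovery is exact.
make_truth_network <- function(config) {
  letters_pool <- nuclear_letters()
  greek <- greek_letters()
  n_prog <- config$n_sexual_diploid + config$n_apo_triploid
  if (n_prog > length(greek)) {
    stop("at most ", length(greek),
         " plastid-bearing progenitors are supported (plastid alphabet size)",
         call. = FALSE)
  }
  if (n_prog + config$n_hybrids > length(letters_pool)) {
    stop("too many taxa for the nuclear type alphabet", call. = FALSE)
  }
  taxa <- list()
  sex <- character(0); apo <- character(0)
  for (i in seq_len(config$n_sexual_diploid)) {
    nm <- paste0("S. sex", i)
    taxa[[length(taxa) + 1L]] <- sim_taxon_row(nm, "sexual", 2, greek[i],
                                               letters_pool[i])
    sex <- c(sex, nm)
  }
  for (i in seq_len(config$n_apo_triploid)) {
    nm <- paste0("S. apo", i)
    taxa[[length(taxa) + 1L]] <- sim_taxon_row(
      nm, "apogamous", 3, greek[config$n_sexual_diploid + i],
      letters_pool[config$n_sexual_diploid + i])
    apo <- c(apo, nm)
  }
  if (isTRUE(config$twin_autotriploid)) {
    taxa[[length(taxa) + 1L]] <- sim_taxon_row("S. sex1-apo", "apogamous", 3,
                                               greek[1], letters_pool[1])
  }
  if (length(apo) == 0 && config$n_hybrids > 0) {
    stop("hybridization-cycle events need at least one triploid apomict",
         call. = FALSE)
  }
  events <- list()
  for (k in seq_len(config$n_hybrids)) {
    s <- sex[(k - 1L) %% length(sex) + 1L]
    a <- apo[(k - 1L) %% length(apo) + 1L]
    # alternate the maternal role between the sexual and apomictic parent
    if (k %% 2L == 1L) {
      events[[length(events) + 1L]] <- sim_event_row(
        sprintf("S. hyb%02d", k), s, a,
        "reduced_meiotic", "irregular_meiosis_reduced")
    } else {
      events[[length(events) + 1L]] <- sim_event_row(
        sprintf("S. hyb%02d", k), a, s,
        "irregular_meiosis_reduced", "reduced_meiotic")
    }
  }
  if (config$n_backcrosses > 0) {
    others <- setdiff(sex, sex[1])
    if (length(others) == 0) {
      stop("backcross events need a second sexual diploid", call. = FALSE)
    }
    for (k in seq_len(config$n_backcrosses)) {
      events[[length(events) + 1L]] <- sim_event_row(
        sprintf("S. bc%02d", k), "S. hyb01",
        others[(k - 1L) %% length(others) + 1L],
        "irregular_meiosis_reduced", "reduced_meiotic")
    }
  }
  list(taxa = do.call(rbind, taxa), events = do.call(rbind, events))
}

# payload rule of a mechanism
mechanism_rule <- function(mechanism) {
  c(reduced_meiotic = "subset_allowed", unreduced_sexual = "all_types",
    unreduced_diplospore = "all_types",
    irregular_meiosis_reduced = "subset_allowed")[mechanism]
}

mechanism_apomictic <- function(mechanism) {
  mechanism %in% c("unreduced_diplospore", "irregular_meiosis_reduced")
}

# realized payload of one gamete, applying intrinsic payload choice,
# then random dropout; a gamete always transmits at least one type
realize_payload <- function(mechanism, parent_types, intended, dropout) {
  rule <- mechanism_rule(mechanism)
  if (rule == "all_types") return(sort(parent_types, method = "radix"))
  payload <- if (is.null(intended)) parent_types else
    intersect(intended, parent_types)
  if (length(payload) == 0) payload <- sample(parent_types, 1)
  if (dropout > 0 && length(payload) > 1) {
    keep <- runif(length(payload)) >= dropout
    if (!any(keep)) keep[sample(length(payload), 1)] <- TRUE
    payload <- payload[keep]
  }
  sort(payload, method = "radix")
}

# gamete ploidy for a mechanism given parental ploidy
mechanism_gamete_ploidy <- function(mechanism, parent_ploidy) {
  switch(mechanism,
         reduced_meiotic = {
           if (parent_ploidy %% 2L != 0L) {
             stop("reduced meiotic gamete from odd ploidy ", parent_ploidy,
                  call. = FALSE)
           }
           parent_ploidy %/% 2L
         },
         unreduced_sexual = parent_ploidy,
         unreduced_diplospore = parent_ploidy,
         irregular_meiosis_reduced = {
           if (parent_ploidy != 3L) {
             stop("irregular meiosis requires a triploid parent", call. = FALSE)
           }
           2L
         },
         stop("unknown gamete mechanism '", mechanism, "'", call. = FALSE))
}

check_event_feasible <- function(mechanism, mode) {
  sexual_mech <- mechanism %in% c("reduced_meiotic", "unreduced_sexual")
  if (sexual_mech && mode != "sexual") {
    stop("mechanism ", mechanism, " requires a sexual parent", call. = FALSE)
  }
  if (!sexual_mech && mode != "apogamous") {
    stop("mechanism ", mechanism, " requires an apogamous parent",
         call. = FALSE)
  }
}

#' Simulate a specimen dataset from a truth network
#'
#' Realizes every hybridization event of a truth network (offspring
#' plastid from the maternal gamete, nuclear types as the union of the
#' two gamete payloads, ploidy as the gamete-ploidy sum, apogamous
#' offspring whenever an apomictic gamete is involved), then emits a
#' specimen table with SSCP-style dosage masking, per-locus gene trees
#' whose clades are the true type genealogy with injected supports, and
#' per-locus FASTA sequences evolved under an equal-rates substitution
#' model.  All randomness (subtype draws, dropout, support noise,
#' sequences) is governed by `seed`; unseeded calls fail.
#'
#' @param config A [sim_config()].
#' @param seed Integer random seed (mandatory).
#' @param network A truth network (`list(taxa, events)`), e.g. from
#'   [hachijoense_network()]; when `NULL` one is built from `config`
#'   via the generator's deterministic topology rules.
#' @param dir Optional directory: writes `specimens.tsv`,
#'   `nuclear.nwk`, `plastid.nwk`, `nuclear.fasta`, `plastid.fasta`.
#' @return A list with `network` (taxa including realized hybrids, and
#'   events with realized payloads), `specimens` (specimen data.frame),
#'   `trees` (`gene_tree` objects per locus), `sequences` (named
#'   character vectors per locus), `references` (species -> type map of
#'   sampled single-type progenitors) and `truth` (data.frame of
#'   (maternal, paternal, offspring) triples).
#' @export
#' @examples
#' sim <- simulate_complex(sim_config(), seed = 1)
#' sim$truth
simulate_complex <- function(config = sim_config(), seed, network = NULL,
                             dir = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("simulate_complex() requires an explicit integer seed", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (is.null(network)) network <- make_truth_network(config)
  taxa <- network$taxa
  events <- network$events

  # realize events in order; parents must precede their offspring
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    mi <- match(ev$maternal, taxa$species)
    pi_ <- match(ev$paternal, taxa$species)
    if (is.na(mi) || is.na(pi_)) {
      stop("event ", ev$offspring, " references an undefined parent",
           call. = FALSE)
    }
    check_event_feasible(ev$maternal_mechanism, taxa$mode[mi])
    check_event_feasible(ev$paternal_mechanism, taxa$mode[pi_])
    gm <- mechanism_gamete_ploidy(ev$maternal_mechanism, taxa$ploidy[mi])
    gp <- mechanism_gamete_ploidy(ev$paternal_mechanism, taxa$ploidy[pi_])
    pm <- realize_payload(ev$maternal_mechanism, taxa$types[[mi]],
                          ev$maternal_payload[[1]], config$dropout)
    pp <- realize_payload(ev$paternal_mechanism, taxa$types[[pi_]],
                          ev$paternal_payload[[1]], config$dropout)
    events$maternal_payload[[i]] <- pm
    events$paternal_payload[[i]] <- pp
    apo <- mechanism_apomictic(ev$maternal_mechanism) ||
      mechanism_apomictic(ev$paternal_mechanism)
    taxa <- rbind(taxa, sim_taxon_row(
      ev$offspring, if (apo) "apogamous" else "sexual", gm + gp,
      taxa$plastid[mi], sort(unique(c(pm, pp)), method = "radix")))
  }

  # subtype labels: progenitor specimens cycle subtypes so every
  # sampled type clade has at least two leaves in the gene tree
  sampled <- taxa[taxa$sampled, , drop = FALSE]
  specs <- list()
  v <- 0L
  for (i in seq_len(nrow(sampled))) {
    for (j in seq_len(config$specimens_per_taxon)) {
      v <- v + 1L
      sub <- (j - 1L) %% config$n_subtypes + 1L
      nuc <- paste0(sampled$types[[i]], sub)
      specs[[length(specs) + 1L]] <- data.frame(
        voucher = sprintf("SIM-%03d", v), locality = "simulated",
        species = sampled$species[i],
        mode = c(sexual = "sex.", apogamous = "apo.")[sampled$mode[i]],
        ploidy_2n_or_multiple = paste0(sampled$ploidy[i], "x"),
        plastid = if (is.na(sampled$plastid[i])) "" else
          paste0(sampled$plastid[i], sub),
        ak1 = paste(sort(nuc, method = "radix"), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  spec_raw <- do.call(rbind, specs)
  specimens <- as_specimens(spec_raw, default_config())

  # references: sampled single-type taxa (progenitors of the truth)
  single <- lengths(sampled$types) == 1 &
    !(sampled$species %in% events$offspring)
  references <- setNames(unlist(sampled$types[single]),
                         sampled$species[single])

  trees <- list(
    nuclear = sim_gene_tree(specimens, locus = "nuclear", config),
    plastid = sim_gene_tree(specimens, locus = "plastid", config))
  sequences <- list(
    nuclear = sim_sequences(specimens, locus = "nuclear", config),
    plastid = sim_sequences(specimens, locus = "plastid", config))

  truth <- data.frame(maternal = events$maternal, paternal = events$paternal,
                      offspring = events$offspring, stringsAsFactors = FALSE)
  out <- list(network = list(taxa = taxa, events = events),
              specimens = specimens, trees = trees, sequences = sequences,
              references = references, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_specimens(specimens, file.path(dir, "specimens.tsv"))
    write_genetree(trees$nuclear, file.path(dir, "nuclear.nwk"))
    write_genetree(trees$plastid, file.path(dir, "plastid.nwk"))
    write_fasta(sequences$nuclear, file.path(dir, "nuclear.fasta"))
    write_fasta(sequences$plastid, file.path(dir, "plastid.fasta"))
  }
  out
}

# distinct (species, allele-label) leaves per locus
locus_leaves <- function(specimens, locus) {
  rows <- list()
  for (i in seq_len(nrow(specimens))) {
    labs <- if (locus == "nuclear") specimens$nuclear[[i]] else
      specimens$plastid[i]
    labs <- labs[!is.na(labs)]
    for (l in labs) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = specimens$species[i], allele = l, stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, rows))
}

# true type genealogy: one supported clade per base type
sim_gene_tree <- function(specimens, locus, config) {
  leaves <- locus_leaves(specimens, locus)
  leaves$type <- vapply(leaves$allele, function(l) parse_label(l)$base, "")
  leaves$label <- paste0(compact_name(leaves$species), "__", leaves$allele)
  types <- sort(unique(leaves$type), method = "radix")
  clades <- vapply(types, function(tp) {
    members <- sort(leaves$label[leaves$type == tp], method = "radix")
    pp <- 1 - config$support_noise * runif(1)
    bp <- 100 * (1 - config$support_noise * runif(1))
    if (length(members) == 1) return(members)
    sprintf("(%s)%.4f/%.1f", paste(members, collapse = ","), pp, bp)
  }, "")
  newick <- if (length(clades) == 1) paste0(clades, ";") else
    paste0("(", paste(clades, collapse = ","), ");")
  gt <- read_genetree(newick)
  # attach true specimen metadata (labels are compacted for Newick)
  m <- match(gt$phylo$tip.label, leaves$label)
  gt$leaves$species <- leaves$species[m]
  gt$leaves$allele <- leaves$allele[m]
  gt
}

# equal-rates substitution model on a random ancestral sequence
sim_sequences <- function(specimens, locus, config) {
  leaves <- locus_leaves(specimens, locus)
  alleles <- sort(unique(leaves$allele), method = "radix")
  types <- sort(unique(vapply(alleles, function(l) parse_label(l)$base, "")),
                method = "radix")
  bases <- c("a", "c", "g", "t")
  L <- config$seq_length
  ancestral <- sample(bases, L, replace = TRUE)
  mutate <- function(seq, n) {
    pos <- sample(L, min(n, L))
    for (p in pos) seq[p] <- sample(setdiff(bases, seq[p]), 1)
    seq
  }
  refs <- lapply(types, function(tp) mutate(ancestral, config$divergence))
  names(refs) <- types
  out <- vapply(alleles, function(al) {
    tp <- parse_label(al)$base
    paste(mutate(refs[[tp]], config$subtype_mutations), collapse = "")
  }, "")
  names(out) <- alleles
  out
}

#' Write a specimen data.frame back to the TSV dialect
#'
#' @param specimens A specimen data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  mode_cell <- c(sexual = "sex.", apogamous = "apo.")[specimens$mode]
  mode_cell[is.na(mode_cell)] <- ""
  df <- data.frame(
    voucher = specimens$voucher, locality = specimens$locality,
    species = specimens$species, mode = mode_cell,
    ploidy_2n_or_multiple = ifelse(is.na(specimens$ploidy), "",
                                   paste0(specimens$ploidy, "x")),
    plastid = ifelse(is.na(specimens$plastid), "", specimens$plastid),
    ak1 = vapply(specimens$nuclear, paste, "", collapse = ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

write_fasta <- function(seqs, path) {
  dna <- ape::as.DNAbin(lapply(seqs, function(s)
    strsplit(s, "", fixed = TRUE)[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Precision and recall of parentage recovery
#'
#' Compares the top-ranked (maternal, paternal, offspring) triples of a
#' parentage inference against the truth triples of the generating
#' network.  Precision is the fraction of inferred triples that are
#' true (reported as 1 when nothing was inferred, by convention);
#' recall is the fraction of truth triples recovered.
#'
#' @param inference A `parentage_inference` (or a data.frame of
#'   inferred triples with columns `maternal`, `paternal`, `species` or
#'   `offspring`).
#' @param truth A truth data.frame (`maternal`, `paternal`,
#'   `offspring`), e.g. `simulate_complex(...)$truth`.
#' @return A list with `precision`, `recall`, and `per_taxon`
#'   (data.frame with `offspring`, `recovered`).
#' @export
recovery_report <- function(inference, truth) {
  if (inherits(inference, "parentage_inference")) {
    th <- top_hypotheses(inference)
    known <- unique(c(inference$summaries$species,
                      inference$registry$lineage))
    missing_names <- setdiff(truth$offspring, inference$summaries$species)
    if (length(missing_names)) {
      stop("truth offspring not present in the inferred dataset: ",
           paste(missing_names, collapse = ", "), call. = FALSE)
    }
    inferred <- th[!is.na(th$maternal),
                   c("maternal", "paternal", "species")]
  } else {
    inferred <- inference
    if ("offspring" %in% names(inferred)) {
      names(inferred)[names(inferred) == "offspring"] <- "species"
    }
  }
  key <- function(m, p, o) paste(m, p, o, sep = " -> ")
  truth_keys <- key(truth$maternal, truth$paternal, truth$offspring)
  inf_keys <- if (nrow(inferred)) {
    key(inferred$maternal, inferred$paternal, inferred$species)
  } else character(0)
  hit <- truth_keys %in% inf_keys
  precision <- if (length(inf_keys) == 0) 1 else
    mean(inf_keys %in% truth_keys)
  list(precision = precision,
       recall = if (length(truth_keys) == 0) 1 else mean(hit),
       per_taxon = data.frame(offspring = truth$offspring, recovered = hit,
                              stringsAsFactors = FALSE))
}
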