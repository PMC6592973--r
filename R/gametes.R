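#' Gamete repertoire of a taxon
#'
#' Enumerates the gametes a taxon can contribute to a cross, given its
#' reproductive mode and ploidy (in multiples of the base number x):
#'
#' * sexual, even ploidy p: a reduced meiotic gamete of ploidy p/2.  Its
#'   allele payload is the full type set for a diploid carrying a single
#'   base type; otherwise segregation may transmit any non-empty subset
#'   (`subset_allowed`).
#' * sexual, any ploidy: an unreduced gamete of ploidy p when
#'   `allow_unreduced_sexual` is enabled (allopolyploid formation).
#' * apogamous, ploidy p: an unreduced diplospore-derived gamete of
#'   ploidy p carrying all parental types.
#' * apogamous, ploidy 3: additionally a reduced diploid (2x) gamete via
#'   irregular meiosis (`allow_irregular_meiosis`), the mechanism of the
#'   hybridization cycle; segregation with recombination means its
#'   payload is `subset_allowed`.
#'
#' Taxa with unknown mode and/or ploidy are expanded over both modes
#' and/or `config$plausible_ploidies`; the `assumed_mode` /
#' `assumed_ploidy` columns record each assumption.
#'
#' @param taxon A one-row `taxon_summary` (see [summarize_taxa()] or
#'   [taxon()]), or a list with elements `species`, `mode`, `ploidy`,
#'   `nuclear_types`.
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A data.frame with one row per gamete: `mechanism`
#'   (`reduced_meiotic`, `unreduced_sexual`, `unreduced_diplospore`,
#'   `irregular_meiosis_reduced`), `gamete_ploidy`, `payload_rule`
#'   (`all_types`/`subset_allowed`), `apomictic` (does the gamete carry
#'   the apomictic developmental pathway), `assumed_mode`,
#'   `assumed_ploidy`.  Zero rows (with a warning) when no mechanism is
#'   available, e.g. a sexual triploid with unreduced gametes disabled.
#' @export
#' @examples
#' gametes(taxon("t", "apogamous", 3, "B"))
gametes <- function(taxon, config = NULL) {
  config <- as_config(config)
  mode <- taxon$mode
  if (is.list(mode)) mode <- mode[[1]]
  ploidy <- taxon$ploidy
  if (is.list(ploidy)) ploidy <- ploidy[[1]]
  types <- taxon$nuclear_types
  if (is.list(types)) types <- types[[1]]

  modes <- if (is.na(mode)) c("sexual", "apogamous") else mode
  ploidies <- if (is.na(ploidy)) config$plausible_ploidies else as.integer(ploidy)

  rows <- list()
  for (m in modes) {
    for (p in ploidies) {
      rows[[length(rows) + 1L]] <- gamete_rows(m, p, types, config)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    warning("taxon '", taxon$species,
            "' has no available gamete mechanism under the configuration")
    out <- gamete_rows("sexual", 2L, types, config)[0, , drop = FALSE]
  }
  out$assumed_mode <- as.character(out$assumed_mode)
  rownames(out) <- NULL
  out
}

gamete_rows <- function(mode, ploidy, types, config) {
  res <- list()
  single_type <- length(types) == 1
  if (mode == "sexual") {
    if (ploidy %% 2L == 0L) {
      res[[length(res) + 1L]] <- data.frame(
        mechanism = "reduced_meiotic", gamete_ploidy = ploidy %/% 2L,
        payload_rule = if (ploidy == 2L && single_type) "all_types" else "subset_allowed",
        apomictic = FALSE, assumed_mode = mode, assumed_ploidy = ploidy,
        stringsAsFactors = FALSE)
    }
    if (config$allow_unreduced_sexual) {
      res[[length(res) + 1L]] <- data.frame(
        mechanism = "unreduced_sexual", gamete_ploidy = ploidy,
        payload_rule = "all_types", apomictic = FALSE,
        assumed_mode = mode, assumed_ploidy = ploidy,
        stringsAsFactors = FALSE)
    }
  } else if (mode == "apogamous") {
    res[[length(res) + 1L]] <- data.frame(
      mechanism = "unreduced_diplospore", gamete_ploidy = ploidy,
      payload_rule = "all_types", apomictic = TRUE,
      assumed_mode = mode, assumed_ploidy = ploidy,
      stringsAsFactors = FALSE)
    if (ploidy == 3L && config$allow_irregular_meiosis) {
      res[[length(res) + 1L]] <- data.frame(
        mechanism = "irregular_meiosis_reduced", gamete_ploidy = 2L,
        payload_rule = "subset_allowed", apomictic = TRUE,
        assumed_mode = mode, assumed_ploidy = ploidy,
        stringsAsFactors = FALSE)
    }
  } else {
    stop("unknown reproductive mode '", mode, "'", call. = FALSE)
  }
  do.call(rbind, res)
}

# Hybridization pattern of one gamete combination.  The four canonical
# patterns (unordered with respect to which parent is maternal):
#   P1: 3x apomict (unreduced 3x) x 2x sexual (reduced 1x) -> 4x
#   P2: 2x apomict (unreduced 2x) x 2x sexual (reduced 1x) -> 3x
#   P3: 3x apomict (irregular 2x) x 2x sexual (reduced 1x) -> 3x
#   P4: 3x apomict (irregular 2x) x 4x sexual (reduced 2x) -> 4x
# Same-taxon doubling is "autopolyploid"; all-sexual combinations with
# an unreduced gamete are "allopolyploid"; anything else "other".
classify_pattern <- function(m, p, same_taxon = FALSE) {
  if (same_taxon) return("autopolyploid")
  key <- function(g) paste(g$assumed_mode, g$assumed_ploidy, g$mechanism,
                           g$gamete_ploidy)
  pair <- sort(c(key(m), key(p)))
  pat <- paste(pair, collapse = " + ")
  p1 <- "apogamous 3 unreduced_diplospore 3 + sexual 2 reduced_meiotic 1"
  p2 <- "apogamous 2 unreduced_diplospore 2 + sexual 2 reduced_meiotic 1"
  p3 <- "apogamous 3 irregular_meiosis_reduced 2 + sexual 2 reduced_meiotic 1"
  p4 <- "apogamous 3 irregular_meiosis_reduced 2 + sexual 4 reduced_meiotic 2"
  if (pat == p1) return("P1")
  if (pat == p2) return("P2")
  if (pat == p3) return("P3")
  if (pat == p4) return("P4")
  if (!m$apomictic && !p$apomictic &&
      ("unreduced_sexual" %in% c(m$mechanism, p$mechanism))) {
    return("allopolyploid")
  }
  "other"
}

pattern_rank <- function(pattern) {
  match(pattern, c("P3", "P1", "P2", "P4", "allopolyploid", "autopolyploid",
                   "other"))
}

# Offspring of a cross involving any apomictic gamete develop
# apogamously; two sexual gametes give a sexual offspring.
offspring_mode <- function(m_apomictic, p_apomictic) {
  ifelse(m_apomictic | p_apomictic, "apogamous", "sexual")
}

#' Enumerate cross outcomes between two taxa
#'
#' Takes the Cartesian product of the parents' gamete repertoires and
#' reports, for every combination, the hybrid ploidy (the sum of gamete
#' ploidies), the offspring reproductive mode, and the hybridization
#' pattern label.  A cross of a taxon with itself is labeled
#' `autopolyploid`.
#'
#' @param maternal,paternal One-row `taxon_summary` objects (see
#'   [taxon()]).
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A data.frame with one row per gamete combination:
#'   maternal/paternal mechanism and gamete ploidy, assumed parental
#'   modes and ploidies, `hybrid_ploidy`, `offspring_mode`, `pattern`.
#' @export
#' @examples
#' apo3 <- taxon("apo3", "apogamous", 3, "B")
#' sex2 <- taxon("sex2", "sexual", 2, "D")
#' cross_taxa(apo3, sex2)
cross_taxa <- function(maternal, paternal, config = NULL) {
  config <- as_config(config)
  gm <- gametes(maternal, config)
  gp <- gametes(paternal, config)
  if (nrow(gm) == 0 || nrow(gp) == 0) {
    return(data.frame())
  }
  same <- identical(maternal$species, paternal$species)
  grid <- expand.grid(i = seq_len(nrow(gm)), j = seq_len(nrow(gp)))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    m <- gm[grid$i[k], ]
    p <- gp[grid$j[k], ]
    data.frame(
      maternal = maternal$species, paternal = paternal$species,
      maternal_mechanism = m$mechanism, maternal_gamete_ploidy = m$gamete_ploidy,
      maternal_mode = m$assumed_mode, maternal_ploidy = m$assumed_ploidy,
      paternal_mechanism = p$mechanism, paternal_gamete_ploidy = p$gamete_ploidy,
      paternal_mode = p$assumed_mode, paternal_ploidy = p$assumed_ploidy,
      hybrid_ploidy = m$gamete_ploidy + p$gamete_ploidy,
      offspring_mode = offspring_mode(m$apomictic, p$apomictic),
      pattern = classify_pattern(m, p, same),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  unique(out)
}

# Non-empty payload subsets a gamete can transmit, with the number of
# parental types it drops.  all_types gametes transmit everything; a
# subset_allowed gamete must still carry at least one genome copy, so
# the empty payload is not an option.
payload_options <- function(rule, types) {
  types <- sort(types, method = "radix")
  if (length(types) == 0) {
    return(list(list(payload = character(0), n_drop = 0L)))
  }
  if (rule == "all_types") {
    return(list(list(payload = types, n_drop = 0L)))
  }
  out <- list()
  n <- length(types)
  for (k in seq_len(n)) {
    sets <- combn(types, k, simplify = FALSE)
    for (s in sets) out[[length(out) + 1L]] <- list(payload = s,
                                                    n_drop = n - k)
  }
  out
}
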