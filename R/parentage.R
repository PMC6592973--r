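#' Orphan allele types
#'
#' A nuclear base type is an orphan when it is observed in the complex
#' but no sampled taxon has it as its *sole* constitution: the allele
#' must have entered the hybrids from an unsampled parental lineage.
#' Each orphan spawns one hypothesized lineage carrying exactly that
#' type, tentatively treated as an individually distinct species.
#'
#' @param summaries A `taxon_summary` data.frame from [summarize_taxa()].
#' @return Sorted character vector of orphan base types.
#' @export
#' @examples
#' orphan_types(summarize_taxa(diplazium_complex()))
orphan_types <- function(summaries) {
  sampled <- summaries[summaries$sampled, , drop = FALSE]
  all_types <- sort(unique(unlist(sampled$nuclear_types)), method = "radix")
  single <- unlist(sampled$nuclear_types[lengths(sampled$nuclear_types) == 1])
  sort(setdiff(all_types, single), method = "radix")
}

# Which nuclear types "own" a plastid base type: the types of
# single-constitution taxa (other than `exclude`) carrying it.
plastid_owners <- function(pi, summaries, exclude = NULL) {
  sampled <- summaries[summaries$sampled &
                         !(summaries$species %in% exclude), , drop = FALSE]
  single <- lengths(sampled$nuclear_types) == 1
  owners <- character(0)
  for (i in which(single)) {
    if (pi %in% sampled$plastid_types[[i]]) {
      owners <- c(owners, sampled$nuclear_types[[i]])
    }
  }
  sort(unique(owners), method = "radix")
}

# A sampled taxon is treated as a progenitor (no parents inferred)
# when it carries a single nuclear type and its plastid is consistent
# with that type; a single-type taxon whose plastid belongs to a
# different progenitor lineage is a hybrid candidate (allele loss).
is_progenitor <- function(row, summaries) {
  types <- row$nuclear_types[[1]]
  if (length(types) != 1) return(FALSE)
  for (pi in row$plastid_types[[1]]) {
    owners <- plastid_owners(pi, summaries, exclude = row$species)
    if (length(owners) > 0 && !(types %in% owners)) return(FALSE)
  }
  TRUE
}

# ---- parent option table -------------------------------------------------

# Expand one pool taxon into concrete (assumption, gamete, payload)
# options.  Hypothesized lineages are tried under the default diploid
# sexual assumption and the alternative triploid apogamous one; using
# the alternative is recorded (`nondefault`) and penalized in ranking.
parent_options <- function(row, config) {
  hyp <- !row$sampled
  types <- row$nuclear_types[[1]]
  assumptions <- if (hyp) {
    list(c("sexual", 2L), c("apogamous", 3L))
  } else {
    modes <- if (is.na(row$mode)) c("sexual", "apogamous") else row$mode
    ploidies <- if (is.na(row$ploidy)) config$plausible_ploidies else row$ploidy
    unlist(lapply(modes, function(m) lapply(ploidies, function(p) c(m, p))),
           recursive = FALSE)
  }
  out <- list()
  for (a in assumptions) {
    g <- gamete_rows(a[1], as.integer(a[2]), types, config)
    if (is.null(g) || nrow(g) == 0) next
    for (i in seq_len(nrow(g))) {
      for (po in payload_options(g$payload_rule[i], types)) {
        out[[length(out) + 1L]] <- list(
          species = row$species, hypothesized = hyp,
          assumed_mode = g$assumed_mode[i], assumed_ploidy = g$assumed_ploidy[i],
          mechanism = g$mechanism[i], gamete_ploidy = g$gamete_ploidy[i],
          apomictic = g$apomictic[i], payload = po$payload,
          n_drop = po$n_drop,
          composite = length(types) > 1,
          nondefault = hyp && g$assumed_mode[i] == "apogamous")
      }
    }
  }
  out
}

type_mask <- function(types, universe) {
  if (length(types) == 0) return(0)
  sum(2^(match(types, universe) - 1L))
}

# ---- candidate enumeration ----------------------------------------------

#' Enumerate parentage hypotheses for one putative hybrid
#'
#' Enumerates ordered (maternal, paternal) parent pairs from a pool of
#' sampled and hypothesized taxa, keeping a hypothesis iff
#' (i) the maternal parent carries the focal taxon's plastid base type
#' (plastids are maternally inherited in ferns); (ii) the parental
#' gamete payloads together deliver exactly the focal nuclear type set
#' — unreduced gametes deliver all parental types, `subset_allowed`
#' gametes may drop types at one allele-loss penalty per dropped type;
#' and (iii) the gamete-ploidy sum and offspring mode match the focal
#' taxon (undetermined focal values are unconstrained).  When the focal
#' plastid type occurs in no pool member the maternal constraint is
#' uninformative: it is waived and the result flagged
#' (`plastid_unmatched`).
#'
#' Hypotheses are ranked by: number of hypothesized (unsampled)
#' parents; number of allele losses; number of hypothesized parents
#' used under the non-default triploid-apogamous assumption; pattern
#' preference (P3 first — the hybridization cycle — then P1, P2, P4,
#' allopolyploid, autopolyploid, other); number of composite
#' (multi-type, i.e. themselves hybrid-derived) parents — a hybrid is
#' invoked as parent only when no progenitor explains the data equally
#' well; sampled maternal parent before hypothesized; then
#' lexicographic tie-breaks.
#'
#' @param focal A list (or one-row `taxon_summary`) with `species`,
#'   `mode`, `ploidy`, `nuclear_types`, and `plastid_type` (single base
#'   letter or `NA`).
#' @param pool A `taxon_summary` data.frame of candidate parents
#'   (sampled taxa plus hypothesized lineages; `sampled = FALSE` rows
#'   are hypothesized).
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return An object of class `parentage_result`: a list with
#'   `species`, `specimen_group`, `hypotheses` (ranked data.frame),
#'   `plastid_unmatched` and `unexplained`.
#' @export
candidate_parents <- function(focal, pool, config = NULL) {
  config <- as_config(config)
  if (NROW(pool) == 0) stop("empty candidate pool", call. = FALSE)
  focal_types <- focal$nuclear_types
  if (is.list(focal_types)) focal_types <- focal_types[[1]]
  focal_plastid <- focal$plastid_type
  if (is.null(focal_plastid)) focal_plastid <- NA_character_
  focal_mode <- if (is.null(focal$mode)) NA_character_ else focal$mode
  focal_ploidy <- if (is.null(focal$ploidy)) NA_integer_ else focal$ploidy

  pool <- pool[pool$species != focal$species, , drop = FALSE]
  universe <- sort(unique(c(focal_types, unlist(pool$nuclear_types))),
                   method = "radix")
  focal_mask <- type_mask(focal_types, universe)

  carries_plastid <- vapply(seq_len(nrow(pool)), function(i)
    !is.na(focal_plastid) && focal_plastid %in% pool$plastid_types[[i]],
    logical(1))
  waived <- is.na(focal_plastid) || !any(carries_plastid)

  opts <- list()
  maternal_ok <- logical(0)
  for (i in seq_len(nrow(pool))) {
    oi <- parent_options(pool[i, , drop = FALSE], config)
    opts <- c(opts, oi)
    maternal_ok <- c(maternal_ok,
                     rep(if (waived) TRUE else carries_plastid[i], length(oi)))
  }
  empty <- empty_hypotheses()
  if (length(opts) == 0) {
    return(new_parentage_result(focal, empty, !is.na(focal_plastid) && waived))
  }
  o_species <- vapply(opts, `[[`, "", "species")
  o_mask <- vapply(opts, function(o) type_mask(o$payload, universe), 0)
  o_gp <- vapply(opts, `[[`, 0L, "gamete_ploidy")
  o_apo <- vapply(opts, `[[`, logical(1), "apomictic")

  grid <- expand.grid(m = which(maternal_ok), p = seq_along(opts))
  grid <- grid[o_species[grid$m] != o_species[grid$p], , drop = FALSE]
  keep <- bitwOr(o_mask[grid$m], o_mask[grid$p]) == focal_mask
  if (!is.na(focal_ploidy)) {
    keep <- keep & (o_gp[grid$m] + o_gp[grid$p]) == focal_ploidy
  }
  if (!is.na(focal_mode)) {
    keep <- keep & offspring_mode(o_apo[grid$m], o_apo[grid$p]) == focal_mode
  }
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) {
    return(new_parentage_result(focal, empty, !is.na(focal_plastid) && waived))
  }
  hyps <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    m <- opts[[grid$m[k]]]
    p <- opts[[grid$p[k]]]
    data.frame(
      maternal = m$species, paternal = p$species,
      maternal_mechanism = m$mechanism, maternal_gamete_ploidy = m$gamete_ploidy,
      maternal_payload = paste(m$payload, collapse = ""),
      maternal_assumed_mode = m$assumed_mode,
      maternal_assumed_ploidy = m$assumed_ploidy,
      paternal_mechanism = p$mechanism, paternal_gamete_ploidy = p$gamete_ploidy,
      paternal_payload = paste(p$payload, collapse = ""),
      paternal_assumed_mode = p$assumed_mode,
      paternal_assumed_ploidy = p$assumed_ploidy,
      hybrid_ploidy = m$gamete_ploidy + p$gamete_ploidy,
      offspring_mode = offspring_mode(m$apomictic, p$apomictic),
      pattern = classify_pattern(m, p, same_taxon = FALSE),
      n_unknown = sum(m$hypothesized, p$hypothesized),
      n_loss = m$n_drop + p$n_drop,
      n_nondefault = sum(m$nondefault, p$nondefault),
      n_composite_parents = sum(m$composite, p$composite),
      maternal_hypothesized = m$hypothesized,
      paternal_hypothesized = p$hypothesized,
      stringsAsFactors = FALSE)
  }))
  hyps <- unique(hyps)
  ord <- order(hyps$n_unknown, hyps$n_loss, hyps$n_nondefault,
               pattern_rank(hyps$pattern), hyps$n_composite_parents,
               hyps$maternal_hypothesized,
               hyps$maternal, hyps$paternal, hyps$maternal_mechanism,
               hyps$paternal_mechanism, hyps$maternal_assumed_ploidy,
               hyps$paternal_assumed_ploidy, hyps$maternal_payload,
               hyps$paternal_payload, method = "radix")
  hyps <- hyps[ord, , drop = FALSE]
  rownames(hyps) <- NULL
  new_parentage_result(focal, hyps, !is.na(focal_plastid) && waived)
}

empty_hypotheses <- function() {
  data.frame(maternal = character(0), paternal = character(0),
             maternal_mechanism = character(0),
             maternal_gamete_ploidy = integer(0),
             maternal_payload = character(0),
             maternal_assumed_mode = character(0),
             maternal_assumed_ploidy = integer(0),
             paternal_mechanism = character(0),
             paternal_gamete_ploidy = integer(0),
             paternal_payload = character(0),
             paternal_assumed_mode = character(0),
             paternal_assumed_ploidy = integer(0),
             hybrid_ploidy = integer(0), offspring_mode = character(0),
             pattern = character(0), n_unknown = integer(0),
             n_loss = integer(0), n_nondefault = integer(0),
             n_composite_parents = integer(0),
             maternal_hypothesized = logical(0),
             paternal_hypothesized = logical(0),
             stringsAsFactors = FALSE)
}

new_parentage_result <- function(focal, hyps, plastid_unmatched) {
  structure(list(
    species = focal$species,
    specimen_group = if (is.null(focal$specimen_group)) NA_character_ else focal$specimen_group,
    focal = list(mode = focal$mode, ploidy = focal$ploidy,
                 plastid_type = focal$plastid_type,
                 nuclear_types = if (is.list(focal$nuclear_types))
                   focal$nuclear_types[[1]] else focal$nuclear_types),
    hypotheses = hyps,
    plastid_unmatched = plastid_unmatched,
    unexplained = nrow(hyps) == 0
  ), class = "parentage_result")
}

#' @export
print.parentage_result <- function(x, n = 3, ...) {
  grp <- if (!is.na(x$specimen_group)) paste0(" [", x$specimen_group, "]") else ""
  cat(sprintf("Parentage of %s%s ({%s}, plastid %s)\n", x$species, grp,
              paste(x$focal$nuclear_types, collapse = ","),
              ifelse(is.na(x$focal$plastid_type), "?", x$focal$plastid_type)))
  if (x$unexplained) {
    cat("  unexplained: no hypothesis satisfies the constraints\n")
  } else {
    top <- head(x$hypotheses, n)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %d. %s (maternal) x %s  [%s, %dx, losses=%d, unknowns=%d]\n",
                  i, top$maternal[i], top$paternal[i], top$pattern[i],
                  top$hybrid_ploidy[i], top$n_loss[i], top$n_unknown[i]))
    }
  }
  invisible(x)
}

# ---- whole-dataset inference --------------------------------------------

#' Infer parentage for every hybrid taxon in a dataset
#'
#' Summarizes the specimen table, identifies progenitor taxa
#' (single-type, plastid-consistent; they receive no parents),
#' postulates one hypothesized lineage per orphan allele type, and runs
#' [candidate_parents()] for every other complex member.  Taxa whose
#' specimens carry more than one plastid base type (evidence of
#' recurrent, reciprocal origins) are inferred per plastid group rather
#' than per taxon.  Hypothesized lineages default to diploid sexual and
#' are promoted to triploid apogamous when the top-ranked hypothesis
#' that uses them requires it.
#'
#' @param specimens A specimen data.frame from [load_specimens()], or a
#'   `taxon_summary` data.frame (then per-group splitting by plastid
#'   type is unavailable).
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return An object of class `parentage_inference`: list with
#'   `summaries`, `orphans`, `registry` (one row per hypothesized
#'   lineage: `lineage`, `type`, `mode`, `ploidy`), `results` (list of
#'   `parentage_result`), `config`.
#' @export
#' @examples
#' inf <- infer_parentage(diplazium_complex())
#' top_hypotheses(inf)
infer_parentage <- function(specimens, config = NULL) {
  config <- as_config(config)
  if (inherits(specimens, "taxon_summary")) {
    summaries <- specimens
    specimens <- NULL
  } else {
    summaries <- summarize_taxa(specimens, config)
  }
  orphans <- orphan_types(summaries)
  lineages <- vapply(orphans, hypothesized_name,
                     species = summaries$species, "")
  hyp_rows <- lapply(seq_along(orphans), function(i)
    taxon(lineages[i], NA, NA, nuclear_types = orphans[i], sampled = FALSE))
  pool <- rbind(summaries, do.call(rbind, c(hyp_rows, list(deparse.level = 0))))

  progenitor <- vapply(seq_len(nrow(summaries)), function(i)
    is_progenitor(summaries[i, , drop = FALSE], summaries), logical(1))
  hybrids <- summaries$species[!progenitor]

  results <- list()
  for (s in sort(hybrids, method = "radix")) {
    row <- summaries[summaries$species == s, , drop = FALSE]
    groups <- list()
    if (!is.null(specimens)) {
      sub <- specimens[specimens$species == s, , drop = FALSE]
      pis <- base_types(sub$plastid, config)
      if (length(pis) > 1) {
        # per-plastid-group inference: recurrent reciprocal origins
        for (pi in pis) {
          in_grp <- !is.na(sub$plastid) &
            vapply(sub$plastid, function(l) base_types(l, config) == pi,
                   logical(1))
          grp <- sub[in_grp, , drop = FALSE]
          modes <- unique(grp$mode[!is.na(grp$mode)])
          ploidies <- unique(grp$ploidy[!is.na(grp$ploidy)])
          groups[[length(groups) + 1L]] <- list(
            species = s, specimen_group = pi,
            mode = if (length(modes) == 1) modes else NA_character_,
            ploidy = if (length(ploidies) == 1) ploidies else NA_integer_,
            plastid_type = pi,
            nuclear_types = base_types(unlist(grp$nuclear), config))
        }
      }
    }
    if (length(groups) == 0) {
      pis <- row$plastid_types[[1]]
      groups <- list(list(
        species = s, specimen_group = NA_character_,
        mode = row$mode, ploidy = row$ploidy,
        plastid_type = if (length(pis) == 1) pis else NA_character_,
        nuclear_types = row$nuclear_types[[1]]))
    }
    for (g in groups) {
      results[[length(results) + 1L]] <- candidate_parents(g, pool, config)
    }
  }

  registry <- data.frame(lineage = unname(lineages), type = unname(orphans),
                         mode = rep("sexual", length(orphans)),
                         ploidy = rep(2L, length(orphans)),
                         stringsAsFactors = FALSE)
  # promote a lineage when the top hypothesis that uses it assumes the
  # triploid apogamous alternative
  for (res in results) {
    if (res$unexplained) next
    top <- res$hypotheses[1, ]
    for (side in c("maternal", "paternal")) {
      if (!top[[paste0(side, "_hypothesized")]]) next
      i <- match(top[[side]], registry$lineage)
      if (is.na(i)) next
      registry$mode[i] <- top[[paste0(side, "_assumed_mode")]]
      registry$ploidy[i] <- top[[paste0(side, "_assumed_ploidy")]]
    }
  }

  structure(list(summaries = summaries, orphans = orphans,
                 registry = registry, results = results,
                 progenitors = summaries$species[progenitor],
                 config = config),
            class = "parentage_inference")
}

#' Top-ranked hypotheses of an inference
#'
#' @param inference A `parentage_inference` from [infer_parentage()].
#' @return A data.frame with one row per inferred origin: `species`,
#'   `specimen_group`, `maternal`, `paternal`, `pattern`,
#'   `hybrid_ploidy`, `n_unknown`, `n_loss`, `plastid_unmatched`.
#'   Unexplained taxa appear with `NA` parents.
#' @export
top_hypotheses <- function(inference) {
  stopifnot(inherits(inference, "parentage_inference"))
  rows <- lapply(inference$results, function(res) {
    if (res$unexplained) {
      data.frame(species = res$species, specimen_group = res$specimen_group,
                 maternal = NA_character_, paternal = NA_character_,
                 pattern = NA_character_, hybrid_ploidy = NA_integer_,
                 n_unknown = NA_integer_, n_loss = NA_integer_,
                 plastid_unmatched = res$plastid_unmatched,
                 stringsAsFactors = FALSE)
    } else {
      top <- res$hypotheses[1, ]
      data.frame(species = res$species, specimen_group = res$specimen_group,
                 maternal = top$maternal, paternal = top$paternal,
                 pattern = top$pattern, hybrid_ploidy = top$hybrid_ploidy,
                 n_unknown = top$n_unknown, n_loss = top$n_loss,
                 plastid_unmatched = res$plastid_unmatched,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.parentage_inference <- function(x, ...) {
  cat("Parentage inference:", nrow(x$summaries), "sampled taxa (",
      length(x$progenitors), "progenitors ),", nrow(x$registry),
      "hypothesized lineages\n")
  print(top_hypotheses(x))
  invisible(x)
}

#' Export a parentage inference as a JSON report
#'
#' Per-taxon ranked hypotheses with constraint evidence and penalties,
#' plus the hypothesized-lineage registry.
#'
#' @param inference A `parentage_inference`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
parentage_report_json <- function(inference, path = NULL) {
  stopifnot(inherits(inference, "parentage_inference"))
  payload <- list(
    orphan_types = inference$orphans,
    hypothesized_lineages = inference$registry,
    progenitors = inference$progenitors,
    results = lapply(inference$results, function(res) {
      list(species = res$species, specimen_group = res$specimen_group,
           focal = res$focal, plastid_unmatched = res$plastid_unmatched,
           unexplained = res$unexplained, hypotheses = res$hypotheses)
    })
  )
  txt <- jsonlite::toJSON(payload, dataframe = "rows", pretty = TRUE,
                          na = "null", auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}
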