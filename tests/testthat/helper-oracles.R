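# Independent brute-force oracles, written from first principles and on
# different code paths than the package implementation.

# --- exhaustive parentage enumeration ------------------------------------

oracle_gamete_table <- function(mode, ploidy, cfg) {
  out <- list()
  if (mode == "sexual") {
    if (ploidy %% 2 == 0) {
      out[[length(out) + 1]] <- list(mech = "reduced_meiotic",
                                     gp = ploidy / 2, rule = "subset",
                                     apo = FALSE)
    }
    if (cfg$allow_unreduced_sexual) {
      out[[length(out) + 1]] <- list(mech = "unreduced_sexual", gp = ploidy,
                                     rule = "all", apo = FALSE)
    }
  } else if (mode == "apogamous") {
    out[[length(out) + 1]] <- list(mech = "unreduced_diplospore", gp = ploidy,
                                   rule = "all", apo = TRUE)
    if (ploidy == 3 && cfg$allow_irregular_meiosis) {
      out[[length(out) + 1]] <- list(mech = "irregular_meiosis_reduced",
                                     gp = 2, rule = "subset", apo = TRUE)
    }
  }
  out
}

oracle_subsets <- function(types) {
  # all non-empty subsets, via binary counting
  n <- length(types)
  if (n == 0) return(list(character(0)))
  out <- list()
  for (code in seq_len(2^n - 1)) {
    out[[length(out) + 1]] <- types[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
  }
  out
}

oracle_assumptions <- function(row, cfg) {
  if (!row$sampled) {
    return(list(list(mode = "sexual", ploidy = 2, hyp = TRUE),
                list(mode = "apogamous", ploidy = 3, hyp = TRUE)))
  }
  modes <- if (is.na(row$mode)) c("sexual", "apogamous") else row$mode
  ploidies <- if (is.na(row$ploidy)) cfg$plausible_ploidies else row$ploidy
  out <- list()
  for (m in modes) for (p in ploidies) {
    out[[length(out) + 1]] <- list(mode = m, ploidy = p, hyp = FALSE)
  }
  out
}

oracle_pattern <- function(a1, g1, a2, g2, same) {
  if (same) return("autopolyploid")
  d <- sort(c(sprintf("%s|%d|%s|%d", a1$mode, a1$ploidy, g1$mech, g1$gp),
              sprintf("%s|%d|%s|%d", a2$mode, a2$ploidy, g2$mech, g2$gp)))
  tag <- paste(d, collapse = "&")
  known <- c(
    "apogamous|3|unreduced_diplospore|3&sexual|2|reduced_meiotic|1" = "P1",
    "apogamous|2|unreduced_diplospore|2&sexual|2|reduced_meiotic|1" = "P2",
    "apogamous|3|irregular_meiosis_reduced|2&sexual|2|reduced_meiotic|1" = "P3",
    "apogamous|3|irregular_meiosis_reduced|2&sexual|4|reduced_meiotic|2" = "P4")
  if (!is.na(known[tag])) return(unname(known[tag]))
  if (!g1$apo && !g2$apo &&
      ("unreduced_sexual" %in% c(g1$mech, g2$mech))) return("allopolyploid")
  "other"
}

# Every hypothesis as a canonical key string, by sheer enumeration.
oracle_parentage_keys <- function(focal, pool, cfg) {
  pool <- pool[pool$species != focal$species, , drop = FALSE]
  ftypes <- focal$nuclear_types
  if (is.list(ftypes)) ftypes <- ftypes[[1]]
  fpl <- focal$plastid_type
  carries <- sapply(seq_len(nrow(pool)), function(i)
    !is.na(fpl) && fpl %in% pool$plastid_types[[i]])
  waived <- is.na(fpl) || !any(carries)
  keys <- character(0)
  for (i in seq_len(nrow(pool))) {
    if (!waived && !carries[i]) next  # maternal must carry the plastid
    for (j in seq_len(nrow(pool))) {
      if (pool$species[i] == pool$species[j]) next
      for (am in oracle_assumptions(pool[i, ], cfg)) {
        for (ap in oracle_assumptions(pool[j, ], cfg)) {
          for (gm in oracle_gamete_table(am$mode, am$ploidy, cfg)) {
            for (gp in oracle_gamete_table(ap$mode, ap$ploidy, cfg)) {
              tm <- pool$nuclear_types[[i]]
              tp <- pool$nuclear_types[[j]]
              pm_opts <- if (gm$rule == "all") list(tm) else oracle_subsets(tm)
              pp_opts <- if (gp$rule == "all") list(tp) else oracle_subsets(tp)
              for (pm in pm_opts) {
                for (pp in pp_opts) {
                  if (length(tm) > 0 && length(pm) == 0) next
                  if (length(tp) > 0 && length(pp) == 0) next
                  if (!setequal(union(pm, pp), ftypes)) next
                  hp <- gm$gp + gp$gp
                  if (!is.na(focal$ploidy) && hp != focal$ploidy) next
                  omode <- if (gm$apo || gp$apo) "apogamous" else "sexual"
                  if (!is.na(focal$mode) && omode != focal$mode) next
                  keys <- c(keys, paste(
                    pool$species[i], pool$species[j], gm$mech, gp$mech,
                    gm$gp, gp$gp, am$mode, am$ploidy, ap$mode, ap$ploidy,
                    paste(sort(pm), collapse = ""),
                    paste(sort(pp), collapse = ""),
                    (length(tm) - length(pm)) + (length(tp) - length(pp)),
                    am$hyp + ap$hyp,
                    oracle_pattern(am, gm, ap, gp, FALSE),
                    sep = "|"))
                }
              }
            }
          }
        }
      }
    }
  }
  sort(unique(keys))
}

impl_parentage_keys <- function(res) {
  h <- res$hypotheses
  if (nrow(h) == 0) return(character(0))
  sort(unique(paste(
    h$maternal, h$paternal, h$maternal_mechanism, h$paternal_mechanism,
    h$maternal_gamete_ploidy, h$paternal_gamete_ploidy,
    h$maternal_assumed_mode, h$maternal_assumed_ploidy,
    h$paternal_assumed_mode, h$paternal_assumed_ploidy,
    h$maternal_payload, h$paternal_payload, h$n_loss, h$n_unknown,
    h$pattern, sep = "|")))
}

# --- exhaustive supported-clade scan for allele typing -------------------

oracle_assign <- function(gt, query, references, cfg) {
  phy <- gt$phylo
  ntip <- length(phy$tip.label)
  nodes <- ntip + seq_len(phy$Nnode)
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  clades <- list()
  for (k in seq_along(nodes)) {
    tips <- tryCatch(ape::extract.clade(phy, nodes[k])$tip.label,
                     error = function(e) phy$tip.label)
    l <- lab[k]
    pp <- bp <- NA_real_
    if (!is.na(l) && nzchar(l)) {
      parts <- strsplit(l, "/", fixed = TRUE)[[1]]
      pp <- suppressWarnings(as.numeric(parts[1]))
      if (length(parts) > 1) bp <- suppressWarnings(as.numeric(parts[2]))
    }
    ok_pp <- !is.na(pp) && pp > cfg$pp_threshold
    ok_bp <- !is.na(bp) && bp > cfg$bp_threshold
    supported <- if (cfg$strict_support) {
      (is.na(pp) || ok_pp) && (is.na(bp) || ok_bp) && !(is.na(pp) && is.na(bp))
    } else ok_pp || ok_bp
    clades[[k]] <- list(tips = tips, supported = supported)
  }
  sizes <- sapply(clades, function(c) length(c$tips))
  spec <- gt$leaves$species[match(phy$tip.label, gt$leaves$label)]
  for (k in order(sizes)) {
    cl <- clades[[k]]
    if (!cl$supported || !(query %in% cl$tips)) next
    ref_tips <- cl$tips[spec[match(cl$tips, phy$tip.label)] %in% names(references)]
    if (length(ref_tips) == 0) next
    tys <- unique(references[spec[match(ref_tips, phy$tip.label)]])
    return(if (length(tys) == 1) unname(tys) else "unassigned")
  }
  "unassigned"
}
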