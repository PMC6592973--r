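#' Read a gene tree with node supports
#'
#' Parses a Newick string or file into a gene tree.  Internal node
#' labels encode clade supports as `"pp/bp"` (posterior probability and
#' bootstrap percentage) or a single `"pp"` value; missing labels mean
#' absent support (not zero).  Leaf labels may carry specimen metadata
#' in the dialect `species__voucher__allele` or `species__allele`;
#' plain leaf labels are kept as allele ids with unknown species.
#'
#' @param text A Newick string, or a file path when `text` does not
#'   contain a `(` or `;` character.
#' @return An object of class `gene_tree`: a list with `phylo` (the
#'   [ape::read.tree()] tree), `leaves` (data.frame `label`, `species`,
#'   `voucher`, `allele`) and `support` (data.frame `node`, `pp`, `bp`,
#'   one row per internal node).
#' @export
#' @examples
#' gt <- read_genetree("((a:1,b:1)0.99/95:1,c:1);")
#' gt$support
read_genetree <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("[(;]", text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "")
  }
  validate_newick(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("not a valid Newick tree", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1], call. = FALSE)
  }
  parts <- strsplit(phy$tip.label, "__", fixed = TRUE)
  leaves <- data.frame(
    label = phy$tip.label,
    species = vapply(parts, function(p) if (length(p) >= 2) p[1] else NA_character_, ""),
    voucher = vapply(parts, function(p) if (length(p) >= 3) p[2] else NA_character_, ""),
    allele = vapply(parts, function(p) p[length(p)], ""),
    stringsAsFactors = FALSE
  )
  structure(list(phylo = phy, leaves = leaves, support = node_supports(phy)),
            class = "gene_tree")
}

# Structural check: one balanced top-level group (ape::read.tree
# silently misreads some malformed strings, e.g. "((a,b)),c;").
validate_newick <- function(text) {
  s <- trimws(text)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  closed_at <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      if (depth == 0L && !is.na(closed_at)) {
        stop("malformed Newick: new group opened after the tree closed at position ",
             closed_at, call. = FALSE)
      }
      depth <- depth + 1L
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i,
                           call. = FALSE)
      if (depth == 0L) closed_at <- i
    }
  }
  if (depth != 0L) stop("malformed Newick: unbalanced parentheses", call. = FALSE)
  if (!is.na(closed_at)) {
    tail <- substring(s, closed_at + 1L)
    if (grepl("[(),]", sub(";.*$", "", tail))) {
      stop("malformed Newick: trailing structure after the root group",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Parse "pp/bp" / "pp" node labels into numeric supports.
node_supports <- function(phy) {
  n_node <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  pp <- bp <- rep(NA_real_, n_node)
  has <- nzchar(lab) & !is.na(lab)
  split2 <- strsplit(lab[has], "/", fixed = TRUE)
  pp[has] <- suppressWarnings(vapply(split2, function(p) as.numeric(p[1]), 0))
  bp[has] <- suppressWarnings(vapply(split2, function(p)
    if (length(p) >= 2) as.numeric(p[2]) else NA_real_, 0))
  data.frame(node = ape::Ntip(phy) + seq_len(n_node), pp = pp, bp = bp)
}

#' Write a gene tree back to Newick
#'
#' Inverse of [read_genetree()]; node supports are re-serialized as
#' `"pp/bp"` internal node labels.
#'
#' @param tree A `gene_tree`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_genetree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  txt <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Is a node's clade supported?
#'
#' A clade counts as supported when its posterior probability exceeds
#' `pp_threshold` (default 0.95) or its bootstrap percentage exceeds
#' `bp_threshold` (default 70).  When only one support type is present
#' that criterion alone decides; with `strict_support = TRUE` a node
#' carrying both values must pass both.
#'
#' @param pp Posterior probability in \[0, 1\] or `NA`.
#' @param bp Bootstrap percentage in \[0, 100\] or `NA`.
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return Logical.
#' @export
#' @examples
#' is_supported(pp = 0.99, bp = 80)
#' is_supported(pp = NA, bp = 71)
is_supported <- function(pp = NA, bp = NA, config = NULL) {
  config <- as_config(config)
  pass_pp <- !is.na(pp) & pp > config$pp_threshold
  pass_bp <- !is.na(bp) & bp > config$bp_threshold
  if (config$strict_support) {
    out <- (is.na(pp) | pass_pp) & (is.na(bp) | pass_bp) & !(is.na(pp) & is.na(bp))
  } else {
    out <- pass_pp | pass_bp
  }
  out
}

# Descendant tip sets of every internal node, as a list indexed by
# internal node order (phangorn does the traversal).
clade_tip_sets <- function(phy) {
  nodes <- ape::Ntip(phy) + seq_len(phy$Nnode)
  phangorn::Descendants(phy, nodes, type = "tips")
}

#' Assign a base type to a gene-tree leaf by clade support
#'
#' Implements clade-support typing: an allele is considered to
#' originate from a parental lineage when its sequence falls in a
#' supported clade together with reference alleles of that lineage.
#' The query's type is read from the *smallest* supported clade that
#' contains the query and at least one reference leaf (the most local
#' statement of shared ancestry); if the reference leaves in that clade
#' carry mixed types, or no supported clade contains any reference, the
#' leaf is left `"unassigned"`.
#'
#' @param tree A `gene_tree` from [read_genetree()].
#' @param query Leaf label to type.
#' @param references Named character vector mapping reference species
#'   to their base type (the taxa whose own constitution is a single
#'   type).
#' @param config A configuration from [default_config()] (or `NULL`).
#' @param outgroup Optional character vector of leaf labels; when given
#'   and the tree is unrooted, the tree is rooted on them before clades
#'   are read.
#' @return A list with `leaf`, `type` (base letter or `"unassigned"`),
#'   and `evidence` (list with the supporting clade's leaf labels and
#'   its `pp`/`bp`), or `NULL` evidence when unassigned.
#' @export
assign_type <- function(tree, query, references, config = NULL,
                        outgroup = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  config <- as_config(config)
  phy <- tree$phylo
  if (!query %in% phy$tip.label) {
    stop("query leaf '", query, "' is not in the tree", call. = FALSE)
  }
  if (!is.null(outgroup) && !ape::is.rooted(phy)) {
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  supp <- node_supports(phy)
  ok <- is_supported(supp$pp, supp$bp, config)
  tips <- clade_tip_sets(phy)
  ref_species <- names(references)
  leaf_species <- tree$leaves$species[match(phy$tip.label, tree$leaves$label)]
  is_ref_leaf <- !is.na(leaf_species) & leaf_species %in% ref_species
  q_idx <- match(query, phy$tip.label)

  sizes <- lengths(tips)
  order_idx <- order(sizes, supp$node)  # smallest clade first, stable
  for (k in order_idx) {
    if (!ok[k]) next
    tip_idx <- tips[[k]]
    if (!(q_idx %in% tip_idx)) next
    refs_in <- tip_idx[is_ref_leaf[tip_idx]]
    if (length(refs_in) == 0) next
    types <- unique(unname(references[leaf_species[refs_in]]))
    if (length(types) == 1) {
      return(list(leaf = query, type = types,
                  evidence = list(clade = phy$tip.label[tip_idx],
                                  pp = supp$pp[k], bp = supp$bp[k])))
    }
    return(list(leaf = query, type = "unassigned",
                evidence = list(clade = phy$tip.label[tip_idx],
                                pp = supp$pp[k], bp = supp$bp[k],
                                note = "mixed reference types in smallest supported clade")))
  }
  list(leaf = query, type = "unassigned", evidence = NULL)
}

#' Type every leaf of a gene tree
#'
#' @inheritParams assign_type
#' @return A data.frame with one row per leaf: `leaf`, `species`,
#'   `allele`, `type`.
#' @export
assign_types <- function(tree, references, config = NULL, outgroup = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  res <- lapply(tree$phylo$tip.label, function(q)
    assign_type(tree, q, references, config, outgroup))
  data.frame(
    leaf = vapply(res, `[[`, "", "leaf"),
    species = tree$leaves$species,
    allele = tree$leaves$allele,
    type = vapply(res, `[[`, "", "type"),
    stringsAsFactors = FALSE
  )
}

#' Count distinct base types among complex members
#'
#' @param assignments A data.frame from [assign_types()] (or any frame
#'   with `species` and `type` columns).
#' @param exclude_species Species to drop before counting (outgroups).
#' @return Integer number of distinct assigned base types.
#' @export
count_types <- function(assignments, exclude_species = character(0)) {
  if (NROW(assignments) == 0) return(0L)
  keep <- !(assignments$species %in% exclude_species) &
    assignments$type != "unassigned" & !is.na(assignments$type)
  length(unique(assignments$type[keep]))
}

#' Export type assignments as a JSON report
#'
#' @param assignments A data.frame from [assign_types()].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
typing_report_json <- function(assignments, path = NULL) {
  txt <- jsonlite::toJSON(assignments, dataframe = "rows", pretty = TRUE,
                          na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}
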