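#' Build the reticulogram from a parentage inference
#'
#' Assembles the directed hybridization network: one node per sampled
#' taxon and per hypothesized lineage, and, for every inference result,
#' a maternal and a paternal in-edge from its top-ranked hypothesis
#' (one autopolyploidization edge when the top hypothesis is a
#' same-taxon doubling).  Lower-ranked hypotheses are not drawn; they
#' remain available in the JSON report.  Taxa inferred per plastid
#' group (recurrent reciprocal origins) contribute one edge pair per
#' group.
#'
#' @param inference A `parentage_inference` from [infer_parentage()].
#' @return An [igraph::graph] with vertex attributes `mode`, `ploidy`,
#'   `sampled` and edge attributes `type` (`maternal`, `paternal` or
#'   `autopolyploidization`) and `provenance` (the focal taxon and
#'   specimen group that produced the edge).  Vertices are ordered
#'   lexicographically for reproducible export.
#' @export
#' @examples
#' g <- build_reticulogram(infer_parentage(diplazium_complex()))
#' igraph::gsize(g)
build_reticulogram <- function(inference) {
  stopifnot(inherits(inference, "parentage_inference"))
  s <- inference$summaries
  nodes <- data.frame(
    name = c(s$species, inference$registry$lineage),
    mode = c(s$mode, inference$registry$mode),
    ploidy = c(s$ploidy, inference$registry$ploidy),
    sampled = c(rep(TRUE, nrow(s)), rep(FALSE, nrow(inference$registry))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$name, method = "radix"), , drop = FALSE]

  edges <- list()
  for (res in inference$results) {
    if (res$unexplained) next
    top <- res$hypotheses[1, ]
    prov <- if (is.na(res$specimen_group)) res$species else
      paste0(res$species, " [", res$specimen_group, "]")
    if (identical(top$pattern, "autopolyploid")) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = top$maternal, to = res$species,
        type = "autopolyploidization", provenance = prov,
        stringsAsFactors = FALSE)
    } else {
      edges[[length(edges) + 1L]] <- data.frame(
        from = c(top$maternal, top$paternal), to = res$species,
        type = c("maternal", "paternal"), provenance = prov,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), type = character(0),
               provenance = character(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$to, edges$type, edges$from, edges$provenance,
                       method = "radix"), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      fb <- igraph::feedback_arc_set(g)
      paste(attr(igraph::ends(g, fb), "dimnames"), collapse = " ")
    }, error = function(e) "")
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("reticulogram contains a cycle through: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  g
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

edge_style <- function(type) {
  c(maternal = "solid", paternal = "dashed",
    autopolyploidization = "solid")[type]
}

#' Export a reticulogram as DOT text
#'
#' Maternal edges are solid, paternal edges dashed, and
#' autopolyploidization edges thin solid (penwidth 0.5); hypothesized
#' lineages are drawn as dashed boxes.  Node and edge ordering is
#' lexicographic and the output carries no timestamps, so exports are
#' byte-stable across runs.
#'
#' @param g A reticulogram from [build_reticulogram()].
#' @param path Optional output path.
#' @return DOT text as a character scalar (invisibly when written).
#' @export
export_dot <- function(g, path = NULL) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  v <- v[order(v$name, method = "radix"), , drop = FALSE]
  e <- e[order(e$to, e$type, e$from, method = "radix"), , drop = FALSE]
  lines <- c("digraph reticulogram {", "  rankdir=BT;",
             "  node [shape=box];")
  for (i in seq_len(nrow(v))) {
    attrs <- sprintf('label=%s, style=%s',
                     dot_quote(sprintf("%s\\n%s %s", v$name[i],
                                       ifelse(is.na(v$ploidy[i]), "?x",
                                              paste0(v$ploidy[i], "x")),
                                       ifelse(is.na(v$mode[i]), "mode?",
                                              v$mode[i]))),
                     if (v$sampled[i]) '"solid"' else '"dashed"')
    lines <- c(lines, sprintf("  %s [%s];", dot_quote(v$name[i]), attrs))
  }
  for (i in seq_len(nrow(e))) {
    extra <- if (e$type[i] == "autopolyploidization") ", penwidth=0.5" else ""
    lines <- c(lines, sprintf('  %s -> %s [style=%s%s, type=%s];',
                              dot_quote(e$from[i]), dot_quote(e$to[i]),
                              edge_style(e$type[i]), extra,
                              dot_quote(e$type[i])))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a reticulogram as GraphML text
#'
#' @inheritParams export_dot
#' @return GraphML text as a character scalar (invisibly when written).
#' @export
export_graphml <- function(g, path = NULL) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  v <- v[order(v$name, method = "radix"), , drop = FALSE]
  e <- e[order(e$to, e$type, e$from, method = "radix"), , drop = FALSE]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="mode" for="node" attr.name="mode" attr.type="string"/>',
    '  <key id="ploidy" for="node" attr.name="ploidy" attr.type="int"/>',
    '  <key id="sampled" for="node" attr.name="sampled" attr.type="boolean"/>',
    '  <key id="type" for="edge" attr.name="type" attr.type="string"/>',
    '  <graph id="reticulogram" edgedefault="directed">')
  for (i in seq_len(nrow(v))) {
    lines <- c(lines,
      sprintf('    <node id="%s">', xml_escape(v$name[i])),
      sprintf('      <data key="mode">%s</data>',
              xml_escape(ifelse(is.na(v$mode[i]), "unknown", v$mode[i]))),
      if (!is.na(v$ploidy[i]))
        sprintf('      <data key="ploidy">%d</data>', v$ploidy[i]),
      sprintf('      <data key="sampled">%s</data>',
              tolower(as.character(v$sampled[i]))),
      '    </node>')
  }
  for (i in seq_len(nrow(e))) {
    lines <- c(lines,
      sprintf('    <edge source="%s" target="%s">',
              xml_escape(e$from[i]), xml_escape(e$to[i])),
      sprintf('      <data key="type">%s</data>', xml_escape(e$type[i])),
      '    </edge>')
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Read a GraphML reticulogram back
#'
#' Minimal reader for the dialect written by [export_graphml()]
#' (node/edge `data` keys as above); used for round-trip checks and to
#' re-import exported networks.
#'
#' @param x GraphML text or a file path.
#' @return An [igraph::graph].
#' @export
read_graphml <- function(x) {
  doc <- if (file.exists(x[1]) && !grepl("<", x[1], fixed = TRUE)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_key <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf('./g:data[@key="%s"]', key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  v <- data.frame(
    name = xml2::xml_attr(nodes, "id"),
    mode = vapply(seq_along(nodes), function(i) get_key(nodes[[i]], "mode"), ""),
    ploidy = suppressWarnings(as.integer(vapply(seq_along(nodes), function(i)
      get_key(nodes[[i]], "ploidy"), ""))),
    sampled = vapply(seq_along(nodes), function(i)
      get_key(nodes[[i]], "sampled"), "") == "true",
    stringsAsFactors = FALSE)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  e <- data.frame(
    from = xml2::xml_attr(edges, "source"),
    to = xml2::xml_attr(edges, "target"),
    type = vapply(seq_along(edges), function(i) get_key(edges[[i]], "type"), ""),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}
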