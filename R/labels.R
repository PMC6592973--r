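#' Parse a haplotype or allele label
#'
#' Labels consist of a single base-type letter followed by an optional
#' subtype index, e.g. `"\u03b43"` (plastid haplotype, base type
#' `"\u03b4"`, subtype 3) or `"B2"` (nuclear allele).  Plastid base types
#' are Greek letters and nuclear base types Latin letters (I is never
#' used); the alphabets can be overridden through [default_config()].
#'
#' @param label A single label string.
#' @param namespace One of `"any"`, `"plastid"`, `"nuclear"`; restricts
#'   which alphabet the base letter may come from.
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A list with elements `base` (single letter), `subtype`
#'   (integer or `NA`) and `namespace` (`"plastid"` or `"nuclear"`).
#' @export
#' @examples
#' parse_label("\u03b43")   # plastid haplotype, subtype 3
#' parse_label("C")         # nuclear allele with no subtype index
parse_label <- function(label, namespace = c("any", "plastid", "nuclear"),
                        config = NULL) {
  namespace <- match.arg(namespace)
  config <- as_config(config)
  if (length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("empty or missing label", call. = FALSE)
  }
  chars <- strsplit(label, "", fixed = TRUE)[[1]]
  base <- chars[1]
  in_plastid <- base %in% config$plastid_alphabet
  in_nuclear <- base %in% config$nuclear_alphabet
  ns <- if (in_plastid) "plastid" else if (in_nuclear) "nuclear" else NA
  ok <- switch(namespace,
               any = in_plastid || in_nuclear,
               plastid = in_plastid,
               nuclear = in_nuclear)
  if (!ok) {
    stop(sprintf("unknown %s base-type letter in label '%s': '%s'",
                 namespace, label, base), call. = FALSE)
  }
  rest <- substring(label, 2L)
  if (!grepl("^[0-9]*$", rest)) {
    stop(sprintf("malformed subtype index in label '%s': '%s'", label, rest),
         call. = FALSE)
  }
  subtype <- if (nzchar(rest)) as.integer(rest) else NA_integer_
  list(base = base, subtype = subtype, namespace = ns)
}

#' Tokenize a concatenated allele string into a set of subtype labels
#'
#' Specimen tables record the nuclear allele constitution of an
#' individual as a concatenation of labels, e.g. `"A1A6B1"`.  Greedy
#' left-to-right tokenization splits it into letter+digits tokens.
#' Duplicate tokens collapse to a set: SSCP band scoring cannot measure
#' allele dosage, so `"A1A1B1"` and `"A1B1"` denote the same observable
#' constitution.
#'
#' @param s The allele string.
#' @param namespace Alphabet restriction as in [parse_label()].
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return Sorted character vector of unique subtype labels.
#' @export
#' @examples
#' parse_allele_string("A1A6B1")
#' parse_allele_string("A1A1B1")  # dosage collapses to {A1, B1}
parse_allele_string <- function(s, namespace = "nuclear", config = NULL) {
  config <- as_config(config)
  if (length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("empty allele string", call. = FALSE)
  }
  letters_allowed <- switch(namespace,
    any = c(config$plastid_alphabet, config$nuclear_alphabet),
    plastid = config$plastid_alphabet,
    nuclear = config$nuclear_alphabet)
  pat <- sprintf("[%s][0-9]*", paste(letters_allowed, collapse = ""))
  m <- gregexpr(pat, s)[[1]]
  tokens <- if (m[1] == -1L) character(0) else regmatches(s, gregexpr(pat, s))[[1]]
  consumed <- paste(tokens, collapse = "")
  if (!identical(consumed, s)) {
    # locate the first position where greedy tokenization fails
    pos <- 1L
    for (tok in tokens) {
      if (substring(s, pos, pos + nchar(tok) - 1L) != tok) break
      pos <- pos + nchar(tok)
    }
    stop(sprintf("unparseable characters in allele string '%s' at position %d ('%s')",
                 s, pos, substring(s, pos, pos)), call. = FALSE)
  }
  sort(unique(tokens), method = "radix")
}

#' Base types of a set of subtype labels
#'
#' @param labels Character vector of subtype labels (e.g. `c("B2","D1")`).
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return Sorted character vector of unique base-type letters.
#' @export
#' @examples
#' base_types(c("B2", "D1", "D3"))
base_types <- function(labels, config = NULL) {
  config <- as_config(config)
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(character(0))
  out <- vapply(labels, function(x) parse_label(x, config = config)$base, "")
  sort(unique(unname(out)), method = "radix")
}
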