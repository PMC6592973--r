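#' Load a specimen table
#'
#' Reads a tab-separated specimen table with columns `voucher`,
#' `locality`, `species`, `mode`, `ploidy_2n_or_multiple`, `plastid`,
#' `ak1` (UTF-8; lines starting with `#` are comments).  `mode` accepts
#' `sex.`/`sexual`, `apo.`/`apogamous` or blank (unknown).  The ploidy
#' column accepts a multiple with a trailing `x` (e.g. `3x`), a bare
#' small integer (taken as the multiple), or a sporophytic chromosome
#' count 2n (any value larger than 8), which is converted with
#' [ploidy_from_2n()] using `config$base_number`.  The nuclear allele
#' column is tokenized with [parse_allele_string()]; dosage information
#' is discarded at parse time because SSCP band patterns cannot measure
#' allele copy number.
#'
#' @param path Path to the TSV file.
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A `data.frame` with one row per specimen: `voucher`,
#'   `locality`, `species`, `mode` (`"sexual"`, `"apogamous"` or `NA`),
#'   `ploidy` (integer multiple of the base number, or `NA`), `plastid`
#'   (haplotype subtype label or `NA`) and `nuclear` (list column of
#'   allele subtype label sets).
#' @export
#' @examples
#' spc <- diplazium_complex()
#' nrow(spc)
load_specimens <- function(path, config = NULL) {
  config <- as_config(config)
  raw <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               quote = "", colClasses = "character", encoding = "UTF-8",
               check.names = FALSE, blank.lines.skip = TRUE),
    error = function(e) stop("cannot read specimen table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  needed <- c("voucher", "locality", "species", "mode",
              "ploidy_2n_or_multiple", "plastid", "ak1")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("specimen table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("specimen table '", path, "' contains no rows",
                           call. = FALSE)
  as_specimens(raw, config)
}

# Build the canonical specimen data.frame from raw character columns.
as_specimens <- function(raw, config) {
  trim <- function(x) {
    x <- enc2utf8(as.character(x))
    x <- gsub("\\s+", " ", trimws(x))
    x[!nzchar(x)] <- NA_character_
    x
  }
  voucher <- trim(raw$voucher)
  if (anyNA(voucher)) stop("missing voucher id in row ",
                           which(is.na(voucher))[1], call. = FALSE)
  dup <- voucher[duplicated(voucher)]
  if (length(dup)) stop("duplicate voucher id: ", dup[1], call. = FALSE)

  species <- trim(raw$species)
  if (anyNA(species)) stop("missing species name in row ",
                           which(is.na(species))[1], call. = FALSE)

  mode <- parse_mode(trim(raw$mode))
  ploidy <- mapply(parse_ploidy_cell, trim(raw$ploidy_2n_or_multiple),
                   seq_along(voucher), MoreArgs = list(config = config))

  plastid <- trim(raw$plastid)
  nuclear <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!is.na(plastid[i])) {
      lab <- tryCatch(parse_label(plastid[i], "plastid", config),
                      error = function(e) stop("row ", i, " (", voucher[i], "): ",
                                               conditionMessage(e), call. = FALSE))
      plastid[i] <- paste0(lab$base, ifelse(is.na(lab$subtype), "", lab$subtype))
    }
    ak <- trim(raw$ak1[i])
    nuclear[[i]] <- if (is.na(ak)) character(0) else
      tryCatch(parse_allele_string(ak, "nuclear", config),
               error = function(e) stop("row ", i, " (", voucher[i], "): ",
                                        conditionMessage(e), call. = FALSE))
  }
  out <- data.frame(voucher = voucher, locality = trim(raw$locality),
                    species = species, mode = mode,
                    ploidy = as.integer(ploidy), plastid = plastid,
                    stringsAsFactors = FALSE)
  out$nuclear <- nuclear
  class(out) <- c("specimen_df", "data.frame")
  out
}

parse_mode <- function(x) {
  out <- rep(NA_character_, length(x))
  sexual <- !is.na(x) & x %in% c("sex.", "sex", "sexual")
  apo <- !is.na(x) & x %in% c("apo.", "apo", "apogamous")
  bad <- !is.na(x) & !sexual & !apo & !(x %in% c("unknown", "?"))
  if (any(bad)) stop("unrecognized reproductive mode '", x[bad][1], "'",
                     call. = FALSE)
  out[sexual] <- "sexual"
  out[apo] <- "apogamous"
  out
}

parse_ploidy_cell <- function(x, row, config) {
  if (is.na(x)) return(NA_integer_)
  if (grepl("^[0-9]+\\s*[x×]$", x)) {
    return(as.integer(sub("\\s*[x×]$", "", x)))
  }
  if (grepl("^[0-9]+$", x)) {
    n <- as.integer(x)
    if (n <= 8L) return(n)
    return(ploidy_from_2n(n, config$base_number))
  }
  stop("row ", row, ": unrecognized ploidy cell '", x, "'", call. = FALSE)
}

#' Packaged specimen table for the Diplazium hachijoense complex
#'
#' The voucher table compiled for the *D. hachijoense* complex: 42
#' specimens of 10 named species and 4 unnamed taxa, with reproductive
#' mode and ploidy where determined, plastid *trnL-F* haplotype subtype,
#' and nuclear *AK1* allele constitution as scored by PCR-SSCP.
#'
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A specimen `data.frame` (see [load_specimens()]).
#' @export
#' @examples
#' head(diplazium_complex())
diplazium_complex <- function(config = NULL) {
  path <- system.file("extdata", "diplazium_hachijoense_complex.tsv",
                      package = "apohybrids", mustWork = TRUE)
  load_specimens(path, config)
}

#' Summarize specimens into per-taxon constitutions
#'
#' Collapses a specimen table to one row per species: the union of
#' plastid and nuclear base types across its specimens, and the
#' consensus reproductive mode and ploidy.  Cells left undetermined in
#' individual specimens do not constrain the consensus; conflicting
#' determined cells (e.g. a species with both sexual diploid and
#' apogamous vouchers) are reported in the `mode_conflict` /
#' `ploidy_conflict` columns rather than silently merged, and leave the
#' consensus `NA` (unconstrained in downstream inference).
#'
#' @param specimens A specimen `data.frame` from [load_specimens()].
#' @param config A configuration from [default_config()] (or `NULL`).
#' @return A `data.frame` of class `taxon_summary` with columns
#'   `species`, `mode`, `ploidy`, `mode_conflict`, `ploidy_conflict`,
#'   `plastid_types` (list), `nuclear_types` (list), `n_specimens`,
#'   `sampled`.
#' @export
#' @examples
#' summarize_taxa(diplazium_complex())
summarize_taxa <- function(specimens, config = NULL) {
  config <- as_config(config)
  if (nrow(specimens) == 0) stop("no specimens to summarize", call. = FALSE)
  sp <- sort(unique(specimens$species), method = "radix")
  rows <- lapply(sp, function(s) {
    sub <- specimens[specimens$species == s, , drop = FALSE]
    modes <- unique(sub$mode[!is.na(sub$mode)])
    ploidies <- unique(sub$ploidy[!is.na(sub$ploidy)])
    data.frame(
      species = s,
      mode = if (length(modes) == 1) modes else NA_character_,
      ploidy = if (length(ploidies) == 1) ploidies else NA_integer_,
      mode_conflict = length(modes) > 1,
      ploidy_conflict = length(ploidies) > 1,
      n_specimens = nrow(sub),
      sampled = TRUE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$plastid_types <- lapply(sp, function(s) {
    labs <- specimens$plastid[specimens$species == s]
    base_types(labs, config)
  })
  out$nuclear_types <- lapply(sp, function(s) {
    labs <- unlist(specimens$nuclear[specimens$species == s])
    base_types(labs, config)
  })
  class(out) <- c("taxon_summary", "data.frame")
  out
}

# A one-row taxon entry assembled by hand (used by the engine, the
# simulator and tests); mode NA and ploidy NA mean "not determined".
taxon <- function(species, mode = NA, ploidy = NA,
                  nuclear_types = character(0),
                  plastid_types = character(0), sampled = TRUE) {
  out <- data.frame(species = species, mode = as.character(mode),
                    ploidy = as.integer(ploidy), mode_conflict = FALSE,
                    ploidy_conflict = FALSE, n_specimens = NA_integer_,
                    sampled = sampled, stringsAsFactors = FALSE)
  out$plastid_types <- list(sort(plastid_types, method = "radix"))
  out$nuclear_types <- list(sort(nuclear_types, method = "radix"))
  class(out) <- c("taxon_summary", "data.frame")
  out
}

#' Name for a hypothesized (unsampled) parental lineage
#'
#' Orphan alleles are tentatively treated as individually distinct
#' unsampled species; this helper names the hypothesized lineage for a
#' base type, reusing the genus prefix shared by the sampled species
#' (e.g. `"D. sp. J"`).
#'
#' @param type Base-type letter of the orphan allele.
#' @param species Character vector of sampled species names used to
#'   derive a shared genus prefix.
#' @return A species name for the hypothesized lineage.
#' @export
#' @examples
#' hypothesized_name("J", c("D. amamianum", "D. takii"))
hypothesized_name <- function(type, species = character(0)) {
  prefix <- ""
  first <- unique(vapply(strsplit(species, " ", fixed = TRUE),
                         function(p) p[1], "", USE.NAMES = FALSE))
  if (length(first) == 1 && length(species) > 0 &&
      any(grepl(" ", species, fixed = TRUE))) {
    prefix <- paste0(first, " ")
  }
  paste0(prefix, "sp. ", type)
}
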