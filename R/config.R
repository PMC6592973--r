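#' Pipeline configuration
#'
#' Collects the tunable parameters used across the pipeline: the clade
#' support thresholds for allele typing, the base chromosome number used
#' to convert 2n counts into ploidy levels, and switches for the optional
#' gamete mechanisms of the hybridization engine.
#'
#' @param base_number Base (monoploid) chromosome number x. The default,
#'   41, is the base number of *Diplazium*, for which 2n = 82/123/164
#'   correspond to diploid/triploid/tetraploid.
#' @param pp_threshold Bayesian posterior probability above which a clade
#'   counts as supported (default `> 0.95`).
#' @param bp_threshold Parsimony bootstrap percentage above which a clade
#'   counts as supported (default `> 70`).
#' @param strict_support If `TRUE`, a node carrying both support values
#'   must pass both thresholds; by default either criterion suffices.
#' @param allow_unreduced_sexual Permit unreduced gametes from sexual
#'   taxa, enabling allopolyploid formation (default `TRUE`).
#' @param allow_irregular_meiosis Permit reduced diploid (2x) gametes
#'   from triploid apomicts via irregular meiosis, the mechanism of the
#'   hybridization cycle (default `TRUE`).
#' @param plausible_ploidies Integer vector of ploidy levels assumed for
#'   taxa whose ploidy was not determined (default `2:4`, the range
#'   observed in sexual/apogamous fern complexes of this kind).
#' @param plastid_alphabet,nuclear_alphabet Single-character vectors
#'   defining the label namespaces.  Defaults follow the convention of
#'   Greek letters for plastid haplotypes and Latin letters (I excluded,
#'   to avoid confusion with the numeral 1) for nuclear alleles; both can
#'   be overridden for datasets using other schemes.
#' @return A named list of class `apohybrids_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$base_number
default_config <- function(base_number = 41L,
                           pp_threshold = 0.95,
                           bp_threshold = 70,
                           strict_support = FALSE,
                           allow_unreduced_sexual = TRUE,
                           allow_irregular_meiosis = TRUE,
                           plausible_ploidies = 2:4,
                           plastid_alphabet = greek_letters(),
                           nuclear_alphabet = nuclear_letters()) {
  stopifnot(base_number >= 1, pp_threshold >= 0, pp_threshold <= 1,
            bp_threshold >= 0, bp_threshold <= 100,
            all(plausible_ploidies >= 1))
  structure(list(
    base_number = as.integer(base_number),
    pp_threshold = pp_threshold,
    bp_threshold = bp_threshold,
    strict_support = isTRUE(strict_support),
    allow_unreduced_sexual = isTRUE(allow_unreduced_sexual),
    allow_irregular_meiosis = isTRUE(allow_irregular_meiosis),
    plausible_ploidies = as.integer(plausible_ploidies),
    plastid_alphabet = plastid_alphabet,
    nuclear_alphabet = nuclear_alphabet
  ), class = "apohybrids_config")
}

# Greek haplotype namespace: alpha..epsilon
greek_letters <- function() c("\u03b1", "\u03b2", "\u03b3", "\u03b4", "\u03b5")

# Latin allele namespace: A-H, J, K (I is never used)
nuclear_letters <- function() LETTERS[c(1:8, 10, 11)]

as_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (inherits(config, "apohybrids_config")) return(config)
  do.call(default_config, config)
}
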