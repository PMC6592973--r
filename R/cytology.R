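#' Reproductive mode from spore counts
#'
#' Sexual fern sporangia carry 64 spores (regular meiosis after four
#' mitotic divisions of spore mother cells); apogamous sporangia carry
#' 32 unreduced diplospores.  Any other count (including the rare
#' 16/64-spore third mechanism, whose products cannot be classified
#' without cytology) maps to `"undetermined"`.
#'
#' @param n_spores Non-negative integer spore count per sporangium.
#' @return `"sexual"`, `"apogamous"` or `"undetermined"`.
#' @export
#' @examples
#' mode_from_spores(64)
#' mode_from_spores(32)
#' mode_from_spores(16)
mode_from_spores <- function(n_spores) {
  if (length(n_spores) != 1 || is.na(n_spores) || n_spores < 0 ||
      n_spores != as.integer(n_spores)) {
    stop("spore count must be a single non-negative integer", call. = FALSE)
  }
  if (n_spores == 64) return("sexual")
  if (n_spores == 32) return("apogamous")
  message("spore count ", n_spores,
          " is neither 64 (sexual) nor 32 (apogamous); mode undetermined")
  "undetermined"
}

#' Ploidy level from a sporophytic chromosome count
#'
#' Converts a mitotic 2n count into a ploidy level as a multiple of the
#' base (monoploid) number x; for *Diplazium* (x = 41), 2n = 82, 123 and
#' 164 give 2x, 3x and 4x.
#'
#' @param two_n Positive sporophytic chromosome count.
#' @param x Base chromosome number (default 41).
#' @return Integer ploidy level.
#' @export
#' @examples
#' ploidy_from_2n(123, 41)
ploidy_from_2n <- function(two_n, x = 41L) {
  if (length(two_n) != 1 || is.na(two_n) || two_n <= 0) {
    stop("2n must be a single positive count", call. = FALSE)
  }
  if (length(x) != 1 || is.na(x) || x <= 0) {
    stop("base number x must be a single positive count", call. = FALSE)
  }
  r <- two_n %% x
  if (r != 0) {
    stop(sprintf("2n = %d is not a multiple of x = %d (remainder %d); aneuploid counts are not representable",
                 as.integer(two_n), as.integer(x), as.integer(r)), call. = FALSE)
  }
  as.integer(two_n %/% x)
}
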