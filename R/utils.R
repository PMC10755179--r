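#' Derive a labelled child seed from a master seed
#'
#' All stochastic stages of the simulator draw their random numbers from a
#' substream whose seed is derived deterministically from a single master seed
#' and a text label. Two runs with the same master seed are therefore
#' bit-identical, and changing one stage's label leaves the other stages'
#' streams untouched.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Leading integer of a sample id ("21-NF2" -> 21L); NA for the ancestor.
#' Map sample ids to evolved-line numbers
#'
#' Population samples are named by their line number ("21"); clones append the
#' non-fruiting clone id ("21-NF2"). The line of a sample is its leading
#' integer. The ancestor has no line and maps to `NA`.
#'
#' @param sample_id character vector of sample ids.
#' @return Integer vector of line numbers (NA for the ancestor).
#' @export
line_of_sample <- function(sample_id) {
  out <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", sample_id)))
  out[!grepl("^[0-9]", sample_id)] <- NA_integer_
  out
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(a, b) if (is.null(a)) b else a
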