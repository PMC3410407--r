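#' @importFrom methods new validObject is slot
#' @importFrom stats rexp runif setNames
#' @importFrom utils head tail read.delim write.table
NULL

## The 20 standard amino acids, in the conventional alphabetical one-letter order.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Letters accepted in protein input: the 20 standard residues plus X (unknown).
AA_ALLOWED <- c(AA_STANDARD, "X")

## DNA letters accepted in genome input.
DNA_ALLOWED <- c("A", "C", "G", "T", "N")

## Recognised family labels for inventory tables.
FAMILY_LEVELS <- c("HAK", "HKT", "TPK", "SHAKER", "OTHER_VG")

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their own seed from the master seed through a
#' named substream, so that e.g. decoy generation can be re-run independently
#' of family simulation. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream substream name (character) or index (integer).
#' @return an integer seed.
#' @keywords internal
subSeed <- function(seed, stream) {
  M <- 2147483629
  if (is.character(stream)) {
    h <- 0
    for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% M
    stream <- h
  }
  h <- (as.numeric(seed) %% M)
  h <- (h * 48271 + as.numeric(stream)) %% M
  h <- (h * 69621 + 7919) %% M
  as.integer(h)
}

## Split a sequence string into a character vector of single letters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Assert that `x` is a single non-NA string.
assertString <- function(x, what = "value") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single string", what), call. = FALSE)
  }
  invisible(x)
}

## BLOSUM62 with the gap opening/extension the curation score definition uses.
alignmentScoring <- function() {
  list(matrix = blosum62Matrix(), gapOpening = 10, gapExtension = 0.5)
}

blosum62env <- new.env(parent = emptyenv())

blosum62Matrix <- function() {
  if (is.null(blosum62env$BLOSUM62)) {
    utils::data("BLOSUM62", package = "Biostrings", envir = blosum62env)
  }
  blosum62env$BLOSUM62
}
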