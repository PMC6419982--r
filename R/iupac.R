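# IUPAC nucleotide ambiguity codes and positional matching of degenerate
# primers against concrete reads. Degenerate codes are expanded on the
# primer side only: a read base matches a primer code iff it belongs to the
# code's base set (N matches any base).

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

IUPAC_CODES_STRING <- paste(names(IUPAC_TABLE), collapse = "")

#' Match a degenerate primer at a fixed offset in reads
#'
#' Vectorised positional matcher: for each read, tests whether the bases at
#' `at, at+1, ...` match the IUPAC primer with zero mismatches. Reads too
#' short to contain the primer at that offset yield `FALSE`.
#'
#' @param primer single IUPAC string (degenerate codes allowed).
#' @param reads character vector of concrete ACGT(N) reads.
#' @param at 1-based offset of the primer's first base within each read.
#' @return logical vector, one element per read.
#' @examples
#' iupacMatchAt("ARG", c("AAGT", "AGGT", "ACGT"), 1)  # TRUE TRUE FALSE
#' @export
iupacMatchAt <- function(primer, reads, at = 1L) {
  stopifnot(length(primer) == 1L, at >= 1L)
  codes <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_TABLE))
  if (length(bad))
    stop("invalid IUPAC code(s) in primer: ", paste(bad, collapse = ", "))
  ok <- nchar(reads) >= at + length(codes) - 1L
  for (j in seq_along(codes)) {
    if (!any(ok)) break
    base <- substr(reads, at + j - 1L, at + j - 1L)
    ok <- ok & base %in% IUPAC_TABLE[[codes[j]]]
  }
  ok
}

#' Expand a degenerate primer to one concrete sequence
#'
#' Replaces each ambiguity code by one of its bases. With `random = FALSE`
#' the alphabetically first base of each code is used; with `random = TRUE`
#' a base is drawn uniformly (uses the current RNG stream).
#'
#' @param primer single IUPAC string.
#' @param random draw expansion bases at random?
#' @return a concrete ACGT string of the same length.
#' @examples
#' expandPrimer("GTGCCAGCMGCCGCGGTAA")
#' @export
expandPrimer <- function(primer, random = FALSE) {
  codes <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_TABLE))
  if (length(bad))
    stop("invalid IUPAC code(s) in primer: ", paste(bad, collapse = ", "))
  paste(vapply(codes, function(cd) {
    opts <- IUPAC_TABLE[[cd]]
    if (random && length(opts) > 1L) sample(opts, 1L) else opts[1L]
  }, character(1)), collapse = "")
}

#' Standard primer pairs
#'
#' The two primer pairs of the default layouts: 515F/806R amplifying the V4
#' region and BSF784F/1064R amplifying V5-V6, given 5'-3' in amplicon
#' orientation.
#'
#' @return named list with elements `V4` and `V5V6`, each a named character
#'   vector with elements `fwd` and `rev`.
#' @export
standardPrimers <- function() {
  list(V4   = c(fwd = "GTGCCAGCMGCCGCGGTAA", rev = "GGACTACHVGGGTWTCTAAT"),
       V5V6 = c(fwd = "RGGATTAGATACCC",      rev = "CGACRRCCATGCANCACCT"))
}
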