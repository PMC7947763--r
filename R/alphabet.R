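#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order. This fixed
#' ordering is also the deterministic tie-break order for maximum a
#' posteriori ancestral states.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# gap plus ambiguity codes treated as missing data downstream
MISSING_SYMBOLS <- c("-", "X", "B", "Z", "J", "U", "O", "*", "?")

#' Standard genetic code
#'
#' Codon to amino-acid mapping for the standard nuclear code, with "*" for
#' stop codons. Used by the counting dN/dS estimator and by the expected
#' property-change distributions.
#'
#' @return Named character vector of length 64; names are codons (DNA,
#'   upper case), values are one-letter amino acids or `"*"`.
#' @examples
#' code <- genetic_code()
#' code[["ATG"]]  # "M"
#' @export
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  # standard code in TCAG nesting order, third position fastest
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

is_missing_residue <- function(x) x %in% MISSING_SYMBOLS | !(x %in% AA_ALPHABET)
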