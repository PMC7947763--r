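#' Region, phosphosite and clade configuration
#'
#' Holds the study design attached to a reference sequence: named regions
#' (e.g. the PLD itself, evolutionary hotspots, a fibril-core window),
#' phosphosite positions, sticker (tyrosine) positions — all in 1-based
#' ungapped reference coordinates — and clade definitions as taxon lists.
#'
#' @param reference Reference taxon identifier.
#' @param regions Named list of length-2 integer vectors `c(start, end)`.
#' @param phosphosites Integer vector of reference positions.
#' @param stickers Integer vector of reference positions.
#' @param clades Named list of character vectors of taxon identifiers.
#' @return An object of class `region_config`.
#' @export
region_config <- function(reference, regions = list(), phosphosites = integer(),
                          stickers = integer(), clades = list()) {
  stopifnot(is.character(reference), length(reference) == 1L)
  regions <- lapply(regions, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || anyNA(iv)) stop("region intervals must be c(start, end)")
    iv
  })
  structure(list(reference = reference, regions = regions,
                 phosphosites = as.integer(phosphosites),
                 stickers = as.integer(stickers),
                 clades = lapply(clades, as.character)),
            class = "region_config")
}

#' Read a region/clade configuration from YAML
#'
#' Expected keys: `reference`, `regions` (name -> [start, end]),
#' `phosphosites`, `stickers`, `clades` (name -> taxon list).
#'
#' @param path Path to a YAML file.
#' @return A [region_config].
#' @export
read_region_config <- function(path) {
  y <- yaml::read_yaml(path)
  region_config(reference = y$reference,
                regions = lapply(y$regions, unlist),
                phosphosites = unlist(y$phosphosites),
                stickers = unlist(y$stickers),
                clades = lapply(y$clades, unlist))
}

#' Resolve a configuration against an alignment
#'
#' Translates all reference-coordinate entries to alignment columns and
#' checks that clade members exist among the alignment taxa.
#'
#' @param config A [region_config].
#' @param aln A [pld_alignment].
#' @return `config` with added integer-column elements
#'   `phosphosite_columns`, `sticker_columns` and `region_columns` (a named
#'   list of column vectors).
#' @export
resolve_config <- function(config, aln) {
  for (cl in names(config$clades)) {
    bad <- setdiff(config$clades[[cl]], aln$taxa)
    if (length(bad))
      stop("configuration error: clade '", cl, "' members not in alignment: ",
           paste(bad, collapse = ", "))
  }
  config$phosphosite_columns <-
    if (length(config$phosphosites))
      ref_coord_to_column(aln, config$reference, config$phosphosites) else integer()
  config$sticker_columns <-
    if (length(config$stickers))
      ref_coord_to_column(aln, config$reference, config$stickers) else integer()
  config$region_columns <- lapply(config$regions, function(iv) {
    cols <- ref_coord_to_column(aln, config$reference, iv[1]:iv[2])
    seq.int(min(cols), max(cols))
  })
  config
}

#' @export
print.region_config <- function(x, ...) {
  cat("Region config (reference: ", x$reference, ")\n", sep = "")
  cat("  regions:     ", paste(names(x$regions), collapse = ", "), "\n")
  cat("  phosphosites:", length(x$phosphosites), " stickers:",
      length(x$stickers), "\n")
  cat("  clades:      ", paste(names(x$clades), collapse = ", "), "\n")
  invisible(x)
}
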