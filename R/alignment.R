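#' Protein multiple sequence alignments
#'
#' A `pld_alignment` stores an aligned set of protein sequences as a
#' character matrix (rows = taxa, columns = alignment columns) over the
#' 20-amino-acid alphabet plus the gap symbol `"-"`. Ambiguity codes
#' (X, B, Z, ...) are retained on read but treated as missing data by all
#' downstream counts. An optional in-frame codon layer can be attached for
#' codon-composition analyses.
#'
#' @param rows Named character vector of aligned residue strings, or a
#'   character matrix with one row per taxon.
#' @param codon_rows Optional named character vector of aligned in-frame
#'   nucleotide strings, each exactly 3x the residue length (gaps as
#'   `"---"`). Must translate to the residue rows under the standard code.
#' @return An object of class `pld_alignment` with elements `taxa`,
#'   `mat` (taxa x columns character matrix), `length`, and optionally
#'   `codon` (taxa x columns character matrix of codons).
#' @export
pld_alignment <- function(rows, codon_rows = NULL) {
  if (is.matrix(rows)) {
    mat <- rows
    if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames")
  } else {
    if (is.null(names(rows)) || any(!nzchar(names(rows))))
      stop("sequences must be named by taxon")
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L)
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
    rownames(mat) <- names(rows)
  }
  if (anyDuplicated(rownames(mat)))
    stop("identity error: duplicate taxon identifiers")
  mat[mat == "."] <- "-"
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, MISSING_SYMBOLS))
  if (length(bad))
    warning("unknown residue symbols retained as missing data: ",
            paste(bad, collapse = " "))
  obj <- structure(list(taxa = rownames(mat), mat = mat,
                        length = ncol(mat)),
                   class = "pld_alignment")
  if (!is.null(codon_rows)) obj <- attach_codons(obj, codon_rows)
  obj
}

attach_codons <- function(aln, codon_rows) {
  codon_rows <- toupper(codon_rows[aln$taxa])
  if (anyNA(codon_rows)) stop("codon rows missing for some taxa")
  if (any(nchar(codon_rows) != 3L * aln$length))
    stop("codon rows must be exactly 3x the residue alignment length")
  code <- genetic_code()
  cod <- matrix(unlist(lapply(codon_rows, function(s) {
    substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  })), nrow = length(codon_rows), byrow = TRUE)
  rownames(cod) <- aln$taxa
  tr <- matrix(code[gsub("U", "T", cod)], nrow = nrow(cod))
  tr[cod == "---"] <- "-"
  mism <- which(!is.na(tr) & tr != aln$mat & !is_missing_residue(aln$mat) &
                  cod != "---")
  if (length(mism))
    stop("codon layer does not translate to the residue alignment (",
         length(mism), " mismatching cells)")
  aln$codon <- cod
  aln
}

#' @export
print.pld_alignment <- function(x, ...) {
  cat("Protein alignment: ", length(x$taxa), " taxa x ", x$length,
      " columns", if (!is.null(x$codon)) " (+codon layer)", "\n", sep = "")
  invisible(x)
}

#' Read a protein alignment from FASTA
#'
#' @param path Path to an aligned FASTA file of protein sequences.
#' @param codon_path Optional path to an aligned, in-frame nucleotide FASTA
#'   for the same taxa.
#' @return A [pld_alignment].
#' @export
read_alignment <- function(path, codon_path = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  rows <- stats::setNames(as.character(seqs),
                          sub("\\s.*$", "", names(seqs)))
  if (any(!nzchar(rows))) stop("empty sequence record in ", path)
  codon_rows <- NULL
  if (!is.null(codon_path)) {
    cr <- Biostrings::readBStringSet(codon_path)
    codon_rows <- stats::setNames(as.character(cr), sub("\\s.*$", "", names(cr)))
  }
  pld_alignment(rows, codon_rows)
}

#' Write a protein alignment to FASTA
#'
#' @param aln A [pld_alignment].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  writeLines(paste0(">", aln$taxa, "\n", seqs), path)
  invisible(path)
}

#' Map ungapped reference coordinates to alignment columns
#'
#' Reference positions follow the field convention of numbering sites on the
#' ungapped reference sequence (e.g. "S30" means the 30th residue of the
#' reference taxon). This returns the bijection onto 1-based alignment
#' columns induced by the gapped reference row.
#'
#' @param aln A [pld_alignment].
#' @param reference Taxon identifier of the reference sequence.
#' @return Integer vector `map` with `map[p]` the alignment column of
#'   ungapped reference position `p`.
#' @examples
#' a <- pld_alignment(c(ref = "M-KS", other = "MAKS"))
#' map_reference_coordinates(a, "ref")  # c(1, 3, 4)
#' @export
map_reference_coordinates <- function(aln, reference) {
  if (!reference %in% aln$taxa)
    stop("reference taxon '", reference, "' not in alignment")
  row <- aln$mat[reference, ]
  which(row != "-")
}

ref_coord_to_column <- function(aln, reference, positions) {
  map <- map_reference_coordinates(aln, reference)
  if (any(positions < 1L | positions > length(map)))
    stop("coordinate error: reference position out of range 1..", length(map))
  map[positions]
}

#' Extract a named region of an alignment
#'
#' @param aln A [pld_alignment].
#' @param config A [region_config] whose regions are given in reference
#'   coordinates.
#' @param region Region name defined in `config`.
#' @return A [pld_alignment] restricted to the region's columns.
#' @export
extract_region <- function(aln, config, region) {
  if (!region %in% names(config$regions))
    stop("lookup error: region '", region, "' not defined")
  iv <- config$regions[[region]]
  if (iv[2] < iv[1]) stop("empty-region error: ", region)
  cols <- ref_coord_to_column(aln, config$reference, iv[1]:iv[2])
  cols <- seq.int(min(cols), max(cols))
  out <- aln
  out$mat <- aln$mat[, cols, drop = FALSE]
  if (!is.null(aln$codon)) out$codon <- aln$codon[, cols, drop = FALSE]
  out$length <- length(cols)
  out$columns <- cols
  out
}
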