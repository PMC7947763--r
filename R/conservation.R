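#' Shannon entropy of one alignment column
#'
#' Computes H = -sum(p_a log p_a) over the residues observed in a column.
#' Gaps and ambiguity codes are excluded from the counts (the study
#' alignments are nearly gap-free, so treating gaps as a 21st state would
#' only add noise).
#'
#' @param aln A [pld_alignment].
#' @param column 1-based column index.
#' @param base Logarithm base: `"nat"` (default) or `"bits"`.
#' @return Entropy in the requested base, or `NA_real_` for an all-missing
#'   column.
#' @examples
#' a <- pld_alignment(c(t1 = "GG", t2 = "GS"))
#' column_entropy(a, 1)  # 0
#' column_entropy(a, 2)  # log(2)
#' @export
column_entropy <- function(aln, column, base = c("nat", "bits")) {
  base <- match.arg(base)
  if (column < 1L || column > aln$length) stop("column out of range")
  res <- aln$mat[, column]
  res <- res[!is_missing_residue(res)]
  if (!length(res)) return(NA_real_)
  p <- table(res) / length(res)
  h <- -sum(p * log(p))
  if (base == "bits") h / log(2) else h
}

#' Per-column entropy profile of an alignment
#'
#' @inheritParams column_entropy
#' @return An object of class `entropy_profile`: a list with `entropy`
#'   (numeric vector, `NA` for all-missing columns), `freq` (list of named
#'   frequency vectors), `n_effective` (non-missing counts) and `base`.
#' @export
entropy_profile <- function(aln, base = c("nat", "bits")) {
  base <- match.arg(base)
  if (aln$length == 0L) stop("empty alignment")
  freq <- vector("list", aln$length)
  h <- numeric(aln$length)
  neff <- integer(aln$length)
  logdiv <- if (base == "bits") log(2) else 1
  for (j in seq_len(aln$length)) {
    res <- aln$mat[, j]
    res <- res[!is_missing_residue(res)]
    neff[j] <- length(res)
    if (!length(res)) { h[j] <- NA_real_; freq[[j]] <- numeric(); next }
    p <- table(res) / length(res)
    freq[[j]] <- stats::setNames(as.numeric(p), names(p))
    h[j] <- -sum(p * log(p)) / logdiv
  }
  structure(list(entropy = h, freq = freq, n_effective = neff, base = base),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("Entropy profile over", length(x$entropy), "columns (", x$base, ")\n")
  cat("  median", stats::median(x$entropy, na.rm = TRUE),
      " max", max(x$entropy, na.rm = TRUE), "\n")
  invisible(x)
}

#' Fully conserved alignment columns
#'
#' Columns where every non-missing residue is identical (optionally also
#' equal to a given residue, e.g. `"Y"` to pick out conserved sticker
#' tyrosines).
#'
#' @inheritParams column_entropy
#' @param residue Optional single residue the column must be conserved as.
#' @return Integer vector of column indices.
#' @export
conserved_columns <- function(aln, residue = NULL) {
  keep <- vapply(seq_len(aln$length), function(j) {
    res <- aln$mat[, j]
    res <- res[!is_missing_residue(res)]
    if (!length(res)) return(FALSE)
    u <- unique(res)
    length(u) == 1L && (is.null(residue) || u == residue)
  }, logical(1))
  which(keep)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, used for region-wise
#' entropy comparisons and site-class rate comparisons. Exact enumeration
#' when the combined sample size is at most 12 and there are no ties;
#' tie-corrected normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `statistic` (Mann-Whitney U for `group_a`), `p_value`,
#'   and `method`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("input error: both groups must be non-empty")
  n <- length(group_a) + length(group_b)
  if (length(unique(c(group_a, group_b))) == 1L)
    return(list(statistic = length(group_a) * length(group_b) / 2,
                p_value = 1, method = "degenerate (all values tied)"))
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- (n <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}
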