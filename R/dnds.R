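# Counting-based dN/dS (Nei-Gojobori 1986 with equal pathway weighting and
# Jukes-Cantor correction). For the closely related, high-identity
# sequences this package targets, the counting estimator is an adequate
# summary of selection strength; it is tagged in its output so downstream
# tables never confuse it with a codon-model ML estimate.

split_codons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  if (nchar(seq) %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

# synonymous fraction of each of the 3 positions of a codon:
# for each position, the fraction of the 3 possible point mutations that
# are synonymous (mutations to stop codons are excluded from the
# denominator, the NG86 convention)
codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("T", "C", "A", "G")
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(bases, substr(codon, pos, pos))
    n_ok <- 0L; n_syn <- 0L
    for (b in alts) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      n_ok <- n_ok + 1L
      if (code[[mut]] == aa) n_syn <- n_syn + 1L
    }
    if (n_ok > 0L) s <- s + n_syn / n_ok
  }
  s
}

# expected syn/nonsyn difference counts between two codons, averaging
# equally over all minimal mutation pathways that avoid stop codons
codon_path_diffs <- function(c1, c2, code) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diffs)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(diffs) else {
    if (nd == 2L) list(diffs, rev(diffs)) else {
      p <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
      p <- p[apply(p, 1L, function(r) length(unique(r)) == 3L), ]
      lapply(seq_len(nrow(p)), function(i) diffs[unlist(p[i, ])])
    }
  }
  acc <- c(syn = 0, nonsyn = 0)
  used <- 0L
  for (ord in perms) {
    cur <- c1
    step <- c(syn = 0, nonsyn = 0)
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") { valid <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) step["syn"] <- step["syn"] + 1
      else step["nonsyn"] <- step["nonsyn"] + 1
      cur <- nxt
    }
    if (valid) { acc <- acc + step; used <- used + 1L }
  }
  if (used == 0L) {
    # all pathways pass through a stop: count every difference nonsyn
    return(c(syn = 0, nonsyn = nd))
  }
  acc / used
}

#' Pairwise dN/dS by the Nei-Gojobori counting method
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame coding sequences, averaging equally over mutation pathways for
#' multi-hit codons, applies the Jukes-Cantor multiple-hit correction to
#' the proportions, and reports the ratio.
#'
#' @param codon_a,codon_b In-frame nucleotide strings of equal length with
#'   no internal stop codons. Codons containing gaps or ambiguous bases are
#'   skipped pairwise.
#' @param code Genetic code, as returned by [genetic_code()].
#' @return List of class `dnds_estimate`: `dn`, `ds`, `omega` (`NA` when
#'   `ds` is 0), the raw site and difference counts, and `method`.
#' @export
pairwise_dnds <- function(codon_a, codon_b, code = genetic_code()) {
  ca <- split_codons(codon_a)
  cb <- split_codons(codon_b)
  if (length(ca) != length(cb)) stop("sequences have different codon counts")
  valid <- grepl("^[TCAG]{3}$", ca) & grepl("^[TCAG]{3}$", cb)
  ca <- ca[valid]; cb <- cb[valid]
  if (any(code[ca] == "*") || any(code[cb] == "*"))
    stop("internal stop codon")
  S_sites <- sum(vapply(ca, codon_syn_sites, numeric(1), code = code) +
                   vapply(cb, codon_syn_sites, numeric(1), code = code)) / 2
  N_sites <- 3 * length(ca) - S_sites
  d <- vapply(seq_along(ca), function(i)
    codon_path_diffs(ca[i], cb[i], code), numeric(2))
  Sd <- sum(d["syn", ]); Nd <- sum(d["nonsyn", ])
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ps <- if (S_sites > 0) Sd / S_sites else 0
  pn <- if (N_sites > 0) Nd / N_sites else 0
  ds <- jc(ps); dn <- jc(pn)
  omega <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  structure(list(dn = dn, ds = ds, omega = omega,
                 syn_sites = S_sites, nonsyn_sites = N_sites,
                 syn_diffs = Sd, nonsyn_diffs = Nd,
                 n_codons = length(ca),
                 method = "Nei-Gojobori counting (equal pathway weights, JC correction)"),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN = %.4g, dS = %.4g, omega = %s  [%s]\n",
              x$dn, x$ds,
              if (is.na(x$omega)) "undefined (dS = 0)" else sprintf("%.4g", x$omega),
              x$method))
  invisible(x)
}
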