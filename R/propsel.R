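# Detection of amino-acid physicochemical properties under selection.
#
# For a chosen property, every single-nucleotide nonsynonymous change
# realizable under the genetic code implies a property-change magnitude
# |delta|. The magnitudes are split into 8 equal-width categories from most
# conserved (1) to most radical (8). The expected category distribution is
# built from the codon composition of the extant sequences (every possible
# point mutation from every observed codon, equally likely); the observed
# distribution scores the mapped substitution events. Deviations are
# summarised by per-category z-scores, a chi-square goodness of fit, and a
# signed selection strength (z of the pooled radical categories: positive
# = diversifying, negative = conserving).

#' Amino-acid property table
#'
#' Returns per-amino-acid values for a set of physicochemical properties,
#' sourced from the AAindex collection shipped with seqinr. The default set
#' contains the properties most relevant to low-complexity domain
#' evolution: tetrapeptide structure-occurrence (RACS820101), polarity
#' (GRAR740102), average flexibility (BHAR880101), and solvation free
#' energy (EISD860101).
#'
#' @param ids Character vector of AAindex accession codes.
#' @return Named list of numeric vectors (length 20, alphabetical
#'   one-letter order); attribute `descriptions`.
#' @export
property_table <- function(ids = c("RACS820101", "GRAR740102",
                                   "BHAR880101", "EISD860101")) {
  aaindex <- NULL
  utils::data("aaindex", package = "seqinr", envir = environment())
  three <- c("Ala", "Cys", "Asp", "Glu", "Phe", "Gly", "His", "Ile", "Lys",
             "Leu", "Met", "Asn", "Pro", "Gln", "Arg", "Ser", "Thr", "Val",
             "Trp", "Tyr")
  out <- list()
  desc <- character()
  for (id in ids) {
    hit <- aaindex[[id]]
    if (is.null(hit)) stop("AAindex property not found: ", id)
    v <- hit$I[three]
    if (anyNA(v)) stop("property ", id, " has missing amino-acid values")
    out[[id]] <- stats::setNames(as.numeric(v), AA_ALPHABET)
    desc[id] <- hit$D
  }
  attr(out, "descriptions") <- desc
  out
}

#' Read a property table from a plain-text file
#'
#' Tab- or whitespace-separated columns: property id, description (quoted
#' or underscore-joined), then 20 values in alphabetical one-letter order
#' (A C D E F G H I K L M N P Q R S T V W Y). Lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return As [property_table()].
#' @export
read_property_table <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  out <- list(); desc <- character()
  for (l in ln) {
    f <- strsplit(l, "\\s+")[[1]]
    if (length(f) < 22L) stop("property line needs id, description, 20 values")
    id <- f[1]
    out[[id]] <- stats::setNames(as.numeric(f[(length(f) - 19L):length(f)]),
                                 AA_ALPHABET)
    desc[id] <- paste(f[2:(length(f) - 20L)], collapse = " ")
  }
  attr(out, "descriptions") <- desc
  out
}

# all ordered amino-acid pairs reachable by one nucleotide change
single_step_aa_pairs <- function(code = genetic_code()) {
  bases <- c("T", "C", "A", "G")
  pairs <- list()
  for (codon in names(code)) {
    if (code[[codon]] == "*") next
    for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*" || code[[mut]] == code[[codon]]) next
      pairs[[length(pairs) + 1L]] <- c(code[[codon]], code[[mut]])
    }
  }
  unique(do.call(rbind, pairs))
}

#' Magnitude category boundaries for one property
#'
#' The range of |delta property| over all amino-acid pairs exchangeable by
#' a single nucleotide nonsynonymous change is split into 8 equal-width
#' bins, category 1 (most conserved) to 8 (most radical).
#'
#' @param property Named numeric vector over the 20 amino acids.
#' @param code Genetic code.
#' @param ncat Number of categories (default 8).
#' @return Numeric vector of `ncat + 1` boundaries (first 0, last the
#'   maximum realizable |delta|).
#' @export
category_bounds <- function(property, code = genetic_code(), ncat = 8L) {
  pairs <- single_step_aa_pairs(code)
  deltas <- abs(property[pairs[, 1]] - property[pairs[, 2]])
  if (max(deltas) == 0)
    stop("degenerate-category signal: property is constant over reachable pairs")
  seq(0, max(deltas), length.out = ncat + 1L)
}

classify_delta <- function(delta, bounds) {
  ncat <- length(bounds) - 1L
  tol <- 1e-9 * max(1, bounds[ncat + 1L])
  # values equal to the extreme bounds up to rounding noise are clamped in
  k <- findInterval(delta, bounds, rightmost.closed = TRUE, left.open = TRUE)
  k[delta <= bounds[1L] + tol] <- 1L
  k[k > ncat & delta <= bounds[ncat + 1L] + tol] <- ncat
  if (any(k < 1L | k > ncat)) stop("impossible-category error: |delta| out of range")
  k
}

#' Expected category distribution from codon composition
#'
#' Enumerates every single-nucleotide nonsynonymous change from every
#' codon, weights each source codon by its frequency among the extant
#' sequences (all point mutations from a codon equally likely), and tallies
#' the property-change categories. When no codon layer is available, an
#' amino-acid composition fallback assumes uniform codon usage within each
#' amino acid's codon family (flagged in the result).
#'
#' @param aln A [pld_alignment] (codon layer used when present).
#' @param property Named numeric vector over the amino acids.
#' @param bounds [category_bounds()] boundaries.
#' @param code Genetic code.
#' @param allow_fallback Permit the amino-acid composition fallback.
#' @return Numeric vector `p` of category proportions (sums to 1);
#'   attribute `fallback` records whether the fallback was used.
#' @export
expected_distribution <- function(aln, property, bounds,
                                  code = genetic_code(),
                                  allow_fallback = TRUE) {
  ncat <- length(bounds) - 1L
  if (!is.null(aln$codon)) {
    cod <- as.vector(aln$codon)
    cod <- cod[grepl("^[TCAGU]{3}$", cod)]
    cod <- gsub("U", "T", cod)
    wt <- table(cod) / length(cod)
    fallback <- FALSE
  } else {
    if (!allow_fallback)
      stop("input error: no codon data and fallback disabled")
    res <- as.vector(aln$mat)
    res <- res[!is_missing_residue(res)]
    aa_freq <- table(res) / length(res)
    fam <- split(names(code), code)
    wt <- numeric()
    for (aa in names(aa_freq)) {
      codons <- fam[[aa]]
      if (is.null(codons)) next
      wt[codons] <- as.numeric(aa_freq[aa]) / length(codons)
    }
    wt <- wt / sum(wt)
    fallback <- TRUE
  }
  bases <- c("T", "C", "A", "G")
  p <- numeric(ncat)
  for (codon in names(wt)) {
    if (code[[codon]] == "*") next
    muts <- character()
    for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*" || code[[mut]] == code[[codon]]) next
      muts <- c(muts, mut)
    }
    if (!length(muts)) next
    # each of the 9 point mutations equally likely; nonsyn ones scored
    for (mut in muts) {
      delta <- abs(property[code[[codon]]] - property[code[[mut]]])
      k <- classify_delta(delta, bounds)
      p[k] <- p[k] + as.numeric(wt[codon]) / 9
    }
  }
  p <- p / sum(p)
  attr(p, "fallback") <- fallback
  p
}

#' Observed category counts from mapped events
#'
#' @param events A [map_substitutions()] event table.
#' @param property Named numeric vector over the amino acids.
#' @param bounds [category_bounds()] boundaries.
#' @param columns Optional column subset (e.g. excluding phosphosites).
#' @return Integer vector of category counts; attribute `skipped` counts
#'   unscorable events.
#' @export
observed_distribution <- function(events, property, bounds, columns = NULL) {
  ncat <- length(bounds) - 1L
  if (!is.null(columns)) events <- events[events$site %in% columns, , drop = FALSE]
  O <- integer(ncat)
  skipped <- 0L
  if (nrow(events)) {
    ok <- events$from %in% AA_ALPHABET & events$to %in% AA_ALPHABET
    delta <- abs(property[events$from[ok]] - property[events$to[ok]])
    # events whose endpoints are not exchangeable by a single nucleotide
    # step can exceed the realizable range; they carry no probability
    # under the expected distribution and are skipped as unscorable
    in_range <- delta <= bounds[length(bounds)] +
      1e-9 * max(1, bounds[length(bounds)])
    skipped <- sum(!ok) + sum(!in_range)
    k <- classify_delta(delta[in_range], bounds)
    O <- as.integer(tabulate(k, nbins = ncat))
  }
  attr(O, "skipped") <- skipped
  O
}

#' Z-scores, goodness of fit and signed selection strength
#'
#' Per-category z = (O - N p) / sqrt(N p (1 - p)); chi-square goodness of
#' fit with `ncat - 1` degrees of freedom; signed strength = z-score of the
#' pooled radical categories (6-8 by default): positive when radical
#' property changes are more frequent than the neutral expectation
#' (diversifying selection), negative when rarer (conserving).
#'
#' @param O Observed category counts.
#' @param p Expected category proportions.
#' @param radical Categories pooled into the signed strength; one of
#'   `"6-8"`, `"7-8"`, `"max"` (maximum |z| radical category, sign kept).
#' @return List: `z` (per category), `chisq`, `df`, `p_value`, `strength`,
#'   `n_events`.
#' @export
selection_scores <- function(O, p, radical = c("6-8", "7-8", "max")) {
  radical <- match.arg(radical)
  N <- sum(O)
  if (N == 0) stop("no scorable events")
  if (any(p == 0 & O > 0))
    stop("impossible-category error: observed events in a zero-probability category")
  z <- (O - N * p) / sqrt(N * p * (1 - p))
  use <- p > 0
  chisq <- sum((O[use] - N * p[use])^2 / (N * p[use]))
  df <- sum(use) - 1L
  pool <- function(idx) {
    pp <- sum(p[idx])
    (sum(O[idx]) - N * pp) / sqrt(N * pp * (1 - pp))
  }
  strength <- switch(radical,
    "6-8" = pool(6:8),
    "7-8" = pool(7:8),
    "max" = { zz <- z[6:8]; zz[which.max(abs(zz))] })
  list(z = z, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       strength = unname(strength), n_events = N)
}

#' Sliding-window positional selection profile
#'
#' Recomputes [selection_scores()] on the events inside each sliding window
#' of alignment columns; windows with fewer than `min_events` events are
#' reported as `NA`.
#'
#' @param events A [map_substitutions()] event table.
#' @param property,bounds,p As in [selection_scores()] /
#'   [observed_distribution()]; `p` is the (global) expected distribution.
#' @param region_columns Columns of the scanned region, in order.
#' @param window Window width in columns (>= 3).
#' @param min_events Minimum events per window to score.
#' @param radical Passed to [selection_scores()].
#' @return `data.frame` with `start_column`, `center_column`, `n_events`,
#'   `strength`.
#' @export
window_scan <- function(events, property, bounds, p, region_columns,
                        window = 15L, min_events = 5L, radical = "6-8") {
  if (window < 3L) stop("window must be >= 3 columns")
  if (window > length(region_columns))
    stop("input error: window longer than region")
  n_win <- length(region_columns) - window + 1L
  out <- data.frame(start_column = region_columns[seq_len(n_win)],
                    center_column = region_columns[seq_len(n_win)] +
                      (window - 1L) %/% 2L,
                    n_events = NA_integer_, strength = NA_real_)
  for (i in seq_len(n_win)) {
    cols <- region_columns[i:(i + window - 1L)]
    O <- observed_distribution(events, property, bounds, columns = cols)
    out$n_events[i] <- sum(O)
    if (sum(O) >= min_events)
      out$strength[i] <- selection_scores(O, p, radical = radical)$strength
  }
  out
}

#' Group correlated properties and average their selection strengths
#'
#' Properties whose per-amino-acid value vectors are strongly rank
#' correlated carry near-duplicate signals; they are grouped by
#' single-linkage (transitive closure) at |Spearman R| > `threshold` and
#' their signed strengths averaged. Anti-correlated members are flipped to
#' the orientation of the group's first member before averaging.
#'
#' @param properties Named list of per-amino-acid value vectors.
#' @param strengths Named numeric vector of signed strengths (same names).
#' @param threshold Absolute Spearman correlation for grouping (default
#'   0.8).
#' @return `data.frame` with one row per group: `group`, `members`,
#'   `mean_strength`, `sd_strength`, `n_members`.
#' @export
cluster_and_average <- function(properties, strengths, threshold = 0.8) {
  ids <- names(properties)
  n <- length(ids)
  if (n < 2L) stop("need >= 2 properties")
  R <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- stats::cor(properties[[i]], properties[[j]], method = "spearman")
    R[i, j] <- R[j, i] <- r
  }
  # union-find transitive closure over |R| > threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(R[i, j]) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(unique(grp), function(g) {
    members <- which(grp == g)
    anchor <- members[1]
    signs <- vapply(members, function(m) {
      if (R[anchor, m] < 0) -1 else 1
    }, numeric(1))
    vals <- strengths[ids[members]] * signs
    data.frame(group = ids[anchor],
               members = paste(ids[members], collapse = ","),
               mean_strength = mean(vals),
               sd_strength = if (length(vals) > 1L) stats::sd(vals) else 0,
               n_members = length(members))
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$mean_strength)), , drop = FALSE]
}
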