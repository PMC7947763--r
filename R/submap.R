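#' Map substitution events onto tree branches
#'
#' Compares the MAP state (or observed leaf residue) at the two endpoints
#' of every branch and records an event wherever they differ. Each event is
#' assigned to the single branch on which the endpoint states differ;
#' multiple hits within one branch are unidentifiable at this resolution
#' and are not inferred. Events touching missing leaf data are skipped.
#'
#' @param recon An `asr` object from [marginal_ancestral_states()].
#' @param aln The [pld_alignment] the reconstruction was computed on.
#' @param min_posterior Minimum MAP posterior required of both endpoints
#'   (leaves count as support 1). 0 keeps every MAP difference; 0.9
#'   reproduces a ">90% reconstruction accuracy" filter.
#' @param columns Optional column subset to map (default: all).
#' @return A `data.frame` of class `substitution_events` with columns
#'   `branch` (edge index in the postorder tree), `parent_node`,
#'   `child_node`, `site`, `from`, `to`, `support` (min endpoint MAP
#'   posterior).
#' @export
map_substitutions <- function(recon, aln, min_posterior = 0, columns = NULL) {
  tree <- recon$tree
  if (!setequal(tree$tip.label, aln$taxa))
    stop("reconciliation error: reconstruction and alignment taxa differ")
  n_tip <- length(tree$tip.label)
  states <- aln$mat[tree$tip.label, , drop = FALSE]
  if (is.null(columns)) columns <- seq_len(aln$length)
  node_key <- as.character(recon$node_ids)
  out <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    p_row <- match(as.character(p), node_key)
    from <- recon$map_state[p_row, columns]
    from_sup <- recon$map_prob[p_row, columns]
    if (v <= n_tip) {
      to <- states[v, columns]
      to_sup <- rep(1, length(columns))
    } else {
      v_row <- match(as.character(v), node_key)
      to <- recon$map_state[v_row, columns]
      to_sup <- recon$map_prob[v_row, columns]
    }
    ok <- !is_missing_residue(from) & !is_missing_residue(to) &
      from != to & pmin(from_sup, to_sup) >= min_posterior
    if (any(ok)) {
      out[[i]] <- data.frame(branch = i, parent_node = p, child_node = v,
                             site = columns[ok], from = from[ok], to = to[ok],
                             support = pmin(from_sup, to_sup)[ok])
    }
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(branch = integer(), parent_node = integer(),
                     child_node = integer(), site = integer(),
                     from = character(), to = character(), support = numeric())
  rownames(ev) <- NULL
  class(ev) <- c("substitution_events", "data.frame")
  attr(ev, "tree") <- tree
  ev
}

#' 20x20 exchange-count matrix
#'
#' @param events A [map_substitutions()] event table.
#' @return Integer matrix (from-state rows, to-state columns) of class
#'   `exchange_matrix`; `sum(m)` equals the number of events.
#' @export
exchange_matrix <- function(events) {
  m <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  if (nrow(events)) {
    tb <- table(factor(events$from, AA_ALPHABET),
                factor(events$to, AA_ALPHABET))
    m[] <- as.integer(tb)
  }
  structure(m, class = c("exchange_matrix", class(m)))
}

#' Toggle summary of an exchange matrix
#'
#' Bidirectional counts for unordered residue pairs (e.g. G/S and A/T, the
#' characteristic toggle exchanges of low-complexity domains) and their
#' combined fraction of all mapped events.
#'
#' @param matrix An [exchange_matrix()].
#' @param pairs List of length-2 character vectors of residues.
#' @return List with `pair_counts` (named integer vector, names like
#'   `"G:S"`), `total_events`, and `fraction` (`NA` when no events).
#' @export
toggle_summary <- function(matrix, pairs = list(c("G", "S"), c("A", "T"))) {
  stopifnot(all(unlist(pairs) %in% AA_ALPHABET))
  counts <- vapply(pairs, function(pr) {
    matrix[pr[1], pr[2]] + matrix[pr[2], pr[1]]
  }, numeric(1))
  names(counts) <- vapply(pairs, function(pr)
    paste(sort(pr), collapse = ":"), character(1))
  total <- sum(matrix)
  list(pair_counts = counts, total_events = total,
       fraction = if (total > 0) sum(counts) / total else NA_real_)
}

#' Phosphosite-occupancy trait
#'
#' Counts, for each taxon (and optionally each reconstructed ancestor), how
#' many configured phosphosite columns carry a serine or threonine. This
#' integer count is the continuous trait used by the drift-vs-selection
#' models.
#'
#' @param aln A [pld_alignment].
#' @param config A [resolve_config()]-resolved [region_config] with
#'   `phosphosite_columns`.
#' @param recon Optional `asr` object; when given, ancestral counts from
#'   MAP states are appended (named by node id).
#' @return Named integer vector.
#' @export
phosphosite_trait <- function(aln, config, recon = NULL) {
  cols <- config$phosphosite_columns
  if (is.null(cols) || !length(cols))
    stop("configuration error: no resolved phosphosite columns (run resolve_config)")
  counts <- apply(aln$mat[, cols, drop = FALSE], 1L,
                  function(r) sum(r %in% c("S", "T")))
  if (!is.null(recon)) {
    anc <- apply(recon$map_state[, cols, drop = FALSE], 1L,
                 function(r) sum(r %in% c("S", "T")))
    counts <- c(counts, anc)
  }
  counts
}

# branches whose descendant leaves all belong to `clade`; optionally the
# stem branch (the branch subtending the clade MRCA) as well
clade_branches <- function(tree, clade, include_stem = TRUE) {
  tips <- match(clade, tree$tip.label)
  if (anyNA(tips)) stop("clade taxa missing from tree")
  desc <- descendant_tips(tree)
  inside <- vapply(seq_len(nrow(tree$edge)), function(i) {
    all(desc[[tree$edge[i, 2L]]] %in% tips)
  }, logical(1))
  if (!include_stem && length(tips) > 1L) {
    mrca <- ape::getMRCA(tree, tips)
    stem <- which(tree$edge[, 2L] == mrca)
    inside[stem] <- FALSE
  } else if (!include_stem && length(tips) == 1L) {
    inside[tree$edge[, 2L] == tips] <- FALSE
  }
  which(inside)
}

#' Phosphosite creation/destruction contingency
#'
#' At phosphosite columns, creating events are G->S and A->T, destroying
#' events are S->G and T->A. Events are stratified into a focal clade
#' (branches all of whose descendant leaves are clade members, stem branch
#' included by default) versus the background, giving a 2x2 table and
#' per-stratum creation/destruction ratios.
#'
#' @param events A [map_substitutions()] event table (computed on the full
#'   alignment).
#' @param config Resolved [region_config] with `phosphosite_columns`.
#' @param clade Name of a clade in `config`, or a character vector of taxa.
#' @param include_stem Count the clade stem branch as part of the clade?
#' @return List with `table` (2x2: rows creating/destroying, columns
#'   clade/background), `ratio_clade`, `ratio_background`, `ratio_total`
#'   (each `Inf` when only creating events, `NA` when no events), and
#'   `fisher_p`.
#' @export
creation_destruction_table <- function(events, config, clade,
                                       include_stem = TRUE) {
  tree <- attr(events, "tree")
  if (is.null(tree)) stop("event table lacks its tree attribute")
  taxa <- if (length(clade) == 1L && clade %in% names(config$clades))
    config$clades[[clade]] else as.character(clade)
  if (!length(taxa)) stop("input error: empty clade")
  cb <- clade_branches(tree, taxa, include_stem)
  ev <- events[events$site %in% config$phosphosite_columns, , drop = FALSE]
  key <- paste0(ev$from, ">", ev$to)
  creating <- key %in% c("G>S", "A>T")
  destroying <- key %in% c("S>G", "T>A")
  in_clade <- ev$branch %in% cb
  tab <- matrix(c(sum(creating & in_clade), sum(creating & !in_clade),
                  sum(destroying & in_clade), sum(destroying & !in_clade)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("creating", "destroying"),
                                c("clade", "background")))
  ratio <- function(cr, de) {
    if (cr == 0 && de == 0) NA_real_ else if (de == 0) Inf else cr / de
  }
  list(table = tab,
       ratio_clade = ratio(tab[1, 1], tab[2, 1]),
       ratio_background = ratio(tab[1, 2], tab[2, 2]),
       ratio_total = ratio(sum(tab[1, ]), sum(tab[2, ])),
       fisher_p = fisher_exact(tab))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by summing all hypergeometric tables with probability no larger
#' than the observed one (the classical two-sided convention). A table with
#' a zero margin returns p = 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # the classical convention: sum all tables no more probable than the
  # observed one, with a small relative slack against rounding
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare per-site rates between two site classes
#'
#' Site-class comparison (e.g. phosphosites versus the rest of a domain)
#' of per-site rate summaries via the Wilcoxon rank-sum test. Rates default
#' to per-site substitution-event counts from an event table.
#'
#' @param rates Named or plain numeric vector of per-site rates indexed by
#'   alignment column, or a [map_substitutions()] event table (per-site
#'   event counts are then used).
#' @param class_a,class_b Integer vectors of column indices.
#' @return [rank_sum_test()] result plus per-class summaries.
#' @export
site_class_rate_compare <- function(rates, class_a, class_b) {
  if (inherits(rates, "substitution_events")) {
    tb <- table(rates$site)
    all_cols <- sort(unique(c(class_a, class_b)))
    rates <- stats::setNames(as.numeric(tb[as.character(all_cols)]), all_cols)
    rates[is.na(rates)] <- 0
  }
  ra <- rates[as.character(class_a)]
  rb <- rates[as.character(class_b)]
  if (is.null(names(rates))) { ra <- rates[class_a]; rb <- rates[class_b] }
  ra[is.na(ra)] <- 0; rb[is.na(rb)] <- 0
  res <- rank_sum_test(ra, rb)
  res$median_a <- stats::median(ra)
  res$median_b <- stats::median(rb)
  res
}
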