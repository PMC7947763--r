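# Coevolution detection from branch-level substitution patterns.
#
# The branch x site binary substitution matrix records where on the tree
# each site changed. For a site pair (i, j), column j is modelled either
# as a single Bernoulli process (independence) or as two Bernoullis
# conditional on whether column i substituted on the same branch
# (dependence). With conjugate Beta(1, 1) priors both marginal likelihoods
# are closed-form Beta functions; the log Bayes factor is the dependence
# score and, at prior odds 1, the posterior probability of association is
# BF / (BF + 1). This is the exact one-parent special case of a
# bounded-in-degree Bayesian network over sites; pairwise association
# needs nothing more.

#' Branch x site binary substitution matrix
#'
#' @param events A [map_substitutions()] event table.
#' @param tree The tree the events were mapped on (defaults to the table's
#'   tree attribute).
#' @param columns Site columns to include (default: all sites present in
#'   the tree's alignment range, taken from the events and `columns`).
#' @return Binary integer matrix, rows = branches (edge indices), columns
#'   = sites; entry 1 iff at least one event.
#' @export
binary_matrix <- function(events, tree = NULL, columns = NULL) {
  if (is.null(tree)) tree <- attr(events, "tree")
  if (is.null(tree)) stop("no tree available")
  if (is.null(columns))
    columns <- if (nrow(events)) sort(unique(events$site)) else integer()
  m <- matrix(0L, nrow(tree$edge), length(columns),
              dimnames = list(NULL, as.character(columns)))
  if (nrow(events)) {
    keep <- events$site %in% columns
    idx <- cbind(events$branch[keep],
                 match(events$site[keep], columns))
    m[idx] <- 1L
  }
  m
}

# log marginal likelihood of binary vector y as iid Bernoulli with a
# Beta(1, 1) prior: B(k + 1, n - k + 1) / B(1, 1)
lbeta_bernoulli <- function(k, n) lbeta(k + 1, n - k + 1) - lbeta(1, 1)

#' Pairwise dependence score between two sites
#'
#' Log Bayes factor comparing column `j` conditional on column `i` against
#' column `j` independent, both under Beta(1, 1) priors; the posterior
#' probability of association assumes prior odds 1.
#'
#' @param matrix A [binary_matrix()].
#' @param site_i,site_j Column names or indices.
#' @return List: `log_bf`, `posterior`.
#' @export
pair_score <- function(matrix, site_i, site_j) {
  xi <- matrix[, site_i]
  xj <- matrix[, site_j]
  if (sum(xi) == 0 || sum(xj) == 0)
    stop("undefined signal: a column has no substitutions")
  n <- length(xj)
  k <- sum(xj)
  log_indep <- lbeta_bernoulli(k, n)
  n1 <- sum(xi == 1L); k1 <- sum(xj[xi == 1L])
  n0 <- n - n1; k0 <- k - k1
  log_dep <- lbeta_bernoulli(k1, n1) + lbeta_bernoulli(k0, n0)
  log_bf <- log_dep - log_indep
  list(log_bf = log_bf, posterior = stats::plogis(log_bf))
}

#' Scan all site pairs for coevolution
#'
#' Scores every unordered pair of sites that each carry at least
#' `min_substitutions` substituted branches; pairs with posterior > the
#' flag threshold are marked.
#'
#' @param matrix A [binary_matrix()].
#' @param min_substitutions Minimum substituted branches per column
#'   (default 2; singleton columns carry no pairwise signal).
#' @param flag_threshold Posterior probability above which a pair is
#'   flagged (default 0.5).
#' @return Object of class `coevolution_result`: `data.frame` with
#'   `site_i`, `site_j` (site_i < site_j), `log_bf`, `posterior`,
#'   `flagged`.
#' @export
coevolution_scan <- function(matrix, min_substitutions = 2L,
                             flag_threshold = 0.5) {
  counts <- colSums(matrix)
  active <- which(counts >= min_substitutions)
  out <- data.frame(site_i = integer(), site_j = integer(),
                    log_bf = numeric(), posterior = numeric(),
                    flagged = logical())
  if (length(active) >= 2L) {
    combs <- utils::combn(active, 2L)
    rows <- vector("list", ncol(combs))
    for (q in seq_len(ncol(combs))) {
      i <- combs[1, q]; j <- combs[2, q]
      # symmetrised score: average of the two conditioning directions
      s_ij <- pair_score(matrix, i, j)$log_bf
      s_ji <- pair_score(matrix, j, i)$log_bf
      lb <- (s_ij + s_ji) / 2
      rows[[q]] <- data.frame(
        site_i = as.integer(colnames(matrix)[i]),
        site_j = as.integer(colnames(matrix)[j]),
        log_bf = lb, posterior = stats::plogis(lb))
    }
    out <- do.call(rbind, rows)
    out$flagged <- out$posterior > flag_threshold
    swap <- out$site_i > out$site_j
    tmp <- out$site_i[swap]
    out$site_i[swap] <- out$site_j[swap]
    out$site_j[swap] <- tmp
    out <- out[order(-out$posterior), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("coevolution_result", "data.frame"),
            min_substitutions = min_substitutions)
}

#' Correlate coevolution probabilities with structural distances
#'
#' Spearman rank correlation (tie-corrected large-sample p) between pair
#' posterior probabilities and inter-residue distances supplied as a
#' precomputed pair table (e.g. Calpha distances in Angstrom).
#'
#' @param result A [coevolution_scan()] result.
#' @param distances `data.frame` with columns `site_i`, `site_j`,
#'   `distance` (unordered pairs).
#' @return List: `rho`, `p_value`, `n_pairs`.
#' @export
distance_correlation <- function(result, distances) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  d <- stats::setNames(distances$distance,
                       key(distances$site_i, distances$site_j))
  matched <- d[key(result$site_i, result$site_j)]
  ok <- !is.na(matched)
  if (sum(ok) < 3L) stop("input error: < 3 pairs overlap the distance table")
  ct <- suppressWarnings(
    stats::cor.test(result$posterior[ok], matched[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = sum(ok))
}
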