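# Felsenstein pruning likelihood and marginal ancestral reconstruction.
#
# Partial likelihoods are propagated postorder with per-site log scaling to
# avoid underflow; discrete-gamma categories are mixed at the site level.
# The outside (root-to-tip) pass reuses the cached per-edge transition
# matrices to give exact marginal posteriors at every internal node.

# integer state matrix (taxa x sites), NA for gap/ambiguity
state_matrix <- function(aln) {
  m <- match(aln$mat, AA_ALPHABET)
  matrix(m, nrow = nrow(aln$mat), dimnames = dimnames(aln$mat))
}

# per-edge, per-category transition matrices for a tree in postorder
edge_pmats <- function(tree, model, rate_scale = 1) {
  rates <- model$rates
  lapply(seq_along(rates), function(k) {
    lapply(seq_len(nrow(tree$edge)), function(i) {
      transition_probabilities(model, tree$edge.length[i] * rate_scale,
                               rates[k])
    })
  })
}

# one postorder pruning pass for one rate category.
# Returns list(partials = list over nodes of 20 x S matrices,
#              logscale = n_node x S accumulated log scalers,
#              site_loglik = per-site log likelihood for this category)
prune_category <- function(tree, states, pmats, pi, n_tip, root) {
  n_sites <- ncol(states)
  n_node <- n_tip + tree$Nnode
  partials <- vector("list", n_node)
  logscale <- matrix(0, n_node, n_sites)
  ones <- matrix(1, 20L, n_sites)
  for (v in (n_tip + 1L):n_node) partials[[v]] <- ones
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    P <- pmats[[i]]
    if (v <= n_tip) {
      s <- states[v, ]
      contrib <- matrix(1, 20L, n_sites)
      obs <- !is.na(s)
      if (any(obs)) contrib[, obs] <- P[, s[obs], drop = FALSE]
    } else {
      contrib <- P %*% partials[[v]]
      logscale[p, ] <- logscale[p, ] + logscale[v, ]
    }
    partials[[p]] <- partials[[p]] * contrib
    if (v > n_tip || i %% 8L == 0L) {
      mx <- apply(partials[[p]], 2L, max)
      mx[mx <= 0] <- 1
      partials[[p]] <- partials[[p]] / rep(mx, each = 20L)
      logscale[p, ] <- logscale[p, ] + log(mx)
    }
  }
  site_loglik <- log(as.vector(pi %*% partials[[root]])) + logscale[root, ]
  list(partials = partials, logscale = logscale, site_loglik = site_loglik)
}

#' Tree log-likelihood under an amino-acid model
#'
#' Felsenstein pruning over the supplied rooted tree, mixing discrete-gamma
#' rate categories (equal weights) at the site level. Gaps and ambiguity
#' codes at the leaves contribute all-ones partial likelihoods.
#'
#' @param aln A [pld_alignment].
#' @param tree A rooted `"phylo"` with branch lengths; leaves must match
#'   the alignment taxa.
#' @param model An [aa_model].
#' @param rate_scale Optional global multiplier on all branch lengths.
#' @return List with `total` log-likelihood and `per_site` vector.
#' @export
tree_log_likelihood <- function(aln, tree, model, rate_scale = 1) {
  validate_tree(tree, aln)
  info <- tree_info(tree)
  tree <- info$tree
  states <- state_matrix(aln)[tree$tip.label, , drop = FALSE]
  if (length(tree$tip.label) == 1L) {
    # single leaf: logL = log pi at each observed state
    s <- states[1L, ]
    per_site <- ifelse(is.na(s), 0, log(model$pi)[s])
    return(list(total = sum(per_site), per_site = per_site))
  }
  pmats <- edge_pmats(tree, model, rate_scale)
  K <- length(model$rates)
  cat_ll <- vapply(seq_len(K), function(k) {
    prune_category(tree, states, pmats[[k]], model$pi,
                   info$n_tip, info$root)$site_loglik
  }, numeric(aln$length))
  cat_ll <- matrix(cat_ll, ncol = K)
  mx <- apply(cat_ll, 1L, max)
  per_site <- mx + log(rowMeans(exp(cat_ll - mx)))
  list(total = sum(per_site), per_site = per_site)
}

#' Marginal ancestral state reconstruction
#'
#' Inside-outside message passing under a reversible model with the root
#' prior equal to the model's equilibrium frequencies. Posteriors are
#' mixture-weighted over the discrete-gamma categories by each category's
#' per-site likelihood. MAP states break ties by alphabetical amino-acid
#' order.
#'
#' @inheritParams tree_log_likelihood
#' @return An object of class `asr` with: `posterior` (list over internal
#'   node ids of 20 x sites matrices), `map_state` / `map_prob` (internal
#'   node x site matrices), `node_ids`, `mean_map`, `sd_map`, `loglik`, and
#'   the inputs (`tree` in postorder, `model`).
#' @export
marginal_ancestral_states <- function(aln, tree, model, rate_scale = 1) {
  validate_tree(tree, aln)
  info <- tree_info(tree)
  tree <- info$tree
  n_tip <- info$n_tip
  n_node <- info$n_node
  root <- info$root
  n_sites <- aln$length
  states <- state_matrix(aln)[tree$tip.label, , drop = FALSE]
  pmats <- edge_pmats(tree, model, rate_scale)
  K <- length(model$rates)
  children <- children_of(tree)
  edge_of_child <- integer(n_node)
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))

  internal <- (n_tip + 1L):n_node
  post <- lapply(internal, function(v) matrix(0, 20L, n_sites))
  names(post) <- as.character(internal)
  cat_sll <- matrix(0, n_sites, K)
  cat_post <- vector("list", K)

  for (k in seq_len(K)) {
    pr <- prune_category(tree, states, pmats[[k]], model$pi, n_tip, root)
    cat_sll[, k] <- pr$site_loglik
    # outside pass (preorder): up[v] is the likelihood of everything
    # outside v's subtree, as a function of v's state
    up <- vector("list", n_node)
    up[[root]] <- matrix(model$pi, 20L, n_sites)
    # per-edge messages child -> parent: P %*% D_child (leaves handled as
    # columns of P); cache for sibling products
    edge_msg <- vector("list", nrow(tree$edge))
    for (i in seq_len(nrow(tree$edge))) {
      v <- tree$edge[i, 2L]
      P <- pmats[[k]][[i]]
      if (v <= n_tip) {
        s <- states[v, ]
        msg <- matrix(1, 20L, n_sites)
        obs <- !is.na(s)
        if (any(obs)) msg[, obs] <- P[, s[obs], drop = FALSE]
      } else {
        msg <- P %*% pr$partials[[v]]  # scaled partials; scale cancels in posterior
      }
      edge_msg[[i]] <- msg
    }
    for (i in rev(seq_len(nrow(tree$edge)))) {  # preorder
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      if (v <= n_tip) next
      sibs <- setdiff(children[[p]], v)
      acc <- up[[p]]
      for (s in sibs) acc <- acc * edge_msg[[edge_of_child[s]]]
      P <- pmats[[k]][[i]]
      up[[v]] <- crossprod(P, acc)   # t(P) %*% acc
      mx <- apply(up[[v]], 2L, max)
      mx[mx <= 0] <- 1
      up[[v]] <- up[[v]] / rep(mx, each = 20L)  # scale; normalised later
    }
    cat_post[[k]] <- lapply(internal, function(v) {
      m <- pr$partials[[v]] * up[[v]]
      tot <- colSums(m)
      tot[tot <= 0] <- 1
      m / rep(tot, each = 20L)
    })
  }
  # category weights per site: P(cat k | data)
  mx <- apply(cat_sll, 1L, max)
  w <- exp(cat_sll - mx)
  w <- w / rowSums(w)
  for (k in seq_len(K)) {
    for (j in seq_along(internal)) {
      post[[j]] <- post[[j]] + cat_post[[k]][[j]] * rep(w[, k], each = 20L)
    }
  }
  map_state <- matrix("", length(internal), n_sites,
                      dimnames = list(as.character(internal), NULL))
  map_prob <- matrix(0, length(internal), n_sites,
                     dimnames = list(as.character(internal), NULL))
  for (j in seq_along(internal)) {
    idx <- apply(post[[j]], 2L, which.max)  # first max = alphabetical tie-break
    map_state[j, ] <- AA_ALPHABET[idx]
    map_prob[j, ] <- post[[j]][cbind(idx, seq_len(n_sites))]
  }
  per_site <- mx + log(rowMeans(exp(cat_sll - mx)))
  structure(list(posterior = post, map_state = map_state, map_prob = map_prob,
                 node_ids = internal, mean_map = mean(map_prob),
                 sd_map = stats::sd(map_prob),
                 loglik = sum(per_site), per_site_loglik = per_site,
                 tree = tree, model = model, taxa = tree$tip.label),
            class = "asr")
}

#' @export
print.asr <- function(x, ...) {
  cat("Marginal ancestral reconstruction:", length(x$node_ids),
      "internal nodes x", ncol(x$map_state), "sites\n")
  cat(sprintf("  mean MAP posterior %.3f +/- %.3f; logL %.3f\n",
              x$mean_map, x$sd_map, x$loglik))
  invisible(x)
}

#' Model choice by Bayesian information criterion
#'
#' Fits each candidate model (optimising the gamma shape where the
#' candidate has one) to the alignment and tree, and ranks candidates by
#' BIC computed with the number of alignment columns as the sample size.
#'
#' @inheritParams tree_log_likelihood
#' @param candidates List of [aa_model] objects; those built with a
#'   non-`NULL` `gamma_shape` have the shape optimised from that start.
#' @return `data.frame` with columns `model`, `gamma`, `shape`, `loglik`,
#'   `k`, `bic`, ordered best (lowest BIC) first; attribute `converged`.
#' @export
select_model_bic <- function(aln, tree, candidates) {
  rows <- lapply(candidates, function(m) {
    shape <- NA_real_
    if (is.null(m$gamma_shape)) {
      ll <- tree_log_likelihood(aln, tree, m)$total
      k <- 0L
    } else {
      opt <- stats::optimize(function(ls) {
        -tree_log_likelihood(aln, tree,
                             aa_model(m$name, gamma_shape = exp(ls), ncat = m$ncat,
                                      exchangeabilities = if (m$name %in% c("custom")) m$S,
                                      frequencies = if (m$name %in% c("custom")) m$pi))$total
      }, interval = log(c(0.05, 30)), tol = 1e-4)
      shape <- exp(opt$minimum)
      ll <- -opt$objective
      k <- 1L
    }
    data.frame(model = m$name,
               gamma = !is.null(m$gamma_shape),
               shape = shape, loglik = ll, k = k,
               bic = -2 * ll + k * log(aln$length))
  })
  out <- do.call(rbind, rows)
  out[order(out$bic), , drop = FALSE]
}

#' Reconstruction-accuracy site filter
#'
#' Sites pass when the minimum MAP posterior over all internal nodes
#' exceeds `threshold` — the site-level counterpart of counting only
#' substitutions whose endpoint reconstructions are confident.
#'
#' @param recon An [marginal_ancestral_states] `asr` object.
#' @param threshold Probability in (0, 1); 0 retains all sites.
#' @return Logical vector over sites.
#' @export
accuracy_filter <- function(recon, threshold) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  apply(recon$map_prob, 2L, min) > threshold
}
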