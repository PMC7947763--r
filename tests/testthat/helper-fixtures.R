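# Shared fixtures, built in code.

# small protein alignment with a gapped reference row
tiny_alignment <- function() {
  pld_alignment(c(ref = "M-KSYG", t2 = "MAKSYG", t3 = "MAKTYG"))
}

# deterministic random alignment over a given tree's tips
random_alignment <- function(tree, n_sites, seed = 1) {
  set.seed(seed)
  rows <- vapply(tree$tip.label, function(i)
    paste0(sample(AA_ALPHABET, n_sites, TRUE), collapse = ""), character(1))
  pld_alignment(rows)
}

# random rooted tree with positive branch lengths
random_tree <- function(n, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# brute-force tree likelihood: sum over all internal-node state
# assignments (equal-rates model); oracle for the pruning algorithm
enumerate_loglik <- function(aln, tree, model) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  states <- match(aln$mat[tree$tip.label, , drop = FALSE], AA_ALPHABET)
  states <- matrix(states, nrow = n_tip)
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    transition_probabilities(model, tree$edge.length[i]))
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(internal))))
  total <- 0
  for (site in seq_len(aln$length)) {
    node_state <- function(v) {
      if (v <= n_tip) rep(states[v, site], nrow(grid))
      else grid[, match(v, internal)]
    }
    lik <- model$pi[grid[, match(n_tip + 1L, internal)]]
    for (i in seq_len(nrow(tree$edge))) {
      a <- node_state(tree$edge[i, 1L])
      b <- node_state(tree$edge[i, 2L])
      term <- ifelse(is.na(b), 1, P[[i]][cbind(a, ifelse(is.na(b), 1L, b))])
      lik <- lik * term
    }
    total <- total + log(sum(lik))
  }
  total
}
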