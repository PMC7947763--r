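#' Read and validate a rooted phylogeny
#'
#' Thin wrapper over [ape::read.tree] that enforces the invariants required
#' downstream: a single root, finite nonnegative branch lengths, and
#' labelled leaves. Trees are used exactly as supplied (no branch-length
#' re-estimation); branch lengths play the role of evolutionary time.
#'
#' @param path Path to a Newick file.
#' @param alignment Optional [pld_alignment] to reconcile leaf labels
#'   against; any mismatch is an error.
#' @return An [ape::read.tree] `"phylo"` object.
#' @export
read_tree <- function(path, alignment = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("format error: could not parse Newick in ", path)
  validate_tree(tree, alignment)
}

validate_tree <- function(tree, alignment = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length))
    stop("format error: tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("format error: branch lengths must be finite and >= 0")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("format error: unlabeled leaves")
  if (anyDuplicated(tree$tip.label)) stop("format error: duplicate leaf labels")
  if (!ape::is.rooted(tree)) stop("format error: tree must be rooted")
  if (!is.null(alignment)) {
    missing <- setdiff(tree$tip.label, alignment$taxa)
    extra <- setdiff(alignment$taxa, tree$tip.label)
    if (length(missing) || length(extra))
      stop("reconciliation error: leaves not in alignment [",
           paste(missing, collapse = ","), "]; taxa not in tree [",
           paste(extra, collapse = ","), "]")
  }
  tree
}

#' Write a tree to Newick
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Precomputed per-tree quantities reused by likelihood and OU code:
# postorder edge matrix, root, per-node depth (root-to-node path length),
# and the tip-pair shared-path matrix s_ij.
tree_info <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  depth <- numeric(n_node)
  # preorder traversal for depths
  pre <- rev(seq_len(nrow(tree$edge)))
  for (i in pre) {
    depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + tree$edge.length[i]
  }
  list(tree = tree, n_tip = n_tip, n_node = n_node, root = root,
       depth = depth)
}

# shared root-to-MRCA path lengths between all tip pairs (vcv of BM with
# unit rate); delegated to ape
shared_path_matrix <- function(tree) {
  ape::vcv(tree)
}

# children list indexed by node
children_of <- function(tree) {
  n_node <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

# for each node, the set of descendant tips (tip indices)
descendant_tips <- function(tree) {
  info <- tree_info(tree)
  tree <- info$tree
  desc <- vector("list", info$n_node)
  for (i in seq_len(info$n_tip)) desc[[i]] <- i
  for (i in seq_len(nrow(tree$edge))) {    # postorder: children first
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}
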