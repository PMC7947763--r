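# Synthetic data generator: trees, site-heterogeneous protein alignments
# with logged true ancestral states and substitution events, clade-biased
# toggle processes, and BM/OU traits. The defaults emulate the structure
# of a mammalian low-complexity domain study: an 85-taxon depth-1
# ultrametric tree, a 160-column alignment with absolutely conserved
# sticker tyrosine columns, fast-toggling two-state phosphosite columns
# (G<->S, A<->T) with a creation bias in one focal clade, a handful of
# conserved phosphosite columns, and JTT+Gamma background evolution.

#' Simulation configuration
#'
#' @param seed Mandatory integer seed; tree, sequences and traits draw
#'   from substreams derived from it.
#' @param n_taxa Number of tips (default 85).
#' @param n_columns Alignment length (default 160).
#' @param tree_mode `"birth_death"` or `"fixed"` (then supply `tree`).
#' @param birth,death Birth-death rates per unit time.
#' @param depth Target root-to-tip depth after rescaling (default 1).
#' @param n_stickers Absolutely conserved tyrosine columns (default 24).
#' @param n_toggle Two-state toggling phosphosite columns (default 24,
#'   split evenly between G/S and A/T).
#' @param n_conserved_phospho Invariant serine phosphosite columns
#'   (default 8; with `n_toggle` they give the 32 phosphosites).
#' @param toggle_rate Total switching rate of a toggle column per unit
#'   branch length (default 0.55).
#' @param toggle_bias Stationary probability of the phosphosite-creating
#'   state (S or T) outside the focal clade (default 0.4: the toggle
#'   chains drift away from phosphosite occupancy).
#' @param root_bias Probability that a toggle column starts in the
#'   creating state at the root (default 0.6, above the stationary value,
#'   so the tree as a whole shows net phosphosite loss while a
#'   creation-biased clade shows net gain).
#' @param clade_bias Multiplier on the creating-direction rate (G->S,
#'   A->T) on focal-clade branches (default 1 = no bias).
#' @param clade_fraction Approximate fraction of tips in the focal clade
#'   (default 0.25); the largest clade not exceeding it is chosen.
#' @param background_model [aa_model] for background columns (default
#'   JTT + Gamma(shape 1), 4 categories).
#' @param background_scale Rate multiplier for background columns
#'   (default 0.08 expected substitutions per site per unit depth).
#' @param trait Trait-process settings for [simulate_trait()]: a list with elements
#'   `process` ("BM", "OU1" or "OU2"), `sigma2`, `alpha`, `theta`,
#'   `theta_clade`, `root_state`.
#' @param tree Fixed `"phylo"` tree for `tree_mode = "fixed"`.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_taxa = 85L, n_columns = 160L,
                              tree_mode = c("birth_death", "fixed"),
                              birth = 1, death = 0.3, depth = 1,
                              n_stickers = 24L, n_toggle = 24L,
                              n_conserved_phospho = 8L,
                              toggle_rate = 0.55, toggle_bias = 0.4,
                              root_bias = 0.6,
                              clade_bias = 1, clade_fraction = 0.25,
                              background_model = NULL,
                              background_scale = 0.08,
                              trait = list(process = "OU1", sigma2 = 4,
                                           alpha = 2, theta = 26,
                                           root_state = 26),
                              tree = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  tree_mode <- match.arg(tree_mode)
  if (is.null(background_model))
    background_model <- aa_model("JTT", gamma_shape = 1, ncat = 4L)
  n_special <- n_stickers + n_toggle + n_conserved_phospho
  if (n_special > n_columns) stop("site classes exceed alignment length")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate (or pass through) a phylogeny
#'
#' Birth-death mode draws a tree with exactly `n_taxa` tips via
#' [ape::rphylo] and rescales branch lengths so the root-to-tip depth
#' equals `depth`. Fixed mode returns the configured tree verbatim.
#'
#' @param config A [simulation_config()].
#' @return Rooted ultrametric `"phylo"`.
#' @export
simulate_tree <- function(config) {
  if (config$tree_mode == "fixed") {
    if (is.null(config$tree)) stop("fixed mode requires a tree")
    return(validate_tree(config$tree))
  }
  set.seed(config$seed + 101L)
  tree <- ape::rphylo(config$n_taxa, birth = config$birth,
                      death = config$death, T0 = 10)
  d <- max(tree_info(tree)$depth)
  tree$edge.length <- tree$edge.length * config$depth / d
  tree$tip.label <- sprintf("t%03d", seq_len(config$n_taxa))
  tree
}

# pick the focal clade: the clade whose tip count is largest while not
# exceeding clade_fraction * n (deterministic given the tree)
pick_focal_clade <- function(tree, fraction) {
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  sizes <- vapply(desc, length, integer(1))
  cand <- which(sizes >= 2L & sizes <= max(2L, floor(fraction * n)))
  cand <- cand[cand > n]                      # internal nodes only
  if (!length(cand)) stop("no candidate focal clade on this tree")
  node <- cand[which.max(sizes[cand])]
  tree$tip.label[desc[[node]]]
}

# deterministic column layout for the synthetic domain
site_class_layout <- function(config) {
  n <- config$n_columns
  cls <- rep("background", n)
  special <- config$n_stickers + config$n_toggle + config$n_conserved_phospho
  pos <- round(seq(1, n, length.out = special))
  pos <- unique(pmin(pmax(pos, 1L), n))
  ords <- rep(c("sticker", "toggle_gs", "toggle_at", "phospho_const"),
              c(config$n_stickers,
                ceiling(config$n_toggle / 2), floor(config$n_toggle / 2),
                config$n_conserved_phospho))
  # interleave classes along the domain
  ords <- sample_interleave(ords)
  cls[pos] <- ords[seq_along(pos)]
  cls
}

# deterministic round-robin interleave of class labels
sample_interleave <- function(labels) {
  groups <- split(seq_along(labels), labels)
  out <- character(length(labels))
  i <- 1L
  while (any(lengths(groups) > 0L)) {
    for (g in names(groups)) {
      if (length(groups[[g]])) {
        out[i] <- g
        groups[[g]] <- groups[[g]][-1L]
        i <- i + 1L
      }
    }
  }
  out
}

# 2-state transition probability for the toggle chain with rates
# r01 (state1 -> state2) and r10
toggle_pmat <- function(r01, r10, t) {
  tot <- r01 + r10
  if (tot == 0) return(diag(2))
  e <- exp(-tot * t)
  p1 <- r10 / tot  # stationary prob of state 1
  matrix(c(p1 + (1 - p1) * e, 1 - p1 - (1 - p1) * e,
           p1 - p1 * e, 1 - p1 + p1 * e),
         2L, 2L, byrow = TRUE)
}

#' Simulate a site-heterogeneous protein alignment with logged truth
#'
#' Root states are drawn from each site class's stationary distribution
#' and evolved tip-ward by exact transition probabilities per branch:
#' sticker and constant-phosphosite columns are invariant, toggle columns
#' follow a two-state chain embedded in the 20-state alphabet (with the
#' creating direction multiplied by `clade_bias` on focal-clade branches),
#' and background columns evolve under the configured model with per-site
#' discrete-gamma rates. Events are logged as net endpoint changes per
#' branch — exactly what ancestral-state mapping can recover.
#'
#' @param tree A rooted `"phylo"`.
#' @param config A [simulation_config()].
#' @return List with `alignment` (a [pld_alignment]), `truth` (list:
#'   `ancestral` character matrix node x site, `events` data.frame,
#'   `site_class`, `site_rate`, `focal_clade`, `clade_branches`), and
#'   `region_config` (a resolved [region_config] describing the layout).
#' @export
simulate_alignment <- function(tree, config) {
  set.seed(config$seed + 202L)
  info <- tree_info(tree)
  tree <- info$tree
  n_tip <- info$n_tip
  n_node <- info$n_node
  n <- config$n_columns
  cls <- site_class_layout(config)
  model <- config$background_model
  focal <- pick_focal_clade(tree, config$clade_fraction)
  cb <- clade_branches(tree, focal, include_stem = TRUE)

  # per-site gamma rate category for background columns
  rates <- model$rates
  site_rate <- rep(1, n)
  bg <- which(cls == "background")
  site_rate[bg] <- sample(rates, length(bg), replace = TRUE)

  toggle_states <- list(toggle_gs = c("G", "S"), toggle_at = c("A", "T"))
  # root sequence
  root_seq <- character(n)
  root_seq[cls == "sticker"] <- "Y"
  root_seq[cls == "phospho_const"] <- "S"
  for (tc in names(toggle_states)) {
    idx <- which(cls == tc)
    root_seq[idx] <- sample(toggle_states[[tc]], length(idx), replace = TRUE,
                            prob = c(1 - config$root_bias, config$root_bias))
  }
  root_seq[bg] <- sample(AA_ALPHABET, length(bg), replace = TRUE,
                         prob = model$pi)

  seqs <- matrix(NA_character_, n_node, n)
  seqs[info$root, ] <- root_seq
  events <- vector("list", nrow(tree$edge))
  # creating direction is state1 -> state2 (G->S, A->T)
  r_create <- config$toggle_rate * config$toggle_bias
  r_destroy <- config$toggle_rate * (1 - config$toggle_bias)

  for (i in rev(seq_len(nrow(tree$edge)))) {   # preorder
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    t <- tree$edge.length[i]
    parent <- seqs[p, ]
    child <- parent
    # toggle columns
    mult <- if (i %in% cb) config$clade_bias else 1
    P2 <- toggle_pmat(r_create * mult, r_destroy, t)
    for (tc in names(toggle_states)) {
      idx <- which(cls == tc)
      if (!length(idx)) next
      st <- match(parent[idx], toggle_states[[tc]])
      child[idx] <- toggle_states[[tc]][
        1L + (stats::runif(length(idx)) > P2[st, 1L])]
    }
    # background columns, grouped by rate category
    for (r in unique(site_rate[bg])) {
      idx <- bg[site_rate[bg] == r]
      P <- transition_probabilities(model, t * config$background_scale, r)
      st <- match(parent[idx], AA_ALPHABET)
      cp <- t(apply(P[st, , drop = FALSE], 1L, cumsum))
      u <- stats::runif(length(idx))
      child[idx] <- AA_ALPHABET[rowSums(cp < u) + 1L]
    }
    seqs[v, ] <- child
    ch <- which(child != parent)
    if (length(ch))
      events[[i]] <- data.frame(branch = i, parent_node = p, child_node = v,
                                site = ch, from = parent[ch], to = child[ch])
  }
  ev <- do.call(rbind, events)
  if (is.null(ev))
    ev <- data.frame(branch = integer(), parent_node = integer(),
                     child_node = integer(), site = integer(),
                     from = character(), to = character())
  rownames(ev) <- NULL

  rows <- apply(seqs[seq_len(n_tip), , drop = FALSE], 1L, paste0, collapse = "")
  names(rows) <- tree$tip.label
  aln <- pld_alignment(rows)

  phospho_cols <- which(cls %in% c("toggle_gs", "toggle_at", "phospho_const"))
  rc <- region_config(reference = tree$tip.label[1L],
                      regions = list(domain = c(1L, n)),
                      phosphosites = phospho_cols,
                      stickers = which(cls == "sticker"),
                      clades = list(focal = focal))
  rc <- resolve_config(rc, aln)

  list(alignment = aln,
       truth = list(ancestral = seqs, events = ev, site_class = cls,
                    site_rate = site_rate, focal_clade = focal,
                    clade_branches = cb, tree = tree),
       region_config = rc)
}

#' Simulate a continuous trait on a tree (BM or OU)
#'
#' Exact transition sampling from root to tips: under OU the child value is
#' `N(parent * e^(-alpha t) + theta (1 - e^(-alpha t)),
#' sigma2/(2 alpha) (1 - e^(-2 alpha t)))`; under BM `N(parent, sigma2 t)`.
#' For `"OU2"` the focal clade's branches (painting supplied via `clades`)
#' use `theta_clade`.
#'
#' @param tree A rooted `"phylo"`.
#' @param process `"BM"`, `"OU1"` or `"OU2"`.
#' @param sigma2 Drift variance rate (>= 0).
#' @param alpha Selection strength (> 0 for OU).
#' @param theta Optimum (OU); `theta_clade` the focal-clade optimum (OU2).
#' @param root_state Trait value at the root.
#' @param clades Named list of clades for `"OU2"` painting.
#' @param seed Integer seed.
#' @return List: `tip` (named vector), `node` (all node values), `painting`.
#' @export
simulate_trait <- function(tree, process = c("BM", "OU1", "OU2"),
                           sigma2 = 1, alpha = 1, theta = 0,
                           theta_clade = NULL, root_state = theta,
                           clades = list(), seed) {
  process <- match.arg(process)
  if (!missing(seed)) set.seed(seed + 303L)
  if (process != "BM" && alpha <= 0) stop("input error: alpha must be > 0 for OU")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  info <- tree_info(tree)
  tree <- info$tree
  painting <- if (process == "OU2") {
    if (is.null(theta_clade) || !length(clades))
      stop("OU2 needs theta_clade and a clade definition")
    paint_regimes(tree, clades)
  } else paint_regimes(tree)
  vals <- numeric(info$n_node)
  vals[info$root] <- root_state
  for (i in rev(seq_len(nrow(tree$edge)))) {   # preorder
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    t <- tree$edge.length[i]
    if (process == "BM") {
      vals[v] <- stats::rnorm(1, vals[p], sqrt(sigma2 * t))
    } else {
      th <- if (painting[i] == "background" || process != "OU2") theta
            else theta_clade
      e <- exp(-alpha * t)
      m <- vals[p] * e + th * (1 - e)
      s2 <- sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t))
      vals[v] <- stats::rnorm(1, m, sqrt(s2))
    }
  }
  tip <- stats::setNames(vals[seq_len(info$n_tip)], tree$tip.label)
  list(tip = tip, node = vals, painting = painting)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: simulates the tree, the alignment with truth, and
#' a trait, all from one seed.
#'
#' @param config A [simulation_config()].
#' @return List: `tree`, `alignment`, `truth`, `region_config`, `trait`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_tree(config)
  sim <- simulate_alignment(tree, config)
  tr <- config$trait
  trait <- simulate_trait(tree, process = tr$process,
                          sigma2 = tr$sigma2,
                          alpha = if (is.null(tr$alpha)) 1 else tr$alpha,
                          theta = if (is.null(tr$theta)) 0 else tr$theta,
                          theta_clade = tr$theta_clade,
                          root_state = if (is.null(tr$root_state))
                            tr$theta else tr$root_state,
                          clades = list(focal = sim$truth$focal_clade),
                          seed = config$seed)
  list(tree = tree, alignment = sim$alignment, truth = sim$truth,
       region_config = sim$region_config, trait = trait)
}
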