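test_that("trees are reproducible, correctly sized and depth-rescaled", {
  cfg <- simulation_config(seed = 4, n_taxa = 40)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_equal(length(t1$tip.label), 40L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(max(tree_info(t1)$depth), 1, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))
  # fixed mode returns the input verbatim
  fx <- simulation_config(seed = 1, tree_mode = "fixed", tree = t1)
  expect_identical(simulate_tree(fx), t1)
  expect_error(simulate_tree(simulation_config(seed = 1, tree_mode = "fixed")),
               "requires a tree")
})

test_that("simulated alignments honour site classes and log a consistent truth", {
  cfg <- simulation_config(seed = 11, n_taxa = 30, n_columns = 80)
  ds <- simulate_dataset(cfg)
  aln <- ds$alignment
  cls <- ds$truth$site_class
  expect_equal(aln$length, 80L)
  # sticker columns: invariant Y across all taxa and all ancestors
  st <- which(cls == "sticker")
  expect_true(all(aln$mat[, st] == "Y"))
  expect_true(all(ds$truth$ancestral[, st] == "Y"))
  # toggle columns stay within their two-state alphabets
  expect_true(all(aln$mat[, cls == "toggle_gs"] %in% c("G", "S")))
  expect_true(all(aln$mat[, cls == "toggle_at"] %in% c("A", "T")))
  # replay: events applied from the root reproduce every node sequence
  tree <- ds$truth$tree
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    s <- ds$truth$ancestral[p, ]
    ev <- ds$truth$events[ds$truth$events$branch == i, ]
    s[ev$site] <- ev$to
    expect_identical(s, ds$truth$ancestral[v, ])
  }
  # determinism
  ds2 <- simulate_dataset(simulation_config(seed = 11, n_taxa = 30,
                                            n_columns = 80))
  expect_identical(ds2$alignment$mat, aln$mat)
  expect_identical(ds2$truth$events, ds$truth$events)
})

test_that("single-branch transition frequencies match the model", {
  # a long cherry simulated many times over independent columns acts as
  # a Monte-Carlo check of the exact transition probabilities
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cfg <- simulation_config(seed = 8, tree_mode = "fixed", tree = tr,
                           n_taxa = 2, n_columns = 3000, n_stickers = 0,
                           n_toggle = 1000, n_conserved_phospho = 0,
                           toggle_rate = 0.8, toggle_bias = 0.5,
                           root_bias = 0.5,
                           background_scale = 0.5)
  sim <- simulate_alignment(tr, cfg)
  cls <- sim$truth$site_class
  anc <- sim$truth$ancestral
  root <- 3L  # two tips -> root node id 3
  # toggle columns: P(change along one branch of length 1)
  gs <- which(cls == "toggle_gs")
  p_change_emp <- mean(anc[1, gs] != anc[root, gs])
  P2 <- toggle_pmat(0.4, 0.4, 1)
  p_change <- P2[1, 2]
  sem <- sqrt(p_change * (1 - p_change) / length(gs))
  expect_lt(abs(p_change_emp - p_change), 3 * sem + 1e-9)
  # background columns: aggregate same-state probability under JTT+G
  bg <- which(cls == "background")
  model <- cfg$background_model
  same_emp <- mean(anc[1, bg] == anc[root, bg])
  # expectation over root frequencies and the site-rate mixture
  rates <- model$rates
  same_theo <- mean(vapply(rates, function(r) {
    P <- transition_probabilities(model, 0.5, r)  # t * background_scale
    sum(model$pi * diag(P))
  }, numeric(1)))
  sem2 <- sqrt(same_theo * (1 - same_theo) / length(bg))
  expect_lt(abs(same_emp - same_theo), 4 * sem2)
})

test_that("clade bias raises the realized creation/destruction ratio in the clade", {
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = s, n_taxa = 50, clade_bias = 5)
    ds <- simulate_dataset(cfg)
    ev <- ds$truth$events
    key <- paste0(ev$from, ">", ev$to)
    inb <- ev$branch %in% ds$truth$clade_branches
    r <- function(idx) {
      cr <- sum(key[idx] %in% c("G>S", "A>T"))
      de <- sum(key[idx] %in% c("S>G", "T>A"))
      (cr + 0.5) / (de + 0.5)
    }
    r(inb) > r(!inb)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trait simulation follows the exact moments and the seed", {
  # sigma2 = 0: everything equals the root value
  tr <- random_tree(10, seed = 2)
  z <- simulate_trait(tr, "BM", sigma2 = 0, root_state = 7, seed = 2)
  expect_true(all(z$node == 7))
  # OU stationary moments on a deep star tree
  star <- ape::stree(4000, "star")
  star$edge.length <- rep(6, 4000)   # alpha * T = 12 >> 1
  w <- simulate_trait(star, "OU1", sigma2 = 3, alpha = 2, theta = 5,
                      root_state = 0, seed = 3)$tip
  expect_equal(mean(w), 5, tolerance = 4 * sqrt(3 / 4 / 4000))
  expect_equal(stats::var(w), 3 / 4, tolerance = 0.1)
  # determinism
  w2 <- simulate_trait(star, "OU1", sigma2 = 3, alpha = 2, theta = 5,
                       root_state = 0, seed = 3)$tip
  expect_identical(w, w2)
  expect_error(simulate_trait(tr, "OU1", alpha = -1, seed = 1), "input error")
})
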