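test_that("event mapping records MAP differences and honours the support filter", {
  # two-taxon tree: ancestor MAP vs leaf states
  m <- aa_model("JTT")
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  aln <- pld_alignment(c(A = "GYS-", B = "SYSA"))
  rec <- marginal_ancestral_states(aln, tr, m)
  ev <- map_substitutions(rec, aln, min_posterior = 0)
  # site 2, 3 identical; site 4 has missing data in A -> event only on B's
  # branch if MAP differs; site 1 G/S differs from the MAP on one branch
  expect_true(all(ev$from != ev$to))
  expect_true(all(ev$site %in% c(1L, 4L)))
  # support filter removes low-confidence events
  ev9 <- map_substitutions(rec, aln, min_posterior = 0.99)
  expect_lte(nrow(ev9), nrow(ev))
  # event conservation: exchange matrix total equals table length
  for (mp in c(0, 0.5, 0.9)) {
    e <- map_substitutions(rec, aln, min_posterior = mp)
    expect_equal(sum(exchange_matrix(e)), nrow(e))
  }
})

test_that("exchange matrix counts and toggle summaries are exact", {
  ev <- data.frame(branch = 1L, parent_node = 1L, child_node = 2L,
                   site = 1:30,
                   from = c(rep("G", 10), rep("S", 5), rep("A", 3),
                            rep("T", 2), rep("Q", 10)),
                   to = c(rep("S", 10), rep("G", 5), rep("T", 3),
                          rep("A", 2), rep("P", 10)),
                   support = 1)
  class(ev) <- c("substitution_events", "data.frame")
  m <- exchange_matrix(ev)
  expect_equal(m["G", "S"], 10L)
  expect_equal(m["S", "G"], 5L)
  expect_equal(sum(m), 30L)
  expect_equal(sum(diag(m)), 0L)
  tog <- toggle_summary(m)
  expect_equal(unname(tog$pair_counts), c(15, 5))
  expect_equal(tog$fraction, 20 / 30)
  # only-toggle matrix gives fraction 1
  only <- exchange_matrix(ev[1:15, ])
  expect_equal(toggle_summary(only, list(c("G", "S")))$fraction, 1)
  # empty table: zero matrix, undefined fraction
  empty <- exchange_matrix(ev[0, ])
  expect_equal(sum(empty), 0L)
  expect_true(is.na(toggle_summary(empty)$fraction))
})

test_that("phosphosite trait equals a direct residue scan", {
  set.seed(31)
  tr <- random_tree(12, seed = 31)
  aln <- random_alignment(tr, 40, seed = 31)
  sites <- sort(sample(40, 10))
  cfg <- resolve_config(region_config(aln$taxa[1], phosphosites = sites), aln)
  ph <- phosphosite_trait(aln, cfg)
  brute <- apply(aln$mat[, cfg$phosphosite_columns, drop = FALSE], 1L,
                 function(r) sum(r == "S" | r == "T"))
  expect_equal(ph, brute)
  all_st <- pld_alignment(c(x = paste(rep("S", 40), collapse = "")))
  cfg2 <- resolve_config(region_config("x", phosphosites = sites), all_st)
  expect_equal(unname(phosphosite_trait(all_st, cfg2)), 10)
  no_st <- pld_alignment(c(x = paste(rep("G", 40), collapse = "")))
  cfg3 <- resolve_config(region_config("x", phosphosites = sites), no_st)
  expect_equal(unname(phosphosite_trait(no_st, cfg3)), 0)
})

test_that("creation/destruction ratios stratify by clade and swap correctly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr <- stats::reorder(tr, "postorder")
  sites <- c(2L, 5L)
  desc <- descendant_tips(tr)
  ab_node <- which(vapply(desc, function(d)
    setequal(tr$tip.label[d], c("A", "B")), logical(1)))
  ab_edges <- which(tr$edge[, 1] == ab_node | tr$edge[, 2] == ab_node)
  in_edge <- which(tr$edge[, 2] %in% match(c("A", "B"), tr$tip.label))[1]
  out_edge <- which(tr$edge[, 2] %in% match(c("C", "D"), tr$tip.label))[1]
  ev <- data.frame(branch = c(in_edge, in_edge, in_edge, out_edge),
                   parent_node = 0L, child_node = 0L,
                   site = c(2L, 2L, 5L, 2L),
                   from = c("G", "A", "G", "S"),
                   to = c("S", "T", "S", "G"), support = 1)
  class(ev) <- c("substitution_events", "data.frame")
  attr(ev, "tree") <- tr
  cfg <- region_config("A", phosphosites = sites,
                       clades = list(ab = c("A", "B")))
  cfg$phosphosite_columns <- sites
  cd <- creation_destruction_table(ev, cfg, "ab")
  expect_equal(cd$table["creating", "clade"], 3)
  expect_equal(cd$table["destroying", "background"], 1)
  expect_equal(cd$ratio_clade, Inf)
  expect_equal(cd$ratio_total, 3 / 1)
  # swapping creating/destroying labels inverts the ratio
  ev_sw <- ev
  ev_sw$from <- ev$to; ev_sw$to <- ev$from
  attr(ev_sw, "tree") <- tr
  cd_sw <- creation_destruction_table(ev_sw, cfg, "ab")
  expect_equal(cd_sw$ratio_total, 1 / cd$ratio_total)
  expect_error(creation_destruction_table(ev, cfg, character()), "empty clade")
})

test_that("Fisher exact matches hypergeometric enumeration on worked cases", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-12)
  # proportional rows are independent
  expect_equal(fisher_exact(matrix(c(4, 2, 6, 3), 2, 2, byrow = TRUE)), 1)
  # zero margin convention
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 5), 2, 2, byrow = TRUE)), 1)
  # random spot-check against the independent stats::fisher.test route
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + 1, 2, 2)
    expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Nei-Gojobori counting matches hand cases and the pathway oracle", {
  code <- genetic_code()
  same <- pairwise_dnds("ATGAAA", "ATGAAA")
  expect_equal(same$dn, 0)
  expect_equal(same$ds, 0)
  # TTT -> TTC is one synonymous difference (Phe -> Phe)
  d <- pairwise_dnds("TTT", "TTC")
  expect_equal(d$syn_diffs, 1)
  expect_equal(d$nonsyn_diffs, 0)
  expect_equal(d$dn, 0)
  # site counts: both TTT and TTC have a 1/3-synonymous third position,
  # averaged over the two sequences
  expect_equal(d$syn_sites, 1 / 3, tolerance = 1e-12)

  # two-hit codon with pathway averaging: TTT (F) -> GTA (V)
  # path1 TTT->GTT(V)->GTA(V): 1 nonsyn + 1 syn; path2 TTT->TTA(L)->GTA(V): 2 nonsyn
  d2 <- pairwise_dnds("TTT", "GTA")
  expect_equal(d2$syn_diffs, 0.5, tolerance = 1e-12)
  expect_equal(d2$nonsyn_diffs, 1.5, tolerance = 1e-12)

  # randomized pairs: counts equal the brute-force codon-wise oracle
  set.seed(17)
  codons <- names(code)[code != "*"]
  for (rep in 1:5) {
    n <- 30
    a <- sample(codons, n, TRUE)
    b <- a
    mut <- sample(n, 8)
    b[mut] <- sample(codons, 8, TRUE)
    est <- pairwise_dnds(paste(a, collapse = ""), paste(b, collapse = ""))
    oracle <- colSums(t(vapply(seq_len(n), function(i)
      codon_path_diffs(a[i], b[i], code), numeric(2))))
    expect_equal(est$syn_diffs, unname(oracle["syn"]), tolerance = 1e-12)
    expect_equal(est$nonsyn_diffs, unname(oracle["nonsyn"]), tolerance = 1e-12)
  }
  expect_error(pairwise_dnds("TAA", "TAA"), "stop")
})

test_that("site-class rate comparison flags faster classes", {
  # identical distributions give p near 1
  rates <- stats::setNames(rep(2, 20), 1:20)
  same <- site_class_rate_compare(rates, 1:10, 11:20)
  expect_gt(same$p_value, 0.9)
  # clearly faster class
  rates2 <- stats::setNames(c(rep(10, 10), rep(1, 10)), 1:20)
  fast <- site_class_rate_compare(rates2, 1:10, 11:20)
  expect_lt(fast$p_value, 0.001)
  # single-site classes exercise the exact small-sample path
  tiny <- site_class_rate_compare(stats::setNames(c(3, 1), 1:2), 1, 2)
  expect_true(tiny$p_value <= 1)
})
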