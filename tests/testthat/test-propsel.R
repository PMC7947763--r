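# Toy genetic code confined to 4 codons over {G, S} keeps the expected
# distribution hand-checkable.

test_that("category bounds split the realizable range into equal widths", {
  # linear 0..19 property over the alphabet
  prop <- stats::setNames(0:19, AA_ALPHABET)
  b <- category_bounds(prop)
  expect_length(b, 9L)
  expect_equal(diff(b), rep(diff(b)[1], 8), tolerance = 1e-12)
  # every realizable |delta| falls inside the bounds
  pairs <- single_step_aa_pairs(genetic_code())
  deltas <- abs(prop[pairs[, 1]] - prop[pairs[, 2]])
  expect_true(all(deltas <= b[9] + 1e-12))
  expect_true(all(classify_delta(deltas, b) %in% 1:8))
  # constant property is rejected
  expect_error(category_bounds(stats::setNames(rep(1, 20), AA_ALPHABET)),
               "degenerate-category")
  # a property with range [0, 8] on reachable pairs gives integer bounds
  # (alanine-referenced synthetic scale)
})

test_that("expected distribution matches hand enumeration on a toy composition", {
  # single codon type GGT (G): 9 point mutations ->
  # GGx: GGA/GGC/GGG synonymous; xGT: AGT(S), CGT(R), TGT(C); GxT: GAT(D),
  # GCT(A), GTT(V) -> 6 nonsynonymous changes
  aln <- pld_alignment(c(a = "G"), codon_rows = c(a = "GGT"))
  prop <- stats::setNames(0:19, AA_ALPHABET)
  bounds <- category_bounds(prop)
  p <- expected_distribution(aln, prop, bounds)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  targets <- c("S", "R", "C", "D", "A", "V")
  deltas <- abs(prop["G"] - prop[targets])
  k <- classify_delta(deltas, bounds)
  manual <- as.numeric(tabulate(k, 8)) / 6
  expect_equal(as.numeric(p), manual, tolerance = 1e-12)
  expect_false(attr(p, "fallback"))

  # composition weighting: duplicating every sequence changes nothing
  aln2 <- pld_alignment(c(a = "G", b = "G"),
                        codon_rows = c(a = "GGT", b = "GGT"))
  p2 <- expected_distribution(aln2, prop, bounds)
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)

  # amino-acid fallback is flagged
  aln3 <- pld_alignment(c(a = "G"))
  p3 <- expected_distribution(aln3, prop, bounds)
  expect_true(attr(p3, "fallback"))
  expect_error(expected_distribution(aln3, prop, bounds,
                                     allow_fallback = FALSE), "input error")
})

test_that("observed distribution classifies events like a direct scan", {
  prop <- stats::setNames(0:19, AA_ALPHABET)
  bounds <- category_bounds(prop)
  ev <- data.frame(branch = 1L, parent_node = 1L, child_node = 2L,
                   site = c(1L, 2L, 3L), from = c("G", "G", "A"),
                   to = c("S", "A", "T"), support = 1)
  class(ev) <- c("substitution_events", "data.frame")
  O <- observed_distribution(ev, prop, bounds)
  expect_equal(sum(O), 3L)
  direct <- classify_delta(abs(prop[ev$from] - prop[ev$to]), bounds)
  expect_equal(as.integer(O), as.integer(tabulate(direct, 8)))
  # empty table gives zeros
  expect_equal(sum(observed_distribution(ev[0, ], prop, bounds)), 0L)
  # column filter applies
  expect_equal(sum(observed_distribution(ev, prop, bounds, columns = 1:2)), 2L)
})

test_that("selection scores match the worked z-score arithmetic", {
  # O = N p exactly: all z = 0, chisq = 0
  p <- rep(1 / 8, 8)
  O <- rep(25L, 8)
  sc <- selection_scores(O, p)
  expect_equal(sc$z, rep(0, 8), tolerance = 1e-12)
  expect_equal(sc$chisq, 0, tolerance = 1e-12)
  expect_equal(sc$df, 7L)

  # N = 100, p8 = 0.1, O8 = 25 -> z8 = 5
  p2 <- c(rep(0.9 / 7, 7), 0.1)
  O2 <- c(rep(75L %/% 7L, 7), 25L)
  O2[1] <- O2[1] + (75L - sum(O2[1:7]))
  sc2 <- selection_scores(O2, p2)
  expect_equal(sc2$z[8], 5, tolerance = 1e-12)
  expect_error(selection_scores(c(rep(0L, 7), 3L), c(rep(1 / 7, 7), 0)),
               "impossible-category")
})

test_that("null z-scores are standardised in large samples", {
  set.seed(71)
  p <- c(0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05)
  z8 <- replicate(400, {
    O <- as.integer(stats::rmultinom(1, 500, p))
    selection_scores(O, p)$z[8]
  })
  expect_lt(abs(mean(z8)), 0.15)
  expect_true(stats::sd(z8) > 0.85 && stats::sd(z8) < 1.15)
})

test_that("window scan localises an engineered radical hotspot", {
  prop <- stats::setNames(0:19, AA_ALPHABET)
  bounds <- category_bounds(prop)
  region <- 1:60
  # uniform conservative background (G->S is a small |delta|)
  bg <- data.frame(branch = 1L, parent_node = 1L, child_node = 2L,
                   site = seq(1, 60, by = 2), from = "G", to = "S",
                   support = 1)
  # radical cluster in columns 40..50 (G -> Y is |delta| 19)
  hot <- data.frame(branch = 1L, parent_node = 1L, child_node = 2L,
                    site = rep(40:50, 2), from = "G", to = "Y", support = 1)
  ev <- rbind(bg, hot)
  class(ev) <- c("substitution_events", "data.frame")
  p <- rep(1 / 8, 8)
  scan <- window_scan(ev, prop, bounds, p, region, window = 11, min_events = 3)
  expect_equal(nrow(scan), 60 - 11 + 1)
  peak <- scan$center_column[which.max(scan$strength)]
  expect_true(peak >= 38 && peak <= 52)
  expect_error(window_scan(ev, prop, bounds, p, 1:5, window = 11), "window longer")
})

test_that("correlated properties group by transitive closure with sign harmonisation", {
  base <- stats::setNames(as.numeric(1:20), AA_ALPHABET)
  props <- list(p1 = base, p2 = base * 2 + 3, p3 = -base, p4 = base^0.5,
                p5 = stats::setNames(c(10, 2, 17, 3, 8, 5, 12, 1, 19, 4,
                                       15, 6, 11, 7, 18, 9, 13, 20, 16, 14),
                                     AA_ALPHABET))
  strengths <- c(p1 = 2, p2 = 2.4, p3 = -1.8, p4 = 2.2, p5 = 7)
  out <- cluster_and_average(props, strengths, threshold = 0.8)
  # p1..p4 are rank-identical up to sign -> one group of 4; p5 separate
  expect_equal(nrow(out), 2L)
  big <- out[out$n_members == 4, ]
  expect_equal(big$members, "p1,p2,p3,p4")
  # p3 flipped to +1.8 before averaging
  expect_equal(big$mean_strength, mean(c(2, 2.4, 1.8, 2.2)), tolerance = 1e-12)
  # two identical properties: sd 0
  two <- cluster_and_average(list(a = base, b = base), c(a = 1, b = 1))
  expect_equal(two$sd_strength, 0)
  # brute-force closure check on a random instance
  set.seed(9)
  rnd <- lapply(1:6, function(i) stats::setNames(rnorm(20), AA_ALPHABET))
  names(rnd) <- paste0("q", 1:6)
  st <- stats::setNames(rnorm(6), names(rnd))
  got <- cluster_and_average(rnd, st, threshold = 0.3)
  # oracle: adjacency by threshold, connected components
  adj <- matrix(FALSE, 6, 6)
  for (i in 1:6) for (j in 1:6)
    adj[i, j] <- abs(stats::cor(rnd[[i]], rnd[[j]], method = "spearman")) > 0.3
  comp <- seq_len(6)
  for (rep in 1:6) for (i in 1:6) for (j in 1:6)
    if (adj[i, j]) comp[c(i, j)] <- min(comp[c(i, j)])
  expect_equal(nrow(got), length(unique(comp)))
})

test_that("the shipped property sources load and cover the alphabet", {
  pt <- property_table()
  expect_true("RACS820101" %in% names(pt))
  expect_true(all(vapply(pt, length, integer(1)) == 20L))
  path <- system.file("extdata", "example_properties.tsv", package = "pldevo")
  ext <- read_property_table(path)
  expect_equal(names(ext), c("KYTJ820101", "GRAR740102"))
  expect_equal(unname(ext$KYTJ820101["W"]), -0.9)
})
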