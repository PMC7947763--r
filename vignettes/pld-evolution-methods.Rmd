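---
title: "Models and methods for prion-like domain evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for prion-like domain evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldevo)
```

This vignette is the package's account of the science behind each stage:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real data.

## The biological setting

Prion-like domains (PLDs) are low-complexity, intrinsically disordered
regions enriched in glycine, serine, glutamine and tyrosine. In
phase-separating proteins such as FUS, the tyrosines act as *stickers*
whose interactions drive condensation, the segments between them act as
flexible *spacers*, and a set of serine/threonine *phosphosites* tunes the
material state of the condensate. The package asks how such a domain
evolves on a fixed species phylogeny: which columns are frozen, which
toggle rapidly between chemically similar residues (G↔S, A↔T), whether
phosphosite numbers drift or are held at an optimum, which physicochemical
properties selection conserves or diversifies, and which sites change
together.

## Conservation profiling

Column conservation is summarised by Shannon entropy
$H_j = -\sum_a p_{aj}\log p_{aj}$ over the residues observed in column
$j$. Two choices matter:

* **Gap handling.** Gaps and ambiguity codes (X, B, Z, ...) are excluded
  from the frequency counts rather than treated as a 21st state. The
  intended inputs are nearly gap-free ortholog alignments, where a gap is
  missing data, not a character state. An all-missing column reports `NA`,
  never 0 — zero entropy means *conserved*, which an empty column is not.
* **Base.** Natural log by default, base 2 available. Every quantity of
  interest downstream (fold differences, rank-sum comparisons) is
  invariant to the base.

Region comparisons use the Wilcoxon rank-sum test: exact enumeration when
the combined sample is at most 12 without ties (so small fixtures are
verifiable by hand), and the tie-corrected normal approximation otherwise.

## Substitution models and ancestral reconstruction

The reconstruction machinery is a standard time-reversible 20-state
continuous-time Markov chain. Exchangeabilities and equilibrium
frequencies come from empirical models (JTT by default; LG, WAG, Dayhoff,
or any matrix in the documented plain-text format, e.g. one trained on
disordered mammalian proteins). The rate matrix is normalised to one
expected substitution per site per unit branch length, so branch lengths
keep their supplied units; trees are used exactly as given, with no
branch-length re-estimation. An optional global rate multiplier is the
only scale parameter.

Rate heterogeneity across sites uses the discrete-gamma approximation
with 4 categories by default; category rates are the conditional means of
the quantile bins, so they average exactly 1. Changing 4 to 8 categories
moves fixture log-likelihoods by well under 0.5%, which is the usual
justification for the cheaper setting.

Likelihoods are computed by Felsenstein pruning with per-site scaling;
marginal ancestral posteriors by an inside–outside pass, with category
posteriors mixed by each category's per-site likelihood. Conventions:

* the root prior is the model's equilibrium distribution (the reversible
  convention);
* leaf gaps/ambiguities contribute all-ones partials (missing data);
* MAP ties break by alphabetical amino-acid order, for determinism;
* model choice is by BIC with the number of columns as the sample size,
  optimising the gamma shape per candidate.

The "reconstruction accuracy" of a site or an event is its MAP posterior.
Two filters are available: a per-site filter (minimum MAP posterior over
all internal nodes, `accuracy_filter()`) and a per-event filter (minimum
of the two endpoint posteriors, the `min_posterior` argument of
`map_substitutions()`). The per-event form is the default for
substitution counting, because an event only needs its own two endpoints
to be credible; the per-site form is stricter and suits column-level
summaries.

## Substitution mapping and phosphosite accounting

An event is recorded where the MAP state (or observed leaf residue)
differs across a branch. This assigns each event to a single branch and
deliberately ignores multiple hits within one branch: with endpoint
reconstructions only, within-branch multiple hits are unidentifiable, and
the synthetic generator logs exactly the same "net endpoint change"
notion so that recovery metrics compare like with like.

Phosphosite occupancy is the count of configured phosphosite columns
holding S or T. Creation events are G→S and A→T; destruction events are
the reverses. The clade stratification assigns a branch to the clade iff
all its descendant leaves are clade members; the stem branch is included
by default (`include_stem = FALSE` available — which convention the
underlying data supports is genuinely ambiguous, so both are provided).
Ratios are reported as `Inf` when only creating events exist and `NA`
when a stratum is empty, never as 0. Fisher's exact test is the classical
two-sided convention: the sum of all hypergeometric tables no more
probable than the observed one.

dN/dS uses the Nei–Gojobori counting estimator with equal pathway
weighting and Jukes–Cantor correction. A full codon-model ML estimate is
out of scope here; for the closely related, high-identity sequences this
package targets, counting is an adequate summary, and every output
carries a method tag so the two are never confused.

## Drift versus stabilizing selection

A continuous trait $X$ (phosphosite count, fibril-core folding free
energy) evolves along each lineage as an Ornstein–Uhlenbeck process
$$dX_i(t) = \alpha\,(\theta - X_i(t))\,dt + \sigma\,dB_i(t),$$
with selection strength $\alpha$ (per unit branch length), drift
intensity $\sigma$, and optimum $\theta$; $\alpha \to 0$ degenerates to
Brownian motion (pure drift). Tip values are jointly Gaussian; with tip
depths $T_i$ and shared path lengths $s_{ij}$,
$\mathrm{cov}(X_i, X_j) = \tfrac{\sigma^2}{2\alpha}
e^{-\alpha(T_i + T_j - 2 s_{ij})}(1 - e^{-2\alpha s_{ij}})$, and the mean
integrates the optima along the root-to-tip path with exponential
weights. Integer traits such as phosphosite counts are treated as
continuous Gaussian — a deliberate simplification shared with the
comparative-methods tradition; no discrete-trait correction is applied.

**Root policy.** The root state is tied to the root regime's optimum.
This keeps the model ladder nested with one added parameter per step —
BM {$x_0$, $\sigma^2$} ⊂ OU1 {$\theta$, $\alpha$, $\sigma^2$} ⊂ OU2 (one
extra $\theta$) — so each likelihood-ratio test has one degree of
freedom. The alternative (a free root state) breaks this nesting.

**Fitting.** At each $(\alpha, \sigma^2)$ the optima are profiled out by
generalized least squares, and Nelder–Mead searches the remaining two
parameters on the log scale from the conventional $(\alpha, \sigma) =
(1, 1)$ start, plus four deterministically jittered restarts and an
explicit near-zero-$\alpha$ start so the BM boundary is always examined.
$\alpha$ is bounded to $[10^{-6}, 10^3]$ per unit branch length; absolute
function tolerance $10^{-8}$, at most 5000 evaluations per start. A
constant trait is refused as degenerate (the $\hat\sigma^2 \to 0$
boundary) rather than fitted.

**Testing.** `compare_models()` computes $2\Delta\log L$ against the
$\chi^2_1$ upper tail. For BM-vs-OU1 the null value of $\alpha$ sits on
the boundary, which makes the $\chi^2_1$ reference conservative; the
measured type-I rate at nominal 5% on 85-tip trees is ≈3.5%, inside the
binomial confidence band, and this is the convention the comparative
literature uses, so it is kept. The tests verify $\alpha \to 0$
continuity with BM (tolerance $10^{-4}$ at $\alpha = 10^{-8}$) and the
exact invariance under rescaling time by $c$ with $(\alpha, \sigma^2)$ by
$1/c$.

## Property selection

For each amino-acid property (values from the AAindex collection;
RACS820101 tetrapeptide structure-occurrence, polarity, flexibility and
solvation free energy ship as the default set, with a documented
plain-text format for the user's own 108-property tables):

1. **Categories.** The range of $|\Delta \text{property}|$ over all
   amino-acid pairs exchangeable by a single nucleotide nonsynonymous
   change is cut into 8 equal-width bins, category 1 (most conserved) to
   8 (most radical) — the equal-width convention of the TreeSAAP family
   of methods.
2. **Expectation.** Every single-nucleotide nonsynonymous change from
   every codon is enumerated, each source codon weighted by its frequency
   in the extant alignment and each point mutation taken as equally
   likely. Building the expectation from the extant composition is what
   makes the approach defensible for low-complexity sequences, whose
   codon usage is far from a structured-protein background. Without codon
   data, an amino-acid composition fallback assumes uniform usage within
   each codon family and is flagged as such.
3. **Scores.** With $N$ scored events, $z_c = (O_c - N p_c) /
   \sqrt{N p_c (1 - p_c)}$ per category, a $\chi^2$ goodness of fit with
   7 degrees of freedom, and a signed *selection strength*: the pooled z
   of the radical categories 6–8 (configurable to 7–8 or the max-|z|
   radical category), positive for diversifying, negative for conserving.
   Events whose endpoints are not single-nucleotide-exchangeable (net
   multi-hit endpoint changes) carry no probability under the expectation
   and are skipped into a diagnostic count rather than mis-binned.
   The conventional significance threshold is $z > 3.09$ ($P < 0.01$);
   the threshold is an argument, not a constant, since reasonable
   analyses also use 0.001.
4. **Windows.** The positional profile recomputes the strength in sliding
   windows (default 15 columns, step 1, minimum 5 events per window —
   below the floor a window reports `NA` rather than a noisy score).
5. **Averaging.** Properties are highly redundant; groups are formed by
   single-linkage closure at $|{\rm Spearman}\ R| > 0.8$ between property
   value vectors, anti-correlated members are sign-flipped to the
   orientation of the group's first member, and the group reports mean ±
   sd of strength.

## Coevolution

The branch × site binary matrix marks where each site substituted. For a
pair $(i, j)$, the marginal likelihood of column $j$ as one Bernoulli
process (conjugate Beta(1,1) prior — uninformative, closed form) is
compared with the product of two Bernoullis conditioned on column $i$'s
state per branch. The log Bayes factor is the dependence score; with
prior odds 1, the association posterior is $BF/(BF+1)$. Scores are
symmetrised by averaging the two conditioning directions. This is the
exact one-parent special case of a bounded-in-degree Bayesian network
over sites: for *pairwise* association it is exact, it needs no MCMC, and
at ~160 sites (~13k pairs) it runs at desk scale. Full multi-parent
structure sampling is explicitly out of scope. Columns need at least 2
substitutions to be scored (default; singletons carry no pairwise
signal), the flag threshold is a configurable posterior of 0.5, and
p-values are reported raw — any multiple-testing policy across the ~13k
pairs is left to the caller. Structural context enters only through a
precomputed residue-pair distance table (Å), compared with pair
posteriors by Spearman rank correlation.

Because substitutions are mapped to branches before scoring, shared
phylogeny is partly controlled for — two sites that each changed once on
the same deep branch score as one co-substitution, not as dozens of
correlated tip states. No further phylogenetic null is applied.

## The synthetic-data generator

The generator is first-class, tested code: it produces the study
conditions under which every downstream claim is validated, with full
ground truth (true ancestral sequences, true event lists that replay
exactly from root to leaves, true trait values at all nodes).

Defaults emulate a mammalian-PLD-scale dataset: 85 taxa on an ultrametric
birth–death tree (birth 1, death 0.3) rescaled to depth 1; 160 columns of
which 24 are frozen sticker tyrosines, 24 are two-state toggle
phosphosites (G/S and A/T halves), 8 are invariant serine phosphosites
(32 phosphosites in all), and the rest evolve under JTT+Γ. The toggle
switching rate (0.55 per unit length) and the background rate multiplier
(0.08) were set so that tree-wide toggle counts and total event counts
sit at the order observed in real mammalian PLD data (a few hundred
events, half or more of them toggles); the toggle stationary bias (0.4)
with a root occupancy above it (0.6) reproduces the empirical pattern of
mild net phosphosite loss across the tree with gains concentrated in a
creation-biased clade. The focal clade is the largest clade holding at
most ~25% of the tips; a `clade_bias` multiplier scales the
creating-direction rate (G→S, A→T) on its branches. Traits follow exact
BM/OU transition sampling along each branch.

What the generator does *not* emulate: indels (real PLD alignments have
a few), alignment error, codon-level selection, among-branch rate
variation, and correlated evolution between toggle columns. Passing tests
therefore demonstrate correctness and calibration of the machinery under
a clean version of the data-generating process — not robustness to
misalignment or model misspecification.

## Validation problem sizes

The test-suite validation runs use: 50 random ≤4-taxon instances against
exhaustive state enumeration (tolerance 1e-10); an 85 × 160 JTT+Γ
simulation (rate multiplier 0.3, so that divergence is informative) for
reconstruction and event-recovery rates; 50 replicates for OU/BM
parameter-recovery medians; 200 drift-simulated replicates for LRT
type-I calibration and 25 optimum-shift replicates (shift = 3 stationary
sd) for power; all 2×2 tables with N ≤ 40 for Fisher's test; 500
multinomial null replicates for the property-χ² calibration; and 100
planted-pair replicates (100 branches × 30 sites) for coevolution
ranking. The planted clade-bias end-to-end run doubles the toggle-column
density (48) and uses bias 8 — a deliberately strong planted signal, so
that a detection failure indicates a defect rather than sampling noise;
the study-scale defaults above are unchanged.

## Known limitations

* Counting dN/dS is not a codon-model ML estimate; use it comparatively,
  not as an absolute ω.
* The OU machinery assumes Gaussianity of an integer trait and fixes the
  root at the root-regime optimum; the BM-vs-OU1 test is slightly
  conservative at the boundary.
* Property categories use equal-width bins over the realizable range;
  heavily skewed properties put most single-step changes in few bins, and
  a category with zero expected mass but observed events raises an error
  by design.
* One-parent coevolution scores cannot separate direct from indirect
  (chained) dependence among three or more sites.
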