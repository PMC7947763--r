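# pldevo

Molecular-evolution toolkit for low-complexity **prion-like domains
(PLDs)** — the intrinsically disordered, G/S/Q/Y-rich regions that drive
liquid–liquid phase separation in RNA-binding proteins such as FUS. Given a
protein multiple sequence alignment, a rooted phylogeny with branch
lengths, and a description of the domain (phosphosites, sticker tyrosines,
clades of interest), the package quantifies how such a domain evolves:

* **Conservation profiling** — per-column Shannon entropy
  `H_j = -Σ_a p_a log p_a`, fully conserved (sticker) columns, and
  Wilcoxon rank-sum comparisons between regions.
* **Ancestral sequence reconstruction** — Felsenstein pruning under
  empirical amino-acid models (JTT by default) with discrete-Γ rate
  heterogeneity, marginal posteriors at every internal node, model choice
  by BIC, and reconstruction-accuracy filtering.
* **Substitution mapping** — events assigned to the branch where parent
  and child MAP states differ, 20×20 exchange-count matrices, and toggle
  summaries for the characteristic G↔S / A↔T exchanges of PLDs.
* **Phosphosite trait analysis** — per-taxon counts of S/T-occupied
  phosphosites; creation/destruction contingency
  `(G→S + A→T) / (S→G + T→A)` stratified by clade with Fisher's exact
  test; counting-based (Nei–Gojobori) dN/dS for site-class comparisons.
* **Drift vs stabilizing selection** — Brownian motion and
  Ornstein–Uhlenbeck models, `dX = α(θ − X)dt + σ dB`, fitted by maximum
  likelihood on the phylogeny (optima profiled by GLS, Nelder–Mead over
  α and σ², multi-optimum regimes painted from clades), compared by
  likelihood-ratio tests.
* **Property selection scanning** — TreeSAAP-style comparison of observed
  amino-acid property changes against the expectation from the extant
  codon composition, in 8 magnitude categories with per-category z-scores,
  χ² goodness of fit, signed selection strength, sliding-window profiles,
  and averaging of rank-correlated properties.
* **Coevolution detection** — branch × site binary substitution matrices
  scored with exact Beta–Bernoulli Bayes factors (the one-parent special
  case of a bounded-in-degree Bayesian network), plus correlation of pair
  posteriors with structural distances.
* **Synthetic data generation** — site-heterogeneous alignments on
  birth–death trees with logged true ancestral states, events and traits,
  used as the test substrate throughout.

## Worked example

Generate a synthetic 85-taxon, 160-column PLD-like dataset with a
phosphosite-creation bias planted in one clade, and run the full pipeline:

```r
library(pldevo)

cfg <- simulation_config(seed = 42, clade_bias = 5)
ds  <- simulate_dataset(cfg)
report <- run_pipeline(ds$alignment, ds$tree, ds$region_config,
                       model = aa_model("JTT", gamma_shape = 1))
print(report)
#> Domain-evolution pipeline report
#>   alignment: 85 taxa x 160 columns; model JTT
#>   median entropy 0.0640; 76 conserved columns
#>   ASR mean MAP posterior 0.999 +/- 0.019
#>   toggle events: G:S=63, A:T=70 (55.4% of 240)
#>   creation/destruction: clade 2.54 vs background 1.05 (Fisher p = 0.0262)
#>   drift vs selection LRT p = 1
#>   one vs two optima LRT p = 4.62e-05
#>   coevolution: 1176 pairs scored, 152 flagged
```

Reading the report: the G↔S and A↔T toggles dominate the mapped events
(55% of 240), as expected for a low-complexity domain. The planted clade
shows a creation/destruction ratio of 2.54 against 1.05 in the background
(Fisher's exact p = 0.026), so the clade has been gaining phosphosites.
The phosphosite-count trait shows no evidence against pure drift under a
single optimum (LRT p = 1), but a two-optimum model with a separate clade
optimum is strongly preferred (p = 4.6e-05) — the same shift seen in the
contingency table, now as a trait optimum.

Individual stages are available as plain functions returning classed
objects — `entropy_profile()`, `marginal_ancestral_states()`,
`map_substitutions()`, `fit_trait_model()` (with `coef()`, `logLik()`,
`compare_models()`), `selection_scores()`, `coevolution_scan()` — and a
thin command-line wrapper is installed at
`inst/scripts/pld_evo.R` (`simulate` and `run` subcommands).

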