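# combokill

Quantitative analysis of why multi-drug chemotherapy combinations work.

Curative combination regimens can succeed through two very different
mechanisms: pharmacological **synergy** (the drugs potentiate each other) or
**independent action with low cross-resistance** (each drug kills its own
fraction of cells, and clones resistant to one drug are killed by another).
`combokill` implements the analyses needed to distinguish the two in cultured
cells:

* **Interaction scoring** on dose-response checkerboards and fixed-ratio
  mixtures. Relative viability is converted to growth-rate-normalized GR
  values (`GR = log2(viability × 2^d) / d`, d = untreated doublings; 1 =
  uninhibited growth, 0 = stasis, < 0 = net killing). Deviation from Bliss
  independence is scored in log-kill units, `EOB = log10(1 − p_expected) −
  log10(1 − p_observed)` with `p_expected = p_a + (1 − p_a) p_b`, and
  deviation from Loewe additivity by isoboles and fractional inhibitory
  concentrations, `FIC = Σᵢ cᵢ / Aᵢ` (1 = additive). Emergent higher-order
  interactions are isolated by composing lower-order FICs dose-additively.
* **DNA-barcode clone tracing.** Per-replicate barcode enrichment
  (post/pre-treatment frequency ratios with a 5%-quantile pretreatment
  floor), replicate aggregation by a floored geometric mean that penalizes
  irreproducible enrichment, vehicle-fitness normalization, and a
  scrambled-label error model that turns coincidental enrichment into
  false-discovery rates for 1-, 2- and 3-drug resistance calls.
* **Pooled CRISPRi/a screens.** sgRNA rho phenotypes (non-targeting-centred
  log2 fold change per population-doubling difference), gene scores
  (mean of the strongest five rho values × −log10 Mann–Whitney p against
  ~4000 non-targeting controls), simulated negative-control genes, and a
  control-calibrated cutoff for multi-drug resistance calls.
* **The cross-resistance parameter ξ.** For single-drug resistance
  frequencies 10⁻ᴬ and 10⁻ᴮ, multi-drug resistance is bounded between
  10⁻ᴬ⁻ᴮ (independent acquisition, ξ = 0) and min(10⁻ᴬ, 10⁻ᴮ) (full
  cross-resistance, ξ = 1); observed MDR solves
  `MDR = ξ·max + (1 − ξ)·min`. The log-kill model `survivors = P₀ ∏ fᵢ`
  quantifies what additive, non-cross-resistant drugs achieve together.
* **Synthetic data generators** for all three assay types (Hill-curve
  checkerboards under Bliss/Loewe/antagonistic rules, clonal populations
  with configurable resistance frequencies and true ξ pushed through drug
  bottlenecks and multinomial sequencing, genome-scale sgRNA libraries with
  known gene effects), so every downstream statistic can be validated
  against known ground truth.

## Worked example

Simulate a clone-tracing experiment with 10⁵ barcoded clones, two drugs at
~0.5% single-drug resistance and a true cross-resistance of ξ = 0.1, then run
the full enrichment pipeline and estimate ξ:

```r
library(combokill)

u <- clone_universe(n_clones = 1e5, drugs = c("doxorubicin", "vincristine"),
                    resistance_freq = 5e-3, true_xi = 0.1, seed = 1)
sim <- simulate_clone_tracing(u, depth = 1e6, seed = 2)
res <- analyze_clone_tracing(sim$counts)

round(res$single_freqs, 4)
#> doxorubicin vincristine
#>      0.0051      0.0048
res$xi[["doxorubicin+vincristine"]]
#> Drug set: doxorubicin + vincristine
#> Single-drug frequencies: 0.00509, 0.00481
#> MDR observed 0.0005  [min 2.448e-05 (xi=0), max 0.00481 (xi=1)]
#> Cross-resistance xi = 0.099
```

The pipeline recovers the configured single-drug resistance frequencies
(0.51% and 0.48% called at geometric-mean enrichment ≥ 10) and an estimated
ξ = 0.099 against a generative truth of 0.1: the observed double-resistant
frequency sits very close to the independent-acquisition minimum.

The same estimator applied to published gene-count bounds — 18 genes
resistant to two drugs, where chance predicts 1 and full overlap 132:

```r
estimate_xi(NULL, observed_mdr = 18, min_mdr = 1, max_mdr = 132)
#> MDR observed 18  [min 1 (xi=0), max 132 (xi=1)]
#> Cross-resistance xi = 0.130
```

And a noise-free Bliss checkerboard scores as an exact interaction null:

```r
s <- simulate_checkerboard(hill_curve(ic50 = 1), hill_curve(ic50 = 5),
                           interaction = "bliss", noise_cv = 0)
excess_over_bliss(s)
#> Excess over Bliss, drug_a x drug_b
#> EOB (log10 kill units) off-margin: min -0.000, median 0.000, max 0.000
```

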