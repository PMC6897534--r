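---
title: "Scoring drug additivity and cross-resistance with combokill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug additivity and cross-resistance with combokill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combokill)
```

## The scientific problem

A combination chemotherapy can outperform its constituents for two distinct
reasons. The drugs may interact pharmacologically (synergy), or they may act
independently on a heterogeneous cell population whose resistant
subpopulations barely overlap, so that each drug's fractional kill
multiplies through. Distinguishing these requires (i) interaction scoring
over full dose ranges and (ii) systematic measurement of cross-resistance
across large clone libraries. `combokill` implements both analyses, plus
generative models of the underlying experiments so every statistic can be
validated against known ground truth.

## Interaction scoring

### GR normalization

Cells divide during a viability assay, so relative cell number confounds
growth inhibition with killing. With `d` untreated population doublings over
the assay window (unitless; about 3 for a 24 h doubling time over 72 h),

$$GR = \frac{\log_2(\text{relative viability} \times 2^d)}{d}.$$

GR = 1 is uninhibited growth, GR = 0 growth arrest (final = initial cell
count), GR < 0 net killing. No lower asymptote is imposed, so deep kills
remain distinguishable on this scale. `compute_gr()` clips relative
viability below `min_viability` (default 1e-6) only to keep logs finite on
fully killed wells.

### Bliss independence and excess over Bliss

If drugs a and b kill independently with probabilities $p_a$ and $p_b$, the
combination is expected to kill $p_{exp} = p_a + (1-p_a)p_b$. Because the
clinically relevant quantity is the *surviving* fraction, deviations are
scored in log-kill units:

$$EOB = \log_{10}(1 - p_{exp}) - \log_{10}(1 - p_{obs}),$$

so one unit of EOB is one extra decade of kill beyond independence (positive
= synergy, negative = antagonism). Kill fractions are $1 -$ relative
viability, clipped to $[0, 1-\varepsilon]$ with $\varepsilon = 10^{-12}$;
margins come from the checkerboard's own zero-dose row and column, so EOB is
exactly zero on the margins by construction.

### Isoboles and the median filter

Isoboles (equal-effect contours) are extracted by linear level-crossing
interpolation between grid nodes in log-dose coordinates
(`grDevices::contourLines`); straight isoboles in linear dose indicate Loewe
additivity, bowing toward the origin synergy. Before contouring, the
response grid may be smoothed by a 3×3 moving-median filter. Two numerical
choices here: edge cells are passed through unfiltered, because a shrunk
even-sized window takes the mean of its middle pair and would perturb even
perfectly monotone data; and the fixed-point property ("no change to a
monotone surface") holds exactly for surfaces monotone along all window
directions (e.g. near-planar grids) and approximately otherwise — the
filter only removes local jaggedness either way.

### Fractional inhibitory concentrations

For a fixed-ratio mixture crossing an effect level (default 50% kill) at
total dose $T$, with single agents crossing at $A_i$ and mixture weights
$w_i$,

$$FIC = \sum_i \frac{w_i T}{A_i},$$

with FIC = 1 additive. Crossings are located by piecewise-linear
interpolation of the kill curve in log10 dose; the first crossing is used
and non-monotone crossings warn. `design_equipotent_mixture()` sets
$w_i \propto A_i$ so each constituent contributes equally; a drug that never
reaches the reference effect within its curve (as happens for a purely
cytostatic agent) raises an error naming it. Confidence intervals are plain
t-intervals over per-replicate FICs, matching an n-of-4 plate design.

### Emergent higher-order interactions

An N-drug mixture can deviate from additivity merely because one of its
pairs does. The exact composition rule used by prior fixed-ratio analyses is
not fully specified, so this package defines its own variant: each
(N−1)-subset mixture is treated as a pseudo-drug whose potency is its
measured FIC, composed dose-additively with the remaining single agent in
equipotent units, giving one prediction per decomposition; the prediction
closest to the observation (smallest |log10 deviation|) is used, and

$$\text{emergent FIC} = \frac{FIC_N}{\text{best lower-order prediction}}.$$

This reduces to 1 under full additivity, equals the observed $FIC_N$ when
all lower orders are additive, and scores a triple containing one
antagonistic pair as ≈ 1 (the pair explains the deviation) — the three
behaviours that define the statistic's purpose.

## Clone-tracing enrichment

Barcode counts are converted to within-sample frequencies; pretreatment
counts are first floored at the sample's 5% quantile so barcodes rare in the
reference cannot score as spuriously enriched from a handful of reads. Each
treated replicate yields an enrichment ratio (post/pre frequency), and
replicates are combined as

$$\text{score} = \Big(\prod_r \max(\text{ratio}_r, 1)\Big)^{1/R},$$

flooring each replicate *before* averaging (the literal reading of the
aggregation rule; flooring the mean instead was considered and rejected —
it would not penalize one-replicate stochastic enrichment). Scores are
divided by the barcode's vehicle (DMSO) enrichment only when that exceeds 1,
so drug scores are never inflated by a vehicle score below 1. Whether the
vehicle division applies per replicate or to the aggregate is ambiguous in
the field's descriptions; the aggregate is divided by default and
`dmso_per_replicate = TRUE` exposes the alternative.

The error model scrambles barcode labels independently within each
replicate column and re-applies the aggregation, preserving every column's
marginal score distribution exactly while destroying within-barcode
coupling. FDR(threshold, multiplicity) = scramble-averaged false count /
observed count. Raw curves can be non-monotone at sparse thresholds, so a
right-to-left cumulative maximum regularizes them (both raw and regularized
values are reported). `mode = "independent"` bootstraps each column instead
of permuting, emulating an unbounded number of scrambled replicate sets.
Thresholds default to the log grid {2, 5, 10, 20, 50, 100}; 10 is the
operating point at which multi-drug false discovery is a few percent on
realistic simulations. Growth-inhibition selections (prednisolone-style
arms) flow through identically; no special casing.

## CRISPR screen scoring

The rho phenotype of an sgRNA is its log2 fold change in frequency between
treated and vehicle arms, centred by the median over **all** non-targeting
sgRNAs (not only those passing the count filter — this also makes rho
exactly invariant to rescaling a sample's depth once frequencies are
formed), divided by the measured population-doubling difference between the
arms. Defaults follow genome-wide screen practice: 10 sgRNAs per gene,
~4000 non-targeting controls, a minimum of 25 raw counts in at least one
compared sample, pseudocount 10 added to all counts (the half-library
preset instead adds 1 to zero counts only), and doubling differences are
user inputs (e.g. 7.60/9.34/7.41/7.53 for the knockdown screens that
motivate the defaults). Gamma (vehicle vs T0) and tau (treated vs T0)
phenotypes use the same machinery.

Gene scores combine effect size and significance: the mean of the strongest
five rho values by absolute magnitude (signed values are averaged; the
magnitude is only used for selection) times −log10 of the two-sided
Mann–Whitney p-value of all the gene's rho values against the non-targeting
controls. The test uses a normal approximation with continuity and tie
corrections — exact enumeration is infeasible at 10-vs-4000 — implemented
in vectorized form for speed and pinned in tests both to
`wilcox.test(exact = FALSE)` (1e-10) and to exact enumeration on 10-vs-50
downsamples. For multi-TSS genes the TSS with the smallest p is kept, ties
broken by larger |mean rho| then lexicographically. Genes with fewer than
eight observed phenotypes are dropped. The hypersensitivity score is the
negative of the resistance score, so each is positive for its own phenotype
direction.

Simulated negative-control genes — random groups of 10 non-targeting
sgRNAs, drawn without replacement within a pseudo-gene and freely across
pseudo-genes, matched in number to real genes — estimate the technical
noise floor. The multi-drug cutoff is the smallest value, scanned in 0.01
increments, at which the control sets average at most one pseudo-gene
exceeding the cutoff in ≥ 2 drugs ("exceeding in ≥ 2 drugs" counts a gene
once, not once per pair; the summed-pairs reading was considered and not
adopted). This is deliberately lenient for single-drug calls: it minimizes
the chance of missing true cross-resistance.

## The cross-resistance parameter

With single-drug resistance frequencies $f_i$, multi-drug resistance is
bracketed by $\prod_i f_i$ (independent acquisition, ξ = 0) and
$\min_i f_i$ (full nesting, ξ = 1), and an observed MDR frequency solves

$$MDR = \xi \min_i f_i + (1 - \xi) \prod_i f_i.$$

For more than two drugs the same weighted-sum form is used with the product
over all drugs as the minimum and the overall smallest frequency as the
maximum — the natural generalization of the two-drug rule. The operation
accepts frequencies, or counts on a common denominator, or directly
supplied bounds (`min_mdr`/`max_mdr`) for published count-scale summaries.
Observations falling outside the bracket (possible under sampling noise)
yield a clamped ξ plus an `out_of_range` flag rather than an error, so
batch analyses do not abort; a degenerate bracket (min = max) yields NA
with a warning. Pipeline summaries report both the arithmetic and the
geometric mean of per-subset ξ values, since either convention is found in
practice.

Design arithmetic in the same module: expected clone coverage of an
inoculum, $1 - (1 - 1/n)^m$; fold enrichment of a fully resistant clone
under fractional growth inhibition, $(1/(1-I))^{\text{divisions}}$; the
per-clone unique-barcode probability $(1 - 1/L)^{n-1}$ (reported as is —
claims of ">99%" for $10^6$ clones in a $7\times10^7$ library rest on a
different approximation; this formula gives 98.6%); and the log-kill model
$P_0 \prod_i f_i$.

## What the generators emulate — and what they do not

* `simulate_checkerboard()` / `simulate_mixture_response()`: Hill-type
  single-drug kill curves (IC50 in arbitrary concentration units, slope,
  maximal kill) combined under exact Bliss, exact Loewe (dose equivalence
  solved by `uniroot` to 1e-12), or a margin-preserving antagonism that
  interpolates the combined kill between Bliss and highest-single-agent —
  a pure power transform of Bliss survival was rejected because it commutes
  with the product and leaves EOB at zero. Noise is multiplicative
  log-normal with configurable CV (mean-one parameterization); plate
  spatial effects are not modelled, mirroring designs that randomize well
  layout precisely to convert spatial bias into random error.
* `clone_universe()` / `simulate_clone_tracing()`: per-drug resistant sets
  at configured marginal frequencies with true ξ realized through the same
  weighted-sum joint frequency the estimator assumes (coupling each drug to
  the first), so parameter recovery is a sharp test; multinomial inoculum
  sampling (default 12-fold clone coverage), per-clone binomial survival
  (sensitive cells killed at 99.9% per pulse by default, resistant cells
  surviving), deterministic fitness-weighted regrowth to twice the inoculum
  (a branching-process regrowth is deliberately not the default — drift
  magnitude between rounds is an experimental unknown, so determinism keeps
  the generative truth sharp), two treatment rounds, and multinomial
  sequencing (default 1e6 reads per sample, pretreatment 20× deeper).
  Real experiments add ENU mutagenesis biology, clone fitness-resistance
  correlations and culture bottleneck structure that are not modelled, so
  passing recovery tests demonstrates the *analysis* is correct, not that
  any particular biological dataset will look like the simulation.
* `screen_universe()` / `simulate_crispr_screen()`: 10 sgRNAs per gene with
  per-guide efficacies, ~4000 zero-effect non-targeting controls, selection
  as exponential growth with per-sgRNA coefficient efficacy × true rho ×
  doubling difference, log-normal abundance dispersion, multinomial
  sequencing. Off-target effects and guide-position biases are not
  modelled.

All generators are deterministic given their `seed`.

## Problem sizes and runtime choices

The shipped tests validate the pipeline at sizes chosen to make sampling
error negligible relative to the tolerances while keeping the suite quick:
clone-tracing recovery at 1e5 clones and 1e6 reads per sample; ξ recovery
over true ξ ∈ {0, 0.1, 0.5, 1} with 20 seeds each at frequencies 1e-2;
screens at 80–300 genes with 400–1000 controls and 2–5e6 reads. The
acceptance script uses the same scales with 10 seeds per ξ value. Scaling
the generators up (e.g. to 19,000 genes or 1e6 clones) changes runtime, not
code paths.

## Known limitations

* FIC interpolation on sparse dose grids carries up to ~1–2% bias; dense
  gradients (≥ 5 points per decade near the crossing) remove it.
* The emergent-FIC composition rule is this package's documented variant;
  other composition conventions exist and will differ away from the
  additive null.
* The Mann–Whitney normal approximation deviates from exact enumeration in
  the far tail (below p ≈ 1e-3 at n = 10 vs 50); gene *ranking* is
  unaffected, and the cutoff calibration is anchored to control genes
  scored with the same approximation.
* ξ estimates inherit the noise of the resistant-set calls feeding them;
  with very rare resistance the observed overlap is a small count and its
  Poisson error propagates into ξ.
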