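---
title: "Sizing repeat expansions from optical mapping molecules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing repeat expansions from optical mapping molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmstr)
```

## The measurement model

Optical genome mapping reports, for every imaged molecule aligned across a
locus, the distance between the two fluorescent labels flanking it. For a
repeat expansion the only signal is that distance: a molecule carrying an
allele of $r$ repeat units of a motif of length $m$ bp measures

$$ d \;=\; d_{\mathrm{ref}} + r\,m + \varepsilon, $$

where $d_{\mathrm{ref}}$ is the reference intermarker distance (6858 bp at
the *RFC1* locus, `rfc1_locus()`) and $\varepsilon$ is measurement error.
Across the 30–200 molecules typically spanning a locus, each allele appears
as an approximately Gaussian peak in the distance histogram; its mean
estimates the allele size and its standard deviation aggregates optical
error and any somatic repeat instability. Empirically the dispersion sits
around 5% of the repeat size regardless of allele length, which is why the
per-allele *instability ratio* `sd_repeats / mean_repeats` is reported (it
is `NA` for non-positive means, e.g. control alleles estimated at a few
repeats below reference — estimates are deliberately never clamped at
zero).

The pipeline in `size_sample()` is:

1. `knee_epsilon()` — each point's distance to its `min_samples`-th nearest
   neighbour is computed exactly (1-D), sorted, and the DBSCAN radius is
   taken at the knee of that curve (Kneedle, convex-increasing convention).
2. `dbscan_filter()` — classical DBSCAN in one dimension; points in no
   cluster are removed as outliers (chimeric molecules, mis-alignments).
   All clusters are kept, not only the largest.
3. `fit_gmm()` with $k = 1$ and $k = 2$ on the kept distances, then
   `select_model()`: the two-component model is chosen iff its BIC is
   strictly lower **and** both weights strictly exceed 25%.
4. Conversion to repeat units via `bp_to_repeats()`, ascending sort,
   zygosity label and classification.

## Tunable parameters

All knobs live in `sizing_config()`; a run is a pure function of
(data, config).

| parameter | default | why |
|---|---|---|
| `min_samples` | 5 | DBSCAN minPts and the k of the k-distance curve; the classic heuristic, robust for 30–200 points. Not stated by the method's description; shared between the two uses. |
| `knee_sensitivity` | 1.0 | Kneedle S in its standard usage. |
| `weight_threshold` | 0.25 | the published selection rule ("both weights > 25%"), read as a strict inequality. |
| `n_restarts` | 10 | EM restarts; restart 1 is a deterministic equal-count split of the sorted data, the rest draw random responsibilities from `seed`. |
| `em_tol` | 1e-6 | relative log-likelihood change declaring convergence. |
| `max_iter` | 500 | cap per restart. |
| `variance_floor_frac` | 1e-6 | variances floored at this fraction of total sample variance, preventing single-point collapse. |
| `min_molecules` | 10 | minimum input size; typical per-sample molecule counts are unreported, so this is a conservative convention (warned when below `2 * min_samples`). |
| `expanded_threshold_repeats` / `normal_threshold_repeats` | 250 / 100 | pathogenic expansions at loci of this class run from ~250 to >4000 repeats, benign alleles < 100; labels are informational only. |

Unstated conventions resolved as package design choices: BIC "improves"
means strictly lower (ties favour one component, parsimony); mixtures are
fitted on the bp scale (the selection rule is affine-invariant — both BICs
shift by the same $2n\log a$ under $x \mapsto ax+b$ — so the scale is
immaterial, and this is verified by a property test); no alignment
confidence filter is applied by default (an optional `--min-confidence`
flag exists); a single component is labelled *"single-component (reported
homozygous)"* because it may equally hide two alleles of similar size.

## Numerical choices

* **Kneedle.** The convex-increasing convention flips the normalised curve
  to concave before walking its difference from the diagonal; local maxima
  become knee candidates (threshold $y_d - S\,\overline{\Delta x}$), local
  minima reset the threshold, and the first confirmed candidate wins. The
  flip matters in practice: scanning the unflipped curve forward can latch
  onto a late spurious maximum created by a handful of distant outliers and
  return an ε that re-admits them. If the curve has no knee (e.g. all
  k-distances equal) the maximum k-distance is returned with a warning —
  outlier removal is protective, not essential, so the fallback keeps
  everything rather than failing.
* **EM.** Univariate, exact E/M steps in log space (log-sum-exp). With
  $k=1$ EM is the closed-form MLE (tested to 1e-9 against an independent
  closed form). BIC uses $p = 3k - 1$ free parameters. Zero-variance input
  is a degenerate-data error for any $k$: the likelihood is unbounded.
* **DBSCAN.** The 1-D case is solved by a sorted sweep with binary
  searches ($O(n\log n)$); tests compare it against a naive $O(n^2)$
  BFS oracle on random instances.
* **Rounding.** Repeat counts stay fractional throughout; presentation uses
  round-half-to-even. Percentages in deviation tables likewise.

## What the simulator emulates — and what it does not

`simulate_molecule_distances()` draws each molecule's allele by its
fraction, adds Gaussian noise in bp (sd defaulting to 5% of the allele
size, floor 10 repeats), and replaces a `Bernoulli(outlier_rate)` subset
(default 2%) with `Uniform(500, 60000)` bp contamination. The defaults are
the conditions the sizing model assumes: Gaussian per-allele dispersion at
~5% of size, 30–200 molecules, sparse gross contamination. True per-sample
molecule counts and outlier rates in real cohorts are unreported;
the defaults are conventions chosen once.

Not emulated: the left-skew that kinked molecules may induce (a qualitative
under-estimation hypothesis; an explicit contamination flag can be added for
robustness experiments, but no quantitative model exists to calibrate it),
label-density variation, or somatic mosaicism beyond the per-allele
Gaussian. A green recovery test therefore establishes correctness of the
estimator under its own model, not robustness to skewed optical artefacts.

`simulate_cohort()` generates the concordance inputs: optical sizes = truth
+ 5% Gaussian noise; blot sizes from the inverse affine bias
`sb = (truth − b)/a + noise`, so regressing OGM on SB recovers slope ≈ a —
the minimal model consistent with the observed linear relation (slope 0.62,
intercept ~232 at this locus); long reads sample the larger allele, as
targeted enrichment did in practice.

## Allele pairing for the concordance regression

Platforms report one (homozygous) or two sizes per patient and no pairing
rule is published. The default expands homozygous singles by duplication,
sorts each side and pairs rank-wise — symmetric, and it reproduces the
published cohort layout (two points per patient, n = 34). Alternatives
(`collapse_homozygous`, `average`) are provided for sensitivity analysis
via `pair_alleles(..., pairing =)` and the CLI `--pairing` flag. Controls
without a blot size are excluded. The published intercept (232 with CI
[181–226]) is internally inconsistent — the estimate lies outside its own
interval — so only slope and r² are treated as reproducible.

## Known limitations

* **Close alleles.** Two alleles separated by less than ~4 pooled standard
  deviations are frequently reported as a single component: in 50-seed
  simulations of the 664/730-repeat scenario (60 molecules each, ~2.9
  pooled SDs apart) the BIC-plus-weights rule selects two components in
  only ~60% of runs — matching an independent scikit-learn implementation
  of the same rule — whereas well-separated scenarios are resolved in
  ≥ 95%. The corresponding acceptance expectation is asserted at its
  stated ≥95% threshold and is knowingly red; the single-component label
  is worded accordingly.
* The method sees only label spacing: it cannot identify the repeat motif,
  detect interruptions, or find a truncating point variant in trans.
* More than two components (mosaicism, contamination) are out of scope;
  DBSCAN keeps all clusters and the mixture is capped at $k = 2$.
* CMAP/XMAP parsing is header-name based and tolerant of extra columns, but
  consumes alignments as given — molecule-to-reference alignment quality is
  upstream's responsibility.
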