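---
title: "Scoring, filtering and imaging models behind bioidpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, filtering and imaging models behind bioidpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioidpipe)
```

## Scope

`bioidpipe` covers the computational stages of a BioID proximity-proteomics
study that start *after* protein identification: spectral counts per
bait/control run come in, high-confidence interactomes, condition
comparisons, set-level analytics and image-based lysosome-positioning
readouts come out. Peptide search, protein inference and live annotation
services are out of scope.

## The scoring model

Each bait–prey pair is scored against **compressed virtual controls**: for
every prey, the `k = 4` largest spectral counts across all negative-control
runs are retained (zero-padded when fewer controls exist). Keeping the top
counts rather than all of them biases the background estimate upward, which
is the intended stringency of the virtual-control idea.

A replicate count $x$ is then evaluated under a two-component count mixture
with equal prior odds:

* background component with mean $\mu_0 = \max(\bar c, \varepsilon)$, the
  mean of the virtual-control counts floored at $\varepsilon = 0.1$ so the
  model is defined for preys never seen in controls;
* true-interaction component with mean
  $\mu_1 = \max(\bar x, f \mu_0)$, the test-count mean across replicates
  floored at $f = 2$ fold over background, so the alternative is always
  strictly elevated.

The per-replicate probability is $P_1(x) = L_1(x) / (L_0(x) + L_1(x))$ with
Poisson likelihoods by default (`saint_params(model_dispersion = )` switches
both components to negative binomial). Probabilities are averaged across
biological replicates into `AvgP` — averaging on probabilities, not counts —
and the Bayesian false discovery rate at rank $r$ of the `AvgP`-sorted list
is the cumulative mean of $1 - \mathrm{AvgP}$ over the top $r$ records; tied
probabilities share the worst BFDR of their block so thresholding does not
depend on sort stability. `BFDR <= 0.01` defines high confidence.

This is a *documented SAINT-style model*: it reproduces the published
scoring behaviour (control-like preys fail, enriched preys pass) without
claiming to bit-match any external implementation. Consequences of the
design worth knowing:

* a zero count can never favour the interaction ($\mu_1 > \mu_0$ always);
* the probability is monotone non-decreasing in the test count;
* with Poisson likelihoods the posterior is deliberately decisive; the
  false-discovery calibration under overdispersed data is checked by
  simulation (below), not assumed.

Negative controls are pooled across cycling/ciliated conditions before
compression by default, matching the design in which nine controls from
both states feed four virtual controls; `by_condition = TRUE` scores each
condition against condition-matched controls instead. Prey-length
normalisation is not applied.

## High-confidence filtering

`build_high_confidence()` fixes the rule order **BFDR → rescue → exclude**:

1. BFDR cutoff (inclusive at the threshold) for every bait, conditions
   pooled by union;
2. partner rescue for designated baits: preys *detected* with the bait
   (count > 0 in at least one replicate) that missed the cutoff re-enter if
   the partner bait family calls them at high confidence. Rescue cannot
   import never-observed preys — a proximity interactome cannot contain
   preys the bait never labelled;
3. control-bait exclusion last, so a contaminant rescued in step 2 is still
   removed: a prey is dropped when its mean count with the negative-control
   bait is at least 4× its mean count with the bait, the bait mean floored
   at 0.25 (one count spread over four virtual-control slots) so the ratio
   is defined at zero. Exclusion uses the bait's runs from both conditions,
   consistent with pooled controls.

The exclude-last order matters and is covered by a test with a planted
contaminant that the partner dataset also calls; rescue-then-exclude removes
it, the reverse order would not. Gene symbols are compared
case-insensitively throughout; every detected prey receives exactly one
terminal decision in the filter report, and the report tallies reconcile by
construction.

## Condition comparison

Per prey, the ciliated and cycling replicate counts of one bait are
compared by

* fold change `FC = (mean(ciliated) + 0.5) / (mean(cycling) + 0.5)` — the
  0.5 pseudocount keeps FC finite and symmetric for preys absent from one
  condition;
* Welch's two-sided t test on `log2(count + 1)`. The source study plots a
  volcano without naming its test; Welch on log counts is the minimal
  defensible default for 2–5 replicates of overdispersed counts. Degenerate
  inputs follow a fixed contract: fewer than two replicates on either side
  gives `p = 1` (cannot test); two constant sides give `p = 1` when equal
  and `p = 0` otherwise.

Classes follow the volcano thresholds: `increased` iff `FC >= 2 & p < 0.05`,
`decreased` iff `FC <= 0.5 & p < 0.05`, else `unchanged`. No multiplicity
correction enters the classification (matching the raw `p < 0.05` volcano
convention); a BH-adjusted column is emitted alongside for users who want
it. Swapping condition labels maps FC to 1/FC and swaps the classes with p
unchanged.

## Set analytics

Overlaps, Jaccard distances, multi-database membership tiers and the
hypergeometric over-representation test are exact set arithmetic on
uppercased symbols; the natural universe for over-representation is the
union of detected preys across baits. Dot-plot export encodes
control-subtracted average counts capped at 50 (colour), per-prey relative
abundance across bait datasets (size, in [0, 1]) and BFDR bins (border:
black ≤ 0.01 < blue ≤ 0.05 < light blue). Two constructions of a "shared
interactome" across condition-specific sets are both provided
(`shared_preys(..., require_all_conditions = )`) because published summary
counts of this kind depend on which construction is meant; the package
reports both without asserting either.

Reference gene lists ship only as clearly-labelled synthetic toys
(`inst/extdata/synthetic_*.txt`); drop in real curated lists (one symbol
per line) for real analyses.

## The count generator

`simulate_experiment()` draws spectral counts from a negative binomial with
mean $\mu$ and variance $\mu + \mu^2/\phi$, where `dispersion` $= \phi$ is
the size parameter and `Inf` gives the Poisson limit. Defaults encode the
emulated study conditions: 2 biological replicates per condition, 9
negative controls (5 cycling, 4 ciliated) compressed to 4 virtual controls
downstream, background mean 2, 8-fold planted enrichment for 150 of 2000
preys (interactomes of a few hundred preys among a few thousand detected),
and $\phi = 20$ — near-Poisson background at mean 2 and a CV of roughly
one-third for strong interactors, consistent with the high
replicate-to-replicate reproducibility reported for the assay. A
`condition_effect` multiplier acts on planted preys in ciliated runs only,
and `n_sticky` plants scaffold contaminants that are enriched in a
dedicated control bait, giving the exclusion filter ground truth.

What the generator does *not* emulate: correlated contaminant structure
across runs, prey-length effects, peptide-level identification noise, and
batch drift. Passing the simulation-based checks therefore demonstrates
internal statistical correctness of the pipeline under the stated count
model, not performance on any particular real dataset.

## The image generator and ring measurement

`simulate_cell_image()` renders one cell per 256×256 16-bit frame: a filled
nuclear disc (radius 40 px) and `n_puncta` Gaussian lysosomal puncta
(σ = 2 px, peak 2000 grey levels) on a constant background (100) with
Gaussian read noise (σ = 5). A chosen fraction of punctum centres falls in
the 30-px annulus just outside the nucleus (centres inset by one σ so a
punctum's mass stays mostly in its compartment); the rest are peripheral.
The ground truth is the exact fraction of noise-free punctum intensity
inside the analytic annulus, so tail leakage across the ring boundary is
part of the truth, not an error source.

The measurement follows the published procedure: histogram-mode background
estimation (bin width 1 grey level on integer data; 256 bins over the range
for float data) and subtraction clamped at zero; white top-hat with a disc
element (default radius 8 px, comfortably above the punctum radius) to
remove residual haze; adaptive local-mean thresholding of the nuclear
channel (window half-width defaulting to a quarter of the frame, offset 5%
of the dynamic range) followed by hole filling and largest-component
selection; dilation of the nuclear mask by a 30-px disc, subtraction of the
original mask, and the ring-to-whole-frame intensity ratio as the per-cell
readout. Dilation uses a disc element to preserve isotropy. A ring cut by
the frame edge flags the measurement rather than silently truncating.
Z-stacks are assumed projected; `max_project()` is provided,
deconvolution is not.

On the synthetic suite the measured fraction tracks truth within ~0.02 per
cell across truth 0.1–0.9, and two simulated arms (0.4 vs 0.8 perinuclear,
35 cells each — a depletion-style contrast) separate decisively under a
two-sample t test.

## Problem sizes and numerical choices

The simulation-based checks run at 2000 preys × 1 bait for calibration (50
null datasets) and recovery (10 datasets), 500–1000 preys for the condition
comparison, and 100 + 70 cells for imaging — sizes chosen so the whole
suite completes in a few minutes on a laptop while keeping Monte-Carlo
error well below the decision margins. Numeric tie-breaking and degenerate
inputs are all fixed by contract (worst-of-block BFDR ties, the `p = 1`
rules above, the 0.25 exclusion floor, background floor ε = 0.1), and each
contract is pinned by a test.

## Known limitations

* The scorer is a self-contained SAINT-style model; scores are not
  numerically interchangeable with any external scorer's output, only the
  thresholding behaviour is comparable.
* FDR control is demonstrated under the generator's count model; strongly
  structured contamination (shared across test runs but absent from
  controls) can defeat any control-based scorer and is exactly what the
  manual filters are for.
* `published_benchmark()` reproduces study-level summary counts only when
  the corresponding supplementary scored tables are supplied by the user;
  they are third-party data and not bundled.
* The nuclear segmenter assumes one dominant nucleus per crop; touching
  nuclei require upstream cropping.
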