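---
title: "Integrated stock assignment for Atlantic bluefin tuna: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated stock assignment for Atlantic bluefin tuna: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunamix)
library(dplyr)
```

## The problem

Atlantic bluefin tuna (*Thunnus thynnus*) spawn in two main areas — the Gulf
of Mexico (GoM) and the Mediterranean Sea (Med) — but adults from both
populations feed together across the central and eastern Atlantic.  Catches
from those mixing areas therefore contain fish of both origins in unknown
proportions, and stock assessment needs a way to assign individual fish back
to their natal population.

Two marker families carry the origin signal:

* **Otolith core stable isotopes.**  The otolith core records the water
  chemistry and temperature of the first year of life.  δ¹⁸O (‰ VPDB) is the
  workhorse: GoM fish centre near −1.5 ‰ and Med fish near −0.7 ‰.  δ¹³C is a
  weaker, partially redundant signal.
* **SNP genotypes.**  A small panel of nuclear markers (here represented by
  RAD2, RAD26, RAD35, RAD213) with differentiated allele frequencies between
  the populations; each call is an unordered categorical value
  (homozygous-reference / heterozygous / homozygous-alternate).

`tunamix` implements the integrated analysis: characterise the two
populations from a *baseline* of fish of known origin, fit a classifier that
mixes continuous and categorical features, assign the mixed-origin sample
with an abstention rule, estimate stock composition, and ask — by forward
simulation — whether the observed δ¹⁸O distribution in the mixing areas is
even consistent with a two-population mixture.

## The classifier and the abstention rule

Classification uses a bootstrap ensemble of Gini-split decision trees
(bagged trees with random feature subsetting — the standard random-forest
construction, here through the `randomForest` engine).  Trees handle the
categorical genotype features natively, and out-of-bag (OOB) votes give an
unbiased self-assignment estimate for every baseline fish: each fish is
voted on only by trees whose bootstrap resample excluded it.

Assignment is thresholded on the vote fraction:

* **t = 0.5** — majority rule; an exact 50/50 tie has no majority and the
  fish is left unassigned (UA).
* **t > 0.5** (conventionally 0.8) — a fish is assigned to a class only if
  that class collects at least `t` of the votes, *inclusive*.  The inclusive
  comparison is a deliberate choice: "over 80 %" versus "below 80 %"
  conventions are contradictory exactly at the threshold, and ≥ is the
  variant under which a vote of exactly 0.80 assigns.

Confusion summaries keep unassigned fish in the denominators: a class that
is 85/94 correct with 9 misassigned and 0 unassigned is 90.4 % correct, and
abstentions reduce per-class accuracy rather than disappearing from it.

Hyperparameters default to the conventional values (`n_trees = 500`,
`mtry = ⌊√p⌋`, `min_leaf = 1`), all exposed in `forest_config()` together
with a mandatory seed; identical configuration and seed reproduce the
ensemble, the votes and the importances exactly.

## Variable importance, interactions, and selection

Importance is reported two ways: mean decrease in Gini impurity (split-based)
and mean decrease in OOB accuracy under feature permutation (overall and per
class).

Interaction strength uses the Friedman H-statistic on the
probability-of-first-class scale.  For feature *j*, with centred partial
dependence functions evaluated at the training points (subsampled to at most
300 for the n² prediction cost),

$$H_j^2 = \frac{\sum_i\left[\tilde F(x_i) - \widetilde{PD}_j(x_{ij}) -
\widetilde{PD}_{-j}(x_{i,-j})\right]^2}{\sum_i \tilde F(x_i)^2},$$

clipped into [0, 1]; a constant prediction function has nothing to decompose
and returns `NA`.  One practical caveat discovered while validating the
statistic: a hard-voting tree ensemble estimates class probabilities as the
fraction of trees voting for a class, which sharpens probabilities towards
0/1 and roughens them wherever labels are genuinely noisy.  Both effects are
*non-additive*, so H measured on a vote-fraction surface is substantially
positive even for generative models that are additive on the probability
scale, whenever class overlap leaves noisy-label regions.  The regime in
which "additive ⇒ H ≈ 0" genuinely holds for this model class — and the one
the package's reference checks use — is a dominant, axis-aligned separating
feature with near-deterministic labels; XOR-style labels sit at the opposite
extreme with H near 1.

Variable selection is a two-stage automated procedure:

1. **Threshold stage.**  Candidates are ranked by Gini importance averaged
   over `r_rank = 25` refits; three *shadow features* (permuted copies of
   real candidates, freshly re-permuted every refit) are appended to each
   refit, and the largest importance any shadow achieves in any refit is the
   noise floor.  Candidates whose mean importance sits at or below the floor
   are discarded.  Taking the tail maximum rather than a shadow average
   matters: a pure-noise *candidate* keeps its data-conditional importance
   luck across refits, while re-permuted shadows average theirs away, so
   only a floor drawn from the upper tail of the shadow distribution rejects
   lucky noise reliably.
2. **Confirmation stage.**  Features are added greedily in rank order and
   kept only if they lower the OOB error.  The with/without errors are
   paired across `r_confirm = 5` refits sharing the same seeds, and the mean
   paired difference must beat one standard error of that difference — a
   sharper test than comparing two independently noisy error estimates.
   The empty model is scored at the majority-class error rate, so a lone
   candidate survives only if it beats always-guessing-Med.  All nested
   confirmation models share the mtry of the full candidate pool: with a
   size-dependent mtry, two-feature pools force single-feature splits, and
   adding even a pure-noise feature measurably lowers OOB error by
   decorrelating trees — an effect that would defeat any error-based
   stopping rule.

The refit counts are configuration: ranking needs more replicates because
importances are compared across features, while the confirmation step
compares nested models on the same data and stabilises faster.

## The quadratic-discriminant comparator

The yearling-baseline comparator fits one bivariate Gaussian per class on
(δ¹³C, δ¹⁸O) — class-specific means and covariances, equal priors — and
thresholds the posterior exactly as the forest thresholds its votes.
Singular class covariances are ridge-regularised (a 10⁻⁶ multiple of the
mean diagonal variance) with a warning rather than refused.

## Composition, mixing coefficients, and the three-way comparison

Composition tables are per-area label proportions including UA.  For the
forward mixture simulation the UA share is renormalised over the assigned
classes — unassigned fish carry no origin information, and renormalisation
is the only convention that returns weights on the simplex.  The Central
Atlantic can be split east/west at a configurable longitude cut (default
45° W, the management boundary) when specimens carry longitudes.

The three-way comparison cross-tabulates genetics-only, chemistry-only and
integrated labels fish-by-fish into a 3×3×3 cube whose marginals equal each
method's label counts, plus the agreement summaries (unassigned by both
single methods, by all three, and single-method disagreements resolved or
not by the integrated model).

## Forward simulation of δ¹⁸O mixtures

`mixture_from_baseline()` matches Gaussian components to each population's
δ¹⁸O sample mean and SD, and `draw_mixture()` simulates the mixed sample
that *would* arise if the mixing areas were a random draw from the baseline
populations at the estimated mixing coefficients (conventionally 10⁶
draws).  Gaussian components are the minimal two-parameter family consistent
with matching a mean and an SD per component.

`compare_mixture()` quantifies the visual comparison with
(a) the Kolmogorov–Smirnov distance between the observed empirical CDF and
the closed-form mixture CDF, reported next to the asymptotic 5 % critical
value 1.358/√n, and (b) the observed-minus-expected probability mass in a
δ¹⁸O window, default [−1.4, −1.2] ‰ — the "intermediate" band in which an
excess of fish signals a contingent characteristic of neither baseline —
with its binomial standard error.  The kernel-density overlay (Gaussian
kernel, Silverman bandwidth) is a display aid only and enters no statistic.

## The isoscape

Otolith δ¹⁸O relates linearly to seawater δ¹⁸O and temperature through the
fractionation equation δ¹⁸O_oto − δ¹⁸O_w = γT + β.  γ and β are
species-specific empirical constants and **mandatory configuration**; the
package ships no numeric default and records the provenance string you
supply.  Seawater δ¹⁸O is treated as an annual-mean field; SST enters as the
July–October mean, the period of fastest otolith growth.  Grids are
cell-centred 1° lon/lat tables in delimited text; land cells are explicit
missing values and propagate.  Regional summaries (mean/min/max over
non-missing cells) use rectangular boxes, half-open on their max edges so
adjacent boxes never double-count; the shipped box list
(`default_regions()`) is deliberately approximate and editable.

## The synthetic-data generator

The generator is the package's study-conditions module, not a test fixture:

* Isotopes per population are bivariate Gaussian.  Defaults: δ¹⁸O means
  −1.5 ‰ (GoM) and −0.7 ‰ (Med) — the separation on which everything rests —
  with SD 0.30 ‰, δ¹³C means −9.0/−8.5 ‰ with SD 0.5 ‰, correlation 0.2.
  The δ¹⁸O SD is consistent with the observation that roughly 4 % of the Med
  population falls in the [−1.4, −1.2] ‰ band (a Gaussian with mean −0.7
  and SD 0.30 puts ≈3.7 % there); the δ¹³C parameters and the correlation
  are plain configuration.
* Genotypes are drawn per marker under Hardy–Weinberg from population
  allele frequencies; the four default markers use deliberately divergent
  frequencies (0.15 vs 0.85) chosen once, *not* calibrated to any real
  panel.  Markers are independent — no linkage is simulated.
* Mixed samples draw each fish's component by the design weights, record
  the true component in a sidecar structure that never enters the specimen
  table handed to the assigner, and can mask genotype calls to missing at a
  configurable rate.
* An optional third "intermediate" component (δ¹⁸O −1.2 to −1.4 ‰) emulates
  fish characteristic of neither population.

What passing tests on these conditions show — and what they do not: the
synthetic baselines reproduce the *chemistry* discrimination problem closely
(self-assignment accuracies within about three percentage points of the real
analysis), but the synthetic
SNPs, being four independent, strongly divergent, cleanly typed markers, are
*more* informative than a real panel with linkage, genotyping error and
intermediate frequencies.  Genetics-only accuracy on synthetic baselines
therefore runs high relative to the real analysis, integrated-model OOB
error runs low, and automated selection often stops after two or three SNPs
because accuracy has already saturated.  Results on real baselines should be
expected to sit between the chemistry-only and the optimistic
synthetic-genetics regimes.

## Numerical and design choices

* Ties: exact vote ties at t = 0.5 abstain; Gini split ties are resolved by
  the engine's enumeration order.
* Genotype missingness is distinct from isotope missingness; a fish enters a
  model only with every required feature present, and is otherwise excluded
  from fitting (warning) or skipped at prediction (per-id warning).
* Assignment tables are written at fixed 6-decimal precision for
  reproducible diffs; grid files keep full double precision so write/read
  round-trips are bit-identical.
* Longitudes normalise to [−180, 180); grids rolled by 360° summarise
  identically.
* The pipeline derives per-stage seeds from one global seed
  (`stage_seed = (seed·97 + stage) mod 2³¹−1`), so stages can be rerun in
  isolation and a rerun of the whole configuration is byte-identical.
* Problem sizes in the package's own checks: baselines of 94/290 (the
  chemistry design) and 45/105 (the combined design), 700-fish mixtures for
  composition recovery, 10⁴-draw replicates for distributional checks, and
  10 refits wherever accuracies are averaged over seeds.

## Known limitations

* The spec of a real 96-SNP panel — linkage, null alleles, genotyping error —
  is out of scope; the generator's four independent markers bound genetics
  performance from above.
* No EM fitting of mixture models: the mixture module simulates forward
  only, as the analysis requires.
* No formal mixed-stock likelihood estimator; composition is assignment
  counting.
* NetCDF grids are not read directly; gridded inputs arrive as long-format
  delimited text.
* Region summaries use rectangles, not polygons; coastal regions inherit
  that coarseness.

## A worked synthetic run

```{r example, eval = FALSE}
pops <- default_populations()
baseline <- make_baseline(pops, n_per_pop = c(Med = 290, GoM = 94), seed = 1)
fit <- fit_forest(baseline, c("d13C", "d18O"), forest_config(seed = 1))
glance(fit)
res <- assign_stock(fit, baseline)
confusion_summary(res, baseline, threshold = 0.8)

mixed <- make_mixed(
  mixture_design(list(pops$GoM, pops$Med), c(0.2, 0.8), n = 700),
  seed = 2
)
est <- composition_by_area(assign_stock(fit, mixed), mixed, threshold = 0.5)
mixing_coefficient(est)
```
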