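# tunamix

Integrated mixed-stock assignment for Atlantic bluefin tuna (*Thunnus
thynnus*) from otolith core stable isotopes (δ¹³C, δ¹⁸O) and SNP genotypes.

## The problem

Bluefin tuna from the Gulf of Mexico (GoM) and Mediterranean (Med) spawning
populations mix across the Atlantic, so catches from the central and eastern
Atlantic contain fish of both origins in unknown proportions.  `tunamix`
characterises the two populations from *baselines* of fish of known origin
and assigns fish of unknown origin to a stock, abstaining when the evidence
is equivocal:

* a bootstrap tree-ensemble classifier over mixed continuous (isotope) and
  categorical (genotype) features, with out-of-bag (OOB) vote bookkeeping so
  baseline self-assignment is unbiased;
* abstention thresholds on the vote fraction: at t = 0.5 a fish takes the
  majority class, at t = 0.8 it is assigned only if a class holds ≥ 80 % of
  votes, otherwise it is unassigned (UA);
* Gini and permutation variable importance, Friedman H-statistic interaction
  measures, and automated shadow-feature variable selection;
* a quadratic-discriminant comparator for isotope-only baselines;
* per-area stock composition, mixing coefficients (UA renormalised over
  assigned fish), and a fish-by-fish three-way comparison of the
  genetics-only / chemistry-only / integrated methods;
* forward simulation of the δ¹⁸O distribution expected under a
  two-component Gaussian mixture matched to the baseline
  (δ¹⁸O_GoM ≈ −1.5 ‰, δ¹⁸O_Med ≈ −0.7 ‰), with a Kolmogorov–Smirnov
  distance and the observed-minus-expected mass in the "intermediate" band
  [−1.4, −1.2] ‰;
* otolith δ¹⁸O isoscapes from gridded seawater δ¹⁸O and July–October mean
  SST via the fractionation equation δ¹⁸O_oto − δ¹⁸O_w = γT + β (γ, β are
  mandatory, provenance-tagged configuration), with regional summaries.

A first-class synthetic-data module (`make_baseline()`, `make_mixed()`,
`make_grid()`) generates baselines, mixed samples and grids with the
statistical structure the analysis assumes — bivariate Gaussian isotope
signatures, Hardy–Weinberg genotypes, configurable mixing weights, missing
genotype contamination and an optional intermediate third component — so the
whole pipeline runs and is tested without any external data.

## A worked example

```r
library(tunamix)

pops <- default_populations()
baseline <- make_baseline(pops, n_per_pop = c(Med = 290, GoM = 94), seed = 1)

fit <- fit_forest(baseline, c("d13C", "d18O"), forest_config(seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>       n n_trees  mtry n_features classes oob_error_pct
#>   <int>   <int> <dbl>      <int> <chr>           <dbl>
#> 1   384     500     1          2 GoM/Med          9.11

res <- assign_stock(fit, baseline)          # baseline fish get OOB votes
confusion_summary(res, baseline, threshold = 0.8)
#> # A tibble: 3 × 6
#>   true    GoM   Med    UA     n pct_correct
#> * <chr> <int> <int> <int> <dbl>       <dbl>
#> 1 GoM      51    10    33    94        54.3
#> 2 Med       8   259    23   290        89.3
#> 3 Total    59   269    56   384        80.7

mixed <- make_mixed(
  mixture_design(list(pops$GoM, pops$Med), c(0.2, 0.8), n = 700),
  seed = 2
)
est <- composition_by_area(assign_stock(fit, mixed), mixed, threshold = 0.5)
mixing_coefficient(est)
#> # A tibble: 1 × 4
#>   area      n weight_GoM weight_Med
#>   <chr> <int>      <dbl>      <dbl>
#> 1 CA      700      0.203      0.797
```

The OOB error (9.1 %) is the fraction of baseline fish whose out-of-bag
majority vote misses their true origin.  At the 80 % abstention threshold
the per-class `pct_correct` counts unassigned fish in the denominator — the
GoM class loses more fish to abstention because it sits closer to the
overlap zone and is the smaller class.  On the 700-fish mixed sample the
majority-rule mixing coefficient (0.203 GoM) recovers the generating weight
(0.2) to within binomial error.

`run_pipeline()` chains the whole analysis (three models, baseline
confusions, mixed-sample assignment, three-way comparison, mixture
simulation) from one YAML/list configuration into an output directory with
a JSON manifest; reruns with the same configuration are byte-identical.

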