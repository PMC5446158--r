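---
title: "Flowering-potential profiles: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowering-potential profiles: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

Grassland plant surveys record, per plot, the percent cover of each species
at peak biomass. Because canopies overlap, plot totals routinely exceed
100%, so covers are first converted to *relative cover*: each species'
cover divided by the plot total, summing to one over the analysed taxa.

The *flowering potential* (FP) of a plot in month $m$ distributes this
peak-season snapshot across the calendar using published flora records of
when each species flowers:

$$\mathrm{FP}(m) \;=\; \sum_{i \in \text{plot}} r_i \, w_i(m),
\qquad w_i(m) = \mathbf{1}\{m \in M_i\},$$

where $r_i$ is species $i$'s relative cover and $M_i \subseteq \{1..12\}$
its flora-reported flowering months. FP lies in $[0, 1]$ and equals 1 only
when every analysed species in the plot flowers that month. For example, a
species with relative cover 0.117 that flowers June through August adds
0.117 to the plot's June, July and August FP and nothing to May.

Subset profiles (exotic, native, forb, C3 graminoid, C4 graminoid, legume)
use the *same* relative covers with weights zeroed outside the subset —
there is no re-normalisation within the subset. Consequently exotic and
native FP add up to total FP wherever provenance is known, and the
functional-group profiles add up to the total in herbaceous-only
communities. We chose this reading (over within-subset re-normalisation)
precisely because it preserves that additivity, making a subset profile
interpretable as the share of whole-community cover in flower.

Two exclusion rules are applied before relativisation: taxa identified only
to genus (e.g. *Carex* sp.) and tree seedlings carry no usable flowering
interval and are removed; so are taxa with no trait record at all, with a
logged warning. Relativising *after* exclusion keeps the analysed
composition summing to one; the alternative order (relativise first, then
drop) would leave plot compositions summing to less than one by an amount
depending on how much unidentifiable cover the plot happened to hold.

The *flowering volume* is the area under a plot's FP-versus-month curve
over January–December, computed by the trapezoidal rule on the month index
(unit spacing, no extrapolation beyond the end months). On the percent
scale a curve pinned at 100% all year integrates to 1100; volumes are
reported in percent-cover · months. Months are treated as equally spaced;
weighting by actual day counts would change volumes by at most a few
percent and has no bearing on treatment comparisons, which share the
spacing.

Scale conventions: proportions internally everywhere; percent (×100) in
all written outputs and in the statistical models, so that profile means,
contrast estimates and volumes are directly readable as percent cover.

## The mixed models

Growing-season FP (May–October) is modelled per subset with a linear mixed
model: fixed effects are the full factorial of nitrogen, phosphorus,
potassium(+micronutrients), month (6 levels) and ecoregion (tall-, mixed-,
short-grass), with random intercepts for site and for block nested within
site. Flowering volume is modelled the same way without the month factor.
Choices the model surface leaves open, and what this package does:

* **Estimation** is REML, the standard for F-tables from nested designs.
* **F tests** are marginal (each term tested last) under sum-to-zero
  factor coding. On the complete balanced factorial these coincide with
  sequential tests (a unit test asserts agreement to $10^{-8}$); under
  mild imbalance marginal tests remain well-defined.
* **Denominator df** follow the containment method as implemented for this
  model class: terms varying within blocks are tested against the
  residual stratum, ecoregion against the site stratum. Numerator df are
  design-determined: with 6 months and 3 ecoregions, Month has 5,
  Ecoregion 2, N×Month 5, Month×Ecoregion and N×Month×Ecoregion 10.
* **No plot-level random effect across months.** The six monthly FP values
  of a plot derive from one survey and are treated as independent
  residuals. This is deliberate, mirroring how the denominator df of
  field analyses of this design scale with the observation count, and it
  is a known pseudo-replication caveat: month-wise inference is
  anti-conservative to the extent that within-plot FP values are
  correlated beyond what site and block effects absorb.
* **Contrasts.** The nitrogen effect per month is the model-based mean of
  the four +N treatment combinations minus the four without N, averaged
  over the other factors — the least-squares-means construction, built
  here as estimable functions on a full reference grid (and cross-checked
  against emmeans in the test suite). p-values use the residual-stratum
  df; the Bonferroni family is exactly the set of contrasts produced by
  one call: 6 when pooled over ecoregions, 18 when split by ecoregion.
  Families are never pooled across response subsets. Stars: \*\*\* < 0.001,
  \*\* < 0.01, \* < 0.05 on adjusted p.

A design with a single site per ecoregion leaves zero denominator df for
the ecoregion main effect (its F is reported as NaN); every other row of
the table, and all nitrogen contrasts, remain valid, which is why the
reduced-scale simulation suites can use such designs.

## The synthetic generator

No field data ship with the package; a generator produces surveys with the
same structure so every stage is testable end to end. It emulates:

* the crossed design — 8 NPK(+μ) combinations per block, 3 blocks per
  site by default, sites split 3/2/3 across tall-, mixed- and short-grass
  ecoregions (a reduced-scale echo of the 6/2/3 split of the field
  network; `synthetic_config_field_scale()` provides 6/2/3 = 11 sites);
* ecoregion species pools (default 40 includable species) with long-tailed
  baseline abundances (Gamma weights, shape 0.7, i.e. Dirichlet-type
  dominance), 25% exotics, and a functional-group mix of 40% forbs, 20%
  C3 graminoids, 20% C4 graminoids, 10% legumes, 10% woody;
* guild-structured phenology: flowering windows are 1–4 months long
  (probabilities 0.20/0.35/0.30/0.15) with starts drawn per guild —
  cool-season C3 graminoids and exotics early (peak May), native forbs
  and legumes mid-to-late summer, warm-season C4 graminoids late (peak
  August–September) — the canonical phenological layering of central-plains
  prairie;
* overlapping canopies: plot cover totals are drawn from 80–160%, so the
  over-100% relativisation path is exercised (individual covers are capped
  at 100%);
* observation noise: each species' expected cover is perturbed by
  log-normal noise with log-scale SD 0.4, a typical between-plot
  coefficient of variation for percent-cover estimates;
* genus-only placeholders and a tree seedling per ecoregion, carrying
  cover that must be excluded by the rules above.

The injected nitrogen effect is *multiplicative on expected absolute
cover*, not on relative cover: under added N, early-flowering (May/June)
exotics are scaled by 1.8 and early C3 graminoids by 1.6, while
late-flowering (September/October) C4 graminoids are scaled by 0.6, in the
tallgrass stratum only by default. Because relativisation follows, the
compositional trade-off — boosted early species crowding out everything
else — emerges rather than being hard-coded, and the resulting expected
FP difference profile (`synthetic_truth()`, the zero-noise limit) is kept
alongside the data for recovery tests. With all multipliers at 1 the truth
is identically zero and the pipeline's contrast family should fire at no
more than its nominal family-wise rate.

Determinism: all randomness flows from one configured seed; the pool is
drawn from `seed` and the covers from `seed + 1`, so repeated calls are
byte-identical file for file.

What the generator does *not* emulate — and therefore what passing tests
do not establish about field data: taxonomic misidentification, spatial
autocorrelation among blocks, year-to-year dynamics, climate covariates,
within-ecoregion site heterogeneity in species pools (all sites of an
ecoregion share one pool), heteroscedasticity between ecoregions, and
flora-to-field mismatch in flowering windows. Calibration results on
synthetic data bound what the method does under its own assumptions, not
how prairie communities behave.

## Problem sizes in the simulation suites

The null-calibration suite runs 500 datasets at one site per ecoregion and
two blocks (48 plots, 288 model rows each) and checks that the pooled
six-contrast Bonferroni family flags anything in at most 5% of datasets
(plus two binomial standard errors). The recovery suite runs 200 datasets
at the full default scale (192 plots) and requires the tallgrass May/June
increases and September/October decreases to be recovered — correct sign
and adjusted p < 0.05 for all four months — in at least 80% of runs, with
no systematic detections in the unaffected ecoregions. These sizes keep
one full check of the package under half an hour on a single core while
leaving the Monte-Carlo error well below the margins being asserted.

## Known limitations

* Monthly resolution only; floras rarely support finer phenology, and no
  within-month interpolation is attempted.
* The FP weight is 0/1; intensity of flowering within the window is not
  modelled.
* Provenance "unknown" species count toward total FP but toward neither
  provenance subset, so the provenance partition is exact only when all
  provenances are known.
* The pseudo-replication caveat above applies to all month-wise inference.
* Containment df, REML and marginal tests are one defensible convention
  set; exact F and df values from other software on unbalanced field data
  will differ.
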