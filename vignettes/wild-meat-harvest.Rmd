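---
title: "Estimating wild-meat harvest, availability and nutrient adequacy on a gridded landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wild-meat harvest, availability and nutrient adequacy on a gridded landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildharvest)
```

## The estimation problem

Subsistence hunting supplies a large share of animal protein to rural
populations across tropical forest landscapes, yet harvest is observed only
at scattered monitored localities. `wildharvest` implements a pipeline that
extrapolates locality-level hunting records to a full gridded landscape
(nominal 10 x 10 km cells, 100 km^2^ each) and follows the harvest through
to its nutritional consequences. Two locality-level metrics anchor
everything:

* **HHR** (hunter harvest rate): animals hunted per hunter per day at a
  locality — total kills divided by total monitored hunter-days, counting
  days with no hunting and days with no harvest.
* **TSOP** (taxon-specific offtake proportion): the fraction of a
  locality's kills belonging to one taxon, so each locality's TSOP vector
  (including an `"undetermined"` share) is a probability vector.

The pipeline stages are: record harmonisation and filtering; trait metrics
with Monte Carlo uncertainty; covariate extraction with temporal epoch
matching; a subsampled random-forest ensemble predicting the harvest
productivity (HP) surface; per-taxon TSOP surfaces clipped to ranges and
renormalised; offtake accounting (individuals and biomass) with density
caps; edible-meat conversion and per-capita availability; and dietary
reference intake (DRI) adequacy.

## The harvest-productivity model

`hp_ensemble()` fits HHR as a function of the covariate stack plus the
recording-span covariate (an effort control: studies that monitored longer
record differently). The ensemble design is:

* 30 members, each a regression forest trained on a seeded 70% subsample of
  localities drawn without replacement;
* one full-data forest fitted solely for the permutation-importance
  ranking;
* spatial prediction per member, then *cellwise* empirical quantiles at
  0.10, 0.25, 0.50, 0.75, 0.90 across members. The mean and standard
  deviation surfaces are computed from that five-grid stack, and the
  reported 90% interval is the q10–q90 pair.

This "subsample, predict, summarise cellwise" scheme reconciles two
requirements with a single mechanism: member-level subsampling expresses
sampling uncertainty, and the five-quantile summary gives monotone,
well-ordered uncertainty surfaces. "Central" is taken to be the member
median. At prediction time the recording-span covariate is frozen at the
training-set median, so surfaces are comparable across cells at a common
reference effort.

Forest hyperparameters are deliberately plain: 500 trees per member, the
engine's default split-candidate count, per-member seeds `base_seed + i`.
The ensemble is reproducible end to end from one seed.

TSOP models are single seeded forests per taxon (no span covariate), for
two reasons: the per-taxon training sets are far smaller, and the
downstream cellwise renormalisation makes member-level uncertainty in the
proportions second-order. The ensemble machinery accepts any member count
should per-taxon ensembles be wanted. Training rows are localities with a
positive TSOP plus explicit zeros where the taxon's range covers a recorded
locality but no kills of it were recorded; localities recording both a
taxon and its enclosing higher taxon are excluded from the lower taxon's
training set (the higher-taxon rows siphon counts and would bias the
proportion downward). Taxa with fewer than 10 usable rows fall back to a
constant surface at the training mean — a deliberate floor, since models
for sparsely recorded taxa are unreliable at any setting.

The per-taxon surfaces are clipped to [0, 1] and to the taxon's range, then
renormalised cellwise so in-range proportions sum to one; cells where every
in-range proportion is zero are masked. Multiplying the overall HP surface
by each normalised TSOP surface yields taxon-specific HP surfaces that sum
back to the overall surface exactly (to floating-point).

## From productivity to offtake, meat and nutrients

* **Hunters.** The rural-population grid (APPS) is the population grid with
  urban cells zeroed and out-of-boundary cells masked. Hunter grids (RHPS)
  are APPS times the hunter-to-consumer ratio quantiles; with no data
  supplied the packaged constants are used (median 0.178; 0.10/0.25/0.75/
  0.90 quantiles 0.168, 0.173, 0.183, 0.187).
* **Offtake.** Annual per-taxon extraction per cell is
  `HP x hunters x 365` (leap years ignored), truncated at the taxon's
  standing density where one is known: the cap is the mean density in
  individuals per 100 km^2^, i.e. per cell, with no harvest-fraction
  multiplier — the interpretation that follows directly from defining the
  cap by average density. Truncation events are flagged so the share of
  cap-bound cells is auditable.
* **Biomass.** Individuals times body mass, propagated quantile by
  quantile (q10 offtake x q10 mass, and so on). Cross-quantile mixing is
  not attempted; the headline surface uses median masses.
* **Edible meat.** The pooled edible fraction 0.585 of undressed biomass by
  default; a group-specific path applies carcass yields per taxonomic group
  (mammals 0.63, birds 0.73, chelonians 0.47, caimans 0.45) and sums.
* **Availability.** Daily edible grams divided by APPS, masked where nobody
  lives (division by zero population is meaningless, not zero).
* **Adequacy.** The APPS grid is split into children/women/men by
  demographic shares, multiplied by per-person daily requirements and
  summed into requirement surfaces; supply is edible grams times nutrient
  content per 100 g. Requirement rules follow the DRI hierarchy: EAR where
  defined, AI/RDA otherwise, the AMDR midpoint (converted through group
  energy requirements) for total fat, EER for energy. The packaged DRI and
  share tables are editable CSVs (`inst/extdata/`); the nutrient-unit
  column is mandatory input because source composition tables vary in
  units. A literature-derived table of continental-scale adequacy
  percentages ships as reference metadata
  (`inst/extdata/reference_adequacy.csv`); it is context, not a test
  target, because it depends on composition and DRI tables outside this
  package's inputs.
* **Counterfactual.** `beef_counterfactual()` converts annual edible
  production into the pasture area needed to replace it at a given beef
  yield (kg ha^-1^ day^-1^) and the associated one-off deforestation
  emissions at 18,000 t CO2 per km^2^. The function exposes the formula;
  published interval endpoints additionally depend on Monte Carlo quantiles
  of production, so area ranges are reported per yield endpoint supplied.

## Monte Carlo uncertainty

Scalar traits (body mass, density, ratios, yields, nutrient contents) are
summarised by `monte_carlo_metric()`: 1,000 draws from a normal with the
estimate's mean and standard error, reported as mean, SD and the
0.10/0.25/0.50/0.75/0.90 quantiles. Two numerical choices matter:

* For strictly positive quantities, negative draws are **redrawn**, not
  truncated to zero: truncation would put a probability atom at 0 and
  distort the lower quantiles.
* Standard errors are `sd/sqrt(n)` from observation tables; a single
  observation gives `se = 0` (an honest point mass rather than an invented
  spread).

Note the q10–q90 span is an 80% central interval of the draw distribution;
its two-sided frequentist coverage of an underlying true mean (when the
input mean is itself an estimate with that standard error) is
`2 * pnorm(qnorm(0.9)) - 1`, about 80%, not 90%. The package reports the
quantile pair as defined and leaves the interpretation to the caller.

## The synthetic-data generator

Real hunting-record datasets of this kind are not publicly distributable,
so validation rests on a generator whose ground truth is known:

* **Covariates** are smoothed white noise (3 x 3 blur, 3 passes):
  the cheapest spatially autocorrelated field with a tunable range —
  sufficient for recovery tests, with no pretence of realistic geography.
  Categorical layers (language families, Indigenous/non-Indigenous, URCA
  travel-time classes) are contiguous quantile patches of smoothed fields.
  Habitat-loss and vegetation-index layers carry 5-yearly epoch variants
  (1985–2020 and 2000–2020) to exercise epoch matching; record years snap
  to the nearest epoch with clamping at both ends.
* **True productivity** is a known monotone function of the
  vegetation-index field (the dominant driver by construction) with weaker
  soil and habitat-loss effects and categorical offsets, scaled to a mean
  of 0.07 individuals per hunter-day — so recovery and variable-importance
  tests have an unambiguous right answer.
* **Taxa** have log-normal body masses (default several orders of
  magnitude, as real hunted assemblages span), log-normal densities for
  ~80% of taxa, and contiguous disc ranges covering at least 10% of the
  landscape.
* **Communities** sit on non-urban in-boundary cells; hunters are binomial
  in consumers at ratio 0.178. Recording spans are uniform over a
  configurable interval so the effort covariate varies.
* **Records** are Poisson in `rate x hunters x span`, with kills assigned
  multinomially from range-restricted true proportions and a small
  undetermined share.

What the generator does **not** emulate: seasonality, hunter behaviour and
trip structure, spatial clustering of communities along rivers, taxonomy
errors beyond a flat relabelling, and reporting biases of secondary
sources. Passing recovery tests therefore demonstrates that the estimation
machinery inverts the generative model it assumes — not that the
assumptions hold for any particular real dataset.

## Problem sizes and numerical tolerances

The reference fixture used throughout the tests and the acceptance script
is a 40 x 40 landscape with 12 taxa and 120 localities (600 localities for
ensemble-recovery checks), chosen so a full pipeline run takes seconds
while leaving every mechanism — filtering, epoch matching, range clipping,
truncation, renormalisation — non-trivially exercised. Conservation and
normalisation identities are asserted to 1e-9 (relative and absolute
respectively); they hold to machine precision. Grid I/O uses a
self-describing ASCII format with `%.17g` values, which round-trips double
precision exactly and keeps every artifact diff-able text.

## Known limitations

* Grids must be pre-aligned on a common lattice; reprojection and
  resampling live upstream.
* The density cap is a standing-stock bound, not a sustainability
  criterion; no population dynamics are modelled.
* Trade and urban consumption are out of scope by design.
* TSOP surfaces for sparsely recorded taxa are constant fallbacks, and the
  undetermined category enters denominators but is never modelled.
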