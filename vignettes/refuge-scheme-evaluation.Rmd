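---
title: "Prioritizing and evaluating farmland goose refuges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing and evaluating farmland goose refuges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

## The management problem

Spring-staging geese commute daily from coastal and lake roosts to
farmland fields, grazing pastures hardest close to the roosts. A subsidy
scheme pays farmers to tolerate geese on selected fields ("refuges"), and
a limited budget forces a choice of *which* fields. `refugia` implements
the whole decision-and-audit loop: rank fields by suitability, spend the
budget down the list, simulate the dropping-count survey used to audit
the scheme, and compute the evaluation statistics, ending in a single
efficiency figure — the share of regional grazing pressure the refuges
capture.

Because the GIS layers behind real schemes are administrative data and
not public, the package treats the synthetic landscape generator as a
first-class module: every downstream stage runs, and is tested, against
seeded artificial landscapes with the statistical structure the analysis
assumes.

## The synthetic landscape

`generate_landscape()` builds a coastal farmland mosaic of
non-overlapping, axis-aligned rectangular fields. Rectangles (rather
than irregular polygons) keep every geometric quantity — centroids,
boundary distances, circle placement margins — exact and cheap, and
nothing downstream depends on parcel shape beyond those quantities.
Fields are laid out in east–west bands starting at the coast line, with
gaps between neighbours drawn from a mixture: about a third of the gaps
are short (0–15 m), so that a realistic fraction of neighbouring fields
counts as adjoined under the 20 m adjacency threshold, and the rest are
30–150 m.

Defaults describe the study conditions the package targets:

| parameter | default | why |
|---|---|---|
| `n_fields` | 1008 | size of the regional field pool |
| `area_range_ha` | 0.2–14.41 | observed range of refuge field sizes |
| field-area law | log-normal, median 2 ha, truncated to the range | right-skewed parcel sizes with a few large fields; the resulting mean (≈ 3–4 ha) matches reported refuge means |
| `pasture_fraction` | 0.26 | grassland share of regional farmland |
| `extent_m` | 20 × 20 km | accommodates ~1000 fields at these sizes with realistic spacing |
| `n_roosts` | 3 (1 coast line + 2 lakes) | geese roost on coasts and lakes |
| `historic_window_years` | 4 | a four-season record of goose use |

Historic use is a binomial draw per season with success probability
`0.75 * exp(-d/5000)` in roost distance `d` — sites near roosts are used
almost every season, distant ones rarely, mirroring the distance decay
the deposition model assumes.

What the generator does *not* emulate: irregular parcel shapes, rivers
as roosts, woodland shading, farm ownership structure, scaring activity,
or between-year dynamics. Tests passing on these landscapes therefore
certify the *workflow* — ranking arithmetic, budget accounting, survey
protocol, estimator behaviour — not any claim about a particular real
region.

## The deposition model

The expected dropping intensity (droppings m⁻²) at the centre of field
*f* is

```
centre(f) = base(f) · m(crop_f) · exp(-d_f / s)
```

with `base` equal to `lambda_refuge` on refuges and `lambda_far`
elsewhere, `m` a crop defecation-rate multiplier, `d_f` the centroid
distance to the nearest roost and `s` the decay scale. Within a field,
intensity falls linearly from the centre value to `edge_gradient` times
it at the boundary, using relative boundary depth as the coordinate —
geese use field centres most and edges (roads, buildings, woodland)
least.

Defaults and their reasoning:

* `lambda_refuge = 3.56`, `lambda_far = 0.27` droppings m⁻²: the
  refuge/non-refuge density contrast observed on pastures; these are
  *centre intensities at distance zero*, so realized field means are
  lower.
* `decay_scale = 5000` m: staging geese do most of their field foraging
  within roughly 5–10 km of the roost; an e-folding scale of 5 km puts
  strong use inside that commute range. Only the *sign* of the resulting
  distance–density correlation is treated as a checkable outcome; its
  magnitude depends on landscape geometry.
* `edge_gradient = 0.5`: edge use at half the centre intensity — a
  moderate edge avoidance. Conveniently, the three-circle protocol
  samples relative depths 1, 2/3 and 1/3, so the protocol mean is the
  same fraction of the centre intensity for every field and the edge
  gradient does not distort between-field comparisons.
* `crop_multiplier = (pasture 1, stubble 0.5, new_sown 0.5, other 0.1)`:
  geese defecate more while grazing grass than grain; "other" crops are
  essentially unused.

Setting `decay_scale = Inf`, `edge_gradient = 1` and a unit multiplier
gives the flat model used in several tests, where intensities equal the
lambdas exactly.

## Ranking, fractiles, allocation

Ranks use average ties so that tied fields contribute identical rank
sums. Two deterministic tie-breaks keep output reproducible: equal rank
sums order by smaller roost distance, then by field id. The fractile
partition slices the priority order into `ceiling(1/width)` consecutive
groups whose sizes differ by at most one, giving any remainder to the
highest-priority fractiles (with 1008 fields and 5 % fractiles the first
eight fractiles hold 51 fields, the rest 50).

Connectivity has no canonical formula in this setting; the package uses
the summed area of fields with centroids within 1000 m — monotone in
local field aggregation and cheap to verify by brute force. The radius is
a configuration knob.

The allocation is a greedy pass, not an optimizer: at each step the
affordable candidate with the lowest *effective* rank sum is selected,
where adjacency to an already-selected field earns a credit of
`adjoin_bonus` rank-sum points (default 200 in the pipeline
configuration — enough to promote a neighbour past ~5 % of a 1008-field
ranking, a mild preference rather than an override; `adjoin_bonus = 0`
reproduces the pure priority list). Fields are subsidized whole or not at
all; pasture is costed at the pasture rate, new-sown and stubble at the
new-sown rate (subsidized stubble is stubble about to be sown); other
crops are ineligible. With uniform costs and no bonus, the selection
provably reduces to the top-k of the ranking, which anchors both a unit
test and the ideal limit of the coverage curve.

## Survey simulation

Circle counts are Poisson with mean `intensity × circle area`; the field
protocol records real counts, so the noise law is a modelling choice —
Poisson is the natural minimal model for counts of independent
droppings, and a negative-binomial hook (`dispersion` in
`survey_design()`) is available for overdispersion studies, off by
default. Dropping persistence is treated as full-season accumulation
with no decay.

Control similarity weighting is defined as
`w = 1 / (1 + |P - P̄| / max(P, P̄))` for candidate perimeter `P`
against the mean refuge perimeter `P̄`: the relative difference is
scaled by the larger of the two so the weight is bounded in (1/2, 1],
symmetric in its arguments, and scale-free. A candidate at the refuge
mean gets weight 1; one with double (or half) the perimeter gets 2/3.

The survey estimand deserves a note: the "true" density of a field is
defined as the noiseless protocol value — the mean intensity at the
three circle centres — because that is the quantity the field protocol
measures. The end-to-end recovery test compares the survey-based
captured share against the share computed from these noiseless
densities averaged over *all* pasture fields of each stratum, so it
checks sampling and noise, not an unattainable area-integral.

## Evaluation statistics

* Refuge/control comparison: two-sample *t*, pooled-variance Student
  form by default (`test = "welch"` available). Degrees of freedom are
  reported from the formula; no attempt is made to reproduce any
  externally reported df.
* Spearman correlations are computed as Pearson on average ranks with a
  *t*-approximation p value — adequate for n in the tens to hundreds;
  no exact permutation.
* Adjoined refuges are analysed as merged units: grouped area, mean of
  member densities, roost distance from the area-weighted member
  centroid.
* No multiple-testing correction is applied anywhere.
* The efficiency report keeps all arithmetic unrounded; printing rounds
  for display only.

## Reproducibility and problem sizes

Every stochastic operation is a pure function of its seed; the pipeline
derives a distinct seed per stage by hashing the master seed with the
stage name, so stages never share an RNG stream and any stage can be
re-run in isolation. All internal computation is in metres and
hectares/km² conversions happen only at interfaces.

The simulation studies in the test suite use 200 small landscapes for
the ranking oracle, 500 landscapes of 78 fields for the
distance-decay sign property, and 100 study-scale replicates (1008
fields, 90 + 138 surveys) for share recovery — sizes chosen to make the
binomial pass criteria (≥ 95 % negative correlations, ≥ 90 % within
3 percentage points) statistically meaningful while keeping a full run
of the suite in the low minutes.

## Known limitations

* Landscape realism is deliberately minimal (rectangles, two roost
  kinds, static season); the generator supports workflow validation,
  not habitat inference.
* Farmer participation is not modelled: the allocation assumes every
  prioritized field is available for subsidy.
* Scaring on neighbouring fields, food quality and depletion, and
  goose population dynamics are all outside the model.
* The captured-share statistic inherits the usual sensitivity to the
  assumed suitable area; the packaged sensitivity check (inflating the
  area 50 %) shows the majority share is robust to that particular
  misspecification, not to all of them.
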