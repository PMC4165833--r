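# refugia

Spring-staging geese feeding on farmland pastures put wildlife managers in
a standing conflict with farmers. One regional answer is a subsidy scheme:
farmers are paid to leave selected fields as undisturbed goose refuges,
and the limited budget is allocated down an ecological priority list.
`refugia` implements that prioritization-and-evaluation workflow end to
end, for managers and ecologists who want to design such a scheme or audit
one — and, because the underlying GIS layers of real schemes are rarely
public, it ships a seeded synthetic-landscape generator so every stage can
be exercised, tested and benchmarked without any external data.

## The method

**Prioritization.** Every field *i* gets a rank on each of four suitability
criteria — area *A_i* (larger is better), connectivity *C_i* (summed area of
fields with centroids within a 1 km radius), seasons of historic goose use
*H_i*, and distance to the nearest roost *D_i* (smaller is better). The
priority score is the rank sum

    S_i = rank(A_i) + rank(C_i) + rank(H_i) + rank(D_i),

with average ranks on ties; fields are ordered by ascending *S_i* and cut
into 5 % and 20 % priority fractiles.

**Allocation.** A fixed budget (default 1.44 M NOK at 3000 NOK ha⁻¹ for
pasture, 1000 NOK ha⁻¹ for new-sown or to-be-sown stubble) is spent
greedily down the priority list; a configurable rank credit favours fields
adjoining already-selected refuges, so refuges merge into larger units.

**Survey.** Goose grazing pressure is measured as dropping density:
three 2 m-radius circles per field (centre, two-thirds and one-third of
the edge-to-centre distance from the nearest edge), the mean count divided
by circle area giving droppings m⁻². Control fields are drawn at random
from non-refuge fields within 2 km of a refuge, weighted by similarity in
circumference to the refuges.

**Evaluation.** Refuge vs control densities are compared by Student's *t*
test per crop stratum, distance decay is tested with Spearman correlations
over merged refuge units, refuge area is tallied over priority fractiles,
and the scheme's efficiency statistic is the captured share of grazing
pressure,

    share = (a_r d_r) / (a_r d_r + a_n d_n),

with *a_r*, *a_n* the refuge and non-refuge pasture areas and *d_r*, *d_n*
their mean dropping densities.

## Worked example

The regional bookkeeping: a 104 km² suitable area of which 26 % is
grassland, 3.6 km² of refuge pasture, and observed mean densities of 3.56
and 0.27 droppings m⁻² on refuge and non-refuge pasture:

```r
library(refugia)
estimate_efficiency(
  suitable_area_km2 = 104, grass_fraction = 0.26,
  refuge_pasture_km2 = 3.6,
  density_refuge = 3.56, density_nonrefuge = 0.27
)
#> <efficiency_report>
#>   grassland 27.0 km^2 (refuge 3.6, non-refuge 23.4)
#>   densities 3.56 vs 0.27 droppings m^-2
#>   share captured 66.9 % on 13.3 % of the pasture area
```

Refuges holding 13 % of the pasture area capture two-thirds of the goose
grazing pressure — the density contrast (a 13-fold ratio) does the work.

A full simulated scheme — generate a ~1000-field coastal landscape, rank,
allocate the budget, survey 90 refuge and 138 control fields, evaluate:

```r
res <- run_pipeline(default_config(master_seed = 1))
res
#> <pipeline_result> 1008 fields -> 215 refuge fields (155 units)
#> <comparison_result> pasture (student t): t = 51.62, df = 60.0, p = 2e-51
#>   means 2.342 vs 0.129 m^-2 (ratio 18.1)
#> <correlation_result> r_s = -0.20, p = 0.0866, n = 74
#> <efficiency_report>
#>   grassland 6.8 km^2 (refuge 2.8, non-refuge 4.0)
#>   densities 2.34 vs 0.13 droppings m^-2
#>   share captured 92.6 % on 40.9 % of the pasture area
```

Here the refuge/control density comparison is overwhelming (the simulated
contrast is strong and the survey precise), density declines with roost
distance across merged refuge units (negative r_s), and the survey-based
captured share (92.6 %) recovers the noiseless truth for this landscape to
about one percentage point. `run_pipeline(cfg, out_dir = "run1")` writes
every stage artifact (landscape GeoJSON, ranking CSV, refuge GeoJSON and
cost ledger, survey CSV, evaluation JSON) plus a manifest of seeds and
file hashes.

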