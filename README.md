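# dogedge

Free-roaming village dogs forage kilometers away from the settlements
that feed them, carrying predation risk, harassment and disease deep into
neighboring wildlife habitat. Because dogs are anchored to residences,
their influence is an **edge effect** that decays with travel distance
from populated areas — and in steep terrain the distance that matters is
the distance walked over the surface, not the straight line on the map.

`dogedge` is an R package for conservation analysts who need to quantify
this edge effect around protected areas: how much habitat lies within
reach of dogs, whether a species' occurrence records avoid that zone, and
which reserves should be prioritized for dog-control programs. It ships a
synthetic-landscape generator so the whole pipeline runs and is tested
without access to sensitive occurrence data.

## The model

1. **Populated areas.** Residence points become a housing-density surface
   via a circular moving window of area exactly 1 km² (radius
   √(10⁶/π) ≈ 564.19 m). Cells with density strictly greater than
   6.25 houses/km² are *populated areas*.
2. **Path distance.** The distance surface is a multi-source shortest
   path over the 8-connected raster lattice with step cost
   √(h² + Δz²) — horizontal step h (cell size, ×√2 on diagonals)
   combined with the elevation change Δz from a DEM — computed exactly by
   Dijkstra's algorithm in compiled code, with populated cells as
   zero-distance sources and nodata cells as impassable barriers.
3. **Zones and effective habitat.** Two path-distance thresholds define
   impact zones: human impact (1,920 m) and the dog foray distance
   (10,900 m). Effective habitat I/II is baseline habitat beyond each
   threshold; the headline quantity is the percent reduction
   100·(baseline − effectiveII)/baseline.
4. **Use versus availability.** Occurrence path distances are compared
   with n = 100 random locations in habitat: the shift of the mean,
   the shift in availability standard deviations, and the fraction of
   occurrences beyond the foray distance. An optional logistic avoidance
   model w(d) = 1/(1+e^−(d−θ)/s) can be fitted by maximum likelihood.
5. **Prioritization.** Habitat inside the dog zone is accounted per
   reserve and classified low (< 50 km²), moderate (< 165 km²) or high
   (≥ 165 km²) — fixed breaks, or re-derived from the data with an exact
   (Fisher dynamic-programming) Jenks natural-breaks optimization.

## Worked example

```r
library(dogedge)

rep <- runPipeline(landscape   = landscapeConfig(seed = 7),
                   occurrences = occurrenceConfig("many_dogs", seed = 7))
rep$effective
#> EffectiveHabitatReport (areas km^2, printed to one decimal)
#>   baseline habitat:          294.8
#>   effective I (human only):  194.5
#>   effective II (human+dog):  39.0
#>   reduction (II vs baseline): 87%
rep$useAvailability
#> UseAvailabilityResult
#>   used: n = 46, mean 13.7 km; available: n = 100, mean 5.1 km (sd 4.7)
#>   shift: 8.6 km (1.83 availability SDs)
#>   used beyond foray distance: 91%
```

This simulates a 20 × 20 km mountain-front landscape (2,000 m relief,
twelve villages strung along the settled valleys), runs the full
pipeline, and reports that dogs reaching 10.9 km from populated areas
would cut effective habitat from 294.8 to 39.0 km² (an 87% reduction),
while the simulated occurrences sit 8.6 km — about 1.8 availability
standard deviations — farther from villages than random habitat, with
91% beyond the foray distance: the signature of strong avoidance.
`rep$threat` holds the per-reserve dog-zone habitat areas and threat
tiers, and `runPipeline(..., outDir = "out")` writes every intermediate
layer (ASCII-grid rasters, CSV/GeoJSON vectors) plus a deterministic
key/value report.

A thin command-line wrapper with the same functionality lives at
`inst/scripts/dogedge.R` (subcommands `simulate`, `density`, `pathdist`,
`zones`, `use-avail`, `prioritize`, `run-all`; configuration via a YAML
file whose defaults equal the package constants).

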