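# zonequant

Joint zonated quantification of hepatic lobule parameters from
co-registered histological slide images.

Liver lobules are roughly hexagonal units with portal fields (PF) at the
periphery and a central vein (CV) at the center; many liver functions and
pathologies are *zonated* along this porto-central axis. `zonequant`
measures a zonated pathology (macrovesicular steatosis) and zonated
immunohistochemical marker expression (GS, CYP enzymes) *jointly*, per
lobule and per intra-lobular zone, from adjacent serial sections — for
researchers quantifying, e.g., how periportal steatosis relates to
pericentral drug-metabolizing enzyme expression.

## Method at its core

From annotated PF/CV rectangle centers, every pixel x gets a **portality**

    portality(x) = 1 − dist(x, closest PF) / (dist(x, closest PF) + dist(x, closest CV))

(1 at a PF, 0 at a CV). **Lobules** are the catchment basins of a
pre-flooded watershed transform of this surface (one basin per CV, shallow
spurious minima suppressed); each lobule is divided into twelve **zones**
by quantizing portality into twelve intervals (zone 1 pericentral, zone 12
periportal). Per stain, pixels are classified into
unstained/positive/negative by a 3-class Gaussian mixture fitted with EM
on the RGB histogram and labeled by nearest class mean; fat droplets are
detected by brightness, area and circularity filters. Per (lobule, zone)
the steatosis area fraction and each marker's positive ratio
positive/(positive+negative) — reported only where at least 5% of the zone
is stained — are joined via CV UUIDs into one table. Zonal gradients are
characterized per lobule by least squares lines p(x) = m·x + p0 over the
normalized lobular position x (0 = PF, 1 = CV), and marker-vs-steatosis
relations by p(s) = m_s·s + p_s0; slopes and intercepts are summarized
across lobules.

A synthetic slide generator (hexagonal vessel lattice, Bernoulli-sampled
stain gradients, budgeted non-overlapping fat droplets, Gaussian color
noise) provides exact ground truth for every stage.

## Worked example

```r
library(zonequant)

spec <- synthetic_slide_spec(image_size = c(512, 512), lattice_pitch_px = 160,
                             margin_px = 16, seed = 42)
layout <- generate_layout(spec)                  # 6 complete lobules
slide  <- render_slide(spec, layout, "pericentral")
ann    <- layout_annotations(layout)

cfg <- zq_config(analysis_downsample = 1, seed = 7)
res <- run_quantify(list(HE = slide$rgb, CYP = slide$rgb), ann, config = cfg)
head(res$table, 3)
#   lobule_id   lobule_label  zone zone_area_px steatosis stained_fraction_CYP   CYP
#   04089319-…             1     1          186    0.0000                 1.000 0.866
#   04089319-…             1     2          568    0.0827                 0.917 0.821
#   04089319-…             1     3          977    0.0972                 0.903 0.709

trends <- run_trends(res$table, cfg)
trends$summaries[, c("response", "predictor", "slope_median", "intercept_median")]
#   response  predictor slope_median intercept_median
#   steatosis position       -0.2032           0.2567
#   CYP       position        0.7867           0.1046
#   CYP       steatosis      -3.8238           1.0872
```

The slide was generated with a periportal steatosis gradient of slope
−0.2 (intercept 0.25) and a pericentral marker gradient of slope +0.8
(intercept 0.1) versus the lobular position x: the pipeline recovers the
steatosis line essentially exactly and the marker slope within a few
percent (the implied marker-vs-steatosis slope is 0.8/−0.2 = −4). Zones 1
and 12 are excluded from the fits because vessel area dominates them.

Figures:

```r
scatter_plot(res$table, "CYP", path = "scatter.png")   # dots + per-zone ellipses
box_whisker(res$table[!res$table$zone %in% c(1, 12), ], "CYP", "zone",
            path = "boxplot.png")
dc <- render_dual_channel(res$table, res$per_stain$CYP$geometry$lobules,
                          res$per_stain$CYP$geometry$zones, "CYP")
write_image_png(dc, "dualmap.png")                     # blue steatosis, red marker
```

A thin command-line front-end with `generate` / `quantify` / `trends` /
`viz` subcommands is installed at `inst/scripts/zonequant.R`.

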