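# afmtrace

Quantification of amyloid-beta (Abeta-42) secondary nucleation from AFM
height maps — for researchers using liquid-cell AFM to watch oligomers and
fibrils form catalytically on the surface of pre-formed (primary) fibrils,
and for anyone who needs tested, ground-truth-validated morphometry of
filamentous objects in scanning-probe topographs.

## What it measures

The raw datum is a calibrated height map `h(x, y)` (nm). An AFM image is
the grayscale dilation of the surface by the tip shape,
`g(p) = max_q [ f(q) + s(p - q) ]`, which broadens lateral sizes but
preserves the apex height of isolated convex objects. All sizing therefore
uses heights: for a sphere or a surface-lying cylinder, apex height above
the support equals the diameter.

Pipeline (one call: `analyze_topograph()`):

* **flatten** — per-scanline polynomial background removal with iterative
  object masking; bare substrate defines height zero;
* **segment + trace** — 8-connected components, fibril/particle split,
  skeleton longest path, sub-pixel ridge refinement, end-corrected arc
  length `L`;
* **size** — fibril diameter `d` = trimmed mean of apex heights above the
  support; particle diameter = mean of 5 sectional apex heights minus the
  support; objects riding a fibril subtract the host level (stacked-height
  subtraction);
* **fingerprint** — windowed, detrended RMS roughness
  `Rq = sqrt(mean(dz^2))` along the backbone separates smooth *primary*
  fibrils (Rq 0.4–2.2 nm) from corrugated *secondary* fibrils
  (Rq 2.5–8.5 nm) at a 2.35 nm threshold;
* **classify** — adsorption site per oligomer (edge within 20 nm of a
  backbone end / backbone / substrate) and catalytic activity per primary
  fibril from the cargo density `lambda` (objects/µm): dormant (none),
  superspreader (`lambda >= 3x` the frame median of non-dormant fibrils),
  else active.

A synthetic-topograph simulator (`scene_spec()`, `simulate_topograph()`)
renders ground-truth scenes — cylindrical fibrils, spherical oligomers,
corrugated secondaries, tip dilation, scan-line artifacts — so every stage
is validated against known geometry. See the methods vignette
(`vignettes/afm-secondary-nucleation.Rmd`) for the model, parameters, and
known systematics.

## Worked example

```r
library(afmtrace)

spec <- scene_spec(
  field_nm = 2000, pixel_size_nm = 2, seed = 7,
  primary_fibrils = list(count = 8),
  oligomers = list(count = 10, diameter_mean_nm = 7.3, diameter_sd_nm = 1.9,
                   p_edge = 0, p_backbone = 0, p_substrate = 1))
sim <- simulate_topograph(spec)   # ideal surface -> tip dilation -> artifacts
an  <- analyze_topograph(sim$map)
an
#> <afm_analysis> 17 object(s): 8 primary fibril(s), 0 secondary fibril(s), 9 oligomer(s)
summarize_population(an$records, "diameter_nm", class = "primary_fibril")
#> <summary_stats> n = 8, mean = 8.17, SD = 1.1
summarize_population(an$records, "length_nm", class = "primary_fibril")
#> <summary_stats> n = 8, mean = 820, SD = 145
summarize_population(an$records, "diameter_nm", class = "oligomer")
#> <summary_stats> n = 9, mean = 7.7, SD = 1.83
```

The measured means sit on the configured populations (diameter
8.3 ± 0.85 nm, length 842 ± 133.5 nm, oligomers 7.3 ± 1.9 nm) to within
the sampling spread of one 2 µm frame (nine of the ten placed oligomers
were recovered). The per-object table
`an$records` carries `frame_id, time_min, object_id, class, diameter_nm,
length_nm, rq_nm, site, activity, host_id` and writes deterministically
with `write_measurements()`.

Multi-frame calibrated studies run from the shipped scene configurations:

```r
cfg <- system.file("extdata", "scenes", "fig7_roughness.yaml",
                   package = "afmtrace")
st <- run_scene_study(cfg, seed = 42)
r <- st$records
mean(r$rq_nm[r$class == "secondary_fibril"]) /
  mean(r$rq_nm[r$class == "primary_fibril"])
#> [1] 3.00   # secondary fibrils are ~3x more corrugated
```

A CLI wrapper with `simulate` / `analyze` / `report` subcommands is
installed at `inst/cli/afmtrace`.

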