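# tubeorient

Depth-resolved quantification of smooth muscle cell (SMC) orientation in
the wall of an intact tubular organ, from 3D nucleus-stained microscopy
stacks.

## The problem

How SMCs are oriented across the muscle layer of a tube — ureter, gut,
blood vessel — determines how the organ contracts, but histological
sectioning distorts exactly the architecture one wants to measure.
Optical sectioning of the intact, mounted organ avoids that, at the price
of a geometric problem: flat image planes cut a *curved* wall, so a single
slice mixes tissue from different wall depths, and near the surface the
field of view is not even fully filled with tissue.

`tubeorient` implements a quantitative pipeline for exactly this setting.
For each slice of a stack acquired from the outer (adventitial) toward the
inner (proprial) side it:

1. enhances elongated bright nucleus profiles with a Hessian-based
   "cellness" filter (the 2D Frangi vesselness response at a single
   nucleus-matched scale), thresholds, clusters, and filters clusters by
   area (removing dye particles and merged cells);
2. restricts analysis to a cylindrical-wall region of interest — a band
   around the apex line of half-width `min(w_c, w_f)`, where
   `w_c = sqrt((R - z + d)^2 - (R - z)^2)` bounds depth crosstalk by `d`
   and `w_f = sqrt(z(2R - z))` guarantees the band is filled with tissue
   (`R` = measured outer radius, `z` = imaging depth);
3. computes each cluster's second-moment tensor; the principal eigenvector
   gives the nucleus angle `alpha` relative to the longitudinal axis
   (axial data in (-90, 90]), and clusters with eigenvalue ratio
   `lambda1 / lambda2 <= 1.5` are excluded as round;
4. summarises the samples with axial circular statistics: a wrapped 2D
   kernel density estimate over (normalized depth, angle) with octile
   curves, circular SD profiles `sqrt(-2 log Rbar)/2` on doubled angles,
   a per-stack dispersion table (25/50/75th percentiles of per-stack SDs
   at normalized depths 0.2–0.8), and per-slice cell densities
   (count / ROI area, in cells per 10^4 um^2).

Because stacks of this kind are not publicly deposited, the package ships
a synthetic stack generator (`synthetic_spec()`, `preset_scenarios()`,
`generate_stack()`) with exact ground truth; the entire pipeline is
validated by parameter recovery. See the vignette
(`vignettes/wall-orientation-methods.Rmd`) for the model, parameters and
design choices.

## Worked example

Simulate three ureter-like stacks (longitudinal orientation whose circular
SD rises 25° to 32° across a 55-um wall, 20 cells per 10^4 um^2, round
nuclei, clutter and shot noise) and fit the orientation model:

```r
library(tubeorient)

specs <- preset_scenarios(field_size_px = c(192, 1024),
                          slice_spacing_um = 1, n_slices = 56, seed = 42)
sims  <- lapply(1:3, function(i) generate_stack(specs$ureter_like, seed = 42 + i))
fit   <- fit_wall_orientation(lapply(sims, `[[`, "stack"))
summary(fit)
#> Wall orientation summary
#>   7418 samples from 3 stack(s)
#>   pooled axial mean -0.4 deg, circular SD 28.7 deg
#>   pooled circular SD profile (deg):
#> z_n=0.2 z_n=0.4 z_n=0.6 z_n=0.8 
#>    27.3    28.2    27.9    32.0 
#>   per-stack SD percentiles (deg):
#>   z_n  p25  p50  p75
#> 1 0.2 27.2 27.3 27.4
#> 2 0.4 27.1 27.2 28.9
#> 3 0.6 27.4 27.7 28.1
#> 4 0.8 30.6 32.1 33.3
#>   cell density range: 11.3 - 27.3 cells per 1e4 um^2
#>   filter chain: 20370 raw -> 15537 area -> 7434 ROI -> 7418 anisotropy
```

Reading the output: the pooled axial mean near 0° says the wall is
predominantly longitudinal; the circular SD profile rises with normalized
depth (the truth here increases 26.4° to 30.6° at these probe depths —
three stacks leave a degree or two of sampling noise); the dispersion
table gives the spread of that SD across stacks; the filter chain shows
how many clusters each stage removed. `plot(fit)` draws the density
surface with octile curves and the per-slice cell-density profiles;
`predict(fit, data.frame(z_n = 0.3, alpha_deg = 0))` evaluates the fitted
density. `write_fit_outputs(fit, "results/")` writes samples, KDE, octile,
dispersion and density tables as CSV plus a JSON run report. A thin
command-line wrapper lives in `inst/cli/tubeorient.R`
(`simulate` / `run` subcommands, YAML config).

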