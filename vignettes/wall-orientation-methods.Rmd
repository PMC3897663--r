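---
title: "Quantifying smooth muscle cell orientation across a tubular wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying smooth muscle cell orientation across a tubular wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
```

## The problem

Smooth muscle cells (SMCs) in the wall of tubular organs — the ureter is the
motivating case — drive peristalsis, and how effectively they do so depends
on how they are oriented relative to the tube axis. Histological sectioning
distorts this architecture, which is one reason published descriptions of
the ureter muscle layer disagree with each other. An alternative is to image
the intact, mounted organ with optical sectioning (e.g. two-photon
microscopy of nucleus-stained tissue) and to *measure* nucleus orientation,
slice by slice, through the entire muscle layer (lamina muscularis, LM).

`tubeorient` implements that measurement as a reproducible pipeline:

1. **Cellness filtering** enhances elongated bright nucleus profiles in each
   slice and suppresses background (a 2D Hessian-eigenvalue "vesselness"
   response applied at a single nucleus-matched scale).
2. **Thresholding, clustering and area filtering** turn the filtered slice
   into candidate nucleus clusters and remove dye particles (too small) and
   erroneously merged adjacent cells (too large).
3. A **cylindrical-wall ROI** restricts analysis to a band around the apex
   line where (a) depth crosstalk from wall curvature is bounded and (b)
   the field is guaranteed to be filled with muscle tissue, so per-area
   densities are meaningful.
4. The **moment tensor** of each cluster gives its principal orientation
   angle `alpha` relative to the longitudinal axis; clusters with eigenvalue
   ratio `lambda1/lambda2 <= 1.5` are discarded as round (orientation
   ill-defined).
5. **Axial circular statistics** summarise the samples: a wrapped 2D kernel
   density estimate over (normalized depth, angle), octile curves, circular
   SD profiles, per-stack dispersion tables and cell-density profiles.

Because real stacks of this kind are not publicly deposited, the package
ships a **synthetic stack generator** with exact ground truth; every stage
of the pipeline is validated by parameter recovery against it.

## Geometry and conventions

A stack is a series of flat planes at increasing depth `z` below the
outer-surface apex of a cylinder of radius `R`; slice 0 is tangent to the
outer surface (adventitial side) and depth increases toward the lumen
(proprial side). The tube axis runs along the image x-direction (matrix
columns). The wall depth of an in-plane point at lateral offset `y` is

```
z_wall(y) = R - sqrt((R - z)^2 + y^2)  <=  z,
```

so a flat plane samples shallower wall depths as it moves off the apex.
Two closed-form half-widths control the ROI:

* crosstalk: `w_c = sqrt((R - z + dmax)^2 - (R - z)^2)` — the offset at
  which the wall depth error reaches `dmax` (default 2 um, a trade-off
  between crosstalk and sample count);
* filling: `w_f = sqrt(z (2R - z))` — the offset at which the plane exits
  the tissue.

The effective half-width is `min(w_c, w_f, field half-width)`; the two
constraints cross exactly at `z = dmax`. Slice 0 has `w_f = 0` and is
excluded. Each retained nucleus inherits its slice's nominal depth; the ROI
bound guarantees the resulting wall-depth error is at most `dmax`.

Angles are **axial** (orientation, not direction): `alpha` and
`alpha + 180` are identified and the canonical representative lies in
(-90, 90], with 0 = longitudinal and ±90 = circumferential. Positive angles
rotate from +x toward +y (increasing image row). All circular statistics
double the angles, apply ordinary circular formulas, and halve the result;
dispersion is the circular SD `sqrt(-2 log Rbar) / 2` (in degrees) of the
doubled angles. Depth is normalized per stack by the LM thickness
(`z_n = z / t`, clipped to [0, 1]) so walls of different thickness are
comparable.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma_kernel_um` | 1.0 | um | Gaussian-derivative scale of the cellness filter. A ridge of Gaussian cross-section sigma_r responds maximally (with gamma = 2 scale normalization) at `sqrt(2) * sigma_r`; for 3-um-wide nuclei (sigma_r ~ 0.75 um) this gives ~1 um. |
| `beta` | 0.5 | — | blobness weight of the vesselness response; the conventional value. |
| `c` | adaptive | intensity | structure/noise weight; half the maximum Hessian norm of the slice, since a sensible absolute value depends on image intensity. |
| `threshold` | 0.35 | — | cutoff on the per-slice max-normalized cellness map. High enough that faint out-of-focus halos and round (Frangi-suppressed) nuclei do not merge adjacent clusters; an Otsu mode is available. |
| `connectivity` | 8 | — | clustering connectivity; 8 avoids splitting thin diagonal nuclei. |
| `area_min_um2`, `area_max_um2` | 8, 120 | um^2 | retained cluster area; brackets the elliptical cross-section estimate pi/4 * short * long (~28 um^2 for 3 x 12 um nucleus axes). |
| `delta_max` | 2 | um | ROI crosstalk tolerance. |
| `min_ratio` | 1.5 | — | eigenvalue-ratio threshold excluding round nuclei. |
| `bandwidth_depth`, `bandwidth_angle` | 0.08, 6 | z_n, deg | KDE bandwidths; chosen as a noise/detail trade-off, overridable. |
| dispersion window | 0.1 | z_n | half-width of the depth window for circular SDs at probe depths {0.2, 0.4, 0.6, 0.8}. |

## The synthetic generator

`synthetic_spec()` describes a cylindrical wall (default R = 150 um,
thickness 55 um — near the median measured in rat ureter — at 0.5 um pixel
size) populated with nucleus-like objects:

* elongated nuclei, default extents 12 x 3 x 3 um, rendered as uniform
  ellipsoids (`hard_ellipsoid = TRUE`) or anisotropic Gaussian profiles;
  in-plane orientation at each nucleus is drawn from a depth-dependent
  axial distribution (von Mises on the doubled angle, concentration solved
  so the axial circular SD matches the requested profile);
* a fraction (default 10%) of round nuclei (6 um discs) that emulate
  foreshortened, transversely oriented or urothelial cells — large enough
  to pass the area filter, so their exclusion must come from the
  anisotropy criterion;
* small bright clutter ("dye particles", ~1.5 um^2, below the area
  minimum);
* Poisson shot noise plus Gaussian read noise (defaults give nucleus SNR
  of roughly 10; the real stacks' noise characteristics are not published,
  so these are conventions).

Solid ellipsoids are the default rendering because a nucleus should remain
detectable over most of its physical depth extent, as real nuclei are: a
Gaussian profile decays so quickly along depth that a nucleus is segmented
in only a fraction of the slices that intersect it, which forces an
unrealistically crowded scene to reach a given per-slice density.

The density target is stated the way the pipeline measures it: expected
detected nuclei per slice per 10^4 um^2 of ROI, under the slice-wise
counting convention (a nucleus counts once in each slice where it is
segmented — the method does not deduplicate across slices, so absolute
volumetric density is not identifiable). The conversion to a volumetric
placement rate divides by `detection_span_um`, the depth extent over which
a rendered nucleus passes the default segmentation; the default (2.0 um)
was calibrated once by simulation against the default parameters and is
documented rather than re-fit.

Because nuclei are solid bodies, overlapping renderings combine by maximum
(occlusion), not by summation — summation would create doubly bright
overlap regions that distort the cellness filter's per-slice adaptive
normalization — and placement is rejection sampling inside the shell that
refuses any candidate whose center falls inside an already placed
nucleus's ellipsoid (bodies may touch but not interpenetrate; bounded
attempts, with failure reporting the achieved density). Preset scenarios:

* `ureter_like` — longitudinal mean everywhere, circular SD rising
  linearly 25 -> 32 degrees across the wall (the gradual-dispersion
  architecture reported for rat ureter);
* `intestine_like` — two layers: longitudinal above mid-wall,
  circumferential below, SD 15 degrees (the classic gut arrangement);
* `uniform_null` — axially uniform angles.

What the generator does **not** emulate: the optical point-spread function
and depth-dependent attenuation, extracellular matrix signal,
photobleaching, nucleus curvature or bending, and ovality of the mounted
tube (the ROI model likewise assumes a perfect circle; for oval vessels it
is conservative). Passing recovery tests therefore demonstrates that the
*algorithmic* chain is unbiased under the stated imaging model, not that
any particular microscope is.

## Numerical choices

* Hessians are computed by separable Gaussian-derivative convolution with
  replicate (clamped) borders; the second-derivative kernel is forced to
  exact zero sum so constant images produce exactly zero response, and
  Hessian norms below float noise are treated as zero.
* The eigenvalue problem per pixel is solved in closed form; the Frangi
  response uses bright-structure polarity (`h2 < 0`).
* The moment tensor is the population covariance of a cluster's pixel
  coordinates (uniform weights). Its principal angle is computed by
  symmetric eigen-decomposition and cross-checked in the tests against the
  half-angle closed form `0.5 * atan2(2 cxy, cxx - cyy)`. Single-pixel
  clusters have no orientation; `lambda2 = 0` (a perfect line) passes the
  anisotropy filter.
* The KDE uses product Gaussian kernels. Angle wrapping sums five kernel
  replicas 180 degrees apart (truncation error < 1e-12 for bandwidths up
  to 20 degrees); samples are canonicalized to (-90, 90] first, which
  makes the estimate exactly invariant under relabeling by 180 degrees.
  Depth edge loss at z_n = 0 and 1 is corrected by renormalizing each
  sample's kernel mass over [0, 1] (chosen over reflection for positivity
  and simplicity); the surface is finally normalized to unit mass.
* Octiles are computed per depth on the conditional density after
  centering at the conditional axial circular mean, so the curves stay
  continuous when the mean orientation crosses ±90 degrees; quantiles are
  inverted by linear interpolation on the gridded CDF. Percentiles across
  stacks use the standard type-7 convention.
* A perfectly uniform axial sample has undefined circular SD (resultant
  length 0); it is reported as `Inf` rather than an arbitrary number.
* Pooled fits weight each stack equally by default (each stack's samples
  carry total mass 1/n_stacks), so a dense stack does not dominate.

## Design choices that were genuinely open

* **"Cellness" response.** The published description ties the filter to
  vesselness filtering without printing the formula; since elongated
  nuclei are ridge-like at the matched scale, the unmodified 2D Frangi
  bright-structure response at a single scale is the most faithful
  reading, and is what this package implements.
* **Structure tensor.** The cluster orientation tensor is interpreted as
  the region second-moment (inertia) tensor of the binary cluster rather
  than a gradient outer-product tensor: for filled convex nuclei the two
  agree in principal direction, and region moments are well defined on
  small clusters. Uniform (mask) weighting is used, since the tensor is
  computed on an identified cluster, not on raw intensities.
* **Eigen-ratio.** The anisotropy criterion uses the ratio of tensor
  eigenvalues (not of axis lengths, their square roots), matching the
  stated "ratio of its eigenvalues".
* **Counting rule for densities.** Cell densities use clusters after area
  filtering but before the anisotropy filter (density should count
  detected nuclei, including round ones), whereas orientation uses the
  stricter anisotropic subset. Both stages are reported.
* **Per-cluster depth.** A cluster's depth is its slice's nominal depth;
  the ROI construction bounds the resulting error by `delta_max` and a
  per-cluster curvature correction is deliberately not attempted.
* **LM thickness.** Thickness is measured metadata supplied per stack
  (the proprial boundary is generally not identifiable from the scans
  themselves); for synthetic data it equals the generated wall thickness.

## Validation problem sizes

The recovery studies run on synthetic stacks of 192 x 2048 px at 0.5 um
pixel size and 1 um slice spacing (56 slices, covering a 55-um wall):
twelve stacks for the single-population (ureter-like) scenario and four
for the two-layer control. The long field along the tube axis is chosen so
that each depth window of the ROI band holds several hundred distinct
nuclei per stack, putting the sampling error of a per-stack circular SD —
and hence of the across-stack median — well below the 1.4-degree
per-window increments of the dispersion profile being recovered; the whole
validation suite still runs on a single CPU in minutes. The acceptance
script (`scripts/acceptance.R`) regenerates all of these from scratch at a
user-supplied seed.

## Known limitations

* Strictly slice-wise (2D) processing: nuclei are re-counted in adjacent
  slices, absolute 3D density is not identifiable, and out-of-plane
  (transverse) orientation is not measurable — transversely oriented
  nuclei appear round and are excluded by the anisotropy filter.
* At realistic densities, adjacent nuclei occasionally merge into one
  cluster; most such merges are rejected by the area or anisotropy
  filters, which removes crossing pairs preferentially and can shrink the
  recovered dispersion by a degree or two where true dispersion is
  largest. The recovery tests quantify this bias.
* The cylindrical ROI model takes the radius as trusted metadata and
  assumes a circular cross-section; ovality makes it conservative.
* The dispersion table requires a depth window (default ±0.1 normalized
  depth); windows narrower than the slice spacing would leave too few
  samples per stack.
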