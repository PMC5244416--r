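---
title: "edgedyn: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{edgedyn: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what a passing test does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

### Boundary, sectors, velocity

A single cell's boundary is extracted per frame from a binary mask: the
mask is lightly Gaussian-smoothed (sigma 1 px) and its 0.5 level set traced
by marching squares, giving a sub-pixel closed contour. The contour is
oriented counter-clockwise, resampled to uniform arclength (~1 px
spacing), circularly smoothed (sigma 1.5 vertices) to suppress pixel
staircase, and outward unit normals are computed from a ±2-vertex central
difference of the tangent. On rasterized disks this recovers perimeters
within 2% and normals within 5 degrees of radial; both are tested.

The boundary is divided into `N = round(perimeter / sector_length)`
contiguous equal-arclength sectors (`sector_length` default 10 um, N >= 4).
Because the analysis needs one heatmap row per sector across the whole
movie, N is fixed by the first frame; later frames reuse it, so sector
arclength breathes slightly as the perimeter changes. Sector 1 is anchored
where the ray from the centroid toward +x crosses the boundary — an
arbitrary but reproducible convention that prevents heatmap rows from
rotating between frames.

Frame-to-frame correspondence casts a ray from each sector midpoint along
±its outward normal and takes the nearest intersection with the next
frame's boundary (search window 5 um); if no intersection exists the
nearest boundary point is used, and sectors whose fallback displacement
still exceeds the window are flagged missing and masked downstream — never
silently zeroed. The sector's normal velocity is V = d·n, i.e. the signed
ray distance. Two consequences worth knowing:

* Under a rigid translation u the per-sector measurement is the normal
  component u·n, so the mean displacement over a closed convex boundary is
  u/2, not u. This is inherent to normal-projection correspondence (and to
  the aperture problem generally), not an implementation artifact.
* V is in um/frame internally; absolute um/s values are obtained by
  dividing by the frame interval and are reported alongside the normalized
  map, because the per-figure normalization constant of any published
  heatmap is not recoverable.

Normalized V divides the raw map by the maximum |V| over the analysis set
(a per-cell maximum when one movie is analyzed alone; a config flag is not
needed since `build_velocity_heatmap(norm_max=)` accepts a cohort-wide
constant). Normalization is odd and sign-preserving: +1 fastest protrusion,
-1 fastest retraction, 0 quiescence.

### Membrane events

Events are connected components (8-connectivity, with circular wraparound
across the sector seam, merged after labeling) of heatmap cells with
|V| >= `value_threshold`, thresholded separately per sign; components
smaller than `min_area` cells are dropped. Defaults `value_threshold = 0.3`
and `min_area = 6` replace the manual region selection used in the
original workflow with a reproducible rule; both are configurable and are
recorded in the run manifest. Per event:

* duration = (last column - first column + 1) x frame interval;
* angle = orientation of the region's major axis from the time axis,
  computed from second central moments of the member cell coordinates
  (sector coordinates unwrapped first if the region crosses the seam) and
  folded to [0, 90] degrees; a square or otherwise axis-degenerate region
  reports 0 by the atan2(0, 0) = 0 tie-break;
* traveling wave iff angle > 10 degrees, strictly — an event at exactly 10
  degrees is not a wave.

Threshold monotonicity (raising `value_threshold` never increases the
event count) holds for separated unimodal events and is tested as such;
it can fail legitimately when two overlapping events merge at a low
threshold and split as it rises.

### Edge-band colocalization

The band is the set of in-mask pixels whose exact Euclidean distance to
the background is at most `band_depth` (default 2 um). Using the distance
transform rather than an integer structuring element keeps the erosion
depth calibration-independent at any pixel size. Band pixels inherit the
sector of the nearest boundary vertex, so the colocalization heatmap has
the same rows as the velocity heatmap and the two can be paired
elementwise.

Per region and frame,
`coloc = Cov(G - muG, R - muR) / sqrt(Var(G - muG) Var(R - muR))`
over background-subtracted pixel pairs — algebraically the Pearson
correlation of (G, R). Regions with fewer than `min_pixels` (10) pixels or
zero variance in either channel are flagged undefined (NA, masked), never
reported as 0, because "no measurement" and "no colocalization" are
different statements. The background is estimated as the mean intensity
outside a 2 um dilation of the cell mask; the source description does not
define its background region (the symbols are typographically missing in
the text), so this reconstruction is configurable — and immaterial to the
coefficient itself, which is invariant to per-channel affine transforms.

The display normalization clips negative correlations to 0 (the published
scale runs 0..1); raw signed values are retained in the output. The
colocalization event threshold (0.5) is likewise not stated anywhere and
is a documented package default.

### Coupling

C = V x coloc elementwise, masked where either parent is. The source text
calls this a "dot product" over an N x t matrix; a scalar dot product
could not be plotted as a per-location heatmap, so the elementwise reading
is primary and the scalar summary mean(C_raw) is exported alongside.
Cross-cell normalization divides every map by the single symmetric scale
s = max(|set max|, |set min|), which maps the extreme coupling in the set
to ±1 while preserving zero and sign — an independent max/min rescale
would move C = 0, destroying its "quiescence" meaning. The five-level
legend (red +1 coupled protrusion/high coloc; orange +0.5; green 0; cyan
-0.5; blue -1 coupled retraction/high coloc) is exposed as
`coupling_legend()`.

### Adhesion, motility

Adhesion sites are detected inside a caller-supplied lamellipodium ROI
polygon (the original workflow drew this by hand): Gaussian smoothing
(sigma 0.2 um), Otsu threshold within the ROI unless a fixed threshold is
given, 8-connected components, exclusion of objects with area < 0.1 um^2.
The source states the exclusion as a volume (0.1 um^3) in a commercial 3D
package although the analysis is planar; it is rendered here as the
corresponding area threshold, configurable. Morphometry uses region
moments (longest axis = 4 sqrt(lambda_max), the ellipse-equivalent
convention); site-to-membrane distance is centroid-to-arc (a flag for
nearest-pixel-to-arc would be a one-line change; centroid is the default
because the reported quantity is a per-site location summary).

Meandering index, wound closure and the C:N ratio are direct formula
implementations; undefined cases (zero path length, zero nuclear mean) are
NA-flagged, and missing track frames are used as given — linear
interpolation across a gap adds collinear points and cannot change either
displacement or path length, so the only honest addition is a `has_gaps`
flag.

## 2. The synthetic world

The generator exists so that every downstream stage can be validated
against planted truth. It emulates the imaging regimes of the study
system: two channels at 5 s intervals for up to 5 min (membrane /
colocalization), 30 s for adhesion snapshots, 8 min for 21 h (wound).
Defaults: pixel size 0.2 um (typical of a 63x confocal; the source reports
magnification, not pixel pitch, so this is a stated default), 512 x 512
field, cell radius 20 um, background 10, cell plateau 100, camera noise
SD 2. Tests and the acceptance script run reduced fields (192-256 px at
0.3 um/px, 16-45 frames) purely for runtime; the physical regime is
unchanged.

### Boundary kinematics

The boundary is a star-convex radial function r(theta, t) around a fixed
center. A kinematic pulse adds (protrusion) or removes (retraction)
`speed x frame_interval` of radius per frame inside an arclength window of
given width, with a cosine taper (2 um) at the window edges; the window
center may drift along the boundary by `drift_sectors_per_frame x
sector_length` per frame, planting a traveling wave whose angle in
heatmap coordinates is atan(drift). Star-convexity makes self-intersection
impossible; configurations that would collapse the radius below 2 um or
overflow the image are rejected with descriptive errors. The planted
normal velocity is computed analytically from consecutive radii with the
cos(psi) obliquity correction (psi the angle between the radial direction
and the boundary normal), so inside a pulse's flat core the planted speed
is exactly the nominal speed.

### Band correlation

Inside the 2 um band, both channels receive a shared latent Gaussian field
z plus independent noise: G gains `amp (sqrt(|rho'|) z + sqrt(1-|rho'|) e1)`
and R the same with sign(rho) on the z term, followed by camera noise of
SD `noise_sd` everywhere. The mixing uses the inflated target
`rho' = rho (amp^2 + noise_sd^2) / amp^2` so that the final pixel
correlation, *including* camera noise, equals the configured rho; configs
for which |rho'| > 1 (amplitude too small for the requested correlation)
are rejected at validation time. Local patches (sector x frame windows
with their own rho) plant colocalization events.

### What the generator does not emulate

Photobleaching, uneven illumination, out-of-focus light, multi-cell
fields, cytoskeletal texture, and nonstationary backgrounds. A green test
therefore establishes that the measurement chain is correct and
deterministic on high-contrast single-cell data with Gaussian noise — not
that segmentation is robust to the pathologies of real microscopy, which
is why the segmenter is deliberately pluggable (`segment_cell` is a
documented substitution for the original platform's graph-cut segmenter
and accepts a fixed threshold).

### Event-fixture validity

Two constraints govern the randomized planted-event movies used by the
acceptance checks, both consequences of the geometry rather than tuning:

* A drifting window on a closed boundary laps itself once its lateral
  travel plus width approaches the perimeter, leaving no well-defined
  planted event; steep (45 degree) pulses are therefore short (7 frames)
  and run on a larger cell.
* The planted "angle" is the streak's slope; the measured angle is the
  region's moment axis, and the two agree only for thin elongated regions
  (for a parallelogram of width w and length L the moment axis deviates
  by an angle growing with w^2/L^2). Steep pulses are therefore planted
  narrow (20 um) and shallow drifts long (14-16 frames). With these
  stated-world constraints, recovery was verified with zero violations
  over 40 seeds (the shipped test uses 20).

## 3. Numerical choices

* **Otsu threshold:** midpoint of the between-class-variance argmax
  plateau. With well-separated classes the criterion is flat across the
  empty histogram gap; the first-bin convention would sit at the edge of
  the background mode and break the ±10% threshold-stability contract.
* **Distance transform:** exact squared-Euclidean (Felzenszwalb &
  Huttenlocher two-pass), with a large finite sentinel instead of IEEE Inf
  for non-target pixels — the envelope intersection otherwise computes
  Inf - Inf = NaN and silently corrupts diagonal distances. The transform
  was validated to zero difference against an independent reference
  implementation on random fixtures.
* **Connected components:** two-pass union-find in C++ (4- or
  8-connectivity); heatmap labeling merges components across the sector
  seam afterwards, which is equivalent to labeling on the cylinder.
* **Angle tie-break:** moment orientation uses 0.5 atan2(2 mu11,
  mu20 - mu02); a degenerate (square) region yields atan2(0, 0) = 0,
  i.e. angle 0, matching the axis-aligned reading.
* **TIFF:** movies are exchanged as uncompressed little-endian float32
  multi-page TIFF written and read by the package itself (no TIFF library
  exists in the target environment); files were verified against an
  independent reader in both directions during development.
* **Determinism:** every generator call seeds R's RNG locally and restores
  the caller's RNG state; identical configs reproduce bit-identical movies,
  ground truth, and pipeline CSV/JSON outputs (tested at byte level). The
  provenance hash stamped into every output covers the scientific
  parameters but not I/O paths.

## 4. Known limitations

* Sector correspondence is normal-ray projection with a nearest-point
  fallback — simpler than mechanical-model boundary mapping; adequate for
  frame-interval-scale motions (the regimes generated and tested), less so
  for displacements comparable to cell curvature radii.
* Fixed N with a breathing perimeter means sector midpoints slide slowly
  along the boundary of a strongly deforming cell; recovered per-sector
  speeds at a pulse's tapered flanks reflect the planted taper sampled at
  the midpoint's instantaneous position, which is why acceptance checks
  compare against the planted field at the recovered midpoint rather than
  a static sector table.
* Moment-axis angles of short or laterally-quantized streaks are biased
  (Section 2); angles of events shorter than ~5 frames should not be
  over-interpreted, matching the acceptance fixtures' validity envelope.
* The colocalization event rule (threshold 0.5, min area 6) and the manual
  selections it replaces have no published reference values; only planted
  synthetic events validate it.
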