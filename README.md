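# edgedyn

Quantification of cell-edge dynamics, edge-band colocalization, and
adhesion morphometry in live-cell fluorescence movies.

## The problem

Migrating cells remodel their boundary continuously: lamellipodia protrude,
the rear retracts, and some protrusions travel laterally along the membrane
as waves. Live-cell studies of proteins that localize to the leading edge
(e.g. a GFP-tagged kinase imaged together with an actin or paxillin
reporter) need these behaviours turned into numbers: how long do membrane
events last, how often do they occur, do they travel; does the tagged
protein colocalize with actin in the thin band just inside the membrane,
and is that colocalization coupled to protrusion or retraction; how large
and how close to the membrane are nascent adhesion sites; how straight do
cells migrate and how fast does a wounded monolayer close.

`edgedyn` implements that pipeline for calibrated two-channel time-lapse
movies of single cells, plus a seeded synthetic-movie generator with
planted ground truth so that every stage is testable without external data.

## The quantities

* **Sector velocity (edge kymograph).** Each frame's cell boundary is
  extracted at sub-pixel resolution, divided into N = round(perimeter / 10 um)
  contiguous sectors (sector 1 anchored on the centroid-to-+x ray), and
  matched to the next frame by casting a ray along the outward normal n from
  each sector midpoint. The displacement d gives the normal velocity
  V = d·n, assembled into an N x (T-1) heatmap and normalized by the maximum
  |V| of the analysis set, so +1 is the fastest protrusion, -1 the fastest
  retraction, 0 quiescence.
* **Membrane events.** Connected regions of |V| above threshold (default
  0.3, 8-connectivity, wrapping across the sector seam) are events, with
  area, duration = (column span) x frame interval, and the orientation of
  the region's major axis relative to the time axis (second central
  moments, folded to [0, 90] degrees). An event with angle strictly
  greater than 10 degrees is a **traveling wave**.
* **Edge-band colocalization.** The band is the 2 um-deep strip inside the
  boundary (distance-transform erosion), partitioned by the same sectors.
  Per region and frame, `coloc = Cov(G-muG, R-muR) / sqrt(Var·Var)` of
  background-subtracted pixel pairs — a Pearson coefficient — plotted as a
  0..1 heatmap, with events extracted the same way (threshold 0.5).
* **Velocity-colocalization coupling.** C = V x coloc elementwise, scaled
  across all cells by s = max(|max|, |min|) so C = +1 means strongly coupled
  protrusion with high colocalization, -1 coupled retraction with high
  colocalization, 0 quiescence.
* **Adhesion morphometry.** Puncta inside a lamellipodium ROI: Gaussian
  smoothing, threshold (Otsu within the ROI by default), connected
  components, exclusion below 0.1 um^2; per site the area, longest-axis
  length (4 sqrt of the largest second-moment eigenvalue) and centroid
  distance to the leading-edge membrane arc.
* **Motility.** Meandering index = displacement / path length; percent
  wound area closed = 100 (A0 - A(t)) / A0; cytoplasmic:nuclear mean
  intensity ratio.

## Worked example

```r
library(edgedyn)

cfg <- sim_config(
  pixel_size_um = 0.3, frame_interval_s = 5, n_frames = 45,
  image_shape = c(256L, 256L), cell_radius_um = 24, seed = 11,
  coloc_rho = 0.2,
  boundary_kinematics = list(
    kinematic_pulse("protrusion", 5, 20, center_arclength_um = 20,
                    width_um = 30, speed_um_per_s = 0.15),
    kinematic_pulse("retraction", 26, 40, center_arclength_um = 90,
                    width_um = 30, speed_um_per_s = 0.1,
                    drift_sectors_per_frame = tan(15 * pi / 180))),
  coloc_patches = list(list(sectors = 1:4, frames = 5:20, rho = 0.9)))

sim <- generate_cell_movie(cfg)
res <- analyze_movie(sim$movie,
                     pipeline_config(pixel_size_um = 0.3,
                                     frame_interval_s = 5,
                                     out_dir = tempfile()))
res$velocity_events[, c("polarity", "duration_s", "angle_deg",
                        "is_traveling_wave")]
```

prints (messages elided):

```
    polarity duration_s angle_deg is_traveling_wave
1 protrusion         75      2.16             FALSE
2 retraction         70     11.58              TRUE
```

The planted protrusion (frames 5-20, i.e. 75 s of active frame pairs, no
lateral drift) is recovered as a 75 s event at ~2 degrees; the retraction
planted with a lateral drift of tan(15 deg) sectors/frame is recovered as a
70 s event at 11.6 degrees and classified as a traveling wave (> 10
degrees). The event summaries:

```
res$velocity_summary   # n_events 2, 0.533 events/min, mean duration 72.5 s,
                       # mean angle 6.87 deg, 50% traveling waves
res$coloc_summary      # 1 colocalization event, 80 s (planted: sectors 1-4,
                       # frames 5-20, rho = 0.9 against background 0.2)
```

`run_pipeline()` writes the same results to disk — masks (TIFF),
boundaries, the three heatmaps and event tables (CSV, each stamped with the
config hash), summaries and a run manifest (JSON).

## Command line

```sh
inst/cli/edgedyn simulate --config sim.yaml --out-dir sim/   # movie + truth
inst/cli/edgedyn all      --config pipeline.yaml             # full analysis
inst/cli/edgedyn adhesion --frame f.tif --roi roi.csv --pixel-size 0.2
inst/cli/edgedyn motility --tracks tracks.csv --wound wound.csv
inst/cli/edgedyn cnratio  --frame f.tif --nucleus n.tif --cytoplasm c.tif
```

`dynamics`, `coloc` and `coupling` are views of the same `all` run.

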