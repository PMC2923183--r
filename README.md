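# aditrack

Segmentation and tracking of point-like and cell-like fluorescent targets
in low signal-to-noise time-lapse microscopy, for researchers who need to
follow many small, poorly resolved, erratically moving objects (endosomal
nanoparticle clusters in cells, lymphocytes in tissue) without assuming
anything about their shape or motion.

## Method in brief

**Segmentation.** Each frame `I_j` (normalized to [0, 1]) is reduced to
single-pixel target marks by four size-sensitive filters: a minimum
filter over a `(2m_m+1) x (2m_m+1)` mask, a value-preserving global
threshold `T` (found iteratively so that a user-counted region yields the
counted number of 8-connected components), a mean filter over
`(2m_b+1) x (2m_b+1)`, and a maximum-based reduction that marks local
maxima of the smoothed image — one saturated pixel per discerned target
of at least 3 px, with no edge detection.

**Tracking.** Differences of consecutive binary detection frames record,
per pixel, the *passage times* — the frames at which a target newly
arrives there (an accumulative difference image, ADI). From each seed the
tracker repeatedly moves to the pixel within Chebyshev radius
`shell_radius` (default 3) holding the smallest later passage time.
Restarting every `incrementostep` frames recovers the loop and crossing
segments a single start misses; crossing sub-trajectories are grouped by
a `Δx·Δy·Δt` proximity test, assembled into a time-ordered *paragon*
table with per-row steps, spliced wherever a step exceeds
`threshold_paragon`, and merged only on explicit user request.

**Statistics.** For Brownian motion the normalized displacement
`u = Δx/√τ` is Gaussian with variance `2D`; the histograms of x- and
y-displacements are fit globally (shared `D`, per-axis amplitude) with
`G(u) = A·exp(−u²/4D)` by weighted least squares with Poisson weights,
yielding the translational diffusion coefficient `D` in µm²/s.

A ground-truth scene simulator (Brownian spots, persistent-walk blobs
with loops, deterministic loop/crossing geometries; Gaussian-spot or disc
rendering with graded background, shot and read noise) makes the whole
pipeline testable without experimental data.

## Worked example

```r
library(aditrack)

# an intracellular scene: 40 spots, D = 0.022 um^2/s, 0.85 s/frame
scene <- simulate_brownian(40, D = 0.022, n_frames = 100,
                           height = 200, width = 200,
                           pixel_size_um = 0.1, frame_interval_s = 0.85,
                           dropout_prob = 0.05, seed = 2,
                           min_separation_px = 12)
stack <- render_scene(scene, render_params(spot_sigma_px = 1.5,
                                           amplitude = 0.6,
                                           background_level = 0.1,
                                           background_gradient = 0.05))

det <- segment_stack(stack, seg_params(threshold = "auto",
                                       expected_count = 38))
det
#> detection_stack: 100 frame(s), 200 x 200 px, 3711 marks, T = 0.1992

trajs <- track_all(det, linking_params(shell_radius = 3, min_length = 3))
trajs
#> trajectory_set: 36 trajectories, lengths 3..67

mr <- match_detections(scene, trajs, tol_px = 3, min_match_frac = 1e-9,
                       det = det)
round(mr$recall, 3)
#> [1] 0.895
```

`det` holds one mark per discerned spot per frame (~37/frame for 38
visible targets, threshold T = 0.199 found from the counted frame-0
targets); `trajs` the linked trajectories; `mr$recall` the fraction of
frame-0-detected particles that received a trajectory — 89.5% on this
single scene (the benchmark mean over 10 scenes is above 90%). Fitting
the diffusion coefficient from the tracked trajectories:

```r
disp <- normalized_displacements(trajs, 0.1, 0.85, max_gap_frames = 1)
fit_gaussian_D(disp)
#> diffusion_fit: D = 0.02531 +/- 0.002 um^2/s (1486 samples, 7 bins)
```

i.e. `D` recovered within ~15% of the simulated 0.022 µm²/s through the
full render → segment → track → fit chain (see the methods vignette for
the known upward bias of the detection/linking stage at this pixel
scale).

Command-line use mirrors the workflow phases:

```sh
Rscript -e 'aditrack::adi_cli()' simulate --n 20 --frames 100 --seed 1 \
    --out-stack scene.tif --truth truth.csv
Rscript -e 'aditrack::adi_cli()' run --input scene.tif --threshold auto \
    --expected-count 20 --pixel-size-um 0.1 --frame-interval-s 0.85 --out out/
```

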