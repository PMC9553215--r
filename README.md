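# cystovol

Quantitative urodynamics from time-lapse X-ray fluoroscopy of a
contrast-filled bladder, for researchers studying lower-urinary-tract
function in freely moving rodents (videocystometry and noninvasive
fluoroscopic volumetry).

In a freely moving animal the image background moves with the animal, so
bladder volume cannot be read from image intensity. `cystovol` instead
delineates the bladder in every frame and converts the outline to volume:

- **Segmentation** — rolling average over 15 frames, contrast
  normalization, dark-object thresholding, morphological cleanup, and
  retention of one closed (hole-filled) largest object per frame. The
  reference operator is classical; any per-frame mask predictor (e.g. a
  trained network) can be plugged in through the same contract.
- **Volumetry** — equivalent-ellipse semi-axes *a*, *b* (mm) from the
  mask's second-order central moments, then the prolate-spheroid volume
  V<sub>ves</sub> = (4/3)·π·a·b² (µl), with linear repair of 1–2-frame
  segmentation dropouts.
- **Signals** — Savitzky–Golay smoothing before differentiation; urethral
  flow rate UFR = −dV/dt (µl/s, positive = outflow); pressure aligned from
  its own 50 Hz timebase onto the 30 frames/s image timebase; urethral flow
  conductance UFC = UFR / p<sub>ves</sub> (µl·s⁻¹·cmH₂O⁻¹, undefined below
  a 3 cmH₂O floor).
- **Events** — void detection on the flow signal; per void: bladder
  capacity BC = V(onset), residual volume RV = V(end), voiding efficiency
  100·(BC−RV)/BC, the t20–80 void-duration measure, peak UFR/UFC/pressure,
  intercontractile interval, and nonvoiding-contraction counts in the 80 s
  pre-void window.
- **Benchmarking** — Dice similarity index 2·|X∩Y|/(|X|+|Y|) against
  ground-truth masks on a seeded 20 % frame holdout.
- **Simulation** — a synthetic fluoroscopy generator (volume/pressure
  dynamics, voiding and nonvoiding contractions, prolate-spheroid
  rendering over a moving high-contrast background with sensor noise, and
  exact ground-truth masks/events) so the whole chain is testable without
  animal data.

See `vignette source in vignettes/fluoroscopic-volumetry.Rmd` for the
models, parameter rationale and validation protocol.

## Worked example

Simulate a 14 s catheterized-style recording (96×96 px at 0.15 mm/px,
fast infusion so one full filling/voiding cycle fits in the clip), analyze
it end to end, and compare the masks to ground truth:

```r
library(cystovol)

cfg <- sim_config(fill_rate = 300, capacity_threshold = 60,
                  residual_fraction = 0.25, duration = 14,
                  image_shape = c(96L, 96L), pixel_size = 0.15, seed = 8)
rec <- simulate_recording(cfg)
rec
#> <sim_truth> 14 s, 1 voids, 0 NVCs, V in [15.0, 61.5] ul, rendered

res <- run_pipeline(rec$frames, rec$pressure_trace,
                    run_config(pixel_size = 0.15), quiet = TRUE)
round(res$voids, 2)
#>   void_id onset_s end_s BC_ul RV_ul voided_ul efficiency_pct t20_80_s
#> 1       1    9.56 10.99 64.15 17.36     46.78          72.93     0.59
#>   ufr_max_ul_s ufc_max p_max_cmH2O ici_s nvc_count
#> 1        56.89    3.26       34.99    NA         0

holdout_evaluate(res$masks, rec$masks, holdout_fraction = 0.2, seed = 1)
#> <dice_report> n = 85 frames: median 0.955, mean 0.950 (sd 0.033)
```

The simulated void (ground truth: onset 9.18 s, 45.1 µl voided from a
~61.5 µl bladder) is recovered as one event with BC ≈ 64 µl, 46.8 µl
voided at 72.9 % efficiency, a 0.59 s t20–80, and peak flow 56.9 µl/s at a
peak pressure of 35 cmH₂O; the per-frame masks agree with ground truth at
a median Dice of 0.955 on the held-out frames. Volumes are in µl, times in
s, pressures in cmH₂O, conductance in µl·s⁻¹·cmH₂O⁻¹.

## Command line

A thin CLI over the same functions lives at `inst/cli/cystovol.R`:

```sh
Rscript inst/cli/cystovol.R simulate  --config sim.yaml --out simdir
Rscript inst/cli/cystovol.R segment   --frames simdir/frames.tif --pixel-size 0.15 --out segdir
Rscript inst/cli/cystovol.R analyze   --frames simdir/frames.tif --pressure simdir/pressure.csv --pixel-size 0.15 --out anadir
Rscript inst/cli/cystovol.R benchmark --pred segdir/masks.tif --truth simdir/masks.tif --out bmdir
```

Frames are multi-page TIFF (or a directory of PNGs), masks 8-bit 0/255
TIFF stacks, traces and event tables plain CSV with headers.

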