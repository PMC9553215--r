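---
title: "Fluoroscopic bladder volumetry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluoroscopic bladder volumetry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Cystometry in freely moving rodents records intravesical pressure while the
bladder fills and voids, but pressure alone says little about how much urine
the bladder holds or expels. Videocystometry adds X-ray fluoroscopy of a
contrast-filled bladder at video rate, so that bladder volume can be read
from the images continuously — including noninvasively, when contrast
reaches the bladder via renal excretion and no catheter is implanted. In a
freely moving animal the background moves with the animal, which rules out
background-subtraction or image-intensity ("opacity") volumetry; the robust
alternative is to delineate the bladder in every frame and compute its
volume from the outline geometry.

`cystovol` implements that analysis chain — per-frame segmentation,
spheroid volumetry, flow and conductance signals, and per-void
parameterization — together with a synthetic fluoroscopy generator that
provides exact ground truth, so every stage is validated by code rather
than by expert annotation.

## Volume model

The bladder outline in a projection image is summarized by the equivalent
ellipse of the binary mask: the ellipse with the same normalized second
central moments as the pixel support. For a solid ellipse the variance
along a principal axis is $a^2/4$, so the semi-axes are twice the square
roots of the eigenvalues of the $2\times2$ moment matrix. This estimator is
deterministic, rotation-invariant, and needs no boundary tracing.

Volume assumes the bladder approaches a prolate spheroid whose out-of-plane
semi-axis equals the short in-plane semi-axis $b$:

$$V_\mathrm{ves} = \tfrac{4}{3}\pi\, a\, b^2,$$

with $a \ge b$ in mm and $V$ in mm³ = µl. The axes are semi-axes ("radii"),
not diameters; the simulator renders with the same convention, and the
round-trip test (mask → moments → volume) closes to within 2 %, which pins
the convention down self-consistently.

## Segmentation

The reference operator is classical; it fills the same contract as a
trained per-frame mask predictor (and `segment_sequence()` accepts any such
predictor as a drop-in through its `predictor` argument):

1. **Temporal rolling average** over 15 frames (0.5 s at 30 frames/s), the
   standard pre-smoothing for rodent fluoroscopy; the window shrinks
   symmetrically at the sequence edges so no frames are lost.
2. **Contrast normalization and inversion** per frame, so the
   contrast-opaque bladder becomes the bright object on a `[0, 1]` scale.
3. **Grayscale opening** (disc radius 4 px) that erases thin high-contrast
   structures — bones sweeping through the field — and noise speckle,
   while the wide bladder blob passes unchanged.
4. **Global threshold.** The default rule is *background + offset* (median
   of the inverted frame + 0.12) rather than Otsu. Under a Beer–Lambert
   edge profile the attenuation falls continuously to zero at the object
   boundary; an inter-mode threshold such as Otsu's cuts where attenuation
   is already substantial and systematically erodes the boundary by a few
   percent of the radius, which cubes into a volume bias. A near-background
   threshold localizes the true support; Otsu and a manual threshold remain
   available (`seg_params(method=)`).
5. **Closing** (radius 3 px) to smooth the binarized boundary.
6. **8-connected component labeling** with **dark-core seeding**: only
   components containing at least one pixel above `seed_level` (0.6 of the
   normalized inverted range) are bladder candidates. The filled bladder is
   by far the most attenuating object in the field, so its core always
   tops the normalized range, while bones do not; this prevents a large
   background structure from winning the size rule on frames where the
   bladder is small.
7. **Largest candidate**, then **appendage cleanup**: where a bone crosses
   or touches the bladder the two merge into one component. Binary openings
   at radii 4, 6 and 8 px each propose the piece holding the darkest core,
   and the proposal most consistent with an elliptical object (highest Dice
   between the piece and its own fitted ellipse) is retained. A final
   iterated pruning to the fitted ellipse support scaled by 1.05 removes
   residual edge protrusions — these barely affect overlap scores but,
   sitting far from the centroid, would badly inflate the second-moment
   axes. The ellipse prior is the same assumption the volume model already
   makes.
8. **Hole filling** of the selected component ("one closed object") and a
   minimum-area gate. The default minimum area is the projected area of a
   4 µl sphere at the configured pixel size — the practical detection floor
   during efficient voids. Frames failing the gate are flagged invalid and
   logged; they never raise errors.

## From masks to urodynamic signals

* `build_volume_trace()` converts each valid mask to µl and repairs brief
  segmentation failures: interior invalid runs of at most `max_gap = 2`
  frames are linearly interpolated between the flanking volumes (matching
  the observed failure mode of one-or-two-frame dropouts); longer runs stay
  invalid.
* `smooth_volume()` applies a Savitzky–Golay filter before
  differentiation. Defaults are window 31 samples (~1 s at 30 frames/s)
  and polynomial order 3: long enough to suppress frame-level volumetry
  noise, short enough to preserve multi-second voids. The filter's boundary
  projection reproduces polynomials exactly at the edges.
* `compute_ufr()` takes the urethral flow rate as $-dV/dt$ by central
  differences (one-sided at the edges); positive means outflow.
* `align_pressure()` linearly interpolates the independently sampled
  pressure (50 Hz nominal) onto the image timebase (30 frames/s nominal),
  clamping at the endpoints. Queries at existing pressure timestamps return
  those samples exactly.
* `compute_ufc()` defines urethral flow conductance as
  $\mathrm{UFC} = \max(\mathrm{UFR}, 0)/p_\mathrm{ves}$ wherever
  $p_\mathrm{ves} \ge 3$ cmH₂O, undefined below that floor. Flow per unit
  driving pressure is the only dimensionally consistent reading of "flow
  conductance", and the floor prevents division blow-ups between
  contractions.

## Void events and their parameters

Voids are detected on the flow signal: maximal runs with
UFR > 2 µl/s are candidates, runs closer than 2 s merge, each candidate's
onset and end are refined to the 5 % crossing of its own peak UFR (linear
interpolation between samples), and candidates must void at least 10 µl.
Thresholding the derivative is robust to slow drift and matches the visual
definition of a void on the volume trace.

Per void: bladder capacity $BC = V(\mathrm{onset})$, residual volume
$RV = V(\mathrm{end})$, voided volume, voiding efficiency
$100\,(BC-RV)/BC$, the void-duration measure $t_{20\text{–}80}$ (time for
the volume to fall from 20 % to 80 % of the voided volume, crossings by
linear interpolation), and the maxima of UFR, UFC and pressure over the
event. The intercontractile interval is onset-to-onset, the conventional
reading of "interval between contractions". When no pressure trace exists
(noninvasive recordings) the pressure-dependent fields are absent and NVC
counting is unavailable.

Nonvoiding contractions in the 80 s window before each void are pressure
excursions ≥ 5 cmH₂O above a 15 s rolling-median baseline, lasting ≥ 1 s,
with no concomitant volume loss (> 2 µl disqualifies — that is a leak or
void, not an NVC). Overlapping excursions form one above-threshold run and
count once. All three constants are exposed in `nvc_params()`.

## The synthetic generator

`simulate_dynamics()` integrates the volume balance
$dV/dt = \mathrm{fill} - g(t)\,p_\mathrm{ves}(t)$ on a 2 ms grid. Defaults
emulate a catheterized-mouse recording: infusion at 20 µl/min, capacity
near 90 µl, baseline pressure 10 cmH₂O, voiding contractions of 25 cmH₂O,
imaging at 30 frames/s and pressure at 50 Hz. For the noninvasive regime
one lowers the fill rate to ~7 µl/min and ignores the pressure trace.

Design choices where the physiology had to be stylized:

* **Raised-cosine pulses** for both the contraction pressure and the
  urethral conductance (peak `void_conductance`, default
  2 µl s⁻¹ cmH₂O⁻¹, peaking mid-void) reproduce smooth single-peaked flow
  traces without asserting a mechanistic model. A void triggers when $V$
  reaches `capacity_threshold` and ends when $V$ reaches
  `residual_fraction` × capacity; the urethra then closes along a 0.15 s
  cosine ramp, started predictively so the residual target is met while
  the outflow stays continuous (a hard cutoff would defeat quadrature
  checks at the 30 Hz export rate).
* **Ground-truth void onset** is logged where outflow crosses 1 % of the
  void's peak — the start of measurable urine expulsion — rather than at
  the contraction trigger, because under a smooth opening profile flow is
  negligible for a while after the trigger and void timing is defined on
  the flow/volume signal.
* **NVCs** are raised-cosine pressure pulses (default 8 cmH₂O, 3 s) at
  Poisson times with a refractory gap so successive contractions never
  overlap; pulses that would collide with a void are dropped. The 3 s / 8
  cmH₂O defaults keep a pulse above the conventional 5 cmH₂O counting
  threshold for more than 1 s, i.e. the generated events are countable
  under the standard definition.
* **Rendering** projects a prolate spheroid with
  $V = \tfrac{4}{3}\pi a b^2$ at a configurable aspect ratio (default
  1.5), attenuating the scene by $\exp(-\mu\,\mathrm{chord})$ with
  $\mu = 0.5$ mm⁻¹ along the X-ray path through the spheroid — a monotone
  attenuation model, no scatter or beam hardening. The center drifts and
  the orientation rotates along a seeded random walk.
* **Background**: two or three rigid high-contrast bars ("bones") at
  distinct orientations (evenly spaced with jitter — separate skeletal
  structures, never a near-parallel pair that would fuse into one wide
  band), translating and rotating along their own random walk. This
  reproduces the moving-background failure mode that makes opacity-based
  volumetry unusable. Additive Gaussian sensor noise (default sd 0.03 on
  the unit intensity scale) completes the frame.
* A fill rate at or above what the urethra can pass during a void would
  make voids unable to empty the bladder; the simulator rejects such
  configurations with a diagnostic instead of producing nonphysical
  cycles.

What the generator does **not** emulate: non-ellipsoidal bladder shapes
and wall deformation, ureters and reflux, catheter artifacts, scatter and
beam hardening, intensity vignetting, and genuinely abrupt posture changes
(drift is a smooth random walk). Passing tests therefore demonstrate the
correctness of the analysis chain under the stated geometric and
attenuation model — not segmentation performance on real animals, which
in the intended workflow comes from a trained network plugged in through
the `predictor` hook.

## Validation protocol and problem sizes

The test-suite checks are all computed against simulator ground truth at
desk scale:

* **Segmentation quality** — `segmentation_benchmark()` simulates three
  recordings at capacities 80/200/400 µl (moderate noise, moving
  background, poses and fill states varying within each clip), segments
  every frame with defaults, and scores per-frame Dice,
  $2|X\cap Y|/(|X|+|Y|)$, on a seeded 20 % holdout — mirroring the
  annotation-holdout protocol used to benchmark trained networks. The
  acceptance bar is a median of 0.95. Frames where both masks are empty
  are 0/0 and are excluded rather than scored 1 (conservative, logged);
  the holdout size rounds up so a nonzero fraction is never empty.
* **Volumetry recovery** — on a noise-free, background-free render at
  0.1 mm/px, the estimated volume must stay within 5 % of truth (relative
  to max(V, 5 µl)) on every frame with $V \ge 5$ µl. The clean render
  isolates the mask→volume stage; robustness to background structures is
  what the Dice benchmark measures.
* **Flow consistency** — on simulated voids, integrated UFR equals the
  volume drop within 2 %, and $t_{20\text{–}80}$ of a linear void equals
  0.6 × its duration within one frame interval.
* **Parameter recovery** — fifteen recordings (capacities 50–400 µl ×
  residual fractions 0/0.25/0.5) must yield the exact void count, BC and
  RV within max(5 %, 3 µl), efficiency within 3 percentage points, and
  ICI within 1 s of ground truth.
* **Determinism** — identical configuration and inputs give byte-identical
  CSV outputs; all randomness flows from the configured seeds.

Fill rates in these scenarios are in the hundreds of µl/min so that full
filling/voiding cycles at capacities up to 400 µl complete within clips of
seconds to a few minutes; the fill rate is an experimenter-controlled pump
setting rather than a biological constant, and the recovered parameters do
not depend on it so long as it stays below the urethral outflow capacity
(which the simulator enforces). Benchmark frames are rendered at
128×128 px and 0.15 mm/px, a realistic field of view and pixel pitch for
mouse bladder fluoroscopy.

## Numerical conventions and degenerate inputs

* Pixel coordinates are 0-based `(row, col)` in the reported geometry;
  masks are pixel supports (a pixel is inside if its center satisfies the
  ellipse inequality).
* The calibration is a single isotropic `pixel_size` (mm/px).
* Empty masks signal a typed condition (`cystovol_empty_mask`); callers
  mark the sample invalid rather than aborting.
* An all-invalid sequence, a non-monotone pressure time axis, a window
  larger than the trace, and non-overlapping time ranges are all rejected
  with diagnostics naming the offending element.
* Both-empty mask pairs have undefined Dice and are excluded from reports.
* CSV outputs are comma-separated with dot decimals and mandatory headers;
  TIFF masks are 8-bit 0/255; frame stacks are written at 16 bits.

## Known limitations

* The prolate-spheroid model understates volumes for strongly
  non-ellipsoidal bladders; no out-of-plane orientation is inferred.
* The reference segmentation assumes the bladder is the most attenuating
  object in the field; a dense implant or contrast pooling elsewhere would
  defeat the dark-core rule (the `predictor` hook is the escape hatch).
* Gap repair is linear and limited to two frames; long occlusions leave
  invalid gaps that propagate into the flow trace via interpolation.
* AVI input is out of scope; convert recordings to multi-page TIFF or a
  PNG sequence first (the supported one-step conversion path).
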