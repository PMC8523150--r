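---
title: "Posture-resolved ratiometric FRET in crawling C. elegans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture-resolved ratiometric FRET in crawling C. elegans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

A freely crawling *C. elegans* bends its body as a traveling dorsoventral
wave. An intramolecular FRET sensor embedded in body-wall muscle reports a
molecular conformation through the ratio of acceptor (mCitrine, E535) to
donor (mCFP, E480) emission. To relate the molecular signal to muscle
mechanics, every video frame must be reduced to (i) a body coordinate
(100 segments from head to tail), (ii) a signed measure of local muscle
state (contracted vs stretched), and (iii) background-subtracted emission
values per segment and body side. `wormfret` implements that reduction, the
downstream contraction-cycle statistics, and a synthetic-video generator
with exact ground truth so that every stage is testable without microscope
data.

# The generative model

The synthetic worm is defined in continuous coordinates and rasterized only
at the end:

* **Midline.** The curvature of the midline is a traveling sine wave,
  $\kappa(s,t) = \kappa_0 \sin(2\pi(\nu s - f t) + \phi_0)$, with $s \in
  [0,1]$ the arc coordinate (0 = head). The midline is obtained by
  integrating the heading angle along the arc. Defaults: amplitude
  $\kappa_0 L = 3$ (dimensionless normalized curvature), wave number $\nu =
  1$ cycle per body length, frequency $f = 1$ Hz — the crawl gait's
  well-known ~1 Hz periodicity and near-body-length wavelength.
* **Body.** The body is the union of discs centred on the midline with
  radius given by a tapered half-width profile (default: elliptical, max
  3.5% of body length; body length 1000 µm, 3.125 µm/px, 512×512 px).
  The geometry is therefore analytically known: the rendered area matches
  $\int 2w(s)\,L\,ds$ and the rasterized side labels derive from the sign
  of the cross product of the local tangent with the pixel offset.
* **Fluorescence.** Per pixel, the side-signed normalized curvature
  $C = \pm\kappa L$ (positive on the contracted side) drives both the
  true ratio $r = r_0 + g\,C(s, t-\tau)$ and the total intensity
  $I = I_0(1 + \beta C)$; the channels are $E_{480} = I(1-r)/2$ and
  $E_{535} = I(1+r)/2$, so the ratiometric index reproduces $r$ exactly
  before noise and both channels brighten on contraction. The coupling
  $g$ distinguishes a "test" sensor strain (default 0.1) from a "control"
  strain (weak or zero coupling); $\tau$ is an optional temporal delay of
  the molecular response (default 0). $\beta$ (default 0.05 per unit $C$)
  is a free synthetic parameter: the contraction-brightening effect is
  qualitative in the source observations and not quantified, so no value
  of $\beta$ is an estimate of the real effect.
* **Nuisances.** A bright pharynx marker blob (3× body intensity, diameter
  10% of body length, centred at $s = 0.05$) is rendered in both
  fluorescence channels; whole-frame translations of up to 10 px every
  ~2 s emulate stage moves; per-pixel Gaussian read noise (default SD 20
  counts) is added and clipped at zero; the donor and acceptor cameras are
  offset by small sub-pixel similarity transforms whose grid control points
  are part of every recording; the fluorescence clock runs at 19.69 fps
  against 37.61 fps brightfield and is desynchronized by half a brightfield
  interval by default.

What the generator does **not** emulate: photobleaching, spectral
bleed-through, point-spread blur, optical effects near the cuticle, 3-D
rolling, self-coiling postures, and realistic locomotion trajectories (the
virtual stage keeps the animal centred). Tests passing on this generator
therefore certify the measurement pipeline's arithmetic and geometry, not
robustness to those effects.

# The analysis pipeline

1. **Registration and pairing.** Grid control points give a closed-form
   least-squares similarity transform per fluorescence camera (SVD of the
   centred cross-covariance). Each fluorescence frame is paired with the
   nearest-in-time brightfield frame, ties toward the earlier frame;
   pairings further than one brightfield interval are flagged unpaired.
2. **Segmentation.** Otsu threshold (the worm is dark on a bright NIR
   background), with a class-separability guard that rejects frames whose
   threshold merely splits the noise distribution; largest plausible
   component (bounds default to 0.5–2× the recording's median area),
   morphological closing (radius 2 px) and hole filling. The intensity
   threshold is estimated once per recording from probe frames.
3. **Midline.** Zhang–Suen thinning, pruning to the longest end-to-end
   skeleton path (double breadth-first search), smoothing-spline fit of
   row/column against arc length, extension along the end tangents to the
   mask tips (skeletons stop short of tapered ends), and resampling to 200
   uniform-arc points. Frames whose skeleton is branched (path covering
   <75% of skeleton pixels) or not elongated are flagged invalid — coiled
   or self-touching postures are discarded, not untangled.
4. **Orientation.** The head is the midline end nearer the pharynx marker,
   detected in the acceptor channel as the largest component brighter than
   2× the median body fluorescence within 15% of a body length of an end;
   frames without a detection inherit the previous frame's orientation.
5. **Side masks and tracking.** The body minus a 1-px-dilated midline band
   must split into exactly two head-to-tail-spanning components. For each
   side, every pixel contributes the angle of its offset from the nearest
   midline point measured in the local frame of the head-to-tail tangent;
   the circular mean of these angles is ±90° for a side lying consistently
   on one lateral flank, and its sign is chirality — invariant while the
   animal stays on one lateral surface — which makes the label persistent.
   Frames where the two side angles share a sign or are separated by less
   than 10° are discarded as ambiguous. (A variant using the whole-side
   centroid against the global tail-to-head chord was implemented first
   and found non-discriminative: in bent postures both centroids fall on
   the concave side of the midline, so that construction tracks the bulge
   direction rather than side identity.)
6. **Sampling.** Every body pixel is assigned to its nearest midline point
   — the nearest-point partition is exactly the set of body-perpendicular
   bands of one inter-point spacing — intersected with the side masks,
   restricted to body-interior pixels (outer-boundary pixels mix body and
   background after sub-pixel registration and would bias thin samples).
   Pixel values are read from each fluorescence camera by bilinear
   interpolation at the registered position; the per-frame background
   (median of non-body pixels) is subtracted per channel. Samples
   overlapping the pharynx marker are excluded (`"pharynx"`), as are
   samples whose total emission is below 3 robust background SDs
   (`"low_emission"`); negative means are clipped to zero and flagged.
7. **Curvature.** Quartic polynomials of row and column against normalized
   arc length, fitted in local windows of ±0.125 body lengths around each
   of the 100 segment centres, give the derivatives for
   $K = |x'y'' - y'x''| / (x'^2+y'^2)^{3/2}$. A single global quartic
   cannot represent a full undulation period (about one period spans the
   body), which visibly distorts curvature; the windowed fit keeps the
   prescribed polynomial family while staying within ~1% of analytic
   curvature for wave numbers up to 1.5. Signed curvature is converted to
   the dimensionless, side-signed normalized curvature $C = \pm K L$
   (positive = contracted side). "Normalized" here means scaled by body
   length — the choice that makes values comparable across animals of
   different sizes. Frames with fit residual RMS > 2 px are flagged.
8. **Kymographs.** Segments × time × side matrices of $C$, E480, E535 and
   FRET share one missing mask; invalid frames are missing columns so the
   time base stays uniform for cycle detection and cross-correlation.

# Cycle statistics

* **Cycles** are detected per segment-side trace as alternating local
  extrema of $C$, keeping extrema with prominence ≥ 0.5× the trace's
  robust SD (1.4826·MAD) and width at half prominence ≥ 0.15 s, assembled
  valley→peak→valley. The thresholds are stated as existing in the source
  method without values; these defaults reject sampling jitter an order of
  magnitude below the undulation amplitude while keeping every true cycle
  of a ~1 Hz wave sampled at ~20 fps.
* **Phase** within a cycle is piecewise linear in time: starting valley
  −90° ≡ 270°, peak exactly 90° (maximum contraction), ending valley 270°
  (maximum relaxation); 0°/360° are the straight postures crossed halfway.
  Summaries use 36 bins of 10° centred on 0°, 10°, …, so 90° and 270° are
  bin centres.
* **Quarter-cycle changes** split each cycle at the sample indices nearest
  the 0/90/180/270° crossings; each quarter's change is signal(last index)
  − signal(first index). Adjacent quarters share their boundary index, so
  the four changes of a complete cycle telescope exactly (to machine
  precision) to the cycle's end-minus-start value. Quarters spanning
  missing data are skipped.
* **Cross-correlation** is mean-subtracted and normalized by the product
  of the population SDs, with missing values removed pairwise per lag, so
  values are in [−1, 1] and comparable across strains; the per-trace peak
  lag and its mode across segments estimate the FRET–curvature delay.
* **Strain comparison** pools quarter changes across cycles, segments and
  animals (each segment treated as an independent sample, replicating the
  source analysis) and runs Welch two-sample t-tests per quarter on
  |ΔFRET| and on per-trace ΔFRET–ΔC correlations. Welch's variant is used
  because "Student's t-test" is unspecified in the source and equal
  variances cannot be assumed between strains.

## The pooling caveat

Treating ~100 segments per animal as independent inflates the effective
sample size. With all animals sharing one undulation clock (identical
frequency, random phases) the pooled Welch test is close to nominal: in
the package's Monte-Carlo calibration (200 replicate null comparisons,
5+5 animals) the type-I error at α = 0.05 falls within the 0.02–0.08
band. Introducing realistic per-animal frequency variation (5–10% SD, see
`cohort_params()`) makes the per-animal quarter-change means heterogeneous
and inflates the pooled test's type-I error several-fold — the expected
failure mode of pooling clustered data. For this reason
`compare_strains()` always reports a per-animal summary (mean |ΔFRET| per
animal, t-test on animal means) alongside the pooled table; when animals
are heterogeneous, the animal-level test is the defensible one.

# Numerical and design choices

* Image convention: matrices indexed (row, col), 1-based, origin top-left;
  x = column and y = row wherever planar geometry (cross products, angles)
  is computed.
* The local quartic design matrices depend only on the (uniform) arc grid,
  so their pseudo-inverses are cached across frames.
* Degenerate inputs error or flag rather than guess: zero-speed
  parameterizations, rank-deficient fits, collinear control points, blank
  frames, circular blobs, first frames without a pharynx detection.
* `fret_value` returns missing (not an error) for zero total emission, and
  is exactly invariant under common rescaling of the two channels — the
  property that removes multiplicative intensity artifacts such as the
  contraction brightening.
* Determinism: identical seeds give bit-identical recordings (the
  generator saves and restores the caller's RNG state); the analysis has
  no random component.
* The side-tracking accuracy statistic fixes the label↔truth
  correspondence on the first valid frame and scores persistence on later
  frames, evaluated by majority vote over mask pixels (on-body pixels have
  a well-defined perpendicular foot on the true midline; the whole-mask
  centroid does not).

## Timing mismatch between cameras

With the default desynchronized clocks a fluorescence frame is up to half
a brightfield interval (~13 ms) away from the geometry used to sample it,
and the worm moves in that window; stage jumps can fall between the two
exposures. This is a real property of dual-rate rigs, and it dominates the
residual error of ratio recovery at body edges. The FRET-identity checks
therefore use recordings with the fluorescence clock synchronous to
brightfield (`fluor_start = 0`, rate = brightfield/2), which isolates the
ratiometric arithmetic; the desynchronized default is used everywhere
else.

# Problem sizes used in tests and the acceptance script

Unit tests run on a desk-scale geometry (450 µm worm, 192×192 px field,
same 3.125 µm/px pitch, 5 s recordings) chosen so the full pipeline stays
fast while every per-frame quantity (segment sample sizes, side-strip
widths) remains a few pixels or more. The side-tracking accuracy study
uses ten 60 s recordings at that geometry with default noise and stage
jumps. Cycle-statistics studies (effect recovery, null calibration, phase
conventions) run at trace level via `simulate_segment_traces()`, whose
default measurement noise (FRET SD 0.02) matches the per-sample noise the
imaging pipeline measures under default conditions; the null calibration
uses 200 replicate 5+5-animal comparisons, and the effect-recovery study
10+10 animals at couplings 0.1 vs 0.02.

# Known limitations

* Coiled and self-overlapping postures are discarded, not resolved.
* Dorsal/ventral identity is a consistent chirality label, not an
  anatomical assignment — the animal may lie on either lateral side.
* No bleed-through or absolute FRET-efficiency calibration: the index is
  ratiometric and its sign depends on the gain balance between channels.
* The quartic window half-width (0.125 body lengths) biases curvature
  toward smoothness for bends far sharper than the default gait.
* The pooled strain test assumes exchangeable segments; see the pooling
  caveat above.
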