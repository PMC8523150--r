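# wormfret

Posture-resolved ratiometric FRET analysis for freely crawling
*Caenorhabditis elegans*.

Intramolecular FRET sensors in body-wall muscle report molecular
conformation through the ratio of acceptor (mCitrine, E535) to donor
(mCFP, E480) emission. Relating that molecular signal to muscle mechanics
in a moving animal requires reducing every video frame to a body
coordinate system: segmenting the worm from near-infrared brightfield,
extracting an ordered head-to-tail midline, discretizing the body into 100
segments, tracking which half of the body is which (dorsal/ventral) as the
animal crawls and turns, and sampling background-subtracted fluorescence
per segment and side. `wormfret` implements this pipeline together with
the downstream statistics, and a seeded synthetic-video generator with
exact ground truth so the whole chain is testable without microscope data.

## The quantities at the core

* **Signed normalized curvature** per segment and side:
  `C = ±K·L`, with `K = |x′y″ − y′x″| / (x′² + y′²)^{3/2}` evaluated from
  local quartic fits of the midline coordinates against arc length, `L`
  the body length; positive on the contracted (inner) side of a bend.
* **Ratiometric FRET index**:
  `FRET = (E535 − E480) / (E535 + E480)`, exactly invariant under common
  intensity rescaling — multiplicative artifacts such as
  contraction-dependent brightening cancel.
* **Contraction-relaxation cycles** detected as prominence- and
  width-filtered extrema of `C`, mapped to 0–360° phase (90° = maximal
  contraction, 270° = maximal relaxation), with quarter-cycle FRET changes
  `ΔFRET = FRET(last index) − FRET(first index)` per quarter and Welch
  t-tests comparing sensor ("test") and control strains.
* **Normalized cross-correlation** of FRET against curvature per segment,
  whose modal peak lag estimates the molecular response delay.

## Worked example

```r
library(wormfret)

params <- worm_model_params(body_length = 450, image_size = c(192L, 192L),
                            duration = 10, strain_coupling = 0.1, seed = 7)
sim <- generate_recording(params)

analysis <- analyze_recording(sim$recording, pipeline_config())
print(analysis)
#> <worm_analysis> 189/197 valid frames, body length 444 um

acc <- evaluate_side_tracking(analysis, sim$truth)
cat(sprintf("side-label accuracy: %.1f%% over %d valid frames\n",
            acc$accuracy_pct, acc$n_valid))
#> side-label accuracy: 100.0% over 189 valid frames

xc <- analysis_cross_correlation(analysis, max_lag_s = 1)
cat(sprintf("modal FRET-curvature peak lag: %.3f s\n", xc$modal_lag_s))
#> modal FRET-curvature peak lag: 0.000 s

q <- analysis_quarter_stats(analysis)
round(tapply(q$d_fret, q$quarter, mean), 4)
#>    0-90  90-180 180-270 270-360
#>  0.3010 -0.2732 -0.3173  0.2871
```

Reading the output: 189 of 197 fluorescence frames survived the validity
gates (segmentation, midline, orientation, side-split, angle threshold);
the persistent dorsal/ventral labels matched the generator's ground truth
on every valid frame; the FRET signal tracks curvature with no delay (the
injected coupling is instantaneous); and the quarter-cycle FRET changes
rise while muscle contracts (0–90°, 270–360°) and fall while it relaxes
(90–270°), with magnitude ≈ coupling × curvature amplitude.

For two-cohort comparisons, `make_strain_pair()` builds matched
test/control cohorts, `analysis_quarter_stats()` pools quarter-cycle
changes, and `compare_strains()` produces the per-quarter comparison table
(pooled Welch tests plus per-animal summaries).

The command-line wrapper `inst/cli/wormfret.R` exposes `simulate`,
`analyze` and `compare` subcommands over the same functions; all pipeline
thresholds live in `pipeline_config()` and round-trip through YAML.

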