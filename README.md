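# punctate

Quantifying phase-separated synaptic protein condensates from fluorescence
imaging.

Presynaptic terminals hold their synaptic vesicle clusters together in part
through liquid–liquid phase separation of soluble proteins (synapsin,
endophilin and other endocytic scaffolds). Characterizing these condensates
quantitatively requires three kinds of image computation, all implemented
here as a tested, reusable R pipeline:

1. **3D single-molecule reconstruction** — turning astigmatic STORM blinking
   movies into drift-corrected 3D localization tables: 2D Gaussian spot
   fitting (pixel-integrated, Levenberg–Marquardt), axial positions from the
   fitted width difference `wx − wy` via a monotone calibration, and
   fiducial-based drift correction.
2. **Object-based two-color cluster colocalization** — binning each
   channel's localizations onto a 10-nm voxel grid, Gaussian smoothing +
   Otsu binarization, extracting the major connected cluster, and computing
   directional Manders coefficients
   `M(A in B) = |A ∩ B| / |A|`, cluster volumes and their ratio, and the
   center-of-mass distance `‖COM_A − COM_B‖`.
3. **Condensate dynamics statistics** — normalized dispersion/recovery
   series `ΔF = (F − F_ref)/F0` from circular-ROI traces, mobile fractions,
   monoexponential fits `y = A (1 − e^(−t/τ))` with an imaging-window
   exclusion rule, FRAP normalization (pre-bleach → 1, bleach point → 0),
   coefficient-of-variation line scans (CV = SD/mean) and 2D droplet
   colocalization.

A first-class synthetic-data module generates every input the pipeline
consumes — blinking movies with an astigmatic PSF, Poisson noise, drift and
fiducials; calibration z-stacks; puncta dispersion time series; FRAP traces
— with exact recorded ground truth, so each stage is validated by recovery
against known answers. Tables are tibbles, results have broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()` methods, and everything
chains with the pipe.

## Worked example

Simulate a two-channel synapse with a known 50% overlap, reconstruct it
through the full pipeline, and compare with truth (about 2 minutes):

```r
library(punctate)

m <- storm_recovery_study(overlap = 0.5, seed = 1)
m[, c("manders_a_in_b", "truth_overlap_a_in_b",
      "com_distance_nm", "truth_com_distance_nm")]
#> # A tibble: 1 × 4
#>   manders_a_in_b truth_overlap_a_in_b com_distance_nm truth_com_distance_nm
#>            <dbl>                <dbl>           <dbl>                 <dbl>
#> 1          0.518                0.498            49.0                    50
```

The recovered Manders coefficient (0.518) sits within 0.021 of the
voxel-exact truth (0.498) and the 50-nm center-of-mass offset is recovered
to within a nanometer — the reconstruction chain is unbiased at the scale
the colocalization analysis needs.

Kinetics of activity-dependent dispersion:

```r
kin <- kinetics_truth(amplitude = 0.36, tau_dispersion = 23.5,
                      tau_recovery = 107.8, noise_sd = 0.02)
traces <- simulate_puncta_timeseries(kin, n_puncta = 10, seed = 1)
ds <- dispersion_metrics(traces)
fit <- fit_monoexponential(ds$mean_dispersion)
glance(fit)
#> # A tibble: 1 × 6
#>        A   tau status         rss     n window
#>    <dbl> <dbl> <chr>        <dbl> <int>  <dbl>
#> 1 -0.363  23.8 converged 0.000641    13     60
```

The fitted amplitude (−0.363; negative because fluorescence disperses out of
the punctum) and time constant (23.8 s) recover the generating parameters
(0.36, 23.5 s); `autoplot(fit)` overlays the fit on the series, and
`mean(ds$mobile$mobile_fraction)` gives the experiment's mobile fraction.

Reproducible end-to-end runs are driven by a YAML/list config:
`run_pipeline(list(seed = 7, out_dir = "out"))` writes localization tables,
colocalization metrics, kinetics fits and a JSON manifest embedding all
parameters; identical configs give byte-identical outputs. A thin
subcommand CLI wrapping the same functions is installed at
`inst/cli/punctate-cli.R`.

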