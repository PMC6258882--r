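# mwfpipe

Myelin water fraction (MWF) mapping from multi-echo T2 relaxation MRI,
with the multi-site reproducibility statistics used to qualify the
measurement for clinical and multicenter use.

## What it does, and for whom

Myelin water — the water trapped between myelin bilayers — relaxes much
faster (T2 ≈ 15 ms) than intra/extracellular water (≈ 70 ms) or CSF
(≥ 2 s). Fitting a nonnegative T2 spectrum \(x\) to each voxel's
32-echo decay curve and taking the spectral fraction inside the
15–40 ms window,

```
MWF = sum(x[15 ms <= T2 <= 40 ms]) / sum(x),
```

gives an in-vivo surrogate of myelin content used to study demyelinating
disease. This package is for quantitative-MRI researchers who need:

1. **The voxelwise fit**: regularized non-negative least squares (NNLS)
   over 40 log-spaced T2s (15 ms–2 s), with **stimulated-echo
   correction** — the true refocusing flip angle of each voxel is
   estimated by comparing the measured decay against extended phase
   graph (EPG) predictions at 8 candidate angles (50–180°), and the
   spectrum is fit with the EPG basis at that angle. The energy penalty
   is set by bisection so the misfit χ² inflates by a controlled 2–2.5%.
2. **The agreement statistics** for paired two-site data:
   small-sample-corrected coefficients of variation
   (COV × (1 + 1/(4n))), Pearson r with exact p, paired t with the
   smallest detectable difference, TOST equivalence at ±0.005 MWF,
   Bland–Altman bias/limits/proportional-bias slope, and noncentral-t
   power analysis for paired designs.
3. **A synthetic two-site phantom generator** with known ground truth
   (three-compartment voxels, smooth B1 flip-angle error, site-dependent
   SNR, between-participant variation) to validate the whole chain end
   to end.

## Worked example

Fit one noisy white-matter-like voxel (true MWF 0.12, true flip angle
155°, SNR 150), then run a small synthetic two-site study end to end:

```r
library(mwfpipe)

curve <- 0.12 * epg_echo_amplitudes(0.015, 1, 155) +
         0.88 * epg_echo_amplitudes(0.070, 1, 155)
set.seed(42)
curve <- curve + rnorm(32, 0, curve[1] / 150)
fit_voxel(curve, make_t2_grid(), echo_train(), fit_config())
#> voxel_fit: MWF 0.0967, angle 156.9 deg, chi2 0.0012 -> 0.00122

study <- generate_two_site_study(6, site1 = list(snr = 200),
                                 site2 = list(snr = 150),
                                 shape = c(5, 5, 1), seed = 7)
dir <- tempfile()
manifest <- write_study(study, dir)
res <- run_pipeline(manifest, pipeline_config(), file.path(dir, "out"))
res$report
#> Intersite reproducibility report
#>   sites: site1 vs site2; TOST bounds +/-0.005, alpha 0.05
#>   mean corrected COV (%) by ROI:
#>     global_wm                  4.93
#>   [global_wm] bias 0.0003559, LoA (-0.01105, 0.01176), r 0.799 (p 0.0565),
#>   paired t p 0.887, TOST p 0.054
```

Reading the output: the fitted voxel recovers the flip angle to ~2° and
the MWF to ~0.02 (the regularized fit is known to run slightly low — see
the methods vignette). In the 6-participant study the mean intersite COV
is ~5%, the bias between sites is ~3.6 × 10⁻⁴ MWF units with limits of
agreement ≈ ±0.011, and at n = 6 neither the correlation nor the TOST
reaches significance — which is exactly why the power analysis exists:

```r
required_sample_size(0.49, 0.90)   # 46 participants for 90% power
required_sample_size(0.49, 0.80)   # 35 participants for 80% power
```

## Command line

```sh
mwfpipe simulate --out-dir sim/ --n 10 --snr1 200 --snr2 150 --seed 1
mwfpipe run --manifest sim/manifest.csv --out-dir results/
mwfpipe fit --decay subj1.nii.gz --mask wm.nii.gz --out-prefix subj1
mwfpipe stats --roi-table roi_summary.csv --out report/ --bounds 0.005
```

(The wrapper script lives at `system.file("cli", "mwfpipe",
package = "mwfpipe")`; all subcommands are also reachable via
`mwfpipe_main()` in R.)

## Layout

- `R/epg.R` — EPG echo amplitudes + isochromat Bloch oracle
- `R/spectrum.R` — T2 grid, NNLS, flip-angle estimation, regularized
  spectrum fit, MWF maps
- `R/phantom.R` — synthetic phantoms and two-site studies
- `R/roi.R` — mask threshold/erode, ROI means, percentiles
- `R/stats.R` — COV, Pearson, paired t, TOST, Bland–Altman, power
- `R/nifti.R`, `R/io.R`, `R/pipeline.R`, `R/cli.R` — I/O, config,
  drivers
- `vignettes/mwf-methods.Rmd` — model, assumptions, tunables, known
  limitations
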