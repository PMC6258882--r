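---
title: "Myelin water fraction mapping and intersite reproducibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin water fraction mapping and intersite reproducibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwfpipe)
```

## The measurement model

A multi-echo spin-echo acquisition (here: 32 echoes, TE = 10, 20, …,
320 ms, i.e. 10 ms echo spacing) samples, in every voxel, a T2 decay
curve that is a mixture of the water compartments present in the tissue:
myelin water trapped between myelin bilayers (short T2, ~15 ms),
intra/extracellular water (~70 ms), and cerebrospinal fluid (≥ 2 s).
Writing the unknown T2 amplitude spectrum as a nonnegative vector $x$
over a grid of $M$ relaxation times, the noiseless signal at echo $i$ is

$$ s_i = \sum_{j=1}^{M} A_{ij}(\alpha)\, x_j, $$

where column $j$ of $A(\alpha)$ is the theoretical decay curve of a pure
compartment with relaxation time $T_{2,j}$ refocused with flip angle
$\alpha$. The **myelin water fraction** (MWF) is the spectral fraction in
the short-T2 window,

$$ \mathrm{MWF} = \frac{\sum_{j:\, T_{2,j} \in [15, 40]\,\mathrm{ms}} x_j}
                      {\sum_{j} x_j}, $$

with both window endpoints inclusive. The default grid has 40
logarithmically spaced points from 15 ms to 2 s, so the first grid point
sits exactly on the window's lower edge and is counted inside it.

## The EPG forward model and stimulated-echo correction

Transmit-field (B1) inhomogeneity makes the actual refocusing flip angle
deviate from the nominal 180°. Under imperfect refocusing the echo train
is *not* mono-exponential: magnetization stored longitudinally between
pulses returns later as stimulated echoes, raising late echoes above the
pure T2 curve. `epg_echo_amplitudes()` computes the echo-top amplitudes
with the extended phase graph (EPG) formalism: configuration states
$(F^+_k, F^-_k, Z_k)$ advance one dephasing order per half echo spacing
(refocusing pulses sit midway between echoes), each pulse mixes states
through the standard rotation operator, and between events transverse
states decay with $e^{-\tau/T_2}$ and longitudinal states with
$e^{-\tau/T_1}$.

Numerical and modeling choices:

* **Excitation is an ideal 90°**; only refocusing pulses carry the
  flip-angle error. Slice-profile and gradient-echo readout effects are
  not modeled.
* **Longitudinal equilibrium regrowth is dropped.** Pathways that were
  never excited cannot contribute echoes within one excitation, and
  repetition-time saturation only rescales the voxel amplitude, which
  cancels in the MWF ratio. The repetition time is recorded in
  `echo_train()` but unused.
* **T1 is not estimated.** All spectrum components are simulated with a
  fixed T1 (default 1.0 s, the conventional white-matter assumption;
  configurable via `fit_config(t1 = )`). At 10 ms echo spacing the fit
  is very weakly sensitive to T1.
* **State truncation.** Orders above $2(n_{\mathrm{echoes}}+1)$
  half-spacing units are unreachable within the train and are not
  allocated.

The EPG recursion is validated against an independent brute-force oracle,
`isochromat_reference()`: explicit Bloch rotation matrices applied to
thousands of isochromats whose per-echo-spacing dephasing uniformly
covers $2\pi$. Because the phases are uniformly *spaced* (not sampled),
the quadrature over dephasing is exact once the spin count exceeds the
highest reachable configuration order, and the two implementations agree
to ~10⁻¹⁵ relative — far below the 10⁻⁵ acceptance threshold. A
consequence worth noting: the "deviation halves as the spin count
doubles" behavior of random-phase ensembles does not apply; convergence
is immediate, and the test suite asserts agreement at both 10³ and 10⁴
spins instead.

## Spectrum fitting

Per voxel, `fit_voxel()` chains three steps.

**1. Flip-angle estimation.** The decay curve is fit by unregularized
non-negative least squares (NNLS) against EPG bases built at 8 candidate
angles linearly spaced on [50°, 180°] (endpoints included). The residual
$\chi^2$ profile over angle is interpolated with a cubic spline
(`stats::splinefun`, "fmm") and minimized on a 0.1° grid clamped to the
candidate range. When some candidate already fits at the noiseless
$\chi^2$ floor, that candidate is returned exactly — interpolating around
an exact zero would only wobble the estimate. On noiseless synthetic
curves this inverts the true angle to ≤ 0.5° at candidates and ≤ 2°
between them; at SNR 200 the estimation error is ~1.5° SD, which has a
negligible effect on the MWF.

**2. Regularized NNLS.** With the basis rebuilt at the estimated angle,
the spectrum solves

$$ \min_{x \ge 0} \; \lVert A x - b \rVert^2 + \mu \lVert x \rVert^2 $$

via row augmentation ($A$ stacked over $\sqrt{\mu} I$, zeros appended to
$b$) and the Lawson–Hanson active-set solver (compiled; verified against
an exhaustive active-set enumeration oracle). The energy penalty $\mu$ is
chosen by bisection on $\log \mu$ so that the misfit inflation
$\chi^2_\mu / \chi^2_{\min}$ lands in **[1.02, 1.025]**, the conventional
criterion of the multi-echo T2 literature. Within that band we converge
to the *lower* edge — the least regularization satisfying the criterion —
which slightly reduces the spectral smearing documented below. Data
whose unregularized misfit is already below $10^{-10}\lVert b \rVert^2$
(noiseless synthetics) are returned unregularized; a bracket
$[10^{-10}, 10^{4}] \times \mathrm{mean}(\mathrm{diag}\,A^\top A)$ and a
60-iteration cap guard the bisection, with a warning and the closest
bracket end on failure.

**3. Windowed fraction.** `compute_mwf()` forms the inclusive-window
ratio; all-zero spectra (zero-signal voxels) are flagged undefined and
excluded from every downstream mean.

MWF and estimated angle are scale invariant — multiplying a curve by
$c > 0$ scales the spectrum by $c$ and changes nothing else — so receiver
gain differences between scanners do not propagate into the statistics.

### Known bias of the regularized estimate

Energy regularization trades misfit for smoothness, smearing the myelin
peak; the part of the smeared peak that crosses the 40 ms window edge is
lost from the numerator. Measured on two-pool synthetic voxels (myelin
T2 15 ms, IE 67.6 ms, angles uniform in [120°, 180°], SNR 200, 1000
replicates per stratum), the bias of the fitted MWF is −0.018 at true
MWF 0.05–0.10 and −0.015 at 0.15–0.20, with per-voxel SD ≈ 0.02. The
unregularized fit is nearly unbiased (−0.008) but far noisier
spectrally. This bias is inherent to the χ²-inflation criterion, sits
just inside the package's 0.02 acceptance bound, and is the main reason
the myelin compartment default in the phantom is 15 ms: with a 20 ms
myelin pool the smeared peak straddles the window edge and the bias
roughly doubles (−0.03 to −0.05). Comparisons should therefore be made
between identically processed datasets, which is exactly the intersite
use case.

## The synthetic two-site phantom

`generate_two_site_study()` emulates the statistical structure a paired
two-site reproducibility analysis assumes, not brain anatomy:

* **Voxel composition.** White-matter voxels mix a myelin pool (15 ms, at
  the assumed short-T2 value for white matter) with an IE pool (70 ms);
  an optional CSF slab (T2 2 s, T1 4 s — CSF is simulated with a physical
  T1 even though the *fit* assumes 1 s, a deliberate, realistic model
  mismatch). Fractions are normalized per voxel; the ground-truth MWF
  equals the fraction of compartments with T2 inside the myelin window.
* **B1 inhomogeneity.** The true refocusing angle varies smoothly as a
  cosine bump, default 165° ± 10° — a typical in-vivo deviation
  magnitude; deterministic, so site B1 differences are controlled.
* **Site differences** are SNR and B1 settings (defaults SNR 200 vs 150:
  a plausible vendor/coil gap). In-plane resolution differences are
  treated as part of the SNR difference rather than an explicit
  resampling chain.
* **Participant variation.** Each participant draws a true MWF offset
  ~ Normal(0, 0.01) around 0.10 — about a 10% between-subject CV, typical
  for global white-matter MWF in healthy adults — shared between that
  participant's two site renderings.
* **Noise** is zero-mean Gaussian on the magnitude signal with SD =
  (mean noiseless first-echo WM signal)/SNR; a Rician mode is available,
  indistinguishable in practice above SNR 50. `snr = Inf` means literally
  noise-free, so a zero-injected-variance study yields exactly zero COVs
  and bias. Seeds: participant $p$ uses `seed + p` for its truth draw and
  `seed + 1000p + {1,2}` for the two site noise streams, so individual
  participants are reproducible in isolation.

What a green synthetic test does *not* establish: robustness to
registration error, partial-volume mixing at tissue boundaries, motion
and flow artifacts, susceptibility effects near the frontal sinuses, or
multi-slice magnetization transfer — none of which are modeled.

## Reproducibility statistics

All statistics operate on per-participant, per-ROI mean MWFs with the
difference convention site1 − site2 and $n{-}1$ sample SDs throughout.

* **Corrected COV** (`corrected_cov`): $100\,(\mathrm{SD}/\mathrm{mean})
  (1 + 1/(4n))$ per participant across its $n{=}2$ site values; the
  small-sample factor at $n{=}2$ is 1.125. Per-ROI summaries are means of
  per-participant corrected COVs.
* **Pearson r** with the exact t-transform p-value
  ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, $n{-}2$ df);
  `pearson_p_from_r()` lets printed (r, n) pairs be verified directly.
* **Paired t** with its 95% CI; the CI half-width
  (`smallest_detectable_difference`) is the smallest intersite difference
  the design could have detected.
* **TOST equivalence**: one-sided tests against ±δ bounds (default
  δ = 0.005 MWF units), overall p = max of the two one-sided p-values,
  equivalence declared when the 90% CI lies inside the bounds. Accepts
  either raw pairs or printed summaries (d̄, SE, df).
* **Bland–Altman**: bias, ±1.96 SD limits of agreement, and a two-sided t
  test on the OLS slope of differences vs pair means (proportional-bias
  check, df $n{-}2$).
* **Power analysis** (`required_sample_size`): smallest $n$ such that a
  two-sided one-sample t-test on paired differences with noncentrality
  $d\sqrt{n}$ and $n{-}1$ df reaches the target power, computed from the
  noncentral t distribution — the same computation G*Power performs for
  "means: difference between two dependent means".

```{r power}
required_sample_size(0.49, 0.90)   # 46
required_sample_size(0.49, 0.80)   # 35
```

## Masks and ROI summaries

`threshold_binarize()` (inclusive threshold) and `erode_mask()`
(6-connected, face-adjacent structuring element; boundary voxels always
erode) implement the conservative-mask construction; the probability
threshold (0.9) and erosion depth (1 pass) are package defaults since the
upstream convention leaves them to the analyst, and both are
CLI-configurable. Percentiles use linear interpolation between order
statistics. Registration, atlas warping and manual mask editing are out
of scope — masks are consumed in the native voxel grid of the decay data.

## File formats and degenerate inputs

NIfTI-1 I/O is implemented in the package (single-file `.nii`/`.nii.gz`,
little-endian, float64 payload, sform affine) because no NIfTI reader is
available in the target installation; it intentionally supports only what
the pipeline writes and reads. Echo times always come from configuration,
never from NIfTI headers. Degenerate inputs are handled explicitly:
all-zero voxels are undefined (flagged, excluded, counted); empty
effective masks are errors; a COV with non-positive mean is an error;
zero-variance pairs make the paired t degenerate ($t{=}0, p{=}1$) and
disable the TOST rather than dividing by zero.

## Design choices made where the design was open

* Candidate angles include both endpoints of [50°, 180°] (8 values,
  spacing 18.57°).
* The continuous-angle spline minimizer (rather than picking the best of
  8 candidates) follows the practice of the stimulated-echo-correction
  lineage; the exact-candidate shortcut at the χ² floor makes noiseless
  inversions exact.
* χ²-band targeting at the lower (least-regularization) edge, as argued
  above.
* The per-ROI table statistic is the mean of per-participant corrected
  COVs, matching the tabulated-summary convention of two-site studies.
* The 90% CI printed by reference reports cannot always be reproduced
  exactly from their rounded d̄ and t; the package verifies the TOST
  overall p instead and exposes the full-precision CI.

## Limitations

Single-T1 EPG without slice profiles or gradient-echo pathways; geometric
(non-anatomical) phantoms; Gaussian-magnitude noise by default; no
registration or segmentation; the regularization-induced negative MWF
bias described above. All empirical figures quoted here are computed by
the test suite or the scripts in this repository.
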