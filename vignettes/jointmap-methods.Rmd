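---
title: "Models and methods behind jointmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jointmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

jointmap implements, end to end and on purely synthetic data, a
free-breathing 3D joint T1/T1rho cardiac mapping framework for low field
(0.55 T): an ECG-triggered sequence that interleaves four 3D volumes with
different magnetisation preparations, a two-echo Dixon readout, image-
navigator-driven respiratory motion correction, iterative SENSE
reconstruction, patch-tensor low-rank denoising, and dictionary-based
joint parameter estimation. This vignette records the models, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

## The signal model

The sequence repeats a block of four heartbeats with preparations
IR, none, none, T1rho:

* **Inversion recovery** flips the longitudinal magnetisation,
  `Mz -> -eff * Mz`, with inversion efficiency `eff` (default 1.0). The
  inversion time TI = 245 ms is measured from the inversion pulse to the
  first imaging readout: with centric profile ordering the first readout
  is the k-space centre, which is what sets image contrast.
* **Spin-lock (T1rho) preparation** is modelled as ideal tip-down, lock,
  tip-up with gradient spoiling: `Mz -> Mz * exp(-TSL/T1rho)` with
  TSL = 40 ms. During the lock the magnetisation does not relax toward
  equilibrium. The spin-lock amplitude (150 Hz) is carried as metadata
  only: off-resonance and B1 effects on the preparation are out of scope.
* **No preparation** leaves `Mz` unchanged.

Each heartbeat then plays a 14-pulse iNAV train at 3 degrees and a
16-pulse spoiled gradient-echo imaging train at 8 degrees, both at
TR = 9.71 ms. With RF and gradient spoiling the transverse magnetisation
is destroyed every TR, so a longitudinal-only (1D) Bloch recursion is
exact: each pulse scales `Mz` by `cos(fa)` and `Mz` relaxes toward `M0`
over the following TR. Gaps are pure T1 relaxation. The 14-pulse iNAV
train sits inside the TI interval, immediately before imaging; its TR is
taken equal to the imaging TR (the sequence documentation does not state
a separate value). The recorded signal per volume is the pre-pulse `Mz`
at the first imaging pulse times `sin(fa)`.

Because only one inversion occurs per four heartbeats, the steady state
retains history across heartbeats: the two unprepared volumes are *not*
interchangeable at physiological T1, and no closed-form expression is
practical. The simulator iterates blocks until the block-start
magnetisation moves by less than `1e-6 * M0` (capped at 100 blocks, with
a warning flag on non-convergence). This fixed-point criterion is
deterministic and independent of heart rate, unlike a fixed number of
dummy blocks. T2 decay at the echo times is deliberately ignored in the
dictionary signal: the dictionary is a pure (T1, T1rho) family.

A consequence worth knowing when testing: properties like "the T1rho
volume equals the unprepared volume when TSL = 0" hold only when T1 is
much shorter than the RR interval (full inter-beat recovery). The test
suite asserts them in that regime and asserts the volumes stay distinct
at T1 = 700 ms.

## Dictionary matching

The dictionary spans T1 = [50:5:1400, 1400:50:1800, 1800:100:3000] ms and
T1rho = [5:5:20, 20:1:80, 80:4:300, 300:100:600] ms (291 x 122 = 35,502
atoms after de-duplicating shared endpoints), simulated at the subject's
heart rate and acquisition window. Each 4-point signal evolution is
L2-normalised; the measured voxel signal is likewise normalised, so the
maximum inner product is equivalent to the minimum sum of squared
differences (`SSD = 2 - 2 * <a, b>` for unit vectors), and the SSD map
follows directly from the winning inner product. The SSD is computed on
normalised signals. Ties break toward smaller T1, then smaller T1rho, by
ordering the atom rows accordingly and taking the first maximum. The
inner-product argmax runs in a small compiled kernel over atom blocks so
the voxel-by-atom score matrix is never materialised.

Signal polarity is restored before matching: the complex water image of
an IR-prepared volume carries the sign of `Mz` in its phase on top of a
smooth background (coil/B0) phase. The background is estimated by
Gaussian low-pass filtering (sigma 8 voxels by default) of the
pseudo-in-phase echo of a *polarity-free reference contrast* — one of the
unprepared volumes, whose steady-state magnetisation is always positive —
and removed from each contrast's phase; the voxel sign is the sign of the
cosine of the residual. Estimating the background from the same contrast
being corrected cannot work where an entire region is inverted (a whole
long-T1 vial at TI = 245 ms): the filter would absorb the pi flip. Using
a no-prep reference avoids this while removing exactly the same
hardware-induced phase, which is common to the interleaved volumes.

## Monte-Carlo precision analysis

For each tissue on a grid (defaults: T1 = 500:50:1400 ms,
T1rho = 40:4:80 ms, typical myocardium at 0.55 T), white Gaussian noise
of fixed SD is added to the signed 4-point signal, the noisy signal is
matched, and bias and coefficient of variation are computed over trials:
`Bias = mean - truth`, `CV = sample SD / mean` (n-1 denominator, reported
in percent; the same convention is used everywhere in the package). The
published description of the noise level is typographically garbled
("1350M0"); the package default reads it as M0/350 — a fraction whose bar
was lost in typesetting — and every result table carries the configured
`sigma` and seed so the interpretation is explicit and overridable. Noise
is added to the signed signal before normalisation, and polarity is
treated as known: the 1D study has no phase images to restore it from.

At this noise level the simulated precision at 60 bpm stays in the
low-teens CV range across the grid, degrading with heart rate and with
longer T1, which is the qualitative behaviour expected of the sequence
(shorter T1 at low field is an advantage here). The validation script
reruns this study at 2,000 trials per tissue for the grid and 10,000 for
the heart-rate sweep; the test suite checks that CV estimates from
disjoint 5,000-trial halves agree to within 10% relative at the default
noise level.

One reported sweep is ambiguous in the source (CV versus T1rho quoted
once at fixed T1 = 1100 ms and once at fixed T1 = 700 ms); `mc_study()`
takes arbitrary grids, so either variant is a one-liner and neither is
baked in.

## Sampling, motion and reconstruction

**Trajectory.** Phase-encode points on the ky-kz plane follow a
variable-density Cartesian scheme with spiral-like interleaves rotated by
the golden angle and centric (centre-out) ordering within each arm, one
arm per heartbeat. The published source for the trajectory gives no
density constants, so the generator here is parameterised openly: a
central ellipse (default 12% relative radius) is always fully sampled;
outside it points are kept by ranking `rho^decay * u` (u uniform,
decay = 3), and the selected points are grouped into arms shell-by-shell
by angular rank against the golden-angle target angles. The nominal arm
angles are stored as metadata. The readout direction is fully sampled and
handled by FFT; trajectory logic lives entirely on ky-kz.

**Motion.** Beat-to-beat translation is estimated from 2D coronal iNAVs
by FFT cross-correlation with quadratic sub-pixel peak interpolation.
Heartbeats are assigned to B = 5 equal-count bins by foot-head
displacement; equal counts keep the per-bin conditioning comparable (the
partition rule is not stated in the source). Within each bin every
heartbeat's k-space lines receive the exact linear phase ramp moving the
object to the bin's median position (Fourier shift theorem); the
reference bin is end-expiration (smallest median FH displacement). Dense
per-bin displacement fields to the reference come from a small
multi-resolution demons-style registration of the bin images
(intensity-driven updates, Gaussian field smoothing, coarse-to-fine),
written here because the vendor engine is unpublished and no 3D
registration package exists in this R stack; any engine with the same
pull-back convention can be substituted, and ground-truth fields can be
injected outright — which is how the motion-correction claim is validated
independently of registration quality.

**Reconstruction.** The encoding operator per contrast is
`E = sum_b A_b F S U_b`: warp the image to bin position (trilinear
interpolation), multiply by coil sensitivities, orthonormal FFT, sample
on the bin's disjoint mask. The warp adjoint is the exact transpose of
the interpolation matrix — not the inverse warp — so the forward/adjoint
pair satisfies `<Ex, y> = <x, E^H y>` to numerical precision, which is
what conjugate gradients on the normal equations requires. The
motion-corrected solve uses 3 CG iterations from zero initialisation (the
online setting); the per-bin reconstructions that feed registration use a
larger budget (default 15 or residual 1e-6) since they are computed once
per bin. A stopping tolerance of zero forces a fixed iteration count for
exact reproducibility.

## Water-fat separation and denoising

At 0.55 T the water-fat shift is `42.577 MHz/T x 0.55 T x 3.4 ppm ~ 79.6
Hz`, so the printed echo times (2.60 / 6.50 ms) give fat phases of about
74 and 186 degrees: a *pseudo*-in-phase and an out-of-phase echo. The
two-point solver therefore uses the exact complex fat phasors at the
configured TEs rather than assuming 0/pi, with a single-peak fat model
(two echoes cannot support a multi-peak spectrum plus a field map). Per
voxel, the two echo magnitudes determine the water/fat amplitude pair up
to a swap; each candidate implies a field frequency from the inter-echo
phase, and the candidate closer to a smoothed neighbourhood field wins,
iterated a few passes from an intensity-weighted global mode seeded with
a mild prior toward zero field — the standard resolution of the global
two-point swap ambiguity, without which a uniformly fatty region would be
read as water plus a chemical-shift-sized field offset. The final complex
amplitudes come from an exact 2x2 solve with the chosen phasor.

Denoising groups, for each reference patch on a stride grid, the most
similar patches across the search window (similarity summed over all
contrasts) into a third-order tensor (patch-voxels x similar-patches x
contrasts) and thresholds the singular values of each mode unfolding at
`lambda` times that mode's leading value, averaging the three
reconstructions and aggregating overlapping estimates by uniform
weighting. Water and fat stacks are denoised separately. The threshold is
*hard* by default: retained components pass through unchanged, so exactly
low-rank (e.g. noiseless piecewise-constant) data is preserved to machine
precision, while noise-level singular values are removed; soft shrinkage
(subtracting the threshold) is available as an option but biases the
leading component by `lambda` even without noise, which is measurable as
a ~7% amplitude error at the default `lambda = 0.07`. Defaults follow the
published reconstruction settings: lambda 0.07, 5x5x5 patches, 20x20x20
window, 20 similar patches.

## The synthetic phantoms and what they do (not) show

`make_phantom()` builds deterministic digital phantoms: a 9-vial T1
plate, a 10-vial joint T1/T1rho plate, an 8-vial water-fat plate with fat
fractions 0-100%, and a simple cardiac geometry (torso, myocardial
annulus, blood pool, liver). The physical phantoms' compositions are not
tabulated anywhere, so vial values are representative defaults spanning
T1 50-3000 ms and T1rho 5-300 ms, overridable per region. Fat is a second
chemical species with its own short T1 (170 ms default) and a
T2-like T1rho stand-in (50 ms) — a documented simplification.
`simulate_acquisition()` composes the Bloch signals with the full
acquisition physics: per heartbeat the echo images are deformed by the
motion state, weighted by smooth synthetic coil maps (Gaussian profiles,
sum-of-squares normalised), Fourier transformed, sampled on that
heartbeat's arm, and perturbed with complex white Gaussian noise; rigid
translation is applied as an exact k-space phase ramp (the sensitivities
ride with the object, the same commutation the intra-bin correction
assumes), and the nonrigid component is quantised to a few amplitude
states so the returned ground-truth per-bin fields agree exactly with
what was applied. iNAVs are coronal projections of the moving phantom
under 3-degree excitation weighting.

Passing the end-to-end tests on these phantoms demonstrates the internal
consistency of the chain — signal model, sampling, reconstruction,
separation, matching — under known ground truth. It does not demonstrate
robustness to things real data contain and the generator does not:
B0/B1 inhomogeneity in the spin-lock preparation, magnetisation transfer
and diffusion confounders, imperfect spoiling, cardiac contraction within
the acquisition window, multi-peak fat, or registration failure modes on
realistic anatomy.

## Problem sizes, tolerances and degenerate inputs

The shipped studies run at desk scale, chosen so the whole validation
suite completes in minutes on one core while the Monte-Carlo statistics
remain stable: 2,000 trials per tissue for the 209-combination grid
study, 10,000 for the 4-heart-rate sweep, a 96 x 96 x 8 phantom at 2 mm
for the end-to-end vial study (acceleration 2, 8 coils, SNR 30 defined as
median vial magnitude over image-domain noise SD), and 48 x 48 x 8 for
the breathing-phantom experiment. Steady-state detection uses the
`1e-6 * M0` fixed point; CG tolerances are stated per use above;
dictionary matching breaks ties deterministically; all-zero voxel
signals, empty ROIs, non-positive log-fit samples and flat navigator
images are either sentinelled or rejected loudly rather than propagated
as NaN. All randomness flows from explicit integer seeds.

## Known limitations

The iNAV TR and the prep-to-iNAV gap are not published; both follow the
documented conventions above and are configurable. The inversion is
ideal up to a scalar efficiency. The T1rho preparation model omits
off-resonance (the published discussion itself defers B0/B1 modelling).
The demons registration is a compact default, not a tuned clinical
engine — the pipeline contract allows swapping it, and ground-truth
injection decouples the reconstruction claims from it. Phantom agreement
statistics against scanner data (regression slopes, Bland-Altman biases,
in vivo values) are not reproducible from code alone since no acquisition
data are deposited; the package instead validates the same statistics on
its own synthetic ground truth.
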