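# jointmap

Simulation, reconstruction and quantitative mapping for free-breathing 3D
**joint T1/T1ρ cardiac MRI with Dixon encoding at low field (0.55 T)** —
built as a fully synthetic-testable R package: every stage of the
published-style acquisition/reconstruction chain is implemented against
digital phantoms with known ground truth, so the pipeline can be validated
end to end without scanner data.

It is aimed at quantitative-MRI methods researchers who want a desk-scale,
inspectable implementation of:

* a **1D longitudinal Bloch simulator** of an ECG-triggered sequence that
  interleaves four 3D volumes over a 4-heartbeat block
  (IR-prep → none → none → T1ρ-prep; TI = 245 ms, TSL = 40 ms, 8° imaging /
  3° iNAV spoiled-GRE trains at TR = 9.71 ms, 155 ms acquisition window);
* **dictionary matching**: a (T1, T1ρ) atom family
  (T1 = [50:5:1400, 1400:50:1800, 1800:100:3000] ms,
  T1ρ = [5:5:20, 20:1:80, 80:4:300, 300:100:600] ms; 35,502 atoms) simulated
  at the subject's heart rate, matched per voxel by maximum inner product of
  L2-normalised 4-point signals (equivalently minimum SSD,
  `SSD = 2 − 2⟨a,b⟩`), with signal-polarity restoration from the
  pseudo-in-phase echo phase;
* a **Monte-Carlo precision study**: white Gaussian noise on the signed
  signals, `Bias(Y) = μ_Y − Y`, `CV(Y) = σ_Y/μ_Y` over tissue grids and
  heart rates;
* **VD-CASPR-style sampling** (variable-density Cartesian spiral profile
  order, golden-angle arm rotation, centric ordering), iNAV translation
  estimation, equal-count respiratory binning with exact intra-bin
  phase-ramp correction, and **nonrigid motion-corrected iterative SENSE**
  (`E = Σ_b A_b F S U_b`, CG on the normal equations, 3 iterations, with the
  interpolation transpose as the exact warp adjoint);
* **two-point Dixon water–fat separation** at the pseudo-in-phase /
  out-of-phase echo times (2.60 / 6.50 ms; Δf ≈ 79.6 Hz at 0.55 T) and
  **multi-contrast patch-tensor low-rank denoising**
  (λ = 0.07, 5³ patches, 20³ window, 20 similar patches);
* **spin-echo reference fitting** (IR-SE Levenberg–Marquardt, T1ρ-SE
  log-linear) and ROI regression / Bland–Altman agreement analysis with the
  myocardial-range filter (T1 ≤ 1300 ms, T1ρ ≤ 150 ms).

## Worked example

Simulate the steady-state signal of typical myocardium at 0.55 T
(T1 = 700 ms, T1ρ = 56 ms) at 60 bpm, build the dictionary, and match one
noisy realisation:

```r
library(jointmap)
seq_par <- sequence_params()          # printed sequence parameters
timing  <- cardiac_timing(hr = 60)
sig <- simulate_signals(seq_par, timing, tissue_params(t1 = 0.7, t1rho = 0.056))
print(sig)
#> 4-point signal evolution (signed, a.u.)
#> [1] -0.037437  0.095993  0.122818  0.074950
#> sampled at 0.3, 1.3, 2.3, 3.3 s; converged: TRUE in 3 blocks
```

Volume 1 (IR-prepared) is negative at TI = 245 ms, volumes 2–3 recover, and
volume 4 is attenuated by `exp(−TSL/T1ρ)` — the 4-point fingerprint the
dictionary match uses.

```r
dict <- generate_dictionary(seq_par, timing)
#> signal dictionary: 35502 atoms ( 291 T1 x 122 T1rho ), HR 60 bpm
set.seed(1)
match_signals(sig$signals + rnorm(4, sd = 1/350), dict)
#>    t1 t1rho          ssd  atom
#> 1 700    65 0.0001641359 15909
```

One noise draw at SD = M0/350 recovers T1 exactly and perturbs T1ρ by 1.6
standard errors (65 vs 56 ms) — consistent with the Monte-Carlo study below,
which quantifies exactly this spread over thousands of draws:

```r
res <- mc_study(t1_grid = 700, t1rho_grid = 56, hrs = c(60, 120),
                n_trials = 2000, noise = noise_model(seed = 7))
res[, c("hr", "bias_t1", "cv_t1", "bias_t1rho", "cv_t1rho", "sigma")]
#>    hr bias_t1 cv_t1 bias_t1rho cv_t1rho   sigma
#> 1  60   0.492   4.8      0.456     9.52 0.00286
#> 2 120   3.987   8.6      0.656    12.97 0.00286
```

Precision degrades with heart rate (fewer relaxation seconds per block),
and T1ρ is the less precise parameter — a single 40 ms spin-lock carries
less encoding than the inversion recovery carries for T1. The `sigma`
column records the configured noise SD (M0/350) with the results.

For the full imaging chain — phantom → k-space simulation → motion-corrected
reconstruction → Dixon → denoising → maps → ROI agreement — see the methods
vignette (`vignettes/jointmap-methods.Rmd`) and the end-to-end blocks in
`tests/testthat/test-acceptance.R`.

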