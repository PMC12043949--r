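# nucleomech

Quantitative analysis of how viscoelastic culture substrates affect the cell
nucleus. The package implements, as tested R functions with synthetic-data
generators for every input type, the measurement pipeline used to
characterize alginate hydrogels and the nuclear responses of fibroblasts
cultured on them:

- **Substrate rheology** — stress-relaxation curves recorded at constant
  compressive strain are fitted with a two-element Maxwell–Wiechert model,
  σ(t) = σ₀·[p + a₁·e^(−t/τ₁) + a₂·e^(−t/τ₂)], and the relaxation half time
  τ₁/₂ (the time for the stress to fall to half its initial value) is
  extracted from the fitted model by root finding. Initial moduli come from
  the 5–10%-strain slope of compression ramps; oscillatory sweeps are
  normalized by G′ at 1 rad s⁻¹.
- **Nuclear morphometry** — DAPI/Hoechst z-stacks are segmented
  (max-intensity projection → Gaussian blur → Otsu → largest component),
  nuclear volume is the per-slice area sum times the z-step, and the
  chromatin compaction index is integrated intensity / volume.
- **Lamina wrinkling** — the wrinkling index is the mean Gaussian-derivative
  edge magnitude inside the eroded nucleoplasm of a lamin-stained nucleus,
  computed on a percentile-normalized image so it is invariant to staining
  gain and offset.
- **FRAP** — bleach-ROI traces are normalized by the prescan mean and fitted
  with a single-exponential recovery; the half time is t₁/₂ = τᵣ·ln 2.
- **Intranuclear dynamics** — particle tracks (e.g. GFP-fibrillarin) are
  corrected for nucleus drift (center-track subtraction) and rotation
  (inverse Kabsch rotations from landmark sets), the time-averaged MSD is
  computed per track, log₁₀MSD is regressed on log₁₀τ over the first half
  of the lags to give the diffusion exponent α and prefactor D (accepted
  when R² > 0.8), and the time to diffuse 1 µm² is T = (1/D)^(1/α).

Audience: mechanobiology labs quantifying substrate stress relaxation and
its downstream nuclear readouts, and anyone needing seeded, ground-truthed
synthetic data (biexponential relaxation records, ellipsoidal nucleus
stacks, wrinkled lamin images, FRAP traces, fractional-Brownian tracks
composited with rigid nucleus motion) to validate such pipelines.

## Worked example

Synthesize a slow-relaxing gel record, fit it, and read off τ₁/₂; then
recover an anomalous-diffusion exponent from drift/rotation-corrupted
tracks:

```r
library(nucleomech)

g <- gen_relaxation(amplitudes = 1.0, taus = 1442.695, sigma0 = 2,
                    t_max = 4000, dt = 1)
fit_relaxation(g$curve)
#> Two-element Maxwell-Wiechert fit
#>   sigma0   : 2 kPa
#>   weights  : a1 = 2.847e-09, a2 = 1, plateau = 2.007e-09
#>   taus     : 1.444 s, 1443 s
#>   tau_half : 1000 s
#>   RMSE     : 1.07e-09 kPa

tracks <- gen_tracks(200, alpha = 0.5, D = 0.01, seed = 1)$tracks
motion <- gen_nucleus_motion(20, drift_per_frame = c(0.3, -0.2),
                             rotation_per_frame = pi / 60, seed = 2)
observed <- compose_observed_tracks(tracks, motion)
corrected <- lapply(observed, function(tr)
  correct_rotation(correct_drift(tr, motion$center_track), motion$rotations))
fits <- lapply(corrected, function(tr) fit_powerlaw(time_avg_msd(tr)))
ensemble_summary(fits)[, c("n_accepted", "n_rejected", "alpha_median", "T_median")]
#>     n_accepted n_rejected alpha_median T_median
#> all        137         63    0.6033474 5827.119
```

One Maxwell arm takes all the weight at the generating time constant
(1442.7 s, the other arm and plateau are numerically zero), and the half
time is the printed slow-relaxing value (1000 s = 1442.695·ln 2). For the
tracks, the accepted-fit median exponent lands near the generating α = 0.5
after the rigid-motion corruption is inverted — the upward shift and the
63 rejections reflect how noisy individual 20-frame log–log fits are;
tracks with R² ≤ 0.8 are counted but excluded from the summary, as in the
original gating.

`run_pipeline()` (or `inst/scripts/nucleomech.R run --config cfg.yaml`)
drives simulate-and-analyze stages from a YAML/list config and writes
results plus a provenance record; see `?run_pipeline`.

## Package layout

- `R/sim-*.R` — seeded generators (curves, images, tracks, rigid motion)
- `R/rheology.R`, `R/morphometry.R`, `R/wrinkling.R`, `R/frap.R`,
  `R/dynamics.R` — the analysis stages
- `R/io.R`, `R/pipeline.R` — strict-schema CSV/TIFF I/O and configured runs
- `vignettes/nuclear-mechanobiology.Rmd` — models, assumptions, parameter
  choices and limitations
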