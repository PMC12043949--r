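---
title: "Quantifying viscoelastic substrates and their nuclear readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying viscoelastic substrates and their nuclear readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomech)
```

Cells sense not only how stiff their substrate is but how fast it relaxes
stress. Alginate hydrogels make the two axes separable: covalent
crosslinks give nearly elastic gels, ionic crosslinks give viscoelastic
gels whose stress-relaxation half time can be tuned roughly tenfold at
fixed stiffness. This package implements the measurement chain used to
quantify such substrates and the nuclear phenotypes of cells cultured on
them: substrate rheology, nuclear volume and chromatin compaction from
confocal stacks, lamina wrinkling from lamin staining, chromatin mobility
by FRAP, and intranuclear particle dynamics by time-averaged MSD. Every
stage has a paired synthetic-data generator with known ground truth, so
each estimator can be validated end to end.

## Substrate rheology

A compression test holds a gel at constant strain (15% ramp, slope taken
at 5–10% strain for the initial modulus) and records the decaying load.
The record is modeled with a two-element Maxwell–Wiechert solid — a spring
in parallel with two Maxwell arms — giving the biexponential decay

$$\sigma(t) = \sigma_0\left[p + a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}\right],
\qquad p + a_1 + a_2 = 1 .$$

The explicit plateau weight $p$ matters: covalently crosslinked gels relax
very little, and without a plateau term a biexponential fit to such data
degenerates into arbitrarily large time constants. Internally the model is
fitted in amplitude form ($p_0, A_1, A_2 \ge 0$ in kPa, via bounded
Levenberg–Marquardt), which makes the weights-sum-to-one constraint a box
constraint rather than a nonlinear one. Initialization is a deterministic
multi-start over time-constant pairs at $t_{max}/100$, $t_{max}/10$ and
$t_{max}$; the lowest residual sum of squares wins, with ties broken
toward the smaller $\tau_1$. A near-constant record, where the exponential
amplitudes are unidentifiable and no start converges, falls back to the
pure-plateau model rather than erroring.

The relaxation half time $\tau_{1/2}$ — the time for the stress to fall to
half its initial value — is computed from the *fitted* model by bracketed
root finding on $[0, 100\,\tau_{max}]$ (tolerance $10^{-10}\tau_{max}$),
not from a raw-data crossing, so it is insensitive to noise at the
crossing point. It is undefined when $p \ge 0.5$ (the stress never
halves); that case is reported as `NA`, not an error. For a single
exponential the root reduces to $\tau \ln 2$, which is how the generator's
ground truth is checked: a time constant of 1442.7 s gives the 1000-s
slow-relaxing condition, 288.5 s the 200-s fast-relaxing one.

```{r rheo}
g <- gen_relaxation(amplitudes = 1.0, taus = 1442.695, sigma0 = 2,
                    t_max = 4000, dt = 1)
fit_relaxation(g$curve)$tau_half
```

Whether the original fits included an equilibrium plateau for ionic gels
is not documented; the plateau is free by default and can be pinned to
zero with `pin_plateau = TRUE`.

## Nuclear volume and chromatin compaction

Stacks are segmented the way a Fiji workflow would: maximum-intensity
projection, Gaussian blur (default $\sigma = 2$ px), Otsu threshold,
largest connected component, holes filled. Volume is the per-slice area
sum times the z-step (default 0.3 µm, the acquisition step), and the
compaction index is integrated in-mask intensity divided by volume —
exactly, by construction, so the index depends only on those two
aggregates.

Two choices here were genuinely open. First, whether the projected mask is
re-thresholded per slice: applying it unchanged to every slice ignores
that an ellipsoidal nucleus has varying cross-sections, so the default
re-thresholds each slice (Otsu restricted to the projected mask), with
`slice_method = "projected"` reproducing the literal mask-applied-as-is
variant. Second, the per-slice threshold is floored at the whole-stack
Otsu cut, and an Otsu split that isolates under 1% of the in-mask pixels
is discarded in favor of that global cut: within-mask Otsu on a slice that
is entirely inside (or entirely beyond) the nucleus is splitting a
unimodal histogram and would otherwise hallucinate a boundary. With these
guards, synthetic ellipsoids (5 × 5 × 3 µm semi-axes, 0.1 µm pixels) are
recovered to well under 1% volume error at the 0.3 µm step, and the error
falls monotonically as the step is refined (0.6 → 0.3 → 0.15 µm). No
background subtraction is applied to the DAPI integral, matching the
described procedure.

## Lamina wrinkling index

The wrinkling score is the mean gradient magnitude inside the nucleoplasm:
nucleus mask → binary erosion (disk element) → Gaussian-derivative edge
map → mean over the eroded region. The original edge operator is an
external plugin; the same family of operator (gradient magnitude at a
Gaussian smoothing scale, default 2 px) is implemented here directly.
Before edge detection the image is rescaled by its 1st–99th percentile
range, which makes the index exactly invariant to staining gain and
offset — supporting the claim that the score is not driven by fluorescence
variation. The erosion radius defaults to 10% of the mask's equivalent
radius for single images, but comparative batches should fix one radius
across all groups (the tests use 10 px), as the original protocol kept
erosion parameters identical between conditions.

The paired generator draws a disk nucleus with a bright lamina band just
inside its boundary and, in the interior, a smoothed sinusoidal ridge
field whose contrast scales linearly with `fold_amplitude`. The field's
wavelength is fixed in pixels (default 8), so fold coverage per unit area
is independent of nucleus radius — this is what makes the score's
area-decorrelation property testable: across radii of 20–60 px at fixed
amplitude the index varies by under 15%, while it rises strictly
monotonically with amplitude and sits near zero (limited by residual rim
gradient bleed, about 2% of a typical signal) for fold-free nuclei. The
generator draws ridges, not a 3D folded lamina; passing these tests shows
the score tracks in-plane edge content at fixed geometry, not that it
captures every real-lamina morphology.

## FRAP half time

Traces follow the acquisition protocol: 7 prescan frames at 740 ms, a
bleach pulse, then 60–180 frames at 1 s. Intensities are normalized by
the prescan mean (idempotently), and the post-bleach trace is fitted with
the single-exponential recovery
$I(t) = I_p - (I_p - I_b)\,e^{-t/\tau_r}$ with deterministic
initialization (first frame, mean of the last 10% of frames, and the
midpoint-crossing time scaled by $1/\ln 2$). "Half of the final
intensity" is read as the midpoint between the bleach floor and the
fitted plateau, giving $t_{1/2} = \tau_r \ln 2$ — the literal
plateau-over-two reading is offset-dependent and not scale-invariant, but
is available via `halfdef = "absolute"`. A flat or decaying trace returns
a typed no-recovery outcome instead of a spurious fit. At 2% noise and
120 frames, $\tau_r$ is recovered with under 2% bias and under 8%
standard deviation over 200 traces. No reference-ROI photobleaching
correction is applied (none was described), and the model is deliberately
single-exponential — no diffusion-model (Soumpasis) fitting.

## Intranuclear dynamics

Tracks of nucleolar particles ride on a nucleus that drifts and rotates.
The forward model is $obs(t) = c(t) + R(t)\,p(t)$; correction inverts it
in two steps, following the original order of operations: subtract the
nucleus center track, then multiply by the inverse rotation. Rotations
come from landmark sets via the Kabsch algorithm (SVD of the centered
cross-covariance, determinant forced to +1). Per-frame rotation matrices
invert rigid motion exactly (to numerical precision, < 1e−9 µm); the
averaged variant — one chordal-mean rotation per trajectory, mirroring
the described averaging — is also provided and leaves a quantifiable
residual on strongly rotating nuclei, which is why the per-frame mode is
the default whenever per-frame matrices are available.

The time-averaged MSD at lag $\tau = k\,\Delta t$ is the mean of
$|r(t+\tau) - r(t)|^2$ over all ordered frame pairs. The source formula
prints a bare sum; the mean-over-pairs convention is used because pair
counts vary with lag and only the mean keeps the log–log slope meaningful
(`average = FALSE` reproduces the literal sum). The anomalous-diffusion
fit regresses $\log_{10} MSD$ on $\log_{10}\tau$ over the first 50% of
available lags (rounded down, minimum 3): slope $\alpha$, prefactor
$D = 10^{\mathrm{intercept}}$ in µm² s⁻ᵅ with no 2d/4d/6d factor divided
out — the time to diffuse 1 µm², $T = (1/D)^{1/\alpha}$, is only
dimensionally consistent with that raw prefactor. Fits are accepted when
$R^2 > 0.8$; rejected tracks are counted but excluded from ensemble
summaries. Both per-track fitting (then medians) and fitting the
ensemble-averaged curve are available, since which was used originally is
not stated.

The generators synthesize fractional Brownian coordinates with exact
covariance (circulant embedding, Cholesky fallback; $\alpha = 2$ is the
degenerate constant-velocity limit), scaled so the dimension-summed MSD
expectation is $D\tau^\alpha$. One estimator property is worth stating
plainly: on 20-frame tracks the per-track log–log fit of $\alpha$ has a
small negative bias (median within about −0.1), and because the intercept
extrapolates from lags of 120–1080 s down to $\tau = 1$ s, that small
exponent bias is amplified exponentially into the per-track $D$ — median
$D$ over hundreds of such tracks runs some tens of percent high. This was
verified against an independent exact multivariate-normal construction of
the same process, so it is a property of the estimator at this track
length, not of the generator. Ensemble-curve fitting largely removes it;
per-track medians of $D$ from short tracks should be interpreted with
that bias in mind.

## Problem sizes, determinism, degenerate inputs

Every generator takes a single integer seed and never touches the
session's RNG stream; identical calls are bit-identical. The validation
suite works at deliberately modest sizes — 200 tracks of 20 frames per
condition (the acquisition's "20 time points at 2-min intervals"), 200
FRAP traces, single nuclei at 0.1 µm pixels — chosen to exercise the
study's own acquisition geometry. Degenerate inputs are typed, not silent:
undefined half times are `NA` outcomes, non-recovering FRAP traces get a
`frap_no_recovery` class, collinear landmark sets and improper rotation
matrices raise geometry errors, fully-eroded masks raise degenerate-input
errors, and strict CSV schemas name the offending column and row.
Calibration (pixel size, z-step, frame interval) always comes from
arguments or config, never from TIFF metadata, because tag conventions
vary silently across acquisition software.

## Known limitations

- No microscope PSF or photophysics simulation; image ground truth is
  geometric.
- No spot detection or linking: trajectories enter as CSV from an
  external tracker, with concatenated-loci tracks excluded upstream.
- No localization-error correction of MSD curves, no Bayesian motion-model
  selection, no Prony series beyond two Maxwell arms.
- The wrinkling generator produces in-plane ridges, not 3D lamina folds;
  tracking of real wrinkle morphology beyond edge content is untested.
- Sequencing-based readouts of the original study (RNA-seq, ATAC-seq) are
  out of scope entirely.
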