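---
title: "Chemical-shift-encoded PDFF mapping: model, optimization, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-shift-encoded PDFF mapping: model, optimization, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdffmap)
```

## The signal model

A spoiled multi-echo gradient-echo acquisition samples each voxel at echo
times $TE_1, TE_1 + \Delta TE, \dots$ The complex signal of a voxel holding
water and fat is

$$ s_n = \left(\rho_W e^{i\varphi_W} + \rho_F e^{i\varphi_F} c_n\right)
   e^{i 2\pi \Delta f \, TE_n} e^{-R_2^* TE_n},
   \qquad c_n = \sum_p a_p e^{i 2\pi f_p TE_n}, $$

with water and fat magnitudes $\rho_W, \rho_F$ and phases $\varphi_W,
\varphi_F$, off-resonance (field-map) frequency $\Delta f$ in Hz, effective
transverse relaxation $R_2^*$ in Hz, and a multi-peak fat spectrum with
normalized amplitudes $a_p$ at frequency offsets $f_p$. Peak positions are
carried in ppm relative to water and converted per field strength with
$\gamma/2\pi = 42.577$ MHz/T at nominal 3.0 / 7.0 T, so one spectrum serves
both fields. Two measured spectra ship with the package (`fat_model()`): a
9-peak peanut-oil/agarose spectrum (dominant peak $-3.51$ ppm) and an 8-peak
subcutaneous-tissue spectrum ($-3.24$ ppm); protocol optimization uses the
conventional single $-3.3$ ppm peak.

Water and fat carry independent phases: the model has six real parameters
per voxel. A shared-phase five-parameter variant would gain a little noise
efficiency but is more fragile under the eddy-current phase errors this
package is designed to study, so it is not the default anywhere.

Sign conventions, declared once and used consistently: positive $\Delta f$
*advances* phase with echo time ($e^{+i2\pi\Delta f\,TE}$); demodulation
multiplies by the conjugate factor $e^{-i2\pi\Delta f\,TE}$. A round-trip
test (simulate at $\Delta f$, demodulate with $\Delta f$, separate, expect a
zero field map) pins the convention.

## Echo-time optimization via NSA*

The *effective number of signal averages* measures the noise efficiency of
estimating parameter $p_k$ from the echo train:

$$ \mathrm{NSA}^*(p_k) = \frac{\sigma^2(p_k)}{\sigma^2(\hat p_k)}, $$

where the denominator is the Cramér–Rao variance with all six parameters
unknown (diagonal of the pseudo-inverse Fisher matrix) and the numerator is
the minimum variance when $p_k$ is the *only* unknown, referred to a single
echo ($N/I_{kk}$ for $N$ echoes). Perfectly complementary echoes give
$\mathrm{NSA}^* = N$: the estimate is as precise as averaging $N$ images.
An echo spacing that repeats the fat–water phase relation at every echo
(one full beat period, $\approx 1.02$ ms at 7 T for $-3.3$ ppm) makes the
separation impossible — the bound diverges and $\mathrm{NSA}^* = 0$.
Treating $R_2^*$ as unknown can only remove information about the other
parameters, so the attainable maximum drops below $N$; both unknown sets
are supported (`include_r2s`).

`nsa_grid_scan()` evaluates the maps over $TE_1, \Delta TE \in [0.5, 5]$ ms
in 0.05 ms steps (91 × 91 combinations) at $R_2^* = 50$ Hz across PDFF
values, the setting under which the shipped protocol presets were chosen:
at 7 T, $TE_1 = 1.9$ ms with $\Delta TE = 2.3$ ms (high NSA*) vs 2.0 ms
(low NSA*), and a 2.2 ms shifted variant; at 3 T, $TE_1 = 2.2$ ms with
$\Delta TE = 3.2$ vs 2.24 ms. The Nyquist spacing for the fat–water beat
($1/(2|f_{fat}|)$, `nyquist_dte()`) is $\approx 1.2$ ms at 3 T and 0.5 ms
at 7 T — both presets undersample the oscillation, which is exactly why
field-map errors and swaps need active mitigation at 7 T.

Degenerate Fisher matrices (PDFF exactly 0 or 1 make one phase
unidentifiable) are pseudo-inverted with a relative eigenvalue cutoff of
$10^{-10}$; a parameter supported by a discarded eigendirection reports
$\mathrm{NSA}^* = 0$. Fisher information uses the total complex noise SD
(`noise_sd`; each real/imaginary channel carries half the variance).
Package-wide, SNR means signal magnitude over total complex noise SD —
`snr_noise_sd(50)` gives the per-channel SD to feed the simulator.

The CRLB itself is validated by simulation: `crlb_mc_check()` refits
thousands of noise realizations with grid-initialized local least squares
(`ml_fit_voxel()`, Levenberg–Marquardt on the stacked real/imaginary
residuals) and compares empirical variances with the bound. At
well-conditioned (high-NSA*) points the ratios sit at 1 within Monte-Carlo
error; at low-NSA* points the estimator becomes multimodal and exceeds the
bound by large factors — the inefficiency NSA* is designed to flag. The
local fit restricts the off-resonance search to one basin ($\pm 45\%$ of
the beat frequency around the truth) because the swap ambiguity makes the
*global* likelihood bimodal.

## Fat–water separation

For fixed $(\Delta f, R_2^*)$ the water and fat amplitudes enter linearly,
so a two-column complex least squares (VARPRO) gives them in closed form and
leaves a projection residual; `residual_lattice()` minimizes that residual
over an $R_2^*$ grid (101 values, 0–400 Hz) for every off-resonance
candidate (401 values, $-300$ to $300$ Hz) and every voxel. The residual
along $\Delta f$ is exactly periodic with $1/\Delta TE$ for equidistant
echoes, and the swapped interpretation (amplitudes exchanged, field shifted
by the fat offset, spectrum mirrored) reproduces single-peak data exactly —
the two faces of the swap ambiguity.

The field map is the minimizer of

$$ E(\psi) = \sum_v D_v(\psi_v) + \lambda \sum_{(v,w)} |\psi_v - \psi_w|, $$

with squared VARPRO residuals as the unary term and a total-variation
smoothness prior over the 4-neighborhood. `fieldmap_graphcut()` iterates
binary *jump moves* — every voxel simultaneously chooses between keeping
its label or shifting by a common offset — each solved exactly by one
min-cut (the convex pairwise cost makes every such move submodular). The
schedule cycles ±{1, 2, 5, 10} grid steps plus frequency-domain jumps: the
beat period, the alias period $1/\Delta TE$, and the swap displacement
folded into the alias period (beat mod $1/\Delta TE$ and its complement).
The folded jumps matter: the swapped branch of the residual reappears
displaced by, e.g., 109 Hz at 3 T — none of the small steps can hop between
branches, and without these moves regularization cannot clean coherent
swap patches. Fifty iterations are the default; the energy is
non-increasing by construction and iteration stops early once a full cycle
yields no improvement.

Two numerical choices deserve justification:

* **Smoothness weight.** $\lambda$ defaults to $0.02\times$ the mean
  second difference of the unary cost at the per-voxel minimum, per Hz.
  The factor is calibrated so the prior keeps neighbors on the same
  residual branch while remaining far too weak to flatten genuine field
  excursions: an uncalibrated curvature weight visibly "swapped away"
  smooth ±250 Hz fields at 3 T during development. The weight is exposed
  (`regularization_weight`) since no single value suits all data.
* **Center bias.** A weak quadratic preference for off-resonances near the
  grid center ($10^{-2}\times$ median signal energy at the grid edge) is
  added to the unary term. The swap ambiguity produces two globally
  *equally smooth* field branches; no pairwise prior can choose between
  them, so the solver — like complex-data separation methods generally —
  assumes the true field map is centered. This is the same assumption that
  makes demodulation effective (it re-centers the field the solver sees).
  The bias is a tie-breaker of the order of the residual noise floor, not
  a constraint on genuine off-center fields.

For small instances `fieldmap_exact()` minimizes the identical energy
globally with a single min-cut over a layered (Ishikawa-style) graph —
exact for convex pairwise costs and any unary term. It is the reference
the iterated solver is tested against; the layered construction itself is
validated against brute-force enumeration on grids small enough to
enumerate. On realistic field-map instances the jump-move solver attains
the exact optimum; on adversarial random unaries it can stop in a local
minimum, which is the known price of move-making optimization.

Background voxels (first-echo magnitude below 5% of the 99th percentile)
are masked and report zeros — the rule that also emulates masking of
low-signal cortical bone. PDFF is computed from the separated magnitudes as
$|F|/(|W|+|F|)$, confined to $[0, 1]$; the signed complex alternative
(`signed = TRUE`) is noise-bias-free at the PDFF extremes but fragile
under phase errors, which is why the magnitude form is the default.

## Phase-error mitigation

Three mechanisms are implemented and compared (`compare_protocols()`):

* **Dual-echo B0 mapping + demodulation.** A two-echo acquisition at
  in-phase echo times (2.04/4.08 ms at 7 T) gives
  $\Delta f = \arg(s_2 \bar s_1)/(2\pi \Delta TE)$ within the aliasing band
  $\pm 1/(2\Delta TE) \approx \pm 245$ Hz; no unwrapping is attempted —
  aliasing is reported, not corrected. The in-phase check uses the dominant
  fat peak only (the multi-peak phasor is never exactly real); a phasor
  angle above 0.2 rad warns. Demodulation multiplies each echo by
  $e^{-i2\pi\Delta f TE_n}$, preserving magnitudes exactly and shrinking
  the off-resonance range the separation must search.
* **TE shift.** Delaying $TE_1$ from 1.9 to 2.2 ms at unchanged spacing
  costs a little NSA* but reduces eddy-current phase errors, which decay
  with time after the excitation. The simulator models this with a
  first-echo phase amplitude scaled by $e^{-TE_1/\tau}$, $\tau = 1.5$ ms.
* **Mixed magnitude/complex refit.** `mixed_fit_refine()` refits each
  voxel using only the *magnitude* of echo 1 (one real residual) and the
  full complex data of echoes 2..N, initialized at the graph-cut solution.
  It repairs first-echo-only phase corruption but cannot remove ramps that
  persist across the echo train — the simulated all-echo ramps (decaying
  with $\tau = 3$ ms over the train) leave a readout-direction PDFF
  gradient after refitting, and the refit is a no-op on clean data.
  Non-convergent voxels fall back to their initial values and are flagged.

## What the synthetic data emulate — and what they do not

`make_vial_phantom()` builds six uniform disks (volume fat fractions 5, 10,
25, 50, 75, 100% by default) in a ring inside a water bath; the VFF is used
1:1 as PDFF ground truth, ignoring proton-density differences between oil
and gel just as the phantom-validation MAE analysis does.
`make_calf_phantom()` is a schematic transversal calf: three muscle
sectors (ANT/SOL/GM, PDFF 3%), a subcutaneous fat ring and bone marrow at
90%, and near-zero-signal cortical bone. `make_field_map()` adds a fixed
low-order polynomial plus dipole-like perturbations anchored at fat/bone
interfaces, each scaled to a requested peak amplitude (inhomogeneities grow
linearly with $B_0$, so 7 T scenarios use proportionally larger values).
Noise is i.i.d. circular complex Gaussian, identical across echoes.

Not modeled, by design: coil sensitivity profiles and multi-coil
combination, chemical-shift displacement and readout-bandwidth blurring,
k-space effects (partial Fourier, bipolar readouts), $T_1$ weighting (real
protocols suppress it with a 3° flip angle), and physiological texture.
Passing tests therefore demonstrate the estimation machinery — separation
accuracy, swap mechanisms and their mitigation, CRLB attainment — not
robustness to every scanner artifact.

## Study conditions used by the test suite

The heavy checks run at deliberately chosen, fixed problem sizes: the vial
phantom at 72 × 72 voxels and SNR 50 for recovery and protocol comparison
(every ROI within 1.5 percentage points of truth; high-NSA* echoes beat
low-NSA* echoes on MAE); the calf phantom at 48 × 48 with a 60 Hz smooth
field plus 200 Hz interface dipoles and first-echo eddy phase (1.2 rad,
0.05 rad/voxel before the $TE_1$ decay) for swap-rate comparison over ten
seeds; ramps of 0.3 rad + 0.01 rad/voxel for the mixed-fit analysis; 6000
noise draws per point for the CRLB check, keeping the Monte-Carlo error of
a variance estimate near 2%. All amplitudes stay inside both the ±300 Hz
search grid and the ±245 Hz B0-map aliasing band, so every scenario is
identifiable in principle and failures would indicate algorithmic defects,
not impossible inputs.

## Known limitations

* The jump-move solver is exact on field-map-like instances but carries no
  global guarantee for arbitrary unaries; `fieldmap_exact()` exists for
  small instances, not full images (its graph has voxels × labels nodes).
* The center-bias assumption misassigns data whose true field is globally
  closer to a swapped branch than to zero — the same failure mode real
  separation algorithms share, and the reason demodulation helps.
* $R_2^*$ is searched per voxel conditional on the field (not spatially
  regularized), and its grid (4 Hz steps) quantizes the map the mixed fit
  inherits as initialization.
* ROI means of the magnitude PDFF inherit its noise bias (positive at low,
  negative at high PDFF, visible as ~1 pp at SNR 50 and PDFF ≤ 5%); the
  signed estimator removes the bias at the cost of phase-error fragility.
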