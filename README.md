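# pdffmap

Proton density fat fraction (PDFF) mapping from multi-echo gradient-echo
MRI, with the acquisition-parameter optimization and post-processing needed
to make it work at high field (3 T and 7 T).

Fatty replacement of skeletal muscle — in neuromuscular disease,
sarcopenia, and aging — is quantified non-invasively by the PDFF: the
fraction of ¹H MR signal originating from fat,
`PDFF = |F| / (|W| + |F|)`, obtained by chemical-shift-encoded fat–water
separation of a six-echo spoiled GRE acquisition. At 7 T the fat–water
beat is faster than vendor sequences can sample and B0 inhomogeneities
double relative to 3 T, so naive echo-time choices produce noisy, biased
maps and fat–water swaps. This package implements the full workflow for
researchers setting up such protocols:

* **Signal model** — multi-peak fat spectra (9-peak peanut-oil phantom and
  8-peak subcutaneous tissue models built in), six-parameter complex voxel
  model, per-field ppm→Hz conversion.
* **Protocol optimization** — Cramér–Rao lower bounds and the effective
  number of signal averages NSA\*(p) = σ²(p)/σ²(p̂) over a TE₁ × ΔTE grid;
  Monte-Carlo validation of the bound.
* **Fat–water separation** — VARPRO residual lattice over off-resonance
  (401 values, ±300 Hz) and R2\* (101 values, 0–400 Hz), graph-cut
  field-map estimation with a total-variation prior solved by iterated
  binary min-cut moves (plus an exact layered-graph reference solver for
  small instances).
* **Phase-error mitigation** — dual-echo B0 mapping, phase demodulation,
  shifted-TE protocols, and a mixed magnitude/complex refit that discards
  the eddy-current-corrupted first-echo phase.
* **Digital phantoms** — vial fat-fraction phantom and calf-like phantom
  with B0 inhomogeneity and eddy-current phase models, for end-to-end
  validation with known ground truth.
* **Quantification** — PDFF maps, ROI statistics, MAE / R² / Spearman
  agreement metrics, and seeded, reproducible experiment orchestration.

## Worked example

Simulate the vial phantom at SNR 50 under the 7 T high-NSA\* protocol,
separate, and compare measured PDFF with the known volume fat fractions:

```r
library(pdffmap)

fm  <- fat_model("phantom")              # 9-peak peanut-oil spectrum
ph  <- make_vial_phantom(grid_size = 72) # VFFs 5..100% in a water bath
ser <- simulate_acquisition(ph, fm, protocol_preset("7T-highNSA"),
                            noise_sd = snr_noise_sd(50), seed = 11)
res <- separate(ser, fws_config(fat_model = fm))
pd  <- pdff_map(res$fat_mag, res$water_mag)$pdff
st  <- roi_stats(pd, phantom_rois(ph, paste0("vial", 1:6)))
cbind(st, truth = c(5, 10, 25, 50, 75, 100) / 100)
#>    name       mean          sd n_voxels truth
#> 1 vial1 0.05015207 0.012876101      160  0.05
#> 2 vial2 0.10185448 0.012615425      163  0.10
#> 3 vial3 0.24967832 0.011570152      163  0.25
#> 4 vial4 0.49984640 0.008512647      160  0.50
#> 5 vial5 0.75010282 0.007442292      163  0.75
#> 6 vial6 0.98968904 0.005159787      163  1.00

mae(c(5, 10, 25, 50, 75, 100) / 100, st$mean)   # mean absolute error
#> [1] 0.2149269
```

Every vial mean lands within ~1 percentage point of its truth; the 100%
vial sits slightly low — the noise bias of the magnitude PDFF definition
at the extremes. Rerunning with `protocol_preset("7T-lowNSA")` (echo
spacing 2.0 ms instead of 2.3 ms) roughly triples the MAE: the NSA\* maps
from `nsa_grid_scan()` predict exactly this ordering, which is how the
preset echo times were chosen.

`run_experiment()` wraps the same pipeline (phantom → simulate →
correction → separate → quantify) behind a seeded configuration with
provenance, and `compare_protocols()` scores fat–water swap rates for the
correction strategies (`none`, `demodulation`, `te-shift`, `both`).

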