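# stableVDI

Extended-Nyquist vector Doppler imaging in R: staggered dual-PRF
dealiasing combined with double-angle transmission, plus a rotating-disk
phantom simulator to exercise the whole chain on synthetic slow-time data.

## The problem

Multi-angle plane-wave vector Doppler imaging (VDI) measures blood
velocity in both the axial and lateral directions by combining Doppler
estimates from several transmit/receive steering-angle pairs. Its
unambiguous range is the Nyquist velocity limit

    VN = PRF_eff * λ / 4,   λ = c / f0,

which collapses at the high transmit frequencies needed for small-animal
cardiac imaging (≥ 30 MHz) and shrinks further by the number of transmit
angles M in a sequential multi-angle sequence (PRF_eff = PRF/M). A
31.25 MHz, 3-angle, 30 kHz design has a limit of about 12 cm/s — far
below murine intracardiac velocities of 60–100 cm/s.

This package implements a transmit-scheme solution whose gain is
multiplicative:

* **double transmission** — each angle fired twice back-to-back, so
  lag-one autocorrelation spans one pulse interval (factor M), using the
  pair-wise estimator `R(1) = 1/(P/2-1) Σ x*(2i) x(2i+1)`;
* **staggered dual PRF** — the center angle's pair fired at
  `PRF2 = (p/q) PRF1` (p, q coprime, p < q). At matched net steering
  angles θ+φ, the common aliasing coefficient
  `ncoeff = round(q (U2 − U1) / (2 VN1))` identifies the per-pixel
  aliasing orders through an enumerated lookup table, extending the
  unambiguous range to `p · VN1` (factor p).

Dealiased per-pair maps feed the usual least-squares solve
`A (vz, vx)ᵀ = 2u` with rows `(cosθ+cosφ, sinθ+sinφ)`. The package
covers scheme geometry (limits, effective PRFs, net-angle matching),
Doppler estimation with a polyphase wall filter, dealiasing, the vector
solve, a rigid rotating-disk simulator with analytic reference fields,
RMSE/NRMSE evaluation, and a small CLI (`inst/cli/stablevdi.R`).

## Worked example

Simulate the standard validation disk — 3.5 mm radius, spinning so its
edge moves at 95% of the extended limit (i.e. well beyond the per-pair
Nyquist limits), 40 dB SNR — and run the full pipeline:

```r
library(stableVDI)

cfg <- scheme_config(f0 = 31.25e6, prf1 = 6e3, p = 2, q = 3,
                     tx_angles = c(-7.5, 0, 7.5), rx_angles = c(-7.5, 0, 7.5))
limit_summary(cfg)
#>                       quantity value_m_s value_cm_s
#> 1          sequential (PRF1/M)   0.02464      2.464
#> 2       double transmit (PRF1)   0.07392      7.392
#> 3       double transmit (PRF2)   0.04928      4.928
#> 4 staggered extended (p * VN1)   0.14784     14.784

phantom <- disk_phantom()   # 3.5 mm disk, 40 x 40 grid
sim <- simulation_config(cfg, snr_db = 40, n_frames = 16L, seed = 11L,
                         edge_speed_fraction = 0.95)
run <- simulate_disk(sim, phantom)
res <- run_pipeline(run)
round(evaluate_pipeline(res, phantom, run$profile), 5)
#>      time rmse_vz rmse_vx rmse_mag nrmse_vz nrmse_vx nrmse_mag
#> 1 0.00858   2e-05 0.00018  0.00013    6e-05  0.00064   0.00093
```

Reading the output: the disk's edge speed (14 cm/s) is nearly twice the
double-transmit limit and almost six times the sequential limit, yet the
recovered field matches the analytic rigid-rotation reference with
axial/lateral NRMSE of 0.006%/0.064% — the dealiasing stage has resolved
every wrap. RMSE values are in m/s; NRMSE is normalized by the reference
range of each component. Running the same disk through the `"double"` or
`"sequential"` scheme kinds (same `scheme_config` call with
`scheme_kind =`) leaves the aliasing unresolved and the NRMSE above 10%.

Other entry points: `scheme_pairing(cfg)` prints the matched net-angle
table for the three-angle design; `build_lookup_table(2, 3)` shows the
aliasing-order table; `varying_profile()` builds the accelerating-disk
motion profile; `wall_filter()` applies the polyphase clutter filter.
The methods vignette (`vignettes/stable-vdi-methods.Rmd`) documents the
models, parameter choices and the simulator's limitations.

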