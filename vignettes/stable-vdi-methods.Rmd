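---
title: "Extended-Nyquist vector Doppler: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-Nyquist vector Doppler: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-angle plane-wave vector Doppler imaging (VDI) reconstructs the axial
and lateral components of blood velocity from Doppler projections measured
at several transmit/receive steering-angle pairs. Its Achilles heel is
aliasing: the unambiguous velocity range of pulsed Doppler is the Nyquist
limit

$$V_N = \frac{\mathrm{PRF}_{\mathrm{eff}}\,\lambda}{4},
\qquad \lambda = c/f_0,$$

and *both* high transmit frequencies (small-animal imaging at 30 MHz and
above) and multi-angle sequential transmission (which divides the effective
PRF by the number of angles $M$) shrink it. For a 31.25 MHz array with
three angles at a 30 kHz absolute PRF the limit is about 12 cm/s, while
murine intracardiac velocities reach 60–100 cm/s.

`stableVDI` implements a transmit-scheme remedy with two multiplicative
ingredients:

1. **Double transmission** — each steering angle is fired twice in
   immediate succession, so lag-one autocorrelation spans a single pulse
   interval and the per-angle effective PRF is the full absolute PRF
   (a factor $M$ on the limit).
2. **Staggered dual-PRF dealiasing** — the center angle's pulse pair runs
   at a second PRF, $\mathrm{PRF}_2 = (p/q)\,\mathrm{PRF}_1$ with $p < q$
   coprime. Comparing the wrapped velocities measured at the two PRFs
   identifies the aliasing order and extends the unambiguous range to
   $p\,V_{N1}$ (a further factor $p$).

Together the unambiguous range is $M\,p$ times the sequential-scheme limit
— 6-fold to 12-fold for $M = 3$ and $p = 2 \dots 4$.

## The estimation chain

**Lag-one autocorrelation.** For a uniformly sampled slow-time window
$x(0),\dots,x(P-1)$ the classic estimator is
$R(1) = \frac{1}{P-1}\sum_{i=0}^{P-2} x^*(i)\,x(i+1)$, and the wrapped
velocity is $U = \frac{\mathrm{PRF}_{\mathrm{eff}}\,c}{4\pi f_0}\arg R(1)$.
Under double transmission only intra-pair lags are uniformly spaced, so
the sum runs over transmit pairs:
$R(1) = \frac{1}{P/2-1}\sum_{i=0}^{P/2-2} x^*(2i)\,x(2i+1)$. We implement
this pair sum literally (the last pair of the window is not consumed by
the sum); inter-pair timing never enters, which is precisely what lets the
center pair run at a different PRF. The principal argument lies in
$(-\pi, \pi]$; we map $+\pi$ onto the negative velocity edge so every map
satisfies $U \in [-V_N, V_N)$ — this makes the wrap behaviour
single-valued at the boundary.

**Wrapping law and the aliasing order.** A true velocity $v$ appears as
$U = v - 2 n_N V_N$ with the integer Nyquist number
$n_N = \lfloor (v + V_N) / (2 V_N) \rfloor$. A floating-point guard
re-folds results that land exactly on the band edge, keeping the half-open
interval contract total.

**Dealiasing.** With wrapped velocities $U_1, U_2$ at the two PRFs and
matched projection geometry, the common aliasing coefficient is
$n_{\mathrm{coeff}} = \mathrm{round}\!\left(q\,(U_2 - U_1)/(2 V_{N1})\right)$,
rounded half away from zero (ties occur only on cell boundaries, a set of
measure zero). In the noiseless case
$n_{\mathrm{coeff}} = q\,n_{N1} - p\,n_{N2}$, and over the extended range
$[-p V_{N1}, p V_{N1})$ the map from coefficient to the pair
$(n_{N1}, n_{N2})$ is one-to-one for coprime $p/q$. We *enumerate* this
lookup table rather than transcribe it: a dense midpoint-offset sweep of
true velocities is wrapped at both PRFs and the mapping recorded, with
bijectivity asserted at construction time. An ambiguous table is a design
error and fails loudly.

**Per-map unfolding versus the weighted mean.** Once $(n_{N1}, n_{N2})$
are known there are two ways to produce unambiguous velocities. The
weighted mean
$\sum_i (q_i/p_i)(U_i + 2 n_{Ni} V_{Ni}) / \sum_i (q_i/p_i)$ (with
$p_1/q_1 = 1$) blends both streams into one estimate and is exposed as
`dealias_pair()`. For map-level processing, however, the two streams of a
matched pair have *slightly* different steering geometry (e.g. net
$-15^\circ$ is reached as $-7.5^\circ{-}7.5^\circ$ at PRF1 but
$0^\circ{-}15^\circ$ at PRF2, whose row vectors differ in the second
decimal), so blending them would mix two projections into one map and
leave a small systematic residual. `dealias_maps()` therefore unfolds
each map with its own measured velocity, $U + 2 n_N V_N$, which is exact
in the noiseless limit; the coefficient/lookup step alone is shared. Both
paths are tested against independent oracles.

**Matched net angles.** The coefficient comparison is only meaningful if
both streams observe (nearly) the same projection, i.e. the same net
steering angle $\theta + \phi$. The matcher searches the center-transmit
receive set for an angle with $\theta_c + \phi_k = \theta_m + \phi_n$ and
fails naming the unmatched net angle; for the default three-angle design
this requires the two extra receive angles $\mp 15^\circ$ at the center
transmit, and the resulting six-row pairing is frozen as a regression
fixture. The rounding margin of the coefficient is $V_{N1}/(2q)$ per
stream: the projection mismatch between matched-but-not-identical
geometries consumes part of it, and the margin shrinks as $q$ grows —
the mechanism behind the degradation at large $p$. A property test sweeps
worst-case perturbations just inside the margin and asserts the inferred
orders never change.

**Least-squares vector solve.** Each pair contributes a row
$(\cos\theta + \cos\phi,\; \sin\theta + \sin\phi)$ to the system
$A\,(v_z, v_x)^T = 2u$. We solve by QR factorization — the contract (the
least-squares minimizer) is identical to the normal-equations
pseudoinverse but better conditioned. Rows masked per pixel are dropped;
pixels with fewer than two usable rows, or rank-collapsed geometry, are
masked rather than extrapolated. In the stable scheme the solve uses all
six dealiased outer-transmit maps plus the dealiased center-transmit maps,
one row per pairing row (so a center map matched twice enters twice,
which is simply a least-squares weighting); the row set is configurable
(`center_rows`) because reasonable designs differ on whether the
$\pm 15^\circ$ center rows should feed the solve or only the dealiasing.
With the shallow default geometry the pseudoinverse row norms make the
lateral component's noise amplification roughly an order of magnitude
larger than the axial one, which is why lateral errors dominate
everywhere in the package's evaluations.

## Wall filter

Clutter filtering is exposed as a zero-phase high-pass with a fractional
cutoff (default 0.05, i.e. 5% of the substream Nyquist frequency),
applied independently to the even- and odd-index polyphase subsequences —
each subsequence is uniformly sampled even though the interleaved
double-transmit stream is not. The realization removes the
discrete-frequency components below the cutoff by orthogonal projection.
We chose projection over a forward–backward recursive filter deliberately:
at Doppler ensemble lengths (16–64 frames) a recursive high-pass with a
0.05 normalized cutoff is dominated by its edge transients (a DC input
leaks at close to half its amplitude through a 32-frame forward–backward
Butterworth), whereas the projection is exactly zero-phase, attenuates DC
to zero, and preserves passband tones. The cutoff is interpreted relative
to the *substream* rate; this is a genuine ambiguity in how "fractional
bandwidth" can be read, so the number is an explicit argument rather than
a constant.

## The disk simulator

The generator emulates the standard validation object of vector-flow
methods: a rigid disk of radius 3.5 mm rotating about its center, sampled
on a pixel grid under the scheme's exact pulse timing. Inside the disk
the ideal field is $v_z = s\,\omega(t)\,(x - x_0)$,
$v_x = -s\,\omega(t)\,(z - z_0)$; the speed is radially linear with edge
speed $\omega R$. Two motion profiles are provided: constant $\omega$,
and a sinusoidal profile parameterized by its peak edge acceleration
(default use: 4000 cm/s²) and peak-to-minimum speed ratio (4.4), both met
exactly by construction, with the modulation period left as the free
parameter.

The forward model is phase-domain: each pixel's slow-time signal advances
in phase by $4\pi f_0 u(t)/c$ per second, where $u(t)$ is the
instantaneous Doppler projection for that Tx–Rx pair, integrated along
the exact pulse times. Aliasing therefore emerges from sampling, never
from explicit wrapping. Complex white Gaussian noise is added at a
configured per-sample SNR (40 dB for the standard protocol) relative to
the unit in-disk amplitude; outside the disk the signal is zero. Inter-pair
spacing within a frame set is fixed at $1/\mathrm{PRF}_1$ — only
intra-pair intervals enter the estimator, so this choice is benign.

**What the generator does not model, and what that implies.** There is no
scatterer-level speckle, no point-spread function, and no beamforming:
the slow-time phase is exact. Consequently (i) estimator variance at
40 dB is far below what speckle-bearing data would show, so the NRMSE
figures from the standard protocol demonstrate the *dealiasing logic* and
noise robustness of the chain, not end-to-end accuracy on real echoes;
(ii) comparisons *between* transmit schemes on aliased data should not be
over-read: the sequential scheme suffers no speckle decorrelation over
its $M\times$ longer autocorrelation lag here, which flatters it, and in
our runs the double-transmit scheme's wider wrap band actually spreads
its aliased estimates further than the sequential scheme's. The package's
property tests therefore assert what the model supports — the stable
scheme recovers the field (NRMSE well under 1%) while both aliased
baselines fail by more than an order of magnitude — and deliberately do
not rank the two failing baselines against each other; and (iii) the
matched-net-angle requirement is exercised through projection geometry
only, not through point-spread-function rotation.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `f0` | Hz | — | transmit center frequency; limits scale as $1/f_0$ |
| `c` | m/s | 1540 | explicit everywhere, never hard-coded |
| `prf1` | Hz | — | absolute PRF of the main pairs |
| `p`, `q` | — | — | coprime, $p<q$; range extension is $p$-fold |
| `tx_angles` | deg | $-7.5, 0, 7.5$ | measured from the axial axis |
| `rx_angles` | deg | $-7.5, 0, 7.5$ | outer-transmit receive set |
| `center_rx_angles` | deg | derived | adds $\mp 15^\circ$ for net matching |
| `window_length` (P) | frames | 32 | even; $P/2$ pairs per estimate |
| `fractional_cutoff` | — | 0.05 | of the substream Nyquist frequency |
| `snr_db` | dB | 40 | per-sample, complex white Gaussian |
| `edge_speed_fraction` | — | 0.95 | of the scheme's velocity limit |
| `mag_floor` | — | $10^{-3}$ | relative autocorrelation magnitude mask |

Windows slide with a hop of one frame pair by default and edges are
truncated, never padded. Pixels whose autocorrelation magnitude falls
below the floor, or whose aliasing coefficient has no lookup entry, are
masked and the mask propagates through the vector solve — no inpainting.

## Numerical choices

* `round` in the coefficient is half-away-from-zero (base R's banker's
  rounding would bias cell boundaries).
* The velocity band $[-V_N, V_N)$ is enforced both at the $\arg$
  conversion ($+\pi \to -V_N$) and in `wrap_velocity()`'s floating-point
  boundary guard.
* Lookup enumeration uses a midpoint-offset grid so no sweep point ever
  sits exactly on a wrap boundary.
* The degenerate ratio $p/q = 1/1$ is accepted and yields the single
  entry $0 \to (0,0)$ (plain double transmission).
* Determinism: all randomness lives in the simulator and is seeded once
  per synthesis; pipeline reruns on stored ensembles are bit-identical,
  and results carry a serialization-based config hash, the seed and a
  timestamp as provenance.

## Problem sizes

Package evaluations use a $40\times 40$ pixel grid over the 3.5 mm disk
(about 1100 in-disk pixels) with $P = 32$ and one window for the
constant-velocity protocol, and a $16\times 16$ to $24\times 24$ grid
with ~100 sliding windows for the varying-velocity window-length study.
These sizes keep a full three-ratio protocol under a second on one CPU
while leaving every wrap regime of the extended range populated; the
grid is a parameter, and nothing in the method depends on its density
beyond pixel statistics.

## Known limitations

* No speckle/PSF physics (see the simulator section): accuracy figures
  are for the estimation chain, not the transducer.
* Two staggered PRFs only; three-PRF designs (for $p > 5$) are out of
  scope.
* The wall filter is frequency-based; subspace (SVD) clutter filtering
  is out of scope.
* The simulator's varying-speed profile is one admissible smooth profile
  meeting the stated acceleration and ratio constraints; the constraints,
  not the waveform, are the contract.
* Spectral Doppler displays and 3-D vector estimation are not provided.
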