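#' Rotating-disk phantom geometry
#'
#' A rigid disk of given radius centered at `(x0, z0)`, sampled on a
#' rectangular pixel grid that covers it. The default grid (40 x 40 over a
#' box 2.1 radii wide) keeps desk-scale runs fast; any grid spacing can be
#' requested.
#'
#' @param radius Disk radius (m). Default 3.5 mm.
#' @param center Numeric `(x0, z0)` disk center (m).
#' @param nx,nz Number of lateral / axial pixels.
#' @param span Grid width as a multiple of the radius.
#' @param rotation_sense +1 or -1, the sense of rotation.
#' @return An object of class `disk_phantom` with coordinate vectors `x`,
#'   `z`, coordinate matrices `X`, `Z` (nz x nx), the in-disk mask
#'   `inside`, and radius matrix `R`.
#' @export
disk_phantom <- function(radius = 3.5e-3, center = c(0, 6e-3),
                         nx = 40L, nz = 40L, span = 2.1,
                         rotation_sense = 1) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (!rotation_sense %in% c(-1, 1))
    stop("`rotation_sense` must be +1 or -1", call. = FALSE)
  half <- span * radius / 2
  x <- seq(center[1] - half, center[1] + half, length.out = nx)
  z <- seq(center[2] - half, center[2] + half, length.out = nz)
  X <- matrix(rep(x, each = nz), nrow = nz)
  Z <- matrix(rep(z, times = nx), nrow = nz)
  R <- sqrt((X - center[1])^2 + (Z - center[2])^2)
  structure(list(radius = radius, center = center, x = x, z = z,
                 X = X, Z = Z, R = R, inside = R <= radius,
                 rotation_sense = rotation_sense),
            class = "disk_phantom")
}

#' @export
print.disk_phantom <- function(x, ...) {
  cat(sprintf("<disk_phantom: radius %g mm at (%g, %g) mm, %d x %d px (%d inside)>\n",
              x$radius * 1e3, x$center[1] * 1e3, x$center[2] * 1e3,
              nrow(x$X), ncol(x$X), sum(x$inside)))
  invisible(x)
}

#' Constant angular-velocity motion profile
#'
#' @param omega Angular velocity (rad/s).
#' @return An object of class `motion_profile` with `omega(t)` and its
#'   running integral `omega_int(t)` (rad).
#' @export
constant_profile <- function(omega) {
  structure(list(kind = "constant",
                 omega = function(t) rep(omega, length(t)),
                 omega_int = function(t) omega * t,
                 omega_max = omega, params = list(omega = omega)),
            class = "motion_profile")
}

#' Sinusoidally varying angular-velocity profile
#'
#' A smooth profile `omega(t) = omega0 + domega * sin(2*pi*t / period)`
#' whose edge-speed excursion satisfies two constraints: the peak
#' tangential acceleration at `edge_radius` equals `peak_accel`, and the
#' ratio of peak to minimum edge speed equals `velocity_ratio`. Both are
#' met exactly by construction; the period follows from the duration of
#' one modulation cycle.
#'
#' @param peak_accel Peak edge acceleration (cm/s^2).
#' @param velocity_ratio Peak / minimum edge speed (> 1).
#' @param edge_radius Radius at which the constraints apply (m).
#' @param duration Modulation period (s).
#' @return An object of class `motion_profile`.
#' @export
varying_profile <- function(peak_accel, velocity_ratio, edge_radius, duration) {
  if (peak_accel <= 0 || edge_radius <= 0 || duration <= 0)
    stop("`peak_accel`, `edge_radius` and `duration` must be positive",
         call. = FALSE)
  if (velocity_ratio <= 1)
    stop("`velocity_ratio` must exceed 1 (use constant_profile otherwise)",
         call. = FALSE)
  a_peak <- peak_accel / 100                     # m/s^2
  domega <- a_peak * duration / (2 * pi * edge_radius)
  omega0 <- domega * (velocity_ratio + 1) / (velocity_ratio - 1)
  w <- 2 * pi / duration
  structure(list(kind = "varying",
                 omega = function(t) omega0 + domega * sin(w * t),
                 omega_int = function(t) omega0 * t + domega / w * (1 - cos(w * t)),
                 omega_max = omega0 + domega,
                 params = list(peak_accel = peak_accel,
                               velocity_ratio = velocity_ratio,
                               edge_radius = edge_radius,
                               duration = duration,
                               omega0 = omega0, domega = domega)),
            class = "motion_profile")
}

#' Ideal rigid-rotation vector field at a time point
#'
#' Inside the disk the rigid rotation gives `vz = s*omega(t)*(x - x0)` and
#' `vx = -s*omega(t)*(z - z0)` (s the rotation sense); outside the disk
#' pixels are masked. The speed is radially linear with edge speed
#' `omega * radius`.
#'
#' @param phantom A [disk_phantom()].
#' @param profile A [constant_profile()] or [varying_profile()].
#' @param t Time (s).
#' @return A [vector_field()] on the phantom grid.
#' @export
velocity_field_at <- function(phantom, profile, t) {
  stopifnot(inherits(phantom, "disk_phantom"),
            inherits(profile, "motion_profile"))
  om <- profile$omega(t)
  s <- phantom$rotation_sense
  vz <- s * om * (phantom$X - phantom$center[1])
  vx <- -s * om * (phantom$Z - phantom$center[2])
  vz[!phantom$inside] <- NA_real_
  vx[!phantom$inside] <- NA_real_
  vector_field(vz, vx, valid = phantom$inside, x = phantom$x, z = phantom$z)
}

#' Simulation configuration
#'
#' @param scheme A [scheme_config()].
#' @param snr_db Per-sample signal-to-noise ratio (dB) of the additive
#'   complex white Gaussian noise. `Inf` disables noise.
#' @param n_frames Number of frame sets to simulate (each set fires every
#'   transmit pair once, so paired ensembles get `2 * n_frames` samples).
#' @param seed RNG seed; identical configurations reproduce bit-identical
#'   ensembles.
#' @param edge_speed_fraction Disk edge speed as a fraction of the scheme's
#'   velocity limit (extended limit for the stable scheme); used by
#'   [simulate_disk()] when constructing the default constant profile.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(scheme, snr_db = 40, n_frames = 16L,
                              seed = 1L, edge_speed_fraction = 0.95) {
  stopifnot(inherits(scheme, "scheme_config"))
  if (!(edge_speed_fraction > 0 && edge_speed_fraction <= 1))
    stop("`edge_speed_fraction` must lie in (0, 1]", call. = FALSE)
  if (n_frames < 2L)
    stop("`n_frames` must be at least 2", call. = FALSE)
  structure(list(scheme = scheme, snr_db = snr_db,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 edge_speed_fraction = edge_speed_fraction),
            class = "simulation_config")
}

# Tx-Rx pair table for a scheme: one row per ensemble to synthesize.
scheme_pairs <- function(scheme) {
  M <- length(scheme$tx_angles)
  if (scheme$scheme_kind == "stable") {
    ctr <- scheme$center_tx_index
    outer_tx <- setdiff(seq_len(M), ctr)
    rows <- rbind(
      expand.grid(rx = seq_along(scheme$rx_angles), tx = outer_tx,
                  KEEP.OUT.ATTRS = FALSE),
      expand.grid(rx = seq_along(scheme$center_rx_angles), tx = ctr,
                  KEEP.OUT.ATTRS = FALSE))
    phi <- ifelse(rows$tx == ctr, scheme$center_rx_angles[rows$rx],
                  scheme$rx_angles[rows$rx])
  } else {
    rows <- expand.grid(rx = seq_along(scheme$rx_angles), tx = seq_len(M),
                        KEEP.OUT.ATTRS = FALSE)
    phi <- scheme$rx_angles[rows$rx]
  }
  data.frame(tx = rows$tx, rx = rows$rx,
             theta = scheme$tx_angles[rows$tx], phi = phi,
             prf_eff = effective_prf(scheme, rows$tx))
}

# Pulse times for every transmit over n_frames frame sets. Paired schemes:
# within each set the pairs fire in Tx order, intra-pair spacing 1/prf for
# that Tx, inter-pair gap 1/prf1. Sequential: round-robin singles at prf1.
pulse_schedule <- function(scheme, n_frames) {
  M <- length(scheme$tx_angles)
  pri1 <- 1 / scheme$prf1
  if (scheme$scheme_kind == "sequential") {
    times <- lapply(seq_len(M), function(m)
      ((seq_len(n_frames) - 1L) * M + (m - 1L)) * pri1)
    return(times)
  }
  pris <- 1 / effective_prf(scheme, seq_len(M))
  offsets <- numeric(M)
  cursor <- 0
  for (m in seq_len(M)) {
    offsets[m] <- cursor
    cursor <- cursor + pris[m] + pri1
  }
  t_frame <- cursor
  lapply(seq_len(M), function(m) {
    starts <- (seq_len(n_frames) - 1L) * t_frame + offsets[m]
    as.vector(rbind(starts, starts + pris[m])) # interleave pair pulses
  })
}

#' Synthesize slow-time ensembles for a rotating disk
#'
#' Phase-domain forward model: for every pixel and Tx-Rx pair the complex
#' slow-time signal advances in phase by `4*pi*f0*u/c` per second, where
#' `u` is the instantaneous Doppler projection of the rigid-rotation
#' velocity onto that pair's steering geometry. Sampling follows the
#' scheme's pulse timing (intra-pair interval `1/prf1` for outer pairs,
#' `1/prf2` for the center pair of the stable scheme), so aliasing emerges
#' from the sampling itself, never from explicit wrapping. Complex white
#' Gaussian noise is added at the configured SNR relative to the unit
#' in-disk signal amplitude.
#'
#' @param phantom A [disk_phantom()].
#' @param profile A [constant_profile()] or [varying_profile()].
#' @param sim A [simulation_config()].
#' @return An object of class `disk_simulation`: `ensembles` (a list of
#'   [slow_time_ensemble()]), `pairs` (the Tx-Rx pair table), plus the
#'   `phantom`, `profile`, `scheme` and `sim` inputs for reference-field
#'   evaluation.
#' @export
synthesize_ensembles <- function(phantom, profile, sim) {
  stopifnot(inherits(phantom, "disk_phantom"),
            inherits(profile, "motion_profile"),
            inherits(sim, "simulation_config"))
  scheme <- sim$scheme
  edge_speed <- profile$omega_max * phantom$radius
  if (edge_speed > scheme$c / 10)
    stop(sprintf("edge speed %.3g m/s is unphysically large for c = %g m/s",
                 edge_speed, scheme$c), call. = FALSE)
  pairs <- scheme_pairs(scheme)
  schedule <- pulse_schedule(scheme, sim$n_frames)
  paired <- scheme$scheme_kind != "sequential"

  s <- phantom$rotation_sense
  dx <- as.vector(phantom$X - phantom$center[1])
  dz <- as.vector(phantom$Z - phantom$center[2])
  inside <- as.vector(phantom$inside)
  amp <- as.numeric(inside)
  noise_sd <- if (is.finite(sim$snr_db)) sqrt(10^(-sim$snr_db / 10) / 2) else 0

  set.seed(sim$seed)
  ensembles <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    th <- pairs$theta[k] * pi / 180
    ph <- pairs$phi[k] * pi / 180
    c1 <- cos(th) + cos(ph)
    c2 <- sin(th) + sin(ph)
    # u(t) = omega(t) * geom ; phase = (4 pi f0 / c) * geom * Omega(t)
    geom <- (s * dx * c1 - s * dz * c2) / 2
    tk <- schedule[[pairs$tx[k]]]
    phase <- (4 * pi * scheme$f0 / scheme$c) *
      outer(geom, profile$omega_int(tk))
    samp <- amp * exp(1i * phase)
    if (noise_sd > 0) {
      n <- length(samp)
      samp <- samp + complex(real = stats::rnorm(n, sd = noise_sd),
                             imaginary = stats::rnorm(n, sd = noise_sd))
    }
    ensembles[[k]] <- slow_time_ensemble(
      samp, pair_pri = 1 / pairs$prf_eff[k],
      tx_index = pairs$tx[k], rx_index = pairs$rx[k],
      pulse_times = tk, theta = pairs$theta[k], phi = pairs$phi[k],
      paired = paired)
  }
  structure(list(ensembles = ensembles, pairs = pairs, phantom = phantom,
                 profile = profile, scheme = scheme, sim = sim),
            class = "disk_simulation")
}

#' @export
print.disk_simulation <- function(x, ...) {
  cat(sprintf("<disk_simulation: %s scheme, %d ensembles, %d frame sets, SNR %g dB>\n",
              x$scheme$scheme_kind, length(x$ensembles), x$sim$n_frames,
              x$sim$snr_db))
  invisible(x)
}

#' Simulate a rotating disk under a transmit scheme
#'
#' Convenience wrapper: builds the default constant-velocity profile whose
#' edge speed is `edge_speed_fraction` of the scheme's velocity limit (the
#' extended limit for the stable scheme, the double-transmit limit for the
#' double scheme, `VN1 / M` for the sequential scheme), then calls
#' [synthesize_ensembles()].
#'
#' @param sim A [simulation_config()].
#' @param phantom A [disk_phantom()].
#' @param profile Optional [constant_profile()] / [varying_profile()];
#'   when omitted the default constant profile above is used.
#' @return A `disk_simulation` (see [synthesize_ensembles()]).
#' @export
simulate_disk <- function(sim, phantom = disk_phantom(), profile = NULL) {
  stopifnot(inherits(sim, "simulation_config"))
  if (is.null(profile)) {
    scheme <- sim$scheme
    vmax <- switch(scheme$scheme_kind,
      stable = extended_nyquist(scheme),
      double = nyquist_limit(scheme$f0, scheme$prf1, scheme$c),
      sequential = nyquist_limit(scheme$f0,
                                 scheme$prf1 / length(scheme$tx_angles),
                                 scheme$c))
    profile <- constant_profile(sim$edge_speed_fraction * vmax / phantom$radius)
  }
  synthesize_ensembles(phantom, profile, sim)
}
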