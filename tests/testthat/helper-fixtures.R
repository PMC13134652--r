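# Shared fixtures: the default 3-angle acquisition design and small disk runs.

default_stable_scheme <- function(prf1 = 6e3, p = 2, q = 3, P = 32L,
                                  f0 = 31.25e6) {
  scheme_config(f0 = f0, prf1 = prf1, p = p, q = q,
                tx_angles = c(-7.5, 0, 7.5), rx_angles = c(-7.5, 0, 7.5),
                window_length = P)
}

# Simulate the standard constant-velocity disk (edge at `fraction` of the
# extended limit) and run the full pipeline once.
run_standard_disk <- function(p, q, snr_db = 40, seed = 11L, n = 40L,
                              prf1 = 6e3, P = 32L, fraction = 0.95) {
  cfg <- default_stable_scheme(prf1 = prf1, p = p, q = q, P = P)
  ph <- disk_phantom(nx = n, nz = n)
  sim <- simulation_config(cfg, snr_db = snr_db, n_frames = P %/% 2L,
                           seed = seed, edge_speed_fraction = fraction)
  ds <- simulate_disk(sim, ph)
  res <- run_pipeline(ds)
  ref <- velocity_field_at(ph, ds$profile, res$windows[[1]]$time)
  list(cfg = cfg, ph = ph, ds = ds, res = res, ref = ref,
       field = res$windows[[1]]$field)
}

# Single-tone paired ensemble: constant intra-pair phase step `phase_step`,
# arbitrary inter-pair phase offsets.
paired_tone <- function(phase_step, n_pairs, inter_pair_phase = 0) {
  if (length(inter_pair_phase) == 1L)
    inter_pair_phase <- rep(inter_pair_phase, n_pairs)
  first <- exp(1i * inter_pair_phase)
  second <- first * exp(1i * phase_step)
  matrix(as.vector(rbind(first, second)), nrow = 1L)
}
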