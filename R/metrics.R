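#' Root-mean-square error between two fields
#'
#' `sqrt(mean((y - yhat)^2))` over pixels that are finite in both the
#' estimate and the reference.
#'
#' @param estimate,reference Numeric vectors or matrices of equal shape.
#' @return RMSE in the fields' units.
#' @export
rmse <- function(estimate, reference) {
  if (length(estimate) != length(reference))
    stop("`estimate` and `reference` shapes differ", call. = FALSE)
  ok <- is.finite(estimate) & is.finite(reference)
  if (!any(ok))
    stop("no valid pixels shared by estimate and reference", call. = FALSE)
  sqrt(mean((estimate[ok] - reference[ok])^2))
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the reference field's range (`max - min` over its valid
#' pixels), the standard normalization for flow-phantom evaluation.
#'
#' @inheritParams rmse
#' @return Dimensionless NRMSE; `NA` (with a warning) when the reference
#'   range is zero.
#' @export
nrmse <- function(estimate, reference) {
  rng <- suppressWarnings(diff(range(reference[is.finite(reference)])))
  if (!is.finite(rng) || rng == 0) {
    warning("reference range is zero: NRMSE undefined", call. = FALSE)
    return(NA_real_)
  }
  rmse(estimate, reference) / rng
}

field_magnitude <- function(field) sqrt(field$vz^2 + field$vx^2)

#' Component-wise error metrics of a vector field
#'
#' RMSE and NRMSE of the axial and lateral components and of the velocity
#' magnitude, against a reference field on the same grid. NRMSE for each
#' quantity is normalized by that quantity's reference range.
#'
#' @param field Estimated [vector_field()].
#' @param reference Reference [vector_field()] (e.g. [velocity_field_at()]).
#' @return One-row data frame: `rmse_vz`, `rmse_vx`, `rmse_mag` (m/s) and
#'   `nrmse_vz`, `nrmse_vx`, `nrmse_mag` (dimensionless).
#' @export
evaluate_field <- function(field, reference) {
  stopifnot(inherits(field, "vector_field"),
            inherits(reference, "vector_field"))
  data.frame(
    rmse_vz = rmse(field$vz, reference$vz),
    rmse_vx = rmse(field$vx, reference$vx),
    rmse_mag = rmse(field_magnitude(field), field_magnitude(reference)),
    nrmse_vz = nrmse(field$vz, reference$vz),
    nrmse_vx = nrmse(field$vx, reference$vx),
    nrmse_mag = nrmse(field_magnitude(field), field_magnitude(reference)))
}

#' Velocity-magnitude NRMSE within a radial region
#'
#' RMSE of the speed over pixels with radius below `r_max`, normalized by
#' the reference speed range over the whole disk (so radially restricted
#' values remain comparable across regions).
#'
#' @param field Estimated [vector_field()].
#' @param reference Reference [vector_field()].
#' @param phantom The [disk_phantom()] defining pixel radii.
#' @param r_max Maximum radius (m); default the full disk.
#' @return Dimensionless NRMSE.
#' @export
nrmse_magnitude <- function(field, reference, phantom, r_max = Inf) {
  stopifnot(inherits(phantom, "disk_phantom"))
  m_est <- field_magnitude(field)
  m_ref <- field_magnitude(reference)
  rng <- diff(range(m_ref[is.finite(m_ref)]))
  sel <- phantom$R <= r_max
  m_est[!sel] <- NA_real_
  rmse(m_est, m_ref) / rng
}

#' Radial NRMSE profile of the velocity magnitude
#'
#' Velocity-magnitude NRMSE within concentric annuli of the disk,
#' normalized by the reference speed range over the whole disk. Empty
#' annuli yield `NA` (a gap in the curve).
#'
#' @param field Estimated [vector_field()].
#' @param reference Reference [vector_field()].
#' @param phantom The [disk_phantom()].
#' @param n_bins Number of equal-width annuli between 0 and the radius.
#' @return Data frame with `r_inner`, `r_outer`, `r_mid` (m), `nrmse`,
#'   `n_pixels`.
#' @export
radial_nrmse_profile <- function(field, reference, phantom, n_bins = 8L) {
  stopifnot(inherits(phantom, "disk_phantom"))
  m_est <- field_magnitude(field)
  m_ref <- field_magnitude(reference)
  rng <- diff(range(m_ref[is.finite(m_ref)]))
  edges <- seq(0, phantom$radius, length.out = n_bins + 1L)
  out <- data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1L])
  out$r_mid <- (out$r_inner + out$r_outer) / 2
  out$nrmse <- NA_real_
  out$n_pixels <- 0L
  for (b in seq_len(n_bins)) {
    sel <- phantom$R > out$r_inner[b] & phantom$R <= out$r_outer[b] &
      is.finite(m_est) & is.finite(m_ref)
    out$n_pixels[b] <- sum(sel)
    if (any(sel))
      out$nrmse[b] <- sqrt(mean((m_est[sel] - m_ref[sel])^2)) / rng
  }
  out
}

#' Evaluate every pipeline window against the ideal disk field
#'
#' Compares each window's vector field with the analytic rigid-rotation
#' reference taken at the window's center time.
#'
#' @param result A [run_pipeline()] result.
#' @param phantom The [disk_phantom()] that generated the data.
#' @param profile The [constant_profile()] / [varying_profile()] used.
#' @return Data frame, one row per window: `time` plus the
#'   [evaluate_field()] columns.
#' @export
evaluate_pipeline <- function(result, phantom, profile) {
  stopifnot(inherits(result, "pipeline_result"))
  rows <- lapply(result$windows, function(w) {
    ref <- velocity_field_at(phantom, profile, w$time)
    cbind(data.frame(time = w$time), evaluate_field(w$field, ref))
  })
  do.call(rbind, rows)
}

#' Write a per-window metrics summary as CSV
#'
#' @param metrics Data frame from [evaluate_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Save / load an ensemble set
#'
#' Serializes a `disk_simulation` (or any ensemble list) to a single
#' portable RDS container, preserving complex samples, pulse times and
#' pair metadata exactly.
#'
#' @param x Object to save.
#' @param path File path.
#' @return `write_ensembles()` returns `path` invisibly;
#'   `read_ensembles()` returns the stored object.
#' @export
write_ensembles <- function(x, path) {
  saveRDS(x, path, version = 2)
  invisible(path)
}

#' @rdname write_ensembles
#' @export
read_ensembles <- function(path) readRDS(path)

#' Nyquist-limit summary of a scheme configuration
#'
#' The velocity limits a design implies: the per-angle sequential limit,
#' the double-transmit limit, and (stable scheme) the staggered-PRF
#' extended limit with its extension factor over the sequential scheme.
#'
#' @param config A [scheme_config()].
#' @return Data frame with `quantity`, `value_m_s`, `value_cm_s`.
#' @export
limit_summary <- function(config) {
  stopifnot(inherits(config, "scheme_config"))
  M <- length(config$tx_angles)
  vals <- c(
    "sequential (PRF1/M)" = nyquist_limit(config$f0, config$prf1 / M, config$c),
    "double transmit (PRF1)" = nyquist_limit(config$f0, config$prf1, config$c))
  if (config$scheme_kind == "stable") {
    vals <- c(vals,
      "double transmit (PRF2)" = nyquist_limit(config$f0, config$prf2, config$c),
      "staggered extended (p * VN1)" = extended_nyquist(config))
  }
  data.frame(quantity = names(vals), value_m_s = unname(vals),
             value_cm_s = unname(vals) * 100, row.names = NULL)
}
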