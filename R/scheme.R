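#' Transmit scheme configuration
#'
#' Bundles the transducer and transmission parameters that define one
#' plane-wave acquisition design: transmit center frequency, speed of sound,
#' the absolute PRFs of the main and staggered pulse streams, the rational
#' PRF ratio p/q, and the transmit/receive steering-angle sets.
#'
#' Three scheme kinds are supported:
#' \describe{
#'   \item{`"sequential"`}{the M transmit angles are fired in a round-robin
#'     cycle, so the effective PRF per angle is `prf1 / M`.}
#'   \item{`"double"`}{each angle is fired twice in immediate succession, so
#'     lag-one autocorrelation spans a single pulse interval and the
#'     effective PRF per angle is `prf1`.}
#'   \item{`"stable"`}{double transmission with the center angle's pulse
#'     pair fired at the staggered rate `prf2 = (p/q) * prf1`, enabling
#'     staggered-PRF dealiasing at matched net steering angles.}
#' }
#'
#' @param f0 Transmit center frequency (Hz).
#' @param prf1 Absolute PRF of the main pulse pairs (Hz).
#' @param tx_angles Ordered transmit steering angles (degrees from the axial
#'   axis, positive toward positive lateral x).
#' @param rx_angles Receive steering angles used with the outer (PRF1)
#'   transmits (degrees).
#' @param c Speed of sound (m/s). Default 1540, soft tissue.
#' @param p,q Coprime positive integers with `p < q` defining the staggered
#'   PRF ratio `prf2 = (p/q) * prf1` (required for `"stable"`).
#' @param prf2 Absolute PRF of the staggered pairs (Hz). Computed from
#'   `p/q` when omitted; if given it must equal `(p/q) * prf1`.
#' @param center_tx_index Index into `tx_angles` of the transmit fired at
#'   PRF2 in the `"stable"` scheme. Defaults to the 0-degree transmit if
#'   present, else the middle one.
#' @param center_rx_angles Receive angles beamformed for the center (PRF2)
#'   transmit. Defaults to `rx_angles` followed by whatever extra angles are
#'   required so that every outer net angle `theta + phi` can be matched at
#'   the center transmit (with the default 3-angle set this appends -15 and
#'   15 degrees).
#' @param window_length Ensemble window length P in slow-time frames.
#' @param scheme_kind One of `"sequential"`, `"double"`, `"stable"`.
#'
#' @return An object of class `scheme_config`.
#' @examples
#' cfg <- scheme_config(f0 = 31.25e6, prf1 = 25e3, p = 2, q = 3,
#'                      tx_angles = c(-7.5, 0, 7.5),
#'                      rx_angles = c(-7.5, 0, 7.5))
#' extended_nyquist(cfg)  # 0.616 m/s
#' @export
scheme_config <- function(f0, prf1, tx_angles, rx_angles,
                          c = 1540, p = NULL, q = NULL, prf2 = NULL,
                          center_tx_index = NULL, center_rx_angles = NULL,
                          window_length = 32,
                          scheme_kind = c("stable", "double", "sequential")) {
  scheme_kind <- match.arg(scheme_kind)
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0)
    stop("`f0` must be a positive scalar (Hz)", call. = FALSE)
  if (!is.numeric(prf1) || length(prf1) != 1L || prf1 <= 0)
    stop("`prf1` must be a positive scalar (Hz)", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("`c` must be a positive scalar (m/s)", call. = FALSE)
  if (length(tx_angles) < 1L)
    stop("at least one transmit angle is required", call. = FALSE)

  if (scheme_kind == "stable") {
    if (is.null(p) || is.null(q))
      stop("`p` and `q` are required for the stable scheme", call. = FALSE)
    check_pq(p, q)
    if (is.null(prf2)) {
      prf2 <- prf1 * p / q
    } else if (abs(prf2 - prf1 * p / q) > 1e-6 * prf1) {
      stop(sprintf("`prf2` (%g Hz) does not equal (p/q) * prf1 = %g Hz",
                   prf2, prf1 * p / q), call. = FALSE)
    }
    if (length(tx_angles) < 2L)
      stop("the stable scheme needs at least 2 transmit angles", call. = FALSE)
    if (is.null(center_tx_index)) {
      hit <- which(abs(tx_angles) < 1e-12)
      center_tx_index <- if (length(hit)) hit[1L] else (length(tx_angles) + 1L) %/% 2L
    }
    if (center_tx_index < 1L || center_tx_index > length(tx_angles))
      stop("`center_tx_index` out of range", call. = FALSE)
    if (is.null(center_rx_angles)) {
      theta_c <- tx_angles[center_tx_index]
      outer <- setdiff(seq_along(tx_angles), center_tx_index)
      nets <- as.vector(outer(tx_angles[outer], rx_angles, `+`))
      need <- nets - theta_c
      extra <- sort(setdiff(round(need, 9), round(rx_angles, 9)))
      center_rx_angles <- c(rx_angles, extra)
    }
  } else {
    p <- if (is.null(p)) 1L else p
    q <- if (is.null(q)) 1L else q
    prf2 <- prf1
    center_tx_index <- NA_integer_
    center_rx_angles <- rx_angles
  }

  structure(list(
    f0 = f0, c = c, prf1 = prf1, prf2 = prf2, p = as.integer(p), q = as.integer(q),
    tx_angles = as.numeric(tx_angles), rx_angles = as.numeric(rx_angles),
    center_tx_index = center_tx_index,
    center_rx_angles = as.numeric(center_rx_angles),
    window_length = as.integer(window_length), scheme_kind = scheme_kind
  ), class = "scheme_config")
}

check_pq <- function(p, q) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x == floor(x)
  if (!ok(p) || !ok(q))
    stop("`p` and `q` must be positive integers", call. = FALSE)
  if (p == 1 && q == 1) return(invisible(TRUE))  # degenerate single-PRF case
  if (p >= q)
    stop("`p` must be smaller than `q` (PRF2 < PRF1)", call. = FALSE)
  if (gcd(p, q) != 1L)
    stop(sprintf("p/q = %d/%d is not in lowest terms", p, q), call. = FALSE)
  invisible(TRUE)
}

gcd <- function(a, b) {
  a <- abs(as.integer(a)); b <- abs(as.integer(b))
  while (b > 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.scheme_config <- function(x, ...) {
  cat(sprintf("<scheme_config: %s>\n", x$scheme_kind))
  cat(sprintf("  f0 = %g MHz, c = %g m/s\n", x$f0 / 1e6, x$c))
  cat(sprintf("  PRF1 = %g kHz", x$prf1 / 1e3))
  if (x$scheme_kind == "stable")
    cat(sprintf(", PRF2 = %g kHz (p/q = %d/%d)", x$prf2 / 1e3, x$p, x$q))
  cat("\n")
  cat(sprintf("  Tx angles: %s deg\n", paste(x$tx_angles, collapse = ", ")))
  cat(sprintf("  Rx angles: %s deg\n", paste(x$rx_angles, collapse = ", ")))
  if (x$scheme_kind == "stable")
    cat(sprintf("  center Tx: #%d (%g deg), center Rx: %s deg\n",
                x$center_tx_index, x$tx_angles[x$center_tx_index],
                paste(x$center_rx_angles, collapse = ", ")))
  cat(sprintf("  window length P = %d frames\n", x$window_length))
  invisible(x)
}

#' Nyquist velocity limit
#'
#' The maximum unambiguous Doppler velocity for pulsed-wave sampling at an
#' effective PRF: `VN = PRF_eff * lambda / 4` with `lambda = c / f0`.
#'
#' @param f0 Transmit center frequency (Hz).
#' @param prf_eff Effective PRF between successive samples of the same
#'   Tx-Rx pair (Hz).
#' @param c Speed of sound (m/s).
#' @return Velocity limit in m/s.
#' @examples
#' nyquist_limit(3e6, 5e3, 1540)       # ~0.64 m/s, typical human cardiac
#' nyquist_limit(31.25e6, 25e3, 1540)  # 0.308 m/s
#' @export
nyquist_limit <- function(f0, prf_eff, c = 1540) {
  if (any(f0 <= 0) || any(prf_eff <= 0) || any(c <= 0))
    stop("`f0`, `prf_eff` and `c` must all be positive", call. = FALSE)
  prf_eff * c / (4 * f0)
}

#' Effective PRF of one transmit angle
#'
#' The rate at which lag-one autocorrelation samples the same Tx angle:
#' `prf1 / M` for the sequential scheme, `prf1` for every angle in the
#' double scheme, and for the stable scheme `prf1` for the outer pairs but
#' `prf2` for the center pair.
#'
#' @param config A [scheme_config()].
#' @param tx_index Index into `config$tx_angles`.
#' @return Effective PRF (Hz).
#' @export
effective_prf <- function(config, tx_index) {
  stopifnot(inherits(config, "scheme_config"))
  if (any(tx_index < 1L) || any(tx_index > length(config$tx_angles)))
    stop("`tx_index` out of range", call. = FALSE)
  switch(config$scheme_kind,
    sequential = rep(config$prf1 / length(config$tx_angles), length(tx_index)),
    double = rep(config$prf1, length(tx_index)),
    stable = ifelse(tx_index == config$center_tx_index, config$prf2, config$prf1),
    stop("unknown scheme kind", call. = FALSE)
  )
}

#' Extended Nyquist limit of a staggered-PRF scheme
#'
#' Staggered dual-PRF dealiasing extends the unambiguous velocity range to
#' `p` times the PRF1 Nyquist limit (equivalently `q` times the PRF2
#' limit).
#'
#' @param config A [scheme_config()] with `scheme_kind = "stable"`.
#' @return Extended velocity limit (m/s).
#' @export
extended_nyquist <- function(config) {
  stopifnot(inherits(config, "scheme_config"))
  if (config$scheme_kind != "stable")
    stop("extended Nyquist limit is defined only for the stable scheme",
         call. = FALSE)
  config$p * nyquist_limit(config$f0, config$prf1, config$c)
}

#' Velocity-limit extension factor over the sequential scheme
#'
#' The stable scheme's extended limit relative to the sequential-angle limit
#' at the same absolute PRF: double transmission contributes a factor M
#' (the number of transmit angles) and staggered-PRF dealiasing a factor p,
#' so the total is `M * p`.
#'
#' @param config A [scheme_config()] with `scheme_kind = "stable"`.
#' @return Dimensionless extension factor.
#' @export
extension_factor <- function(config) {
  stopifnot(inherits(config, "scheme_config"))
  if (config$scheme_kind != "stable")
    stop("extension factor is defined only for the stable scheme", call. = FALSE)
  length(config$tx_angles) * config$p
}

#' Match net steering angles between the two PRF streams
#'
#' Staggered-PRF dealiasing compares wrapped velocities estimated at the two
#' PRFs, which is only valid when both estimates share the same net steering
#' angle `theta + phi` (the Doppler projection direction). This pairs every
#' outer (PRF1) Tx-Rx combination with the center-transmit (PRF2) receive
#' angle that yields an identical net angle.
#'
#' @param tx_angles Transmit steering angles (degrees).
#' @param rx_angles Receive angles used with the outer transmits (degrees).
#' @param center_tx_index Index of the center transmit (fired at PRF2).
#' @param center_rx_angles Receive angles available at the center transmit.
#'   Defaults to `rx_angles`.
#' @param tol Angle matching tolerance (degrees).
#'
#' @return A `net_angle_pairing` data frame with one row per outer Tx-Rx
#'   combination, ordered by net angle: columns `net_angle`, `tx1`, `rx1`
#'   (indices of the PRF1 pair), `tx2`, `rx2` (indices of the matched PRF2
#'   pair, `rx2` indexing `center_rx_angles`), and the angles themselves.
#' @examples
#' match_net_angles(c(-7.5, 0, 7.5), c(-7.5, 0, 7.5), 2,
#'                  c(-7.5, 0, 7.5, -15, 15))
#' @export
match_net_angles <- function(tx_angles, rx_angles, center_tx_index,
                             center_rx_angles = rx_angles, tol = 1e-9) {
  if (center_tx_index < 1L || center_tx_index > length(tx_angles))
    stop("`center_tx_index` out of range", call. = FALSE)
  theta_c <- tx_angles[center_tx_index]
  outer_tx <- setdiff(seq_along(tx_angles), center_tx_index)
  if (length(outer_tx) == 0L) {
    # single-transmit degenerate case: pair the center with itself
    outer_tx <- center_tx_index
  }
  rows <- expand.grid(rx1 = seq_along(rx_angles), tx1 = outer_tx,
                      KEEP.OUT.ATTRS = FALSE)
  net <- tx_angles[rows$tx1] + rx_angles[rows$rx1]
  rx2 <- vapply(net, function(n) {
    k <- which(abs(theta_c + center_rx_angles - n) <= tol)
    if (length(k) == 0L)
      stop(sprintf(paste0("no receive angle at the center transmit gives net ",
                          "angle %g deg (need phi = %g deg)"),
                   n, n - theta_c), call. = FALSE)
    k[1L]
  }, integer(1))
  out <- data.frame(
    net_angle = net,
    tx1 = rows$tx1, rx1 = rows$rx1,
    tx2 = rep(center_tx_index, length(net)), rx2 = rx2,
    theta1 = tx_angles[rows$tx1], phi1 = rx_angles[rows$rx1],
    theta2 = rep(theta_c, length(net)), phi2 = center_rx_angles[rx2]
  )
  out <- out[order(out$net_angle, out$tx1, out$rx1), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("net_angle_pairing", "data.frame")
  out
}

#' Net-angle pairing for a scheme configuration
#'
#' Convenience wrapper calling [match_net_angles()] with the angles stored
#' in a stable [scheme_config()].
#'
#' @param config A [scheme_config()] with `scheme_kind = "stable"`.
#' @return A `net_angle_pairing` data frame.
#' @export
scheme_pairing <- function(config) {
  stopifnot(inherits(config, "scheme_config"))
  if (config$scheme_kind != "stable")
    stop("net-angle pairing is defined only for the stable scheme", call. = FALSE)
  match_net_angles(config$tx_angles, config$rx_angles,
                   config$center_tx_index, config$center_rx_angles)
}

#' Read / write a scheme configuration
#'
#' Scheme configurations round-trip through plain-text YAML or JSON (chosen
#' by file extension); angles in degrees, frequencies in Hz.
#'
#' @param config A [scheme_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scheme_config()` returns a [scheme_config()];
#'   `write_scheme_config()` returns `path` invisibly.
#' @export
write_scheme_config <- function(config, path) {
  stopifnot(inherits(config, "scheme_config"))
  x <- unclass(config)
  x$center_tx_index <- if (is.na(x$center_tx_index)) NULL else x$center_tx_index
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_scheme_config
#' @export
read_scheme_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scheme_config(
    f0 = x$f0, prf1 = x$prf1, tx_angles = unlist(x$tx_angles),
    rx_angles = unlist(x$rx_angles), c = x$c, p = x$p, q = x$q,
    prf2 = x$prf2, center_tx_index = x$center_tx_index,
    center_rx_angles = if (is.null(x$center_rx_angles)) NULL else unlist(x$center_rx_angles),
    window_length = x$window_length, scheme_kind = x$scheme_kind
  )
}
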