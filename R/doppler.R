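#' Slow-time ensemble for one Tx-Rx pair
#'
#' The complex slow-time samples of every pixel for a single Tx-Rx steering
#' pair, together with the pulse timing metadata that governs its Nyquist
#' limit. For double-transmission schemes the frames come in consecutive
#' pairs separated by `pair_pri`; lag-one autocorrelation then spans a
#' single intra-pair interval.
#'
#' @param samples Complex matrix, pixels x frames.
#' @param pair_pri Intra-pair pulse repetition interval (s); `1 / pair_pri`
#'   is the effective PRF of this pair.
#' @param tx_index,rx_index Angle identifiers.
#' @param pulse_times Acquisition time of each frame (s); length must match
#'   `ncol(samples)`.
#' @param theta,phi Transmit and receive steering angles (degrees), carried
#'   through to the Doppler map.
#' @param paired Logical: frames arranged as double-transmit pairs.
#' @return An object of class `slow_time_ensemble`.
#' @export
slow_time_ensemble <- function(samples, pair_pri, tx_index, rx_index,
                               pulse_times = NULL, theta = NA_real_,
                               phi = NA_real_, paired = TRUE) {
  if (!is.matrix(samples) || !is.complex(samples))
    stop("`samples` must be a complex matrix (pixels x frames)", call. = FALSE)
  if (!is.numeric(pair_pri) || length(pair_pri) != 1L || pair_pri <= 0)
    stop("`pair_pri` must be a positive scalar (s)", call. = FALSE)
  if (!is.null(pulse_times) && length(pulse_times) != ncol(samples))
    stop("`pulse_times` length must equal the number of frames", call. = FALSE)
  structure(list(samples = samples, pair_pri = pair_pri,
                 tx_index = tx_index, rx_index = rx_index,
                 pulse_times = pulse_times, theta = theta, phi = phi,
                 paired = paired),
            class = "slow_time_ensemble")
}

#' @export
print.slow_time_ensemble <- function(x, ...) {
  cat(sprintf("<slow_time_ensemble: Tx%s Rx%s, %d pixels x %d frames, PRI %.3g s%s>\n",
              x$tx_index, x$rx_index, nrow(x$samples), ncol(x$samples),
              x$pair_pri, if (isTRUE(x$paired)) ", paired" else ""))
  invisible(x)
}

ensemble_samples <- function(x) {
  if (inherits(x, "slow_time_ensemble")) x$samples
  else if (is.matrix(x) && is.complex(x)) x
  else stop("expected a slow_time_ensemble or a complex matrix", call. = FALSE)
}

#' Lag-one autocorrelation, sequential sampling
#'
#' The classic lag-one estimator over a uniformly sampled slow-time window:
#' `R(1) = 1/(P-1) * sum_{i=0}^{P-2} conj(x(i)) * x(i+1)`, evaluated per
#' pixel (row).
#'
#' @param ensemble A [slow_time_ensemble()] or complex matrix
#'   (pixels x frames).
#' @return Complex vector, one autocorrelation value per pixel.
#' @export
lag_one_autocorr_sequential <- function(ensemble) {
  x <- ensemble_samples(ensemble)
  P <- ncol(x)
  if (P < 2L)
    stop("lag-one autocorrelation needs at least 2 frames", call. = FALSE)
  prods <- Conj(x[, -P, drop = FALSE]) * x[, -1L, drop = FALSE]
  rowSums(prods) / (P - 1L)
}

#' Lag-one autocorrelation, double-transmission sampling
#'
#' For double-transmit schemes only the intra-pair lags are uniformly
#' spaced, so the estimator uses them alone:
#' `R(1) = 1/(P/2-1) * sum_{i=0}^{P/2-2} conj(x(2i)) * x(2i+1)` (0-based).
#' Inter-pair timing never enters, which is what permits the center pair of
#' the stable scheme to run at a different absolute PRF.
#'
#' @inheritParams lag_one_autocorr_sequential
#' @return Complex vector, one autocorrelation value per pixel.
#' @export
lag_one_autocorr_double <- function(ensemble) {
  x <- ensemble_samples(ensemble)
  P <- ncol(x)
  if (P < 4L || P %% 2L != 0L)
    stop("double-transmit autocorrelation needs an even window length >= 4",
         call. = FALSE)
  n_terms <- P %/% 2L - 1L          # pairs (0,1), (2,3), ..., (P-4, P-3)
  a <- 2L * seq_len(n_terms) - 1L   # 1-based first index of each pair used
  prods <- Conj(x[, a, drop = FALSE]) * x[, a + 1L, drop = FALSE]
  rowSums(prods) / n_terms
}

#' Wrapped Doppler velocity from a lag-one autocorrelation value
#'
#' `U = PRF_eff * c / (4 * pi * f0) * arg(R)`, with the principal argument
#' in (-pi, pi] and +pi mapped onto the negative edge so the result lies in
#' `[-VN, VN)`. Positive velocity is motion toward the transducer.
#'
#' @param R Complex autocorrelation value(s).
#' @param prf_eff Effective PRF (Hz).
#' @param f0 Transmit center frequency (Hz).
#' @param c Speed of sound (m/s).
#' @return Wrapped velocity (m/s); `NA` where `R == 0` (undefined phase).
#' @export
velocity_from_autocorr <- function(R, prf_eff, f0, c = 1540) {
  vn <- nyquist_limit(f0, prf_eff, c)
  v <- prf_eff * c / (4 * pi * f0) * Arg(R)
  v[v >= vn] <- -vn   # principal value +pi -> negative velocity edge
  v[R == 0] <- NA_real_
  v
}

#' Per-pixel wrapped Doppler map for one Tx-Rx pair
#'
#' Runs the lag-one estimator appropriate for the sampling (intra-pair for
#' paired ensembles, uniform otherwise) and converts the phase to a wrapped
#' velocity. Pixels whose autocorrelation magnitude falls below `mag_floor`
#' times the window's maximum are flagged invalid rather than returning
#' noise-driven velocities.
#'
#' @param ensemble A [slow_time_ensemble()].
#' @param f0 Transmit center frequency (Hz).
#' @param c Speed of sound (m/s).
#' @param net_angle Net steering angle `theta + phi` (degrees).
#' @param mag_floor Relative magnitude floor for the validity mask.
#' @return An object of class `doppler_map` with fields `velocity` (m/s,
#'   in `[-nyquist, nyquist)`), `nyquist`, `net_angle`, `tx_index`,
#'   `rx_index`, `valid`.
#' @export
doppler_map <- function(ensemble, f0, c = 1540,
                        net_angle = ensemble$theta + ensemble$phi,
                        mag_floor = 1e-3) {
  stopifnot(inherits(ensemble, "slow_time_ensemble"))
  R <- if (isTRUE(ensemble$paired)) lag_one_autocorr_double(ensemble)
       else lag_one_autocorr_sequential(ensemble)
  prf_eff <- 1 / ensemble$pair_pri
  v <- velocity_from_autocorr(R, prf_eff, f0, c)
  valid <- is.finite(v) & (Mod(R) >= mag_floor * max(Mod(R), 1e-300))
  v[!valid] <- NA_real_
  structure(list(velocity = v, nyquist = nyquist_limit(f0, prf_eff, c),
                 net_angle = net_angle, tx_index = ensemble$tx_index,
                 rx_index = ensemble$rx_index, theta = ensemble$theta,
                 phi = ensemble$phi, valid = valid),
            class = "doppler_map")
}

#' @export
print.doppler_map <- function(x, ...) {
  cat(sprintf("<doppler_map: Tx%s Rx%s, net %g deg, VN = %.4g m/s, %d px (%d valid)>\n",
              x$tx_index, x$rx_index, x$net_angle, x$nyquist,
              length(x$velocity), sum(x$valid)))
  invisible(x)
}

#' Polyphase wall (clutter) filter
#'
#' Zero-phase high-pass filtering of the slow-time signal to suppress
#' stationary and slowly moving tissue echoes. Following the polyphase
#' decomposition of the double-transmit sampling, the even-index and
#' odd-index subsequences are filtered independently (each substream is
#' uniformly sampled even though the interleaved stream is not).
#'
#' The filter removes, by orthogonal projection, the discrete-frequency
#' components whose normalized frequency lies below `fractional_cutoff`
#' (expressed as a fraction of the substream Nyquist frequency). This
#' realization is exactly zero-phase, rejects DC completely, and is free of
#' the edge transients that recursive filters exhibit on Doppler ensembles
#' of a few tens of samples.
#'
#' @param ensemble A [slow_time_ensemble()] or complex matrix.
#' @param fractional_cutoff High-pass cutoff as a fraction of the substream
#'   Nyquist frequency, in (0, 1). Default 0.05.
#' @param polyphase Filter even/odd substreams separately (default `TRUE`,
#'   matching double-transmit sampling). Set `FALSE` for uniformly sampled
#'   ensembles.
#' @return Filtered object of the same type and shape as the input.
#' @export
wall_filter <- function(ensemble, fractional_cutoff = 0.05, polyphase = TRUE) {
  if (!is.numeric(fractional_cutoff) || length(fractional_cutoff) != 1L ||
      fractional_cutoff <= 0 || fractional_cutoff >= 1)
    stop("`fractional_cutoff` must lie strictly between 0 and 1", call. = FALSE)
  x <- ensemble_samples(ensemble)
  if (polyphase) {
    even <- seq(1L, ncol(x), by = 2L)   # 0-based even indices
    odd <- seq(2L, ncol(x), by = 2L)
    y <- x
    y[, even] <- highpass_project(x[, even, drop = FALSE], fractional_cutoff)
    y[, odd] <- highpass_project(x[, odd, drop = FALSE], fractional_cutoff)
  } else {
    y <- highpass_project(x, fractional_cutoff)
  }
  if (inherits(ensemble, "slow_time_ensemble")) {
    ensemble$samples <- y
    ensemble
  } else {
    y
  }
}

# Remove DFT components with |f| < cutoff (in Nyquist units, i.e. cutoff
# relative to fs/2) by projection. Rows are pixels, columns time.
highpass_project <- function(x, cutoff) {
  n <- ncol(x)
  if (n < 2L) return(x * 0)
  k <- 0:(n - 1L)
  fnorm <- pmin(k, n - k) * 2 / n     # frequency of bin k in Nyquist units
  stopband <- fnorm < cutoff
  X <- t(stats::mvfft(t(x)))
  X[, stopband] <- 0
  t(stats::mvfft(t(X), inverse = TRUE)) / n
}
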