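#' Wrap a true velocity into the Nyquist band
#'
#' Aliasing maps an unambiguous Doppler velocity `v` onto
#' `v - 2 * nN * vn` with the Nyquist number (aliasing order)
#' `nN = floor((v + vn) / (2 * vn))`, so the wrapped value always lies in
#' `[-vn, vn)`.
#'
#' @param v_true True (unambiguous) velocity, m/s. Vectorized.
#' @param vn Nyquist velocity limit, m/s (positive scalar).
#' @return A list with components `wrapped` (m/s) and `n_nyquist`
#'   (integer aliasing order).
#' @examples
#' wrap_velocity(1.5, 1)   # wrapped -0.5, order 1
#' wrap_velocity(-1.5, 1)  # wrapped +0.5, order -1
#' @export
wrap_velocity <- function(v_true, vn) {
  if (!is.numeric(vn) || length(vn) != 1L || vn <= 0)
    stop("`vn` must be a positive scalar", call. = FALSE)
  nN <- floor((v_true + vn) / (2 * vn))
  wrapped <- v_true - 2 * nN * vn
  # guard the half-open band against floating-point boundary rounding
  hi <- wrapped >= vn
  wrapped[hi] <- wrapped[hi] - 2 * vn
  nN[hi] <- nN[hi] + 1
  lo <- wrapped < -vn
  wrapped[lo] <- wrapped[lo] + 2 * vn
  nN[lo] <- nN[lo] - 1
  list(wrapped = wrapped, n_nyquist = nN)
}

# round half away from zero; ties sit only on aliasing-cell boundaries
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Common aliasing coefficient of a staggered-PRF velocity pair
#'
#' From the wrapped velocities observed at the two PRFs,
#' `ncoeff = round(q * (u2 - u1) / (2 * vn1))` (rounding half away from
#' zero). Over the extended range the coefficient identifies the pair of
#' Nyquist numbers via the lookup table.
#'
#' @param u1 Wrapped velocity at PRF1 (m/s). Vectorized.
#' @param u2 Wrapped velocity at PRF2 (m/s). Vectorized.
#' @param vn1 Nyquist limit at PRF1 (m/s).
#' @param q Denominator of the PRF ratio p/q.
#' @return Integer coefficient(s).
#' @export
alias_coefficient <- function(u1, u2, vn1, q) {
  round_half_away(q * (u2 - u1) / (2 * vn1))
}

#' Build the aliasing-order lookup table for a PRF ratio
#'
#' Constructed by exhaustive enumeration rather than transcription: a dense
#' grid of true velocities spanning the extended range `[-p*VN1, p*VN1)` is
#' wrapped at both PRFs, the common aliasing coefficient is evaluated for
#' each, and the mapping `ncoeff -> (nN1, nN2)` is recorded. Construction
#' fails if any coefficient maps to two distinct Nyquist-number pairs
#' (which would signal an invalid p/q design).
#'
#' @param p,q Coprime positive integers with `p < q` (`p = q = 1` is the
#'   accepted degenerate single-PRF case).
#' @param n_grid Number of sweep points per unit of `VN1` (the sweep uses
#'   `2 * p * n_grid` midpoint-offset samples).
#' @return An object of class `alias_lookup` with fields `p`, `q`,
#'   `entries` (data frame `ncoeff`, `nn1`, `nn2`) and `valid_range`
#'   (in units of `VN1`).
#' @examples
#' build_lookup_table(2, 3)
#' @export
build_lookup_table <- function(p, q, n_grid = 4096L) {
  check_pq(p, q)
  p <- as.integer(p); q <- as.integer(q)
  vn1 <- 1
  vn2 <- p / q
  n <- 2L * p * n_grid
  # midpoint-offset grid: never lands exactly on a wrap boundary
  v <- -p + (seq_len(n) - 0.5) * (2 * p / n)
  w1 <- wrap_velocity(v, vn1)
  w2 <- wrap_velocity(v, vn2)
  nc <- alias_coefficient(w1$wrapped, w2$wrapped, vn1, q)
  cells <- unique(data.frame(ncoeff = nc, nn1 = w1$n_nyquist, nn2 = w2$n_nyquist))
  if (anyDuplicated(cells$ncoeff))
    stop(sprintf(paste0("ambiguous lookup table for p/q = %d/%d: some ncoeff ",
                        "maps to multiple Nyquist-number pairs"), p, q),
         call. = FALSE)
  cells <- cells[order(cells$ncoeff), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(p = p, q = q, entries = cells, valid_range = c(-p, p)),
            class = "alias_lookup")
}

#' @export
print.alias_lookup <- function(x, ...) {
  cat(sprintf("<alias_lookup: p/q = %d/%d, valid |v| < %d * VN1>\n",
              x$p, x$q, x$p))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Look up Nyquist-number pairs for aliasing coefficients
#'
#' @param table An [build_lookup_table()] result.
#' @param ncoeff Integer coefficient(s).
#' @return A list with integer vectors `nn1`, `nn2` (`NA` where `ncoeff`
#'   has no entry, i.e. the pixel is unresolved).
#' @export
lookup_nyquist_numbers <- function(table, ncoeff) {
  stopifnot(inherits(table, "alias_lookup"))
  idx <- match(ncoeff, table$entries$ncoeff)
  list(nn1 = table$entries$nn1[idx], nn2 = table$entries$nn2[idx])
}

#' Dealias one wrapped-velocity pair by the staggered-PRF weighted mean
#'
#' Resolves the aliasing order from the common coefficient and combines the
#' two unfolded estimates with weights `q_i / p_i` (weight 1 for the PRF1
#' stream): `v = sum_i (q_i/p_i) * (u_i + 2*nN_i*vn_i) / sum_i (q_i/p_i)`.
#'
#' @param u1,u2 Wrapped velocities at PRF1 / PRF2 (m/s). Vectorized.
#' @param vn1 Nyquist limit at PRF1 (m/s); the PRF2 limit is `(p/q)*vn1`.
#' @param table An [build_lookup_table()] result.
#' @return A list with `velocity` (m/s; `NA` where unresolved), `resolved`
#'   (logical), `nn1`, `nn2`.
#' @export
dealias_pair <- function(u1, u2, vn1, table) {
  stopifnot(inherits(table, "alias_lookup"))
  vn2 <- table$p / table$q * vn1
  nc <- alias_coefficient(u1, u2, vn1, table$q)
  nn <- lookup_nyquist_numbers(table, nc)
  w2 <- table$q / table$p
  v <- (1 * (u1 + 2 * nn$nn1 * vn1) + w2 * (u2 + 2 * nn$nn2 * vn2)) / (1 + w2)
  resolved <- !is.na(nn$nn1)
  v[!resolved] <- NA_real_
  list(velocity = v, resolved = resolved, nn1 = nn$nn1, nn2 = nn$nn2)
}

#' Dealias matched-net-angle Doppler map pairs
#'
#' For every PRF1 (outer-transmit) map, uses its net-angle-matched PRF2
#' (center-transmit) partner to infer per-pixel aliasing orders via the
#' common coefficient and lookup table, then unfolds each map with its own
#' measured velocity and Nyquist limit (`u + 2*nN*vn`). Both streams are
#' returned dealiased; all output maps carry the extended Nyquist limit
#' `p * vn1`. Pixels whose coefficient has no lookup entry (noise beyond
#' the design range) are masked, not clamped.
#'
#' @param maps_prf1 List of wrapped [doppler_map()]s at PRF1 (outer Tx).
#' @param maps_prf2 List of wrapped [doppler_map()]s at PRF2 (center Tx).
#' @param pairing A [match_net_angles()] pairing; `tx1`/`rx1` must match
#'   the `tx_index`/`rx_index` of `maps_prf1`, `tx2`/`rx2` those of
#'   `maps_prf2`.
#' @param table An [build_lookup_table()] result for the scheme's p/q.
#' @return A list with `prf1` and `prf2`: lists (one element per pairing
#'   row) of dealiased `doppler_map`s carrying the extended limit.
#' @export
dealias_maps <- function(maps_prf1, maps_prf2, pairing, table) {
  stopifnot(inherits(pairing, "net_angle_pairing"),
            inherits(table, "alias_lookup"))
  key <- function(m) paste(m$tx_index, m$rx_index, sep = "/")
  idx1 <- vapply(maps_prf1, key, character(1))
  idx2 <- vapply(maps_prf2, key, character(1))
  out1 <- vector("list", nrow(pairing))
  out2 <- vector("list", nrow(pairing))
  for (k in seq_len(nrow(pairing))) {
    row <- pairing[k, ]
    i1 <- match(paste(row$tx1, row$rx1, sep = "/"), idx1)
    i2 <- match(paste(row$tx2, row$rx2, sep = "/"), idx2)
    if (is.na(i1) || is.na(i2))
      stop(sprintf("no Doppler map for pairing row %d (net %g deg)",
                   k, row$net_angle), call. = FALSE)
    m1 <- maps_prf1[[i1]]; m2 <- maps_prf2[[i2]]
    if (length(m1$velocity) != length(m2$velocity))
      stop("pixel grids of paired Doppler maps differ", call. = FALSE)
    vn1 <- m1$nyquist; vn2 <- m2$nyquist
    if (abs(vn2 / vn1 - table$p / table$q) > 1e-9)
      stop("map Nyquist limits are inconsistent with the table's p/q",
           call. = FALSE)
    nc <- alias_coefficient(m1$velocity, m2$velocity, vn1, table$q)
    nn <- lookup_nyquist_numbers(table, nc)
    ok <- !is.na(nn$nn1) & m1$valid & m2$valid
    v_ext <- table$p * vn1
    d1 <- m1; d2 <- m2
    d1$velocity <- m1$velocity + 2 * nn$nn1 * vn1
    d2$velocity <- m2$velocity + 2 * nn$nn2 * vn2
    d1$velocity[!ok] <- NA_real_
    d2$velocity[!ok] <- NA_real_
    d1$valid <- ok; d2$valid <- ok
    d1$nyquist <- v_ext; d2$nyquist <- v_ext
    out1[[k]] <- d1; out2[[k]] <- d2
  }
  list(prf1 = out1, prf2 = out2)
}

#' Export a lookup table as plain JSON
#'
#' @param table An [build_lookup_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "alias_lookup"))
  jsonlite::write_json(
    list(p = table$p, q = table$q, valid_range = table$valid_range,
         entries = table$entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
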