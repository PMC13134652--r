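#' Steering matrix for least-squares vector Doppler
#'
#' Each Tx-Rx pair observes the projection
#' `vz*(cos(theta)+cos(phi)) + vx*(sin(theta)+sin(phi)) = 2*U`, so the
#' linear system's matrix has one row `(cos(theta_k)+cos(phi_k),
#' sin(theta_k)+sin(phi_k))` per pair. Rank 2 is required for a solvable
#' system and is checked at build time.
#'
#' @param pairs Data frame or matrix with columns `theta`, `phi` (degrees),
#'   one row per Tx-Rx pair.
#' @param pair_ids Optional identifiers carried along (default row numbers).
#' @return An object of class `steering_matrix`: fields `A` (n x 2 matrix),
#'   `pair_ids`, `theta`, `phi`.
#' @export
build_steering_matrix <- function(pairs, pair_ids = NULL) {
  pairs <- as.data.frame(pairs)
  if (!all(c("theta", "phi") %in% names(pairs)))
    stop("`pairs` needs columns `theta` and `phi` (degrees)", call. = FALSE)
  if (nrow(pairs) < 2L)
    stop("at least 2 Tx-Rx pairs are required", call. = FALSE)
  th <- pairs$theta * pi / 180
  ph <- pairs$phi * pi / 180
  A <- cbind(cos(th) + cos(ph), sin(th) + sin(ph))
  colnames(A) <- c("axial", "lateral")
  if (qr(A)$rank < 2L)
    stop("degenerate steering geometry: matrix rank < 2 (all net angles equal?)",
         call. = FALSE)
  if (is.null(pair_ids)) pair_ids <- seq_len(nrow(A))
  structure(list(A = A, pair_ids = pair_ids,
                 theta = pairs$theta, phi = pairs$phi),
            class = "steering_matrix")
}

#' @export
print.steering_matrix <- function(x, ...) {
  cat(sprintf("<steering_matrix: %d Tx-Rx pairs, rank %d>\n",
              nrow(x$A), qr(x$A)$rank))
  invisible(x)
}

#' Project a velocity vector onto per-pair Doppler velocities
#'
#' The forward model of the least-squares system:
#' `u_k = (vz * A[k,1] + vx * A[k,2]) / 2`.
#'
#' @param v Velocity: length-2 vector `(vz, vx)` or a 2 x npixels matrix.
#' @param matrix A [build_steering_matrix()] result.
#' @return Per-pair Doppler velocities: a vector (one per pair) or an
#'   npairs x npixels matrix.
#' @export
forward_project <- function(v, matrix) {
  stopifnot(inherits(matrix, "steering_matrix"))
  if (is.null(dim(v))) v <- matrix(v, nrow = 2L)
  if (nrow(v) != 2L)
    stop("`v` must be (vz, vx): length 2 or a 2 x npixels matrix", call. = FALSE)
  u <- (matrix$A %*% v) / 2
  if (ncol(u) == 1L) drop(u) else u
}

#' Least-squares vector velocity from per-pair Doppler velocities
#'
#' Solves `A %*% c(vz, vx) = 2 * u` in the least-squares sense per pixel,
#' via QR factorization (numerically equivalent to the normal-equations
#' pseudoinverse but better conditioned). Rows with missing velocities are
#' dropped per pixel; pixels left with fewer than 2 usable rows, or whose
#' remaining rows are rank deficient, are masked.
#'
#' @param u Per-pair Doppler velocities: a vector (length = npairs) or an
#'   npairs x npixels matrix; `NA` marks masked rows.
#' @param matrix A [build_steering_matrix()] result.
#' @return A list with `vz`, `vx` (m/s, `NA` where masked) and `valid`.
#' @export
solve_vector <- function(u, matrix) {
  stopifnot(inherits(matrix, "steering_matrix"))
  A <- matrix$A
  if (is.null(dim(u))) u <- matrix(u, ncol = 1L)
  if (nrow(u) != nrow(A))
    stop("`u` must have one row per steering-matrix row", call. = FALSE)
  npix <- ncol(u)
  vz <- rep(NA_real_, npix); vx <- rep(NA_real_, npix)
  finite <- is.finite(u)
  pattern <- apply(finite, 2L, function(f) paste(which(f), collapse = ","))
  for (pat in unique(pattern)) {
    rows <- as.integer(strsplit(pat, ",", fixed = TRUE)[[1L]])
    cols <- which(pattern == pat)
    if (length(rows) < 2L) next
    Ak <- A[rows, , drop = FALSE]
    qrA <- qr(Ak)
    if (qrA$rank < 2L) next
    sol <- qr.coef(qrA, 2 * u[rows, cols, drop = FALSE])
    vz[cols] <- sol[1L, ]
    vx[cols] <- sol[2L, ]
  }
  list(vz = vz, vx = vx, valid = is.finite(vz) & is.finite(vx))
}

#' Noise amplification factors of a steering geometry
#'
#' Row norms of the pseudoinverse of `A / 2`: the factor by which
#' independent unit-variance noise on the per-pair Doppler velocities
#' inflates the standard deviation of the axial and lateral solutions.
#' For shallow steering geometries the lateral factor exceeds the axial
#' one, which is why lateral estimates carry larger errors.
#'
#' @param matrix A [build_steering_matrix()] result.
#' @return Named numeric vector `c(axial = ..., lateral = ...)`.
#' @export
noise_amplification <- function(matrix) {
  stopifnot(inherits(matrix, "steering_matrix"))
  A <- matrix$A / 2
  pinv <- solve(crossprod(A), t(A))
  c(axial = sqrt(sum(pinv[1L, ]^2)), lateral = sqrt(sum(pinv[2L, ]^2)))
}

#' Per-pixel vector field
#'
#' Container for axial (`vz`, positive toward the transducer) and lateral
#' (`vx`) velocity estimates on a pixel grid, with a validity mask.
#'
#' @param vz,vx Numeric matrices (nz x nx), m/s.
#' @param valid Logical matrix of the same shape; defaults to finiteness of
#'   both components.
#' @param x,z Optional pixel coordinate vectors (m).
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(vz, vx, valid = NULL, x = NULL, z = NULL) {
  if (!identical(dim(vz), dim(vx)))
    stop("`vz` and `vx` must have identical shape", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(vz) & is.finite(vx)
  vz[!valid] <- NA_real_
  vx[!valid] <- NA_real_
  structure(list(vz = vz, vx = vx, valid = valid, x = x, z = z),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field: %s px, %d valid, max |v| = %.4g m/s>\n",
              paste(dim(x$vz), collapse = " x "), sum(x$valid),
              suppressWarnings(max(sqrt(x$vz^2 + x$vx^2), na.rm = TRUE))))
  invisible(x)
}

#' Export a vector field as CSV
#'
#' One row per pixel: `x`, `z` (m), `vz`, `vx` (m/s), `valid`.
#'
#' @param field A [vector_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  nz <- nrow(field$vz); nx <- ncol(field$vz)
  xs <- if (is.null(field$x)) seq_len(nx) else field$x
  zs <- if (is.null(field$z)) seq_len(nz) else field$z
  df <- data.frame(x = rep(xs, each = nz), z = rep(zs, times = nx),
                   vz = as.vector(field$vz), vx = as.vector(field$vx),
                   valid = as.vector(field$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
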