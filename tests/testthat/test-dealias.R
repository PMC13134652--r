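ratios <- list(c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L))

test_that("wrap_velocity implements the floor-based aliasing law", {
  w <- wrap_velocity(0, 1)
  expect_equal(w$wrapped, 0); expect_equal(w$n_nyquist, 0)
  w <- wrap_velocity(1.5, 1)
  expect_equal(w$wrapped, -0.5); expect_equal(w$n_nyquist, 1)
  w <- wrap_velocity(-1.5, 1)
  expect_equal(w$wrapped, 0.5); expect_equal(w$n_nyquist, -1)
  # total function, always lands in [-vn, vn)
  v <- seq(-10, 10, length.out = 2001)
  w <- wrap_velocity(v, 0.7)
  expect_true(all(w$wrapped >= -0.7 & w$wrapped < 0.7))
  expect_equal(w$wrapped + 2 * w$n_nyquist * 0.7, v, tolerance = 1e-12)
  expect_error(wrap_velocity(1, -1), "positive")
})

test_that("the common aliasing coefficient matches the hand oracle", {
  # u1 = u2 = 0 is unaliased
  expect_equal(alias_coefficient(0, 0, 1, 4L), 0)
  # p/q = 3/4, v = 1.2*vn1: u1 = -0.8, u2 = -0.3 (vn2 = 0.75), ncoeff = 1
  vn1 <- 1
  v <- 1.2
  u1 <- wrap_velocity(v, vn1)$wrapped
  u2 <- wrap_velocity(v, 0.75)$wrapped
  expect_equal(u1, -0.8)
  expect_equal(u2, -0.3, tolerance = 1e-12)
  expect_equal(alias_coefficient(u1, u2, vn1, 4L), 1)
  # piecewise constant over the sweep, jumping exactly at wrap boundaries:
  # ncoeff must equal q*nN1 - p*nN2 everywhere (noiseless identity)
  v <- seq(-3, 3, length.out = 9999)  # even count: never hits a boundary
  w1 <- wrap_velocity(v, 1); w2 <- wrap_velocity(v, 0.75)
  nc <- alias_coefficient(w1$wrapped, w2$wrapped, 1, 4L)
  expect_equal(nc, 4 * w1$n_nyquist - 3 * w2$n_nyquist)
})

test_that("rounding in the coefficient is half-away-from-zero", {
  # q*(u2-u1)/(2*vn1) = +/-0.5 exactly: away from zero on both sides
  expect_equal(alias_coefficient(0, 0.25, 1, 4L), 1)
  expect_equal(alias_coefficient(0, -0.25, 1, 4L), -1)
})

test_that("lookup tables are built by enumeration and are bijective", {
  # degenerate single-PRF case
  tab <- build_lookup_table(1L, 1L)
  expect_equal(tab$entries, data.frame(ncoeff = 0, nn1 = 0, nn2 = 0))
  # frozen 2/3 table from an independent cell-by-cell enumeration:
  # boundaries at v/vn1 in {-2, -1, -2/3, 2/3, 1, 2} give 5 cells
  tab23 <- build_lookup_table(2L, 3L)
  expect_equal(tab23$entries,
               data.frame(ncoeff = c(-2, -1, 0, 1, 2),
                          nn1 = c(0, -1, 0, 1, 0),
                          nn2 = c(1, -1, 0, 1, -1)))
  # 3/4 contains the worked example's entry 1 -> (1, 1)
  tab34 <- build_lookup_table(3L, 4L)
  expect_equal(unlist(lookup_nyquist_numbers(tab34, 1L)),
               c(nn1 = 1L, nn2 = 1L))
  # bijectivity for every supported ratio: each ncoeff names one cell and
  # every (nN1, nN2) cell arising over the extended range is present
  for (pq in ratios) {
    tab <- build_lookup_table(pq[1], pq[2])
    expect_false(anyDuplicated(tab$entries$ncoeff) > 0)
    expect_false(anyDuplicated(tab$entries[c("nn1", "nn2")]) > 0)
    v <- seq(-pq[1] + 1e-6, pq[1] - 1e-6, length.out = 4001)
    w1 <- wrap_velocity(v, 1); w2 <- wrap_velocity(v, pq[1] / pq[2])
    nc <- alias_coefficient(w1$wrapped, w2$wrapped, 1, pq[2])
    expect_true(all(nc %in% tab$entries$ncoeff))
  }
  expect_error(build_lookup_table(2L, 4L), "lowest terms")
  expect_error(build_lookup_table(4L, 3L), "smaller")
})

test_that("dealias_pair inverts wrapping over the extended range", {
  # worked example: p/q = 3/4, v = 1.2*vn1 recovered exactly
  tab34 <- build_lookup_table(3L, 4L)
  out <- dealias_pair(-0.8, -0.3, 1, tab34)
  expect_equal(out$velocity, 1.2, tolerance = 1e-12)
  expect_equal(c(out$nn1, out$nn2), c(1, 1))
  # zero in, zero out
  expect_equal(dealias_pair(0, 0, 1, tab34)$velocity, 0)
  # identity on the unaliased band uses nN = (0, 0)
  for (pq in ratios) {
    tab <- build_lookup_table(pq[1], pq[2])
    vn2 <- pq[1] / pq[2]
    v <- seq(-vn2 + 1e-9, vn2 - 1e-9, length.out = 101)
    out <- dealias_pair(v, v, 1, tab)
    expect_equal(out$nn1, rep(0, length(v)))
    expect_equal(out$nn2, rep(0, length(v)))
    expect_equal(out$velocity, v, tolerance = 1e-12)
  }
  # an out-of-table coefficient flags the sample unresolved, not clamped
  tab23 <- build_lookup_table(2L, 3L)
  bad <- dealias_pair(-0.99, 0.6, 1, tab23)  # ncoeff 2.4 -> 2 is in range;
  far <- dealias_pair(-0.99, 0.99, 1, tab23) # ncoeff 3 is not
  expect_true(bad$resolved)
  expect_false(far$resolved)
  expect_true(is.na(far$velocity))
})

test_that("wrap-then-dealias is the identity on a dense extended-range grid", {
  for (pq in ratios) {
    tab <- build_lookup_table(pq[1], pq[2])
    vn1 <- 0.0739  # m/s scale of the disk experiments; units must not matter
    span <- 0.99 * pq[1] * vn1
    v <- seq(-span, span, length.out = 10000)
    u1 <- wrap_velocity(v, vn1)$wrapped
    u2 <- wrap_velocity(v, pq[1] / pq[2] * vn1)$wrapped
    out <- dealias_pair(u1, u2, vn1, tab)
    expect_true(all(out$resolved))
    expect_equal(out$velocity, v, tolerance = 1e-9)
  }
})

test_that("aliasing orders tolerate velocity perturbations below vn1/(2q)", {
  for (pq in ratios) {
    p <- pq[1]; q <- pq[2]
    tab <- build_lookup_table(p, q)
    vn1 <- 1
    v <- seq(-0.99 * p, 0.99 * p, length.out = 600)
    u1 <- wrap_velocity(v, vn1)$wrapped
    u2 <- wrap_velocity(v, p / q * vn1)$wrapped
    nom <- dealias_pair(u1, u2, vn1, tab)
    eps <- 0.999 * vn1 / (2 * q)
    for (s in list(c(eps, -eps), c(-eps, eps), c(eps, eps), c(-eps, -eps))) {
      pert <- dealias_pair(u1 + s[1], u2 + s[2], vn1, tab)
      expect_equal(pert$nn1, nom$nn1)
      expect_equal(pert$nn2, nom$nn2)
    }
  }
})

test_that("dealias_maps unfolds matched map pairs and masks mismatches", {
  cfg <- default_stable_scheme()
  pairing <- scheme_pairing(cfg)
  tab <- build_lookup_table(2L, 3L)
  vn1 <- nyquist_limit(cfg$f0, cfg$prf1, cfg$c)
  vn2 <- 2 / 3 * vn1
  v_true <- seq(-1.9, 1.9, length.out = 25) * vn1
  mk <- function(tx, rx, theta, phi, vn) {
    u <- wrap_velocity(v_true, vn)$wrapped
    structure(list(velocity = u, nyquist = vn, net_angle = theta + phi,
                   tx_index = tx, rx_index = rx, theta = theta, phi = phi,
                   valid = rep(TRUE, length(u))), class = "doppler_map")
  }
  maps1 <- lapply(seq_len(nrow(pairing)), function(k)
    mk(pairing$tx1[k], pairing$rx1[k], pairing$theta1[k], pairing$phi1[k], vn1))
  maps2 <- lapply(unique(pairing$rx2), function(r)
    mk(2L, r, 0, cfg$center_rx_angles[r], vn2))
  out <- dealias_maps(maps1, maps2, pairing, tab)
  for (k in seq_len(nrow(pairing))) {
    expect_equal(out$prf1[[k]]$velocity, v_true, tolerance = 1e-10)
    expect_equal(out$prf2[[k]]$velocity, v_true, tolerance = 1e-10)
    expect_equal(out$prf1[[k]]$nyquist, 2 * vn1)
  }
  # all-zero maps dealias to zero
  zero1 <- lapply(maps1, function(m) { m$velocity[] <- 0; m })
  zero2 <- lapply(maps2, function(m) { m$velocity[] <- 0; m })
  outz <- dealias_maps(zero1, zero2, pairing, tab)
  expect_true(all(vapply(outz$prf1, function(m) all(m$velocity == 0), logical(1))))
  # a missing partner map is a pairing error
  expect_error(dealias_maps(maps1[-1], maps2, pairing, tab), "no Doppler map")
  # grid mismatch is a shape error
  short <- maps2
  short[[1]]$velocity <- short[[1]]$velocity[-1]
  expect_error(dealias_maps(maps1, short, pairing, tab), "grids")
})
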