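# brute-force lag-one oracle: term-by-term evaluation of the defining sum
brute_lag_one <- function(x) {
  P <- length(x)
  acc <- 0 + 0i
  for (i in seq_len(P - 1L)) acc <- acc + Conj(x[i]) * x[i + 1L]
  acc / (P - 1L)
}
brute_lag_one_double <- function(x) {
  P <- length(x)
  acc <- 0 + 0i
  for (i in 0:(P / 2 - 2)) acc <- acc + Conj(x[2 * i + 1L]) * x[2 * i + 2L]
  acc / (P / 2 - 1L)
}

test_that("sequential lag-one autocorrelation matches the brute-force sum", {
  set.seed(42)
  for (P in c(2L, 5L, 32L)) {
    x <- matrix(complex(real = rnorm(3 * P), imaginary = rnorm(3 * P)),
                nrow = 3L)
    R <- lag_one_autocorr_sequential(x)
    expect_equal(R, apply(x, 1L, brute_lag_one), tolerance = 1e-12)
  }
  # pure tone: unit-modulus autocorrelation at the tone's phase step
  fd <- 0.21
  tone <- matrix(exp(1i * 2 * pi * fd * (0:31)), nrow = 1L)
  R <- lag_one_autocorr_sequential(tone)
  expect_equal(Mod(R), 1, tolerance = 1e-12)
  expect_equal(Arg(R), 2 * pi * fd, tolerance = 1e-12)
  # constant real signal has zero phase
  expect_equal(Arg(lag_one_autocorr_sequential(matrix(1 + 0i, 1L, 8L))), 0)
  expect_error(lag_one_autocorr_sequential(matrix(1 + 0i, 1L, 1L)),
               "at least 2")
})

test_that("double-transmit autocorrelation uses intra-pair lags only", {
  set.seed(43)
  for (P in c(4L, 8L, 32L)) {
    x <- matrix(complex(real = rnorm(2 * P), imaginary = rnorm(2 * P)),
                nrow = 2L)
    expect_equal(lag_one_autocorr_double(x),
                 apply(x, 1L, brute_lag_one_double), tolerance = 1e-12)
  }
  # arbitrary inter-pair phase jumps are irrelevant: arg R equals the
  # constant intra-pair step
  phi <- 0.8
  x <- paired_tone(phi, n_pairs = 16L, inter_pair_phase = runif(16L, -pi, pi))
  expect_equal(Arg(lag_one_autocorr_double(x)), phi, tolerance = 1e-12)
  # P = 4 degenerates to a single product term
  x4 <- matrix(c(1 + 0i, 1i, 123 + 5i, -7i), nrow = 1L)
  expect_equal(lag_one_autocorr_double(x4), Conj(x4[1]) * x4[2])
  expect_error(lag_one_autocorr_double(matrix(1 + 0i, 1L, 5L)), "even")
  expect_error(lag_one_autocorr_double(matrix(1 + 0i, 1L, 2L)), "even")
})

test_that("velocity conversion wraps the principal phase into [-VN, VN)", {
  f0 <- 31.25e6; prf <- 6e3; c0 <- 1540
  vn <- nyquist_limit(f0, prf, c0)
  # arg = pi maps to the negative velocity edge
  expect_equal(velocity_from_autocorr(-1 + 0i, prf, f0, c0), -vn)
  # proportionality to the phase
  expect_equal(velocity_from_autocorr(exp(1i * pi / 3), prf, f0, c0), vn / 3,
               tolerance = 1e-12)
  # zero autocorrelation is an undefined-velocity marker
  expect_true(is.na(velocity_from_autocorr(0 + 0i, prf, f0, c0)))
})

test_that("tone velocities are recovered exactly and wrap per the alias law", {
  f0 <- 31.25e6; prf <- 6e3; c0 <- 1540
  vn <- nyquist_limit(f0, prf, c0)
  tone_at <- function(v) {
    step <- 4 * pi * f0 * v / (c0 * prf)   # phase per intra-pair interval
    paired_tone(step, n_pairs = 16L)
  }
  # sub-Nyquist tones recover to >= 10 significant digits
  for (frac in c(-0.9, -0.5, 0.05, 0.5, 0.999)) {
    v <- frac * vn
    est <- velocity_from_autocorr(lag_one_autocorr_double(tone_at(v)), prf, f0, c0)
    expect_equal(est, v, tolerance = 1e-11)
  }
  # super-Nyquist tones land on v - 2*nN*VN (dense sweep against the oracle)
  for (v in seq(-3.9, 3.9, length.out = 41) * vn) {
    est <- velocity_from_autocorr(lag_one_autocorr_double(tone_at(v)), prf, f0, c0)
    expect_equal(est, wrap_velocity(v, vn)$wrapped, tolerance = 1e-9 * vn)
  }
})

test_that("wall filter rejects DC, passes fast tones, and is polyphase", {
  P <- 32L
  # DC attenuated below 1% of input power
  dc <- matrix(3 + 2i, nrow = 1L, ncol = P)
  out <- wall_filter(dc, 0.05)
  expect_lt(mean(Mod(out)^2) / mean(Mod(dc)^2), 0.01)
  # tone at half the substream Nyquist is preserved within 5%
  k <- P %/% 8L  # substream frequency 0.5 in Nyquist units
  sub <- exp(1i * 2 * pi * (k / (P / 2)) * (0:(P / 2 - 1)))
  x <- matrix(as.vector(rbind(sub, sub)), nrow = 1L)  # same tone on both substreams
  y <- wall_filter(x, 0.05)
  expect_lt(max(Mod(y - x)) / max(Mod(x)), 0.05)
  # filtering interleaved streams separately == interleaving filtered streams
  set.seed(7)
  x <- matrix(complex(real = rnorm(2 * P), imaginary = rnorm(2 * P)), nrow = 2L)
  y <- wall_filter(x, 0.05, polyphase = TRUE)
  even <- seq(1L, P, 2L); odd <- seq(2L, P, 2L)
  expect_equal(y[, even], wall_filter(x[, even], 0.05, polyphase = FALSE),
               tolerance = 1e-12)
  expect_equal(y[, odd], wall_filter(x[, odd], 0.05, polyphase = FALSE),
               tolerance = 1e-12)
  # shape preserved, cutoff validated
  expect_identical(dim(y), dim(x))
  expect_error(wall_filter(x, 0), "between 0 and 1")
  expect_error(wall_filter(x, 1), "between 0 and 1")
  # ensemble in, ensemble out
  ens <- slow_time_ensemble(x, pair_pri = 1e-4, tx_index = 1L, rx_index = 1L)
  expect_s3_class(wall_filter(ens, 0.05), "slow_time_ensemble")
})

test_that("velocity noise at 40 dB SNR stays below 2% of the Nyquist limit", {
  f0 <- 31.25e6; prf <- 6e3; c0 <- 1540
  vn <- nyquist_limit(f0, prf, c0)
  v <- 0.4 * vn
  step <- 4 * pi * f0 * v / (c0 * prf)
  n_mc <- 400L
  set.seed(314)
  tones <- paired_tone(step, 16L)[rep(1L, n_mc), ]
  noise_sd <- sqrt(10^(-40 / 10) / 2)
  tones <- tones + complex(real = rnorm(length(tones), sd = noise_sd),
                           imaginary = rnorm(length(tones), sd = noise_sd))
  est <- velocity_from_autocorr(lag_one_autocorr_double(tones), prf, f0, c0)
  expect_lt(sd(est), 0.02 * vn)
  expect_equal(mean(est), v, tolerance = 0.02 * vn)
})

test_that("doppler_map masks low-magnitude pixels and bounds velocities", {
  set.seed(9)
  P <- 32L
  step <- 0.7
  good <- paired_tone(step, P %/% 2L)
  noise <- matrix(1e-6 * complex(real = rnorm(P), imaginary = rnorm(P)),
                  nrow = 1L)
  ens <- slow_time_ensemble(rbind(good, noise), pair_pri = 1 / 6e3,
                            tx_index = 1L, rx_index = 2L,
                            theta = -7.5, phi = 0)
  m <- doppler_map(ens, 31.25e6, 1540)
  expect_true(m$valid[1])
  expect_false(m$valid[2])
  expect_true(is.na(m$velocity[2]))
  expect_true(m$velocity[1] >= -m$nyquist && m$velocity[1] < m$nyquist)
  expect_equal(m$net_angle, -7.5)
})
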