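test_that("in-phase noiseless field is mirror-symmetric about the midpoint", {
  p <- dipole_field_params(psi = 0, noise_sd = 0, duration = 8, T = 8,
                           grid_spacing = 3)
  field <- gen_dipole_field(p)
  for (k in c(1L, 5L)) {
    fr <- field_frame(field, k)
    mirrored <- fr
    mirrored$x <- -fr$x
    m <- merge(fr, mirrored, by = c("x", "y"), suffixes = c("", ".m"))
    expect_equal(m$u, -m$u.m, tolerance = 1e-12)
    expect_equal(m$v, m$v.m, tolerance = 1e-12)
  }
})

test_that("zero-amplitude field is pure zero-mean noise", {
  p <- dipole_field_params(amplitude = 0, noise_sd = 0.2, duration = 8)
  field <- gen_dipole_field(p)
  n <- nrow(field)
  expect_lt(abs(mean(field$u)), 4 * 0.2 / sqrt(n))
  expect_lt(abs(mean(field$v)), 4 * 0.2 / sqrt(n))
  # and with noise_sd = 0 the field vanishes identically
  p0 <- dipole_field_params(amplitude = 0, noise_sd = 0, duration = 8)
  f0 <- gen_dipole_field(p0)
  expect_true(all(f0$u == 0 & f0$v == 0))
})

test_that("generators are reproducible for a fixed seed", {
  p <- dipole_field_params(psi = 1, seed = 42L, duration = 8)
  expect_identical(gen_dipole_field(p), gen_dipole_field(p))
  expect_identical(gen_divergence_trace(seed = 9L),
                   gen_divergence_trace(seed = 9L))
  expect_false(identical(gen_divergence_trace(seed = 9L)$value,
                         gen_divergence_trace(seed = 10L)$value))
})

test_that("closed-form divergence matches numerical differentiation", {
  p <- dipole_field_params(psi = 0.7, noise_sd = 0, duration = 8)
  h <- 1e-5
  pts <- data.frame(x = c(3, -5, 0, 10, -8.5), y = c(2, 1, 6, -4, 0.5))
  t <- 2.25
  ev <- function(x, y) cellgait:::dipole_field_eval(p, x, y, t)
  num_div <- (ev(pts$x + h, pts$y)$u - ev(pts$x - h, pts$y)$u) / (2 * h) +
    (ev(pts$x, pts$y + h)$v - ev(pts$x, pts$y - h)$v) / (2 * h)
  expect_equal(num_div, dipole_field_divergence(p, pts$x, pts$y, t),
               tolerance = 1e-6)
})

test_that("ring flux around one pinch matches quadrature and is negative when contracting", {
  p <- dipole_field_params(psi = 0, noise_sd = 0, duration = 8,
                           separation = 30, sigma = 4)
  t <- p$T / 4                       # maximal contraction of unit A
  R <- 6
  th <- seq(0, 2 * pi, length.out = 2001L)[-1L]
  cx <- p$center_A[1L]
  f <- cellgait:::dipole_field_eval(p, cx + R * cos(th), R * sin(th), t)
  flux_num <- sum(f$u * cos(th) + f$v * sin(th)) * R * (2 * pi / length(th))
  expect_equal(flux_num, dipole_ring_flux(p, R, t, "A"), tolerance = 1e-3)
  expect_lt(flux_num, 0)             # pinching: inward flow
})

test_that("imposed front-back lag is recovered through the oscillation stage", {
  p <- dipole_field_params(psi = pi / 2, T = 8, duration = 32, seed = 5,
                           noise_sd = 0.02)
  field <- gen_dipole_field(p)
  geom <- dipole_field_geometry(p)
  kymo <- kymograph(divergence_field(field), geom)
  tr <- front_back_traces(kymo, geom)
  # unit B (front) lags unit A (back) by psi T / 2pi = 2 min
  lag <- cross_correlate(tr$back, tr$front)
  expect_true(lag$found)
  expect_lt(abs(lag$lag - p$T * p$psi / (2 * pi)), p$dt + 1e-9)
})

test_that("synthetic traces behave as designed", {
  tr <- gen_divergence_trace(period = 6, amplitude = 1, noise_sd = 0,
                             duration = 24, dt = 0.5)
  expect_equal(mean(tr$value), 0, tolerance = 1e-10)
  per_idx <- 6 / 0.5
  expect_equal(tr$value[seq_len(nrow(tr) - per_idx)],
               tr$value[seq_len(nrow(tr) - per_idx) + per_idx],
               tolerance = 1e-10)
  flat <- gen_divergence_trace(period = 5, amplitude = 0, noise_sd = 0.3,
                               seed = 3)
  expect_false(find_period(autocorrelate(flat))$found)
  noisy <- gen_divergence_trace(period = 5, amplitude = 1, noise_sd = 0.2,
                                duration = 36, dt = 0.5, seed = 11)
  pe <- find_period(autocorrelate(noisy))
  expect_true(pe$found)
  expect_lt(abs(pe$period - 5), 0.5 + 1e-9)
  sp <- gen_speed_trace(mean_v = 0.4, period = 8, amplitude = 0.2,
                        noise_sd = 0.02, seed = 2)
  expect_equal(mean(sp$value), 0.4, tolerance = 0.05)
})

test_that("generator rejects invalid parameters", {
  expect_error(dipole_field_params(T = -1), "positive")
  expect_error(dipole_field_params(dt = 0), "positive")
  expect_error(dipole_field_params(sigma = 0), "positive")
  expect_error(gen_divergence_trace(period = 10, duration = 15),
               "at least 2")
})
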