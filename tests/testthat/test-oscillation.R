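test_that("grid divergence reproduces analytic fields", {
  # uniform field: zero divergence
  f1 <- fun_field(function(x, y) list(u = rep(2, length(x)),
                                      v = rep(-1, length(x))))
  d1 <- divergence_field(f1)
  inner <- d1$frames[[1L]][3:(length(d1$y) - 2), 3:(length(d1$x) - 2)]
  expect_equal(max(abs(inner)), 0, tolerance = 1e-12)
  # pure dilation u = k x: divergence 2k everywhere
  k <- 0.07
  f2 <- fun_field(function(x, y) list(u = k * x, v = k * y))
  d2 <- divergence_field(f2)
  inner <- d2$frames[[1L]][3:(length(d2$y) - 2), 3:(length(d2$x) - 2)]
  expect_equal(mean(inner), 2 * k, tolerance = 1e-10)
  expect_lt(max(abs(inner - 2 * k)), 1e-10)
})

test_that("grid divergence of the Gaussian pinch matches the closed form", {
  p <- dipole_field_params(psi = 0, noise_sd = 0, duration = 4, T = 8,
                           sigma = 5, grid_spacing = 5 / 8)
  field <- gen_dipole_field(p)
  divf <- divergence_field(field)
  k <- 5L                                   # t = T/4, maximal contraction
  g <- expand.grid(x = divf$x, y = divf$y)
  truth <- dipole_field_divergence(p, g$x, g$y, (k - 1L) * p$dt)
  est <- divf$frames[[k]][cbind(match(g$y, divf$y), match(g$x, divf$x))]
  # exclude the kernel cusp at each centre (direction discontinuity)
  rA <- sqrt((g$x - p$center_A[1L])^2 + g$y^2)
  rB <- sqrt((g$x - p$center_B[1L])^2 + g$y^2)
  keep <- rA > p$sigma / 2 & rB > p$sigma / 2
  expect_lt(sqrt(mean((est[keep] - truth[keep])^2)) /
              sqrt(mean(truth[keep]^2)), 0.05)
  keep <- rA > p$sigma & rB > p$sigma
  rms_err <- sqrt(mean((est[keep] - truth[keep])^2))
  expect_lt(rms_err / sqrt(mean(truth[keep]^2)), 0.05)
})

test_that("divergence_field rejects degenerate geometry", {
  bad <- vector_field_series(
    data.frame(frame = 1L, x = 1:10, y = rep(0, 10), u = 0, v = 0), dt = 1)
  expect_error(divergence_field(bad), "degenerate")
})

test_that("autocorrelation is coefficient-normalized and matches the circular oracle", {
  n <- 70L; P <- 10L                        # integer number of cycles
  x <- cos(2 * pi * (0:(n - 1L)) / P)
  tr <- cellgait:::new_trace((0:(n - 1L)) * 0.5, x, dt = 0.5)
  ac <- autocorrelate(tr)
  expect_identical(ac$value[1L], 1)
  # circular oracle: value 1 at one full period for integer-period sampling
  circ <- function(x, k) {
    xc <- x - mean(x)
    sum(xc * xc[((seq_along(xc) - 1L + k) %% length(xc)) + 1L]) / sum(xc^2)
  }
  expect_equal(circ(x, P), 1, tolerance = 1e-10)
  # the biased linear estimator tapers the circular value by (n - k)/n
  expect_equal(ac$value[P + 1L], (n - P) / n * circ(x, P), tolerance = 1e-9)
  expect_lte(max(abs(ac$value)), 1 + 1e-12)
})

test_that("white-noise correlogram stays within the significance band", {
  tr <- gen_divergence_trace(period = 5, amplitude = 0, noise_sd = 1,
                             duration = 36, dt = 0.5, seed = 7)
  ac <- autocorrelate(tr)
  expect_lt(max(abs(ac$value[-1L])), 3 / sqrt(attr(ac, "n")))
})

test_that("constant traces give a degenerate correlogram and no period", {
  tr <- cellgait:::new_trace(0:20, rep(3.5, 21L), dt = 1)
  ac <- autocorrelate(tr)
  expect_true(attr(ac, "degenerate"))
  expect_identical(ac$value[1L], 1)
  expect_false(find_period(ac)$found)
})

test_that("find_period selects the first qualifying peak", {
  n <- 72L
  x <- cos(2 * pi * (0:(n - 1L)) / 10)
  tr <- cellgait:::new_trace((0:(n - 1L)), x, dt = 1)
  pe <- find_period(autocorrelate(tr))
  expect_true(pe$found)
  expect_equal(pe$period, 10)
})

test_that("find_period is invariant to scaling and offsets", {
  tr <- gen_divergence_trace(period = 7, amplitude = 1, noise_sd = 0.15,
                             duration = 42, dt = 0.5, seed = 13)
  p1 <- find_period(autocorrelate(tr))
  tr2 <- tr; tr2$value <- 50 * tr$value + 12
  p2 <- find_period(autocorrelate(tr2))
  expect_equal(p1$period, p2$period)
  expect_equal(p1$peak_value, p2$peak_value, tolerance = 1e-12)
})

test_that("white-noise false positives stay below ten percent", {
  found <- vapply(1:100, function(i) {
    tr <- gen_divergence_trace(period = 5, amplitude = 0, noise_sd = 1,
                               duration = 36, dt = 0.5, seed = 5000 + i)
    find_period(autocorrelate(tr))$found
  }, logical(1L))
  expect_lt(mean(found), 0.10)
})

test_that("cross-correlation recovers imposed lags with the documented sign", {
  tr <- gen_divergence_trace(period = 8, amplitude = 1, noise_sd = 0,
                             duration = 32, dt = 0.5, seed = 1)
  self <- cross_correlate(tr, tr)
  expect_equal(self$lag, 0)
  expect_equal(self$value, 1, tolerance = 1e-9)
  # back delayed by 2 samples: front leads -> positive lag
  n <- nrow(tr)
  shifted <- tr
  shifted$value <- c(tr$value[c(n - 1L, n)], tr$value[seq_len(n - 2L)])
  cc <- cross_correlate(tr, shifted)
  expect_equal(cc$lag, 2 * 0.5)
  # antisymmetry: cc(f, g)(tau) = cc(g, f)(-tau)
  cc_rev <- cross_correlate(shifted, tr)
  expect_equal(cc_rev$lag, -cc$lag)
  expect_equal(cc_rev$value, cc$value, tolerance = 1e-9)
})

test_that("generator pairs with psi = pi/2 give lag T/4", {
  T <- 8; dt <- 0.5
  front <- gen_divergence_trace(period = T, amplitude = 1, noise_sd = 0.1,
                                duration = 40, dt = dt, seed = 21)
  back <- gen_divergence_trace(period = T, amplitude = 1, noise_sd = 0.1,
                               duration = 40, dt = dt, seed = 22,
                               phase = pi / 2)
  cc <- cross_correlate(front, back)
  expect_true(cc$found)
  expect_lt(abs(cc$lag - T / 4), dt + 1e-9)
})

test_that("phase shift wraps correctly", {
  expect_equal(phase_shift(0, 8), 0)
  expect_equal(phase_shift(4, 8), pi)
  expect_equal(phase_shift(2, 8), pi / 2)
  expect_equal(phase_shift(6, 8), -pi / 2)   # 3T/4 wraps to -pi/2
  expect_equal(phase_shift(-2, 8), -pi / 2)
  expect_error(phase_shift(1, 0), "positive")
})

test_that("speed series separates instantaneous and persistent speed", {
  # straight constant-velocity track
  tpos <- data.frame(x = 0.3 * (0:20), y = 0)
  ss <- speed_series(tpos, axis = c(1, 0), dt = 1)
  expect_equal(ss$persistent, 0.3, tolerance = 1e-12)
  expect_true(all(abs(ss$instantaneous$value - 0.3) < 1e-12))
  # symmetric back-and-forth: zero persistent speed
  osc <- data.frame(x = sin(2 * pi * (0:40) / 10), y = 0)
  so <- speed_series(osc, axis = c(1, 0), dt = 1)
  expect_equal(so$persistent, 0, tolerance = 1e-12)
  expect_true(so$period$found)
  expect_equal(so$period$period, 10, tolerance = 1)
})
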