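# Reduced integration settings keep these tests fast; the acceptance
# suite runs the full-resolution study configurations.
fast <- function(mode, ...) {
  bead_model(mode, ..., steps_per_cycle = 600L, n_transient = 2L,
             n_cycles = 5L)
}

test_that("gait stays within bounds and lags unit B by psi", {
  m <- bead_model("swimmer", T = 8, d = 0.5, psi = pi / 3)
  t <- seq(0, 16, by = 0.05)
  g <- gait(m, t)
  expect_true(all(g$L_A >= m$D - 1e-12 & g$L_A <= m$D + m$d + 1e-12))
  expect_true(all(g$L_B >= m$D - 1e-12 & g$L_B <= m$D + m$d + 1e-12))
  # B equals A delayed by psi T / 2pi
  delay <- m$psi * m$T / (2 * pi)
  gB <- gait(m, t - delay)
  expect_equal(g$L_B, gB$L_A, tolerance = 1e-10)
  # psi = 0: identical units
  g0 <- gait(bead_model("swimmer", psi = 0), t)
  expect_equal(g0$L_A, g0$L_B, tolerance = 1e-12)
})

test_that("square gait visits the four alternating states in order", {
  m <- bead_model("swimmer", T = 8, d = 0.5, psi = pi / 2,
                  waveform = "square", square_smooth = 0.05)
  # sample mid-quadrant phases over one cycle
  t <- c(1, 3, 5, 7)
  g <- gait(m, t)
  state <- function(L) ifelse(L > m$D + m$d / 2, "long", "short")
  states <- paste(state(g$L_A), state(g$L_B))
  expect_equal(states, c("long short", "long long",
                         "short long", "short short"))
  # time reversal equals the psi = -pi/2 gait up to a half-period shift
  mneg <- bead_model("swimmer", T = 8, d = 0.5, psi = -pi / 2,
                     waveform = "square", square_smooth = 0.05)
  tt <- seq(0.2, 7.8, by = 0.2)
  g_rev <- gait(m, -tt)
  g_neg <- gait(mneg, tt + m$T / 2)
  expect_equal(g_rev$L_A, g_neg$L_A, tolerance = 1e-9)
  expect_equal(g_rev$L_B, g_neg$L_B, tolerance = 1e-9)
})

test_that("reciprocal gaits produce no net motion (scallop theorem)", {
  for (mode in c("swimmer", "crawler")) {
    tr <- simulate(fast(mode, psi = 0))
    m <- attr(tr, "model")
    expect_lt(abs(mean_velocity(tr)) * m$T / m$d, 1e-3)
    # square waveform is reciprocal at psi = 0 as well
    trs <- simulate(fast(mode, psi = 0, waveform = "square"))
    expect_lt(abs(mean_velocity(trs)) * m$T / m$d, 1e-3)
  }
})

test_that("velocity is odd under reversal of the phase shift", {
  for (mode in c("swimmer", "crawler")) {
    Vp <- mean_velocity(simulate(fast(mode, psi = pi / 2)))
    Vm <- mean_velocity(simulate(fast(mode, psi = -pi / 2)))
    expect_gt(abs(Vp), 0)
    expect_lt(abs(Vp + Vm), 1e-4 * abs(Vp) + 1e-13)
  }
})

test_that("the swimmer is force-free at every sampled instant", {
  tr <- simulate(fast("swimmer", psi = pi / 2))
  total <- abs(tr$F1 + tr$F2 + tr$F3 + tr$F4)
  expect_lt(max(total), 1e-10 * max(abs(c(tr$F1, tr$F2, tr$F3, tr$F4))))
})

test_that("cycle displacement is converged in the timestep", {
  for (mode in c("swimmer", "crawler")) {
    V1 <- mean_velocity(simulate(bead_model(
      mode, psi = pi / 2, steps_per_cycle = 500L,
      n_transient = 2L, n_cycles = 4L)))
    V2 <- mean_velocity(simulate(bead_model(
      mode, psi = pi / 2, steps_per_cycle = 1000L,
      n_transient = 2L, n_cycles = 4L)))
    expect_lt(abs(V2 - V1) / abs(V2), 0.01)
  }
})

test_that("velocity response is odd in psi and vanishes at zero", {
  m <- fast("crawler")
  vr <- velocity_response(m, psi_values = c(-2, -1, 0, 1, 2))
  expect_lt(abs(vr$V[3L]), 1e-14)
  expect_lt(max(abs(vr$V[1:2] + rev(vr$V[4:5]))), 1e-3 * max(abs(vr$V)))
  expect_gt(max(abs(vr$V)), 0)
})

test_that("instantaneous speed oscillates at the gait period about a non-zero mean", {
  tr <- simulate(fast("swimmer", psi = pi / 2, T = 8))
  st <- speed_trace(tr)
  pe <- find_period(autocorrelate(st))
  expect_true(pe$found)
  expect_lt(abs(pe$period - 8), 8 / 60)   # within one trace sample
  expect_gt(abs(mean_velocity(tr)), 0)
  # psi = 0: the mirror-symmetric swimmer has no centre motion at all
  tr0 <- simulate(fast("swimmer", psi = 0))
  m0 <- attr(tr0, "model")
  expect_lt(max(abs(tr0$V)) * m0$T / m0$d, 1e-3)
})

test_that("model D-Q cycles have finite area only for phase-shifted gaits", {
  dq0 <- model_multipoles(simulate(fast("crawler", psi = 0)))
  dqq <- model_multipoles(simulate(fast("crawler", psi = pi / 2)))
  a0 <- cycle_area(dq0$D, dq0$Q, 8, attr(dq0, "dt"))
  aq <- cycle_area(dqq$D, dqq$Q, 8, attr(dqq, "dt"))
  expect_gt(aq$normalized, 10 * a0$normalized)
})

test_that("configuration validation and power-law fits work", {
  expect_error(bead_model("crawler", D = 50, r = 40), "overlap")
  expect_error(bead_model("swimmer", T = -2), "positive")
  expect_true(bead_model("crawler")$regime_ok)
  expect_false(bead_model("crawler", d = 3)$regime_ok)
  x <- c(1, 2, 4, 8)
  expect_equal(fit_power_law(x, 5 / x^2)$slope, -2, tolerance = 1e-10)
  expect_error(fit_power_law(x, c(1, 0, 1, 1)), "zero")
})
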