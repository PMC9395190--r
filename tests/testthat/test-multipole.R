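test_that("dipole tensor matches hand-computed sums", {
  # radial inward flow on a symmetric 4-point set
  fr <- make_frame(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                   u = -0.1 * c(1, -1, 0, 0), v = -0.1 * c(0, 0, 1, -1))
  S <- dipole_tensor(fr, c(0, 0))
  expect_equal(S, diag(c(-0.2, -0.2)), tolerance = 1e-14)
  # rigid rotation: symmetrization removes the antisymmetric part
  om <- 0.3
  fr_rot <- make_frame(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                       u = -om * c(0, 0, 1, -1), v = om * c(1, -1, 0, 0))
  expect_equal(dipole_tensor(fr_rot, c(0, 0)), matrix(0, 2, 2),
               tolerance = 1e-14)
  # zero field
  fr0 <- make_frame(x = c(1, 2, 3), y = c(0, 1, 2), u = 0, v = 0)
  expect_equal(dipole_tensor(fr0, c(0, 0)), matrix(0, 2, 2))
  expect_error(dipole_tensor(fr0[0, ], c(0, 0)), "empty")
})

test_that("quadrupole tensor matches hand-computed sums", {
  # mirror-symmetric two-point pinch: dipole without quadrupole
  fr <- make_frame(x = c(2, -2), y = c(0, 0), u = c(-0.1, 0.1), v = c(0, 0))
  S <- dipole_tensor(fr, c(0, 0))
  Q <- quadrupole_tensor(fr, c(0, 0))
  expect_equal(S[1, 1], -0.4, tolerance = 1e-14)
  expect_equal(Q[1, 1, 1], 0, tolerance = 1e-14)
  # off-centre single pinch: dipole and quadrupole
  fr2 <- make_frame(x = c(1, 3), y = c(0, 0), u = c(0.1, -0.1), v = c(0, 0))
  S2 <- dipole_tensor(fr2, c(0, 0))
  Q2 <- quadrupole_tensor(fr2, c(0, 0))
  expect_equal(S2[1, 1], -0.2, tolerance = 1e-14)
  expect_equal(Q2[1, 1, 1], -0.8, tolerance = 1e-14)
  # zero field
  expect_equal(quadrupole_tensor(make_frame(1:3, 1:3, 0, 0), c(0, 0)),
               array(0, c(2, 2, 2)))
})

test_that("tensors are symmetric, translation-covariant and linear", {
  set.seed(1)
  fr <- make_frame(x = rnorm(40), y = rnorm(40),
                   u = rnorm(40), v = rnorm(40))
  S <- dipole_tensor(fr, c(0.3, -0.2))
  expect_identical(S[1, 2], S[2, 1])
  # translating samples and centre together changes nothing
  sh <- c(5.5, -3.1)
  fr_t <- fr; fr_t$x <- fr$x + sh[1]; fr_t$y <- fr$y + sh[2]
  expect_equal(dipole_tensor(fr_t, c(0.3, -0.2) + sh), S, tolerance = 1e-12)
  expect_equal(quadrupole_tensor(fr_t, c(0.3, -0.2) + sh),
               quadrupole_tensor(fr, c(0.3, -0.2)), tolerance = 1e-12)
  # superposed fields: tensors add
  fr2 <- fr; fr2$u <- rnorm(40); fr2$v <- rnorm(40)
  fr_sum <- fr; fr_sum$u <- fr$u + fr2$u; fr_sum$v <- fr$v + fr2$v
  expect_equal(dipole_tensor(fr_sum, c(0, 0)),
               dipole_tensor(fr, c(0, 0)) + dipole_tensor(fr2, c(0, 0)),
               tolerance = 1e-12)
})

test_that("principal components follow the eigenvalue conventions", {
  S <- diag(c(-5, 1))
  Q0 <- array(0, c(2, 2, 2))
  pc <- principal_components(S, Q0, axis = c(1, 0))
  expect_equal(pc$D, -5)
  expect_equal(abs(pc$dipole_axis), c(1, 0))
  expect_false(pc$degenerate)
  # signed-largest convention picks +1 instead
  pc_s <- principal_components(S, Q0, axis = c(1, 0), mode = "signed")
  expect_equal(pc_s$D, 1)
  # isotropic tensor: magnitude reported, axis flagged degenerate
  pc_i <- principal_components(diag(c(-2, -2)), Q0, axis = c(1, 0))
  expect_equal(abs(pc_i$D), 2)
  expect_true(pc_i$degenerate)
  # axis-contracted quadrupole: Q_xxx along x
  Qt <- array(0, c(2, 2, 2)); Qt[1, 1, 1] <- -0.8
  expect_equal(principal_components(S, Qt, axis = c(1, 0))$Q, -0.8)
})

test_that("field scaling propagates as lambda to D, Q and lambda^2 to area", {
  p <- dipole_field_params(psi = pi / 2, T = 8, duration = 16, seed = 2,
                           noise_sd = 0, grid_spacing = 3)
  field <- gen_dipole_field(p)
  geom <- dipole_field_geometry(p)
  lam <- 2.5
  field2 <- field; field2$u <- lam * field$u; field2$v <- lam * field$v
  dq1 <- dq_trajectory(field, geom, radii = 1)
  dq2 <- dq_trajectory(field2, geom, radii = 1)
  expect_equal(dq2$D, lam * dq1$D, tolerance = 1e-10)
  expect_equal(dq2$Q, lam * dq1$Q, tolerance = 1e-10)
  a1 <- cycle_area(dq1$D, dq1$Q, p$T, p$dt)
  a2 <- cycle_area(dq2$D, dq2$Q, p$T, p$dt)
  expect_equal(a2$absolute, lam^2 * a1$absolute, tolerance = 1e-10)
  expect_equal(a2$normalized, a1$normalized, tolerance = 1e-10)
})

test_that("shoelace cycle area reproduces the ellipse and degenerates", {
  A <- 3; B <- 0.7; n <- 100L; T <- 10
  t <- (0:(n - 1L)) * T / n
  D <- A * cos(2 * pi * t / T); Q <- B * sin(2 * pi * t / T)
  ca <- cycle_area(D, Q, period = T, dt = T / n)
  expect_equal(ca$absolute, pi * A * B, tolerance = 0.01 * pi * A * B)
  expect_equal(ca$n_cycles, 1L)
  # collinear trajectory: exactly zero area
  ca0 <- cycle_area(D, 0.3 * D, period = T, dt = T / n)
  expect_lt(ca0$absolute, 1e-12 * A^2)
  expect_error(cycle_area(D, Q, period = 3 * T / n, dt = T / n), "4 points")
  expect_error(cycle_area(D[1:3], Q[1:3], period = T, dt = T / n), "shorter")
  expect_warning(cycle_area(D, Q, period = NA, dt = T / n), "one cycle")
})

test_that("two-dipole fields give the expected D-Q structure", {
  base <- function(psi, seed) {
    dipole_field_params(psi = psi, T = 8, duration = 16, dt = 0.5,
                        seed = seed, noise_sd = 0.01, grid_spacing = 3)
  }
  geom0 <- dipole_field_geometry(base(0, 4))
  dq0 <- dq_trajectory(gen_dipole_field(base(0, 4)), geom0, radii = 1)
  dqq <- dq_trajectory(gen_dipole_field(base(pi / 2, 4)), geom0, radii = 1)
  # in phase: Q stays at the noise level; in quadrature it oscillates
  expect_lt(max(abs(dq0$Q)), 0.3 * max(abs(dqq$Q)))
  # phase-shifted gait encloses far more area than the reciprocal one
  a0 <- cycle_area(dq0$D, dq0$Q, 8, 0.5)
  aq <- cycle_area(dqq$D, dqq$Q, 8, 0.5)
  expect_gt(aq$normalized, 5 * a0$normalized)
})

test_that("uniaxial two-pinch fields align the dipole axis with the unit line", {
  # two uniaxial contraction units at (-8, 0) and (8, 0), pulling along x
  g <- expand.grid(x = seq(-20, 20, by = 2), y = seq(-20, 20, by = 2))
  pinch_u <- function(cx, s) -s * (g$x - cx) * exp(-((g$x - cx)^2 + g$y^2) / 18)
  frames <- lapply(1:8, function(k) {
    ph <- 2 * pi * (k - 1) / 8
    data.frame(frame = k, x = g$x, y = g$y,
               u = pinch_u(-8, sin(ph)) + pinch_u(8, sin(ph)),
               v = 0)
  })
  field <- vector_field_series(do.call(rbind, frames), dt = 1)
  geom <- cell_geometry_series(data.frame(
    frame = 1:8, cx = 0, cy = 0, ax = 1, ay = 0,
    front_x = 8, front_y = 0, back_x = -8, back_y = 0), dt = 1)
  dq <- dq_trajectory(field, geom, radii = 1)
  strong <- abs(dq$D) > 0.5 * max(abs(dq$D))
  ang <- acos(pmin(abs(dq$axis_x[strong]), 1)) * 180 / pi
  expect_lt(stats::median(ang), 10)
})

test_that("dipole alignment angles behave at the extremes", {
  dq <- data.frame(frame = 1:3, t = 0:2, radius = 1, cutoff_um = Inf,
                   D = 1, Q = 0, axis_x = c(1, 0, sqrt(0.5)),
                   axis_y = c(0, 1, sqrt(0.5)), degenerate = FALSE)
  class(dq) <- c("dq_trajectory", "data.frame")
  al <- dipole_alignment(dq, motion = c(1, 0))
  expect_equal(al$angles, c(0, 90, 45), tolerance = 1e-10)
})
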