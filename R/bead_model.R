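#' Minimal bead model of a cell driven by two oscillating force dipoles
#'
#' Configures an idealized crawling or swimming cell: four collinear beads
#' of radius `a` forming two dipolar units ("A" at the back, "B" at the
#' front) whose lengths oscillate between `D` and `D + d` with period `T`,
#' unit B lagging unit A by the phase shift `psi`.  The unit centers are
#' held a distance `r` apart, so the shape of the assembly is fully
#' prescribed by the gait and only rigid translation is free.
#'
#' Two transmission modes are available:
#' \describe{
#'   \item{`swimmer`}{the beads are immersed in a Newtonian fluid and
#'     interact hydrodynamically through an Oseen-type `1/distance`
#'     mobility kernel with self-mobility `1/(6 pi eta a)`.  The assembly
#'     is force-free at every instant.  Net swimming obeys the scallop
#'     theorem (no motion for `psi = 0`) and scales as `d^2 / T` at small
#'     amplitude.}
#'   \item{`crawler`}{no hydrodynamics; the beads adhere to a linear
#'     elastic matrix through bonds of stiffness `bond_stiffness` that
#'     turn over with unbinding rate `k_off` and mechanosensitivity length
#'     `delta_off`.  In the fast-binding, small-force limit this gives a
#'     slip law `F = xi0 * w / (1 + |w| / v_adh)` with friction
#'     `xi0 = bond_stiffness / k_off` and adhesion velocity scale
#'     `v_adh = delta_off * k_off`.  The matrix couples the beads through a
#'     `1/distance` elastic compliance kernel (shear modulus `mu`),
#'     so the two units interact through the deformation they create;
#'     this coupling is what allows a phase-shifted gait to rectify into
#'     net crawling.  Transmitted forces sum to zero at every instant.}
#' }
#'
#' @param mode `"crawler"` or `"swimmer"`.
#' @param a bead radius (um).
#' @param D dipole rest length (um).
#' @param d oscillation amplitude (um); unit length oscillates in
#'   `[D, D + d]`.
#' @param r distance between the two unit centers (um).
#' @param T oscillation period (min).
#' @param psi phase shift of unit B relative to unit A, in `(-pi, pi]`
#'   (radians).  `psi = 0` is a reciprocal gait.
#' @param waveform `"sinusoid"` (default) or `"square"`; the square wave is
#'   smoothed over a fraction `square_smooth` of the period and visits the
#'   four alternating contraction/extension states of the idealized cycle.
#' @param square_smooth smoothing parameter of the square waveform
#'   (dimensionless, default 0.1).
#' @param eta fluid viscosity (arbitrary force units; cancels from swimmer
#'   velocities).
#' @param mu matrix shear modulus (force units consistent with
#'   `bond_stiffness`).
#' @param k_off adhesion unbinding rate at zero force (1/min).
#' @param delta_off bond mechanosensitivity length (um);
#'   `v_adh = delta_off * k_off`.
#' @param bond_stiffness adhesion bond stiffness per bead (force/um).  The
#'   default, together with `mu` and `a`, sets the adhesion-matrix
#'   relaxation time `tau_m = bond_stiffness / (k_off * 6 pi mu a)` to one
#'   minute, the order of the matrix recoil time observed after local
#'   detachment.
#' @param steps_per_cycle integration steps per gait cycle.
#' @param n_transient cycles discarded before averaging.
#' @param n_cycles cycles averaged for the mean velocity.
#' @return An object of class `bead_model` (a validated parameter list
#'   with derived quantities `v_adh`, `xi0`, `tau_m` and a small-amplitude
#'   regime flag `regime_ok` asserting `d << a << D << r`).
#' @seealso [simulate.bead_model()], [gait()], [velocity_response()],
#'   [sweep_velocity()]
#' @examples
#' m <- bead_model("swimmer", T = 8, d = 0.5, psi = pi / 2)
#' tr <- simulate(m)
#' mean_velocity(tr)
#' @export
bead_model <- function(mode = c("crawler", "swimmer"),
                       a = 1, D = 10, d = 0.5, r = 60,
                       T = 8, psi = pi / 2,
                       waveform = c("sinusoid", "square"),
                       square_smooth = 0.1,
                       eta = 1, mu = 1,
                       k_off = 10, delta_off = 0.1,
                       bond_stiffness = 60 * pi * mu * a,
                       steps_per_cycle = 2000,
                       n_transient = 3, n_cycles = 10) {
  mode <- match.arg(mode)
  waveform <- match.arg(waveform)
  for (nm in c("a", "D", "r", "T", "eta", "mu", "k_off", "delta_off",
               "bond_stiffness")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("`", nm, "` must be a single positive number")
    }
  }
  if (d < 0) stop("`d` must be non-negative")
  if (D + d >= r) stop("units overlap: need D + d < r")
  psi <- wrap_angle(psi)
  structure(list(
    mode = mode, a = a, D = D, d = d, r = r, T = T, psi = psi,
    waveform = waveform, square_smooth = square_smooth,
    eta = eta, mu = mu, k_off = k_off, delta_off = delta_off,
    bond_stiffness = bond_stiffness,
    v_adh = delta_off * k_off,
    xi0 = bond_stiffness / k_off,
    tau_m = bond_stiffness / (k_off * 6 * pi * mu * a),
    regime_ok = (d / D <= 0.05 && a / D <= 0.2 && r / D >= 5),
    steps_per_cycle = as.integer(steps_per_cycle),
    n_transient = as.integer(n_transient),
    n_cycles = as.integer(n_cycles)
  ), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model: %s> a=%g D=%g d=%g r=%g um; T=%g min; psi=%.3f rad; %s gait\n",
              x$mode, x$a, x$D, x$d, x$r, x$T, x$psi, x$waveform))
  if (x$mode == "crawler") {
    cat(sprintf("  adhesion: k_off=%g /min, delta_off=%g um (v_adh=%g um/min), tau_m=%g min\n",
                x$k_off, x$delta_off, x$v_adh, x$tau_m))
  }
  if (!x$regime_ok) cat("  note: outside small-amplitude regime d<<a<<D<<r\n")
  invisible(x)
}

wrap_angle <- function(psi) {
  psi <- (psi + pi) %% (2 * pi) - pi
  if (psi == -pi) psi <- pi
  psi
}

# dimensionless waveform s(theta) in [0, 1] and its derivative
gait_shape <- function(theta, waveform, eps) {
  if (waveform == "sinusoid") {
    list(s = (1 - cos(theta)) / 2, ds = sin(theta) / 2)
  } else {
    z <- sin(theta) / eps
    list(s = (1 + tanh(z)) / 2,
         ds = cos(theta) / (2 * eps) / cosh(z)^2)
  }
}

#' Target actuator lengths of the two dipole units
#'
#' @param model a [bead_model()].
#' @param t time or vector of times (min).
#' @return Data frame with columns `t`, `L_A`, `L_B` (um) and rate columns
#'   `dL_A`, `dL_B` (um/min).  Lengths stay in `[D, D + d]`; unit B lags
#'   unit A by `psi * T / (2 pi)`.
#' @export
gait <- function(model, t) {
  w <- 2 * pi / model$T
  sa <- gait_shape(w * t, model$waveform, model$square_smooth)
  sb <- gait_shape(w * t - model$psi, model$waveform, model$square_smooth)
  data.frame(t = t,
             L_A = model$D + model$d * sa$s,
             L_B = model$D + model$d * sb$s,
             dL_A = model$d * sa$ds * w,
             dL_B = model$d * sb$ds * w)
}

# bead offsets from the assembly centroid, and their rates
bead_offsets <- function(model, t) {
  g <- gait(model, t)
  cbind(-model$r / 2 - g$L_A / 2, -model$r / 2 + g$L_A / 2,
        model$r / 2 - g$L_B / 2,  model$r / 2 + g$L_B / 2)
}
bead_offset_rates <- function(model, t) {
  g <- gait(model, t)
  cbind(-g$dL_A / 2, g$dL_A / 2, -g$dL_B / 2, g$dL_B / 2)
}

# 1/distance kernels on the line of centers
oseen_matrix <- function(off, eta, a) {
  n <- length(off)
  rho <- abs(outer(off, off, "-"))
  M <- 1 / (4 * pi * eta * rho)
  diag(M) <- 1 / (6 * pi * eta * a)
  M
}
kernel_dot <- function(off, u, mu) {
  rho <- outer(off, off, "-")
  rhod <- outer(u, u, "-")
  Gd <- -sign(rho) * rhod / (4 * pi * mu * rho^2)
  diag(Gd) <- 0
  Gd
}

# swimmer: instantaneous center velocity and bead forces from shape + rates
swimmer_state <- function(model, t) {
  off <- drop(bead_offsets(model, t))
  u <- drop(bead_offset_rates(model, t))
  M <- oseen_matrix(off, model$eta, model$a)
  A <- rbind(M[2, ] - M[1, ], M[3, ] - M[2, ], M[4, ] - M[3, ], rep(1, 4))
  b <- c(u[2] - u[1], u[3] - u[2], u[4] - u[3], 0)
  F <- solve(A, b)
  list(W = mean(M %*% F), F = F)
}

# crawler: precompute per-time-point kernel data over one gait cycle
crawler_tables <- function(model, h) {
  nspc <- model$steps_per_cycle
  ts <- (seq_len(2L * nspc) - 1L) * (h / 2)
  lapply(ts, function(t) {
    off <- drop(bead_offsets(model, t))
    u <- drop(bead_offset_rates(model, t))
    G <- oseen_matrix(off, model$mu, model$a)
    sol <- solve(G, cbind(diag(4), rep(1, 4)))
    list(Ginv = sol[, 1:4], Gi1 = sol[, 5], Gd = kernel_dot(off, u, model$mu),
         u = u)
  })
}

# slip velocity from transmitted force, F = xi0 w / (1 + |w|/v_adh)
slip_from_force <- function(F, xi0, v_adh) {
  denom <- xi0 - abs(F) / v_adh
  if (any(denom <= 0.1 * xi0)) {
    stop("adhesion linearization overloaded (|F| approaching xi0*v_adh); ",
         "reduce d or increase delta_off")
  }
  F / denom
}

# d/dt of transmitted forces and instantaneous center velocity
crawler_rhs <- function(F, tab, xi0, v_adh) {
  b <- tab$u - slip_from_force(F, xi0, v_adh) - drop(tab$Gd %*% F)
  y1 <- drop(tab$Ginv %*% b)
  W <- -sum(y1) / sum(tab$Gi1)
  list(Fdot = y1 + W * tab$Gi1, W = W)
}

#' Simulate a bead-model trajectory
#'
#' Integrates the configured gait over `n_transient + n_cycles` periods
#' (fixed-step 4th order Runge-Kutta for the crawler's bond-force state;
#' Simpson quadrature for the shape-prescribed swimmer) and returns the
#' center position, instantaneous velocity and transmitted bead forces.
#' The cycle-averaged velocity is measured over the last `n_cycles`
#' periods.
#'
#' @param object a [bead_model()].
#' @param nsim unused (one deterministic trajectory).
#' @param seed unused (the model is deterministic); accepted for
#'   compatibility with [stats::simulate()].
#' @param keep_every store every `keep_every`-th step (default 10) in the
#'   returned data frame; the velocity average always uses every step.
#' @param ... ignored.
#' @return A `bead_trajectory`: data frame with columns `t`, `X` (center
#'   position, um), `V` (instantaneous center velocity, um/min) and bead
#'   forces `F1..F4`, with attributes `V_mean` (cycle-averaged velocity
#'   over the analysis window, um/min) and `model`.
#' @export
simulate.bead_model <- function(object, nsim = 1, seed = NULL,
                                keep_every = 10L, ...) {
  model <- object
  nspc <- model$steps_per_cycle
  h <- model$T / nspc
  n_tot <- (model$n_transient + model$n_cycles) * nspc
  keep <- seq(1L, n_tot, by = keep_every)
  X <- 0; X_mark <- NA_real_
  out_t <- out_X <- out_V <- numeric(length(keep))
  out_F <- matrix(0, length(keep), 4L)
  ki <- 1L

  if (model$mode == "swimmer") {
    # center velocity depends on time only; Simpson rule per step
    states <- lapply((seq_len(2L * nspc) - 1L) * (h / 2),
                     function(t) swimmer_state(model, t))
    for (k in seq_len(n_tot)) {
      j0 <- 2L * ((k - 1L) %% nspc) + 1L      # index of t_k in half-step table
      j1 <- j0 + 1L                            # t_k + h/2
      j2 <- if (j0 + 2L > 2L * nspc) 1L else j0 + 2L
      st <- states[[j0]]
      X <- X + h / 6 * (st$W + 4 * states[[j1]]$W + states[[j2]]$W)
      if (k == model$n_transient * nspc) X_mark <- X
      if (ki <= length(keep) && k == keep[ki]) {
        out_t[ki] <- (k - 1L) * h; out_X[ki] <- X; out_V[ki] <- st$W
        out_F[ki, ] <- st$F; ki <- ki + 1L
      }
    }
  } else {
    tabs <- crawler_tables(model, h)
    F <- rep(0, 4)
    for (k in seq_len(n_tot)) {
      j0 <- 2L * ((k - 1L) %% nspc) + 1L
      j1 <- j0 + 1L
      j2 <- if (j0 + 2L > 2L * nspc) 1L else j0 + 2L
      k1 <- crawler_rhs(F, tabs[[j0]], model$xi0, model$v_adh)
      k2 <- crawler_rhs(F + h / 2 * k1$Fdot, tabs[[j1]], model$xi0, model$v_adh)
      k3 <- crawler_rhs(F + h / 2 * k2$Fdot, tabs[[j1]], model$xi0, model$v_adh)
      k4 <- crawler_rhs(F + h * k3$Fdot, tabs[[j2]], model$xi0, model$v_adh)
      F <- F + h / 6 * (k1$Fdot + 2 * k2$Fdot + 2 * k3$Fdot + k4$Fdot)
      X <- X + h / 6 * (k1$W + 2 * k2$W + 2 * k3$W + k4$W)
      if (k == model$n_transient * nspc) X_mark <- X
      if (ki <= length(keep) && k == keep[ki]) {
        out_t[ki] <- (k - 1L) * h; out_X[ki] <- X; out_V[ki] <- k1$W
        out_F[ki, ] <- F; ki <- ki + 1L
      }
    }
  }

  V_mean <- (X - X_mark) / (model$n_cycles * model$T)
  df <- data.frame(t = out_t, X = out_X, V = out_V,
                   F1 = out_F[, 1], F2 = out_F[, 2],
                   F3 = out_F[, 3], F4 = out_F[, 4])
  structure(df, V_mean = V_mean, model = model,
            class = c("bead_trajectory", "data.frame"))
}

#' Cycle-averaged net velocity of a simulated trajectory
#' @param trajectory a `bead_trajectory` from [simulate.bead_model()].
#' @return Mean center velocity over the analysis window (um/min).
#' @export
mean_velocity <- function(trajectory) attr(trajectory, "V_mean")

#' @export
print.bead_trajectory <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("<bead_trajectory: %s> T=%g min, psi=%.3f; V_mean = %.4g um/min (V T/d = %.3g)\n",
              m$mode, m$T, m$psi, attr(x, "V_mean"),
              attr(x, "V_mean") * m$T / max(m$d, .Machine$double.eps)))
  invisible(x)
}

#' @export
plot.bead_trajectory <- function(x, what = c("velocity", "position"), ...) {
  what <- match.arg(what)
  if (what == "velocity") {
    plot(x$t, x$V, type = "l", xlab = "t (min)", ylab = "V (um/min)", ...)
    abline(h = attr(x, "V_mean"), lty = 2, col = 2)
  } else {
    plot(x$t, x$X, type = "l", xlab = "t (min)", ylab = "X (um)", ...)
  }
  invisible(x)
}

#' Instantaneous speed trace of a bead-model trajectory
#'
#' Returns the center velocity as a uniformly sampled trace suitable for
#' [autocorrelate()] / [find_period()]; for a migrating configuration the
#' trace oscillates about a non-vanishing mean with the gait period.
#'
#' @param trajectory a `bead_trajectory`.
#' @return A `divergence_trace`-style data frame (columns `t`, `value`)
#'   with `dt` attribute; values in um/min.
#' @export
speed_trace <- function(trajectory) {
  dt <- diff(trajectory$t[1:2])
  new_trace(trajectory$t, trajectory$V, dt = dt, label = "center velocity")
}

#' Cycle-averaged velocity as a function of the phase shift
#'
#' @param model a [bead_model()].
#' @param psi_values phase shifts to evaluate (radians).
#' @return Data frame with columns `psi` and `V` (um/min).  For a
#'   mirror-symmetric gait the response is odd in `psi` and vanishes at
#'   `psi = 0` (scallop theorem).
#' @export
velocity_response <- function(model, psi_values = seq(-3, 3, by = 0.5)) {
  V <- vapply(psi_values, function(p) {
    m <- model; m$psi <- wrap_angle(p)
    mean_velocity(simulate(m))
  }, numeric(1L))
  data.frame(psi = psi_values, V = V)
}

#' Parameter sweeps of the cycle-averaged velocity
#'
#' Runs the model over a grid of periods and/or amplitudes and returns one
#' row per run, for scaling-law fits.
#'
#' @param model a [bead_model()] providing all non-swept parameters.
#' @param T_values,d_values vectors of periods (min) / amplitudes (um); the
#'   non-swept one defaults to the model's value.
#' @return Data frame with columns `mode`, `T`, `d`, `psi`, `V`.
#' @export
sweep_velocity <- function(model, T_values = model$T, d_values = model$d) {
  grid <- expand.grid(T = T_values, d = d_values)
  V <- mapply(function(T, d) {
    m <- model; m$T <- T; m$d <- d
    mean_velocity(simulate(m))
  }, grid$T, grid$d)
  data.frame(mode = model$mode, T = grid$T, d = grid$d, psi = model$psi, V = V)
}

#' Least-squares power-law exponent of |V| against a parameter
#'
#' @param x positive predictor values (e.g. period or amplitude).
#' @param v velocities; magnitudes are used.
#' @return List with `slope`, `se`, `ci` (95 percent) from the log-log fit.
#' @export
fit_power_law <- function(x, v) {
  if (any(v == 0)) stop("zero velocity in power-law fit")
  fit <- stats::lm(log(abs(v)) ~ log(x))
  # a perfect power law makes summary.lm warn about zero residuals
  s <- suppressWarnings(summary(fit)$coefficients[2L, ])
  ci <- suppressWarnings(stats::confint(fit)[2L, ])
  list(slope = unname(s[1L]), se = unname(s[2L]), ci = unname(ci))
}

#' Model-generated trajectory in dipole-quadrupole space
#'
#' Converts the transmitted bead forces of a simulated trajectory into a
#' synthetic matrix displacement-rate field (linear elastic response with
#' a `1/distance` kernel regularized at the bead radius) sampled on a grid
#' around the cell, and runs it through the multipole stage.  Migrating
#' configurations (`psi != 0`) trace cycles of finite area in the D-Q
#' plane; reciprocal gaits collapse onto a line.
#'
#' @param trajectory a `bead_trajectory`.
#' @param frames_per_cycle number of evenly spaced output frames per gait
#'   cycle (default 36).
#' @param n_cycles number of cycles to convert (default 2).
#' @param grid_spacing sample spacing of the synthetic field (um).
#' @param halfwidth transverse half-extent of the sample grid (um).
#' @return A `dq_trajectory` data frame (see [dq_trajectory()]).
#' @export
model_multipoles <- function(trajectory, frames_per_cycle = 36L,
                             n_cycles = 2L, grid_spacing = 2,
                             halfwidth = 10) {
  model <- attr(trajectory, "model")
  t0 <- model$n_transient * model$T
  dt_out <- model$T / frames_per_cycle
  times <- t0 + seq(0, n_cycles * model$T - dt_out, by = dt_out)
  # interpolate stored state onto output times
  Xc <- stats::approx(trajectory$t, trajectory$X, xout = times)$y
  Fmat <- sapply(1:4, function(i) {
    stats::approx(trajectory$t, trajectory[[paste0("F", i)]], xout = times)$y
  })
  if (model$mode == "swimmer") Fmat <- -Fmat  # force on fluid = -force on bead
  ext <- model$r / 2 + model$D + 4 * grid_spacing
  gx <- seq(-ext, ext, by = grid_spacing)
  gy <- seq(-halfwidth, halfwidth, by = grid_spacing)
  gpts <- expand.grid(x = gx, y = gy)
  # matrix displacement x-component from point forces, kernel 1/(4 pi mu rho)
  disp_x <- function(ti) {
    off <- drop(bead_offsets(model, times[ti]))
    bx <- Xc[ti] + off
    m <- rep(0, nrow(gpts))
    for (i in 1:4) {
      rho <- pmax(sqrt((gpts$x - bx[i])^2 + gpts$y^2), model$a)
      m <- m + Fmat[ti, i] / (4 * pi * model$mu * rho)
    }
    m
  }
  disp <- lapply(seq_along(times), disp_x)
  frames <- lapply(seq_along(times), function(ti) {
    nxt <- if (ti == length(times)) ti else ti + 1L
    prv <- if (ti == length(times)) ti - 1L else ti
    data.frame(frame = ti, x = gpts$x, y = gpts$y,
               u = (disp[[nxt]] - disp[[prv]]) / dt_out, v = 0)
  })
  field <- vector_field_series(do.call(rbind, frames), dt = dt_out)
  geom <- cell_geometry_series(data.frame(
    frame = seq_along(times), cx = Xc, cy = 0, ax = 1, ay = 0,
    front_x = Xc + model$r / 2, front_y = 0,
    back_x = Xc - model$r / 2, back_y = 0), dt = dt_out)
  dq_trajectory(field, geom, radii = 1)
}
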