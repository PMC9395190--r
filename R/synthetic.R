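#' Parameters of the two-dipole synthetic displacement field
#'
#' Describes the idealized deformation-rate field of a cell with two
#' contraction centers ("A" at the back, "B" at the front) straddling the
#' nucleus: each unit pinches the matrix toward its own center with a
#' radially symmetric Gaussian-enveloped kernel of width `sigma`, with a
#' periodic waveform of period `T`; unit B lags unit A by `psi`.
#'
#' The spatial profile of a pinch in a fibrous matrix is not constrained
#' by measurements, so the kernel is a design choice:
#' `u(x, t) = -A(t) (x - c)/|x - c| exp(-|x - c|^2 / (2 sigma^2))`,
#' whose divergence and ring flux have closed forms used as test oracles
#' ([dipole_field_divergence()]).
#'
#' @param separation distance between the two contraction centers (um);
#'   they sit at `(-separation/2, 0)` and `(+separation/2, 0)`.
#' @param T oscillation period (min).
#' @param amplitude peak matrix displacement per half cycle (um); the peak
#'   displacement rate is `pi * amplitude / T`.
#' @param psi phase shift of the front unit relative to the back unit,
#'   in `(-pi, pi]`.
#' @param sigma spatial width of each pinch (um).
#' @param noise_sd standard deviation of additive iid Gaussian noise on
#'   each displacement-rate component (um/min), emulating tracker jitter.
#' @param dt frame interval (min).
#' @param duration total duration (min); at least `2 T` is needed for
#'   period recovery downstream.
#' @param grid_spacing spacing of the regular sample grid (um).
#' @param extent half-size of the sampled square region (um); default
#'   covers both units plus a `3 sigma` margin.
#' @param seed integer seed making the generated field reproducible.
#' @return An object of class `dipole_field_params`.
#' @export
dipole_field_params <- function(separation = 15, T = 8, amplitude = 2.5,
                                psi = 0, sigma = 5, noise_sd = 0.05,
                                dt = 0.5, duration = 36,
                                grid_spacing = 2, extent = NULL,
                                seed = 1L) {
  for (nm in c("separation", "T", "sigma", "dt", "duration", "grid_spacing")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("`", nm, "` must be a single positive number")
    }
  }
  if (amplitude < 0 || noise_sd < 0) stop("amplitude and noise_sd must be >= 0")
  if (is.null(extent)) extent <- separation / 2 + 3 * sigma
  structure(list(separation = separation, T = T, amplitude = amplitude,
                 psi = wrap_angle(psi), sigma = sigma, noise_sd = noise_sd,
                 dt = dt, duration = duration, grid_spacing = grid_spacing,
                 extent = extent, seed = as.integer(seed),
                 center_A = c(-separation / 2, 0),
                 center_B = c(separation / 2, 0)),
            class = "dipole_field_params")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# waveform of the two units' contraction rate amplitudes (um/min)
dipole_waveforms <- function(params, t) {
  rate0 <- pi * params$amplitude / params$T
  w <- 2 * pi / params$T
  list(A = rate0 * sin(w * t), B = rate0 * sin(w * t - params$psi))
}

# noiseless kernel field of one unit with unit amplitude
pinch_kernel <- function(x, y, center, sigma) {
  dx <- x - center[1L]; dy <- y - center[2L]
  rho <- sqrt(dx^2 + dy^2)
  env <- exp(-rho^2 / (2 * sigma^2))
  safe <- pmax(rho, .Machine$double.eps)
  list(u = -env * dx / safe, v = -env * dy / safe)
}

# noiseless field of both units at arbitrary positions / time
dipole_field_eval <- function(params, x, y, t) {
  g <- dipole_waveforms(params, t)
  kA <- pinch_kernel(x, y, params$center_A, params$sigma)
  kB <- pinch_kernel(x, y, params$center_B, params$sigma)
  list(u = g$A * kA$u + g$B * kB$u, v = g$A * kA$v + g$B * kB$v)
}

#' Generate the synthetic two-dipole displacement-rate field
#'
#' Samples the noiseless kernel field plus Gaussian noise on a regular
#' grid for `duration / dt` frames.  Deterministic for a fixed seed.
#'
#' @param params a [dipole_field_params()].
#' @return A [vector_field_series()]; the generating waveforms are kept in
#'   the `waveforms` attribute for parameter-recovery tests.
#' @examples
#' field <- gen_dipole_field(dipole_field_params(psi = pi / 2, seed = 7))
#' field
#' @export
gen_dipole_field <- function(params) {
  stopifnot(inherits(params, "dipole_field_params"))
  gx <- seq(-params$extent, params$extent, by = params$grid_spacing)
  gpts <- expand.grid(x = gx, y = gx)
  n_fr <- max(2L, floor(params$duration / params$dt))
  times <- (seq_len(n_fr) - 1L) * params$dt
  with_seed(params$seed, {
    frames <- lapply(seq_len(n_fr), function(k) {
      f <- dipole_field_eval(params, gpts$x, gpts$y, times[k])
      data.frame(frame = k, x = gpts$x, y = gpts$y,
                 u = f$u + stats::rnorm(nrow(gpts), 0, params$noise_sd),
                 v = f$v + stats::rnorm(nrow(gpts), 0, params$noise_sd))
    })
    field <- vector_field_series(do.call(rbind, frames), dt = params$dt,
                                 meta = list(generator = "gen_dipole_field",
                                             seed = params$seed))
    g <- dipole_waveforms(params, times)
    attr(field, "waveforms") <- data.frame(t = times, g_A = g$A, g_B = g$B)
    attr(field, "params") <- params
    field
  })
}

#' Cell geometry matching a synthetic dipole field
#'
#' Static geometry: center at the origin, axis along x, nucleus back/front
#' at the two contraction centers.
#'
#' @param params a [dipole_field_params()].
#' @return A [cell_geometry_series()] with one row per frame.
#' @export
dipole_field_geometry <- function(params) {
  n_fr <- max(2L, floor(params$duration / params$dt))
  cell_geometry_series(data.frame(
    frame = seq_len(n_fr), cx = 0, cy = 0, ax = 1, ay = 0,
    front_x = params$center_B[1L], front_y = 0,
    back_x = params$center_A[1L], back_y = 0), dt = params$dt)
}

#' Closed-form divergence and ring flux of the noiseless dipole field
#'
#' For one pinch with instantaneous rate amplitude `A(t)` the divergence
#' at radius `rho` is `-A exp(-rho^2/(2 sigma^2)) (1/rho - rho/sigma^2)`
#' and the outward flux through a circle of radius `R` centred on the
#' unit is `-2 pi R A exp(-R^2/(2 sigma^2))` (negative: pinching).
#'
#' @param params a [dipole_field_params()].
#' @param x,y evaluation positions (um).
#' @param t time (min).
#' @return `dipole_field_divergence()`: divergence values (1/min);
#'   `dipole_ring_flux()`: flux through a ring of radius `R` around unit
#'   `unit` at time `t` (um^2/min).
#' @export
dipole_field_divergence <- function(params, x, y, t) {
  g <- dipole_waveforms(params, t)
  div_one <- function(center, A) {
    rho <- sqrt((x - center[1L])^2 + (y - center[2L])^2)
    rho <- pmax(rho, .Machine$double.eps)
    -A * exp(-rho^2 / (2 * params$sigma^2)) * (1 / rho - rho / params$sigma^2)
  }
  div_one(params$center_A, g$A) + div_one(params$center_B, g$B)
}

#' @rdname dipole_field_divergence
#' @param R ring radius (um).
#' @param unit `"A"` or `"B"`.
#' @export
dipole_ring_flux <- function(params, R, t, unit = c("A", "B")) {
  unit <- match.arg(unit)
  g <- dipole_waveforms(params, t)
  A <- if (unit == "A") g$A else g$B
  -2 * pi * R * A * exp(-R^2 / (2 * params$sigma^2))
}

#' Synthetic oscillatory divergence trace
#'
#' Zero-mean sinusoid plus white noise, sampled at `dt`; emulates the
#' front/back divergence traces extracted from kymographs.
#'
#' @param period oscillation period (min).
#' @param amplitude waveform amplitude (1/min).
#' @param noise_sd white-noise standard deviation (1/min).
#' @param duration trace duration (min); must be at least `2 * period`.
#' @param dt sampling interval (min).
#' @param seed integer seed.
#' @param phase phase offset (radians), for generating lagged pairs.
#' @return A `divergence_trace` (see [extract_trace()]).
#' @export
gen_divergence_trace <- function(period = 5, amplitude = 1, noise_sd = 0.1,
                                 duration = 36, dt = 0.5, seed = 1L,
                                 phase = 0) {
  if (duration < 2 * period) stop("duration must be at least 2 * period")
  t <- seq(0, duration - dt, by = dt)
  with_seed(seed, {
    val <- amplitude * sin(2 * pi * t / period - phase) +
      stats::rnorm(length(t), 0, noise_sd)
    new_trace(t, val, dt = dt, label = "synthetic divergence")
  })
}

#' Synthetic instantaneous-speed trace
#'
#' Oscillation about a non-vanishing mean, as observed for the
#' instantaneous speed of migrating cells.
#'
#' @param mean_v mean speed (um/min).
#' @param noise_sd white-noise standard deviation (um/min).
#' @param period,amplitude,duration,dt,seed as in [gen_divergence_trace()].
#' @return A trace data frame (columns `t`, `value`), class
#'   `divergence_trace` for reuse of the correlogram tools.
#' @export
gen_speed_trace <- function(mean_v = 0.5, period = 8, amplitude = 0.3,
                            noise_sd = 0.05, duration = 64, dt = 0.5,
                            seed = 1L) {
  if (duration < 2 * period) stop("duration must be at least 2 * period")
  t <- seq(0, duration - dt, by = dt)
  with_seed(seed, {
    val <- mean_v + amplitude * sin(2 * pi * t / period) +
      stats::rnorm(length(t), 0, noise_sd)
    new_trace(t, val, dt = dt, label = "synthetic speed")
  })
}
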