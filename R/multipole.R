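#' Force dipole tensor of a displacement-rate field frame
#'
#' `S = (D + t(D)) / 2` with `D_ij = sum_n Delta_i(n) u_j(n)`, where
#' `Delta(n)` is the vector from the cell centre to sample `n` and `u(n)`
#' the displacement-rate vector.  `S` is exactly symmetric by
#' construction; a negative principal value signals contraction.  Units:
#' um^2/min.
#'
#' @param frame data frame with columns `x`, `y`, `u`, `v` (one field
#'   frame, see [field_frame()]).
#' @param center length-2 cell centre (um).
#' @return Symmetric 2 x 2 matrix (um^2/min).
#' @export
dipole_tensor <- function(frame, center) {
  if (nrow(frame) == 0L) stop("empty field frame")
  dx <- frame$x - center[1L]; dy <- frame$y - center[2L]
  D <- rbind(c(sum(dx * frame$u), sum(dx * frame$v)),
             c(sum(dy * frame$u), sum(dy * frame$v)))
  (D + t(D)) / 2
}

#' Force quadrupole tensor of a displacement-rate field frame
#'
#' `Q_ijk = sum_n Delta_i(n) Delta_j(n) u_k(n)`; units um^3/min.  The
#' quadrupole is origin-dependent whenever the dipole is non-zero, so the
#' centre convention travels with the result.
#'
#' @inheritParams dipole_tensor
#' @return 2 x 2 x 2 array (um^3/min) with `Q[i, j, k]` symmetric in
#'   `i, j`.
#' @export
quadrupole_tensor <- function(frame, center) {
  if (nrow(frame) == 0L) stop("empty field frame")
  dx <- frame$x - center[1L]; dy <- frame$y - center[2L]
  Q <- array(0, c(2L, 2L, 2L))
  del <- cbind(dx, dy)
  u <- cbind(frame$u, frame$v)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    Q[i, j, k] <- sum(del[, i] * del[, j] * u[, k])
  }
  Q
}

#' Main dipole and quadrupole projected on the cell axis
#'
#' The main dipole is the eigenvalue of `S` of largest magnitude (sign
#' retained: contraction gives a negative value) with its eigenvector as
#' the dipole axis; set `mode = "signed"` for the algebraically largest
#' eigenvalue instead.  The quadrupole is reduced along the cell axis by
#' full contraction, `Q = Q_ijk e_i e_j e_k`, the rank-3 analogue of
#' `e' S e`.
#'
#' @param S dipole tensor ([dipole_tensor()]).
#' @param Qten quadrupole tensor ([quadrupole_tensor()]).
#' @param axis length-2 cell axis (normalised internally).
#' @param mode `"magnitude"` (default) or `"signed"` eigenvalue choice.
#' @return List with `D` (um^2/min), `Q` (um^3/min), `dipole_axis` (unit
#'   vector, sign chosen to align with the cell axis), `degenerate`
#'   (`TRUE` when `S` is isotropic and the axis direction is arbitrary).
#' @export
principal_components <- function(S, Qten, axis,
                                 mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  axis <- axis / sqrt(sum(axis^2))
  e <- eigen(S, symmetric = TRUE)
  i <- if (mode == "magnitude") which.max(abs(e$values)) else 1L
  vec <- e$vectors[, i]
  if (sum(vec * axis) < 0) vec <- -vec
  degenerate <- abs(e$values[1L] - e$values[2L]) <=
    1e-10 * max(abs(e$values), .Machine$double.eps)
  Qproj <- 0
  for (i2 in 1:2) for (j in 1:2) for (k in 1:2) {
    Qproj <- Qproj + Qten[i2, j, k] * axis[i2] * axis[j] * axis[k]
  }
  list(D = e$values[i], Q = Qproj, dipole_axis = vec,
       degenerate = degenerate)
}

#' Dipole-quadrupole phase-space trajectory of a field series
#'
#' For every frame and every cutoff radius, samples within the radius of
#' the cell centre enter the dipole and quadrupole sums; the main dipole
#' `D(t)` and axis-projected quadrupole `Q(t)` give one point per frame in
#' the D-Q plane.  Radii are expressed as multiples of the cell
#' half-length (centre to nucleus front).
#'
#' @param field a [vector_field_series()].
#' @param geometry a [cell_geometry_series()].
#' @param radii cutoff radii as multiples of the field extent (the
#'   largest sample distance from the cell centre; default
#'   `c(0.6, 0.8, 1, 1.2)`); values `>= 1` use all samples.
#' @param mode eigenvalue convention, see [principal_components()].
#' @return A `dq_trajectory`: data frame with columns `frame`, `t`,
#'   `radius`, `cutoff_um`, `D`, `Q`, `axis_x`, `axis_y`, `degenerate`,
#'   with attribute `dt`.
#' @export
dq_trajectory <- function(field, geometry, radii = c(0.6, 0.8, 1, 1.2),
                          mode = "magnitude") {
  dt <- attr(field, "dt")
  frames <- sort(unique(field$frame))
  out <- list()
  prev_axis <- NULL
  for (k in frames) {
    fr <- field_frame(field, k)
    g <- geometry_frame(geometry, k)
    centre <- c(g$cx, g$cy)
    axis <- c(g$ax, g$ay)
    rho <- sqrt((fr$x - centre[1L])^2 + (fr$y - centre[2L])^2)
    ref_len <- max(rho)
    for (rmul in radii) {
      cutoff <- if (is.finite(rmul)) rmul * ref_len else Inf
      sub <- fr[rho <= cutoff, ]
      if (nrow(sub) < 3L) stop("cutoff radius leaves fewer than 3 samples")
      S <- dipole_tensor(sub, centre)
      Qt <- quadrupole_tensor(sub, centre)
      pc <- principal_components(S, Qt, axis, mode = mode)
      ax <- pc$dipole_axis
      if (pc$degenerate && !is.null(prev_axis)) ax <- prev_axis
      prev_axis <- ax
      out[[length(out) + 1L]] <- data.frame(
        frame = k, t = (k - 1L) * dt, radius = rmul, cutoff_um = cutoff,
        D = pc$D, Q = pc$Q, axis_x = ax[1L], axis_y = ax[2L],
        degenerate = pc$degenerate)
    }
  }
  structure(do.call(rbind, out), dt = dt,
            class = c("dq_trajectory", "data.frame"))
}

#' @export
print.dq_trajectory <- function(x, ...) {
  cat(sprintf("<dq_trajectory> %d frames x %d radii; D in [%.3g, %.3g] um^2/min\n",
              length(unique(x$frame)), length(unique(x$radius)),
              min(x$D), max(x$D)))
  invisible(x)
}

#' @export
plot.dq_trajectory <- function(x, radius = NULL, ...) {
  if (is.null(radius)) radius <- unique(x$radius)[1L]
  s <- x[x$radius == radius, ]
  plot(s$D, s$Q, type = "o", pch = 16, cex = 0.5,
       xlab = "D (um^2/min)", ylab = "Q (um^3/min)", ...)
  invisible(x)
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Enclosed area of dipole-quadrupole cycles
#'
#' The D-Q trajectory is cut into consecutive windows of one oscillation
#' period; each window is closed (last point joined to the first) and its
#' signed area computed with the shoelace formula.  The absolute area is
#' the mean cycle |area| (um^5/min^2); the normalized area expresses it
#' as a percentage of the axis-aligned bounding rectangle of the whole
#' trajectory.  A finite area is the signature of broken time-reversal
#' symmetry (a migrating gait); reciprocal gaits collapse to zero-area
#' figures.
#'
#' @param D,Q numeric vectors, one point per frame (single cutoff
#'   radius).
#' @param period oscillation period (min); when `NA`, the whole
#'   trajectory is treated as one closed cycle (with a warning).
#' @param dt frame interval (min).
#' @return A `cycle_area` list: `absolute` (um^5/min^2), `normalized`
#'   (percent, in `[0, 100]`), `signed` (per-cycle signed areas),
#'   `n_cycles`.
#' @export
cycle_area <- function(D, Q, period, dt) {
  if (length(D) != length(Q)) stop("D and Q must have equal length")
  if (is.na(period)) {
    warning("no period supplied; treating the whole trajectory as one cycle")
    per_len <- length(D)
  } else {
    per_len <- max(1L, round(period / dt))
  }
  if (per_len < 4L) stop("fewer than 4 points per cycle")
  n_cyc <- length(D) %/% per_len
  if (n_cyc < 1L) stop("trajectory shorter than one period")
  signed <- vapply(seq_len(n_cyc), function(c_) {
    i <- ((c_ - 1L) * per_len + 1L):(c_ * per_len)
    shoelace(D[i], Q[i])
  }, numeric(1L))
  absolute <- mean(abs(signed))
  w <- diff(range(D)); h <- diff(range(Q))
  normalized <- if (w * h > 0) 100 * absolute / (w * h) else 0
  structure(list(absolute = absolute, normalized = normalized,
                 signed = signed, n_cycles = n_cyc),
            class = "cycle_area")
}

#' @export
print.cycle_area <- function(x, ...) {
  cat(sprintf("cycle area: %.4g um^5/min^2 (%.2f%% of bounding box; %d cycles)\n",
              x$absolute, x$normalized, x$n_cycles))
  invisible(x)
}

#' Cycle areas of a D-Q trajectory across cutoff radii
#'
#' Applies [cycle_area()] per cutoff radius and summarises the spread, the
#' radius ensemble standing in for an error bar.
#'
#' @param dq a [dq_trajectory()].
#' @param period oscillation period (min), e.g. from [find_period()].
#' @return Data frame with one row per radius (`radius`, `absolute`,
#'   `normalized`) plus attribute `summary` (mean and sd across radii).
#' @export
dq_cycle_areas <- function(dq, period) {
  radii <- unique(dq$radius)
  rows <- lapply(radii, function(r) {
    s <- dq[dq$radius == r, ]
    ca <- cycle_area(s$D, s$Q, period, attr(dq, "dt"))
    data.frame(radius = r, absolute = ca$absolute,
               normalized = ca$normalized)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    absolute_mean = mean(out$absolute), absolute_sd = stats::sd(out$absolute),
    normalized_mean = mean(out$normalized),
    normalized_sd = stats::sd(out$normalized))
  out
}

#' Alignment of the main dipole axis with the direction of motion
#'
#' @param dq a [dq_trajectory()] (one cutoff radius is selected).
#' @param motion length-2 direction of motion (normalised internally).
#' @param radius cutoff radius to use (default: first).
#' @return List with per-frame acute `angles` (degrees, in `[0, 90]`) and
#'   their `median`.
#' @export
dipole_alignment <- function(dq, motion, radius = NULL) {
  if (is.null(radius)) radius <- unique(dq$radius)[1L]
  s <- dq[dq$radius == radius, ]
  motion <- motion / sqrt(sum(motion^2))
  cosang <- abs(s$axis_x * motion[1L] + s$axis_y * motion[2L])
  ang <- acos(pmin(cosang, 1)) * 180 / pi
  list(angles = ang, median = stats::median(ang))
}
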