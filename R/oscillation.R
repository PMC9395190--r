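new_trace <- function(t, value, dt, label = "", region = NULL) {
  structure(data.frame(t = t, value = value),
            dt = dt, label = label, region = region,
            class = c("divergence_trace", "data.frame"))
}

#' @export
print.divergence_trace <- function(x, ...) {
  cat(sprintf("<divergence_trace> %s: %d points, dt = %g min, sd = %.3g\n",
              attr(x, "label"), nrow(x), attr(x, "dt"),
              stats::sd(x$value)))
  invisible(x)
}

#' @export
plot.divergence_trace <- function(x, ...) {
  plot(x$t, x$value, type = "l", xlab = "t (min)",
       ylab = attr(x, "label"), ...)
  invisible(x)
}

#' Divergence of a scattered displacement-rate field on a regular grid
#'
#' Samples are averaged onto a regular grid (cells without samples are
#' filled by iterative neighbour averaging) and the divergence
#' `du/dx + dv/dy` is taken by central finite differences; units 1/min.
#'
#' @param field a [vector_field_series()].
#' @param grid_spacing grid cell size (um); defaults to the median nearest
#'   sample spacing.
#' @return A `divergence_field_series`: list with `x`, `y` (grid centre
#'   coordinates), `frames` (list of divergence matrices `[y, x]`), `dt`.
#' @export
divergence_field <- function(field, grid_spacing = NULL) {
  fr1 <- field_frame(field, unique(field$frame)[1L])
  if (length(unique(fr1$x)) < 3L || length(unique(fr1$y)) < 3L) {
    stop("degenerate sample geometry: need spread in both x and y")
  }
  if (is.null(grid_spacing)) {
    grid_spacing <- stats::median(diff(sort(unique(fr1$x))))
  }
  gx <- seq(min(fr1$x), max(fr1$x) + grid_spacing / 2, by = grid_spacing)
  gy <- seq(min(fr1$y), max(fr1$y) + grid_spacing / 2, by = grid_spacing)
  bin_frame <- function(fr) {
    ix <- pmin(pmax(round((fr$x - gx[1L]) / grid_spacing) + 1L, 1L), length(gx))
    iy <- pmin(pmax(round((fr$y - gy[1L]) / grid_spacing) + 1L, 1L), length(gy))
    idx <- cbind(iy, ix)
    U <- matrix(NA_real_, length(gy), length(gx))
    V <- matrix(NA_real_, length(gy), length(gx))
    cnt <- matrix(0, length(gy), length(gx))
    us <- tapply(fr$u, list(iy, ix), mean)
    vs <- tapply(fr$v, list(iy, ix), mean)
    U[cbind(as.integer(rownames(us))[row(us)],
            as.integer(colnames(us))[col(us)])] <- us
    V[cbind(as.integer(rownames(vs))[row(vs)],
            as.integer(colnames(vs))[col(vs)])] <- vs
    for (pass in 1:10) {
      if (!anyNA(U)) break
      U <- fill_na_neighbours(U)
      V <- fill_na_neighbours(V)
    }
    U[is.na(U)] <- 0; V[is.na(V)] <- 0
    list(U = U, V = V)
  }
  frames <- lapply(sort(unique(field$frame)), function(k) {
    uv <- bin_frame(field_frame(field, k))
    div_central(uv$U, uv$V, grid_spacing)
  })
  structure(list(x = gx, y = gy, frames = frames, dt = attr(field, "dt"),
                 grid_spacing = grid_spacing),
            class = "divergence_field_series")
}

fill_na_neighbours <- function(M) {
  nas <- which(is.na(M), arr.ind = TRUE)
  if (nrow(nas) == 0L) return(M)
  nr <- nrow(M); nc <- ncol(M)
  out <- M
  for (i in seq_len(nrow(nas))) {
    r <- nas[i, 1L]; c_ <- nas[i, 2L]
    nb <- M[cbind(pmin(pmax(r + c(-1L, 1L, 0L, 0L), 1L), nr),
                  pmin(pmax(c_ + c(0L, 0L, -1L, 1L), 1L), nc))]
    if (any(!is.na(nb))) out[r, c_] <- mean(nb, na.rm = TRUE)
  }
  out
}

div_central <- function(U, V, h) {
  nr <- nrow(U); nc <- ncol(U)
  dudx <- matrix(0, nr, nc)
  dudx[, 2:(nc - 1)] <- (U[, 3:nc] - U[, 1:(nc - 2)]) / (2 * h)
  dudx[, 1L] <- (U[, 2L] - U[, 1L]) / h
  dudx[, nc] <- (U[, nc] - U[, nc - 1L]) / h
  dvdy <- matrix(0, nr, nc)
  dvdy[2:(nr - 1), ] <- (V[3:nr, ] - V[1:(nr - 2), ]) / (2 * h)
  dvdy[1L, ] <- (V[2L, ] - V[1L, ]) / h
  dvdy[nr, ] <- (V[nr, ] - V[nr - 1L, ]) / h
  dudx + dvdy
}

#' @export
print.divergence_field_series <- function(x, ...) {
  cat(sprintf("<divergence_field_series> %d frames on %d x %d grid (%g um)\n",
              length(x$frames), length(x$y), length(x$x), x$grid_spacing))
  invisible(x)
}

#' Divergence kymograph along the cell axis
#'
#' For every frame, grid divergence values within a band of half-width
#' `band_halfwidth` around the cell axis are averaged into bins along the
#' axis (positions relative to the cell centre, positive towards the
#' front), producing one column per frame.
#'
#' @param divf a `divergence_field_series` from [divergence_field()].
#' @param geometry a [cell_geometry_series()].
#' @param band_halfwidth half-width of the averaging band perpendicular to
#'   the axis (um).
#' @param bin_width bin size along the axis (um); defaults to the grid
#'   spacing.
#' @return A `kymograph`: matrix `[position bin, frame]` with attributes
#'   `positions` (bin centres, um), `times` (min) and `dt`.
#' @export
kymograph <- function(divf, geometry, band_halfwidth = 5,
                      bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- divf$grid_spacing
  gpts <- expand.grid(x = divf$x, y = divf$y)
  n_fr <- length(divf$frames)
  smin <- -max(abs(c(divf$x, divf$y))); smax <- -smin
  breaks <- seq(smin, smax + bin_width, by = bin_width)
  centres <- breaks[-length(breaks)] + bin_width / 2
  K <- matrix(NA_real_, length(centres), n_fr)
  for (k in seq_len(n_fr)) {
    g <- geometry_frame(geometry, k)
    rx <- gpts$x - g$cx; ry <- gpts$y - g$cy
    s <- rx * g$ax + ry * g$ay
    p <- -rx * g$ay + ry * g$ax
    vals <- as.vector(divf$frames[[k]][cbind(
      match(gpts$y, divf$y), match(gpts$x, divf$x))])
    keep <- abs(p) <= band_halfwidth
    bin <- findInterval(s[keep], breaks, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= length(centres)
    sums <- tapply(vals[keep][ok], bin[ok], mean)
    K[as.integer(names(sums)), k] <- sums
  }
  used <- rowSums(!is.na(K)) > 0
  structure(K[used, , drop = FALSE],
            positions = centres[used],
            times = (seq_len(n_fr) - 1L) * divf$dt,
            dt = divf$dt, band_halfwidth = band_halfwidth,
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d axis bins x %d frames, dt = %g min\n",
              nrow(x), ncol(x), attr(x, "dt")))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  pos <- attr(x, "positions"); tim <- attr(x, "times")
  image(tim, pos, t(unclass(x)), xlab = "t (min)",
        ylab = "axis position (um)",
        col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Extract a front/back divergence trace from a kymograph
#'
#' Averages the kymograph over an axis-position window and subtracts the
#' trace mean (background removal), giving the contraction-extension time
#' series of one cell end.
#'
#' @param kymo a [kymograph()].
#' @param center window centre, as axis position relative to the cell
#'   centre (um).
#' @param width window width (um), conventionally 2-5 um.
#' @return A `divergence_trace` (data frame `t`, `value`, 1/min).
#' @export
extract_trace <- function(kymo, center, width = 3) {
  pos <- attr(kymo, "positions")
  sel <- abs(pos - center) <= width / 2
  if (!any(sel)) stop("empty region: no kymograph bins within the window")
  val <- colMeans(kymo[sel, , drop = FALSE], na.rm = TRUE)
  val <- val - mean(val, na.rm = TRUE)
  new_trace(attr(kymo, "times"), val, dt = attr(kymo, "dt"),
            label = sprintf("divergence @ %g um", center),
            region = list(center = center, width = width))
}

#' Front and back traces located from the cell geometry
#'
#' @param kymo a [kymograph()].
#' @param geometry a [cell_geometry_series()]; the first frame's nucleus
#'   front/back positions are projected on the axis to centre the windows.
#' @param width window width (um).
#' @return List with elements `front` and `back` ([extract_trace()]
#'   results).
#' @export
front_back_traces <- function(kymo, geometry, width = 3) {
  g <- geometry_frame(geometry, 1L)
  s_front <- (g$front_x - g$cx) * g$ax + (g$front_y - g$cy) * g$ay
  s_back <- (g$back_x - g$cx) * g$ax + (g$back_y - g$cy) * g$ay
  list(front = extract_trace(kymo, s_front, width),
       back = extract_trace(kymo, s_back, width))
}

#' Normalized autocorrelation of a trace
#'
#' Biased estimator with coefficient normalization, so the value at zero
#' lag is exactly 1 and all magnitudes stay within 1.
#'
#' @param trace a `divergence_trace` (or any data frame with `t`,
#'   `value`).
#' @param max_lag largest lag in samples (default: two thirds of the
#'   trace length).
#' @return A `correlogram`: data frame with `lag` (min) and `value`, with
#'   attributes `dt` and `degenerate` (constant input).
#' @export
autocorrelate <- function(trace, max_lag = NULL) {
  x <- trace$value
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 2L, floor(2 * n / 3))
  dt <- attr(trace, "dt")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom < .Machine$double.eps) {
    val <- c(1, rep(0, max_lag))
    return(structure(data.frame(lag = (0:max_lag) * dt, value = val),
                     dt = dt, degenerate = TRUE, n = n,
                     class = c("correlogram", "data.frame")))
  }
  val <- vapply(0:max_lag, function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, numeric(1L))
  structure(data.frame(lag = (0:max_lag) * dt, value = val),
            dt = dt, degenerate = FALSE, n = n,
            class = c("correlogram", "data.frame"))
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags, dt = %g min\n", nrow(x), attr(x, "dt")))
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  plot(x$lag, x$value, type = "h", xlab = "lag (min)",
       ylab = "correlation", ...)
  abline(h = 0, col = "grey")
  invisible(x)
}

#' Oscillation period from a correlogram
#'
#' Selects the first strict local maximum at positive lag whose amplitude
#' exceeds `threshold_sd` standard deviations of the positive-lag
#' correlogram values (a scale-free threshold; the dispersion of the
#' correlogram itself sets the significance scale).  Because that
#' dispersion collapses for structureless traces, the threshold is never
#' taken below the lag-dependent white-noise significance band
#' `3 sqrt(n - k) / n` of the biased estimator, which keeps the
#' false-positive rate on pure noise below ten percent.  If no
#' qualifying peak exists the trace is reported as aperiodic rather than
#' failing.
#'
#' @param corr a [autocorrelate()] result.
#' @param threshold_sd threshold in correlogram standard deviations
#'   (default 1).
#' @return A `period_estimate`: list with `found`, `period` (min, `NA` if
#'   not found), `peak_value` and `threshold`.
#' @export
find_period <- function(corr, threshold_sd = 1) {
  if (isTRUE(attr(corr, "degenerate"))) {
    return(structure(list(found = FALSE, period = NA_real_,
                          peak_value = NA_real_, threshold = NA_real_),
                     class = "period_estimate"))
  }
  v <- corr$value[-1L]
  lag <- corr$lag[-1L]
  n <- attr(corr, "n")
  k <- seq_along(v)
  # white-noise band of the biased estimator shrinks as sqrt(n - k)/n
  guard <- 3 * sqrt(pmax(n - k, 1L)) / n
  thr <- pmax(threshold_sd * stats::sd(v), guard)
  peak <- which(diff(sign(diff(v))) == -2) + 1L  # strict local maxima
  peak <- peak[v[peak] > thr[peak]]
  if (length(peak) == 0L) {
    return(structure(list(found = FALSE, period = NA_real_,
                          peak_value = NA_real_, threshold = thr[1L]),
                     class = "period_estimate"))
  }
  p <- peak[1L]
  structure(list(found = TRUE, period = lag[p], peak_value = v[p],
                 threshold = thr[p]),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("period %.3g min (peak %.3f > threshold %.3f)\n",
                x$period, x$peak_value, x$threshold))
  } else {
    cat("no period identified\n")
  }
  invisible(x)
}

#' Cross-correlation lag between two traces
#'
#' Normalized cross-correlogram of the front and back traces; the lag of
#' the largest-magnitude strict local extremum (positive or negative
#' peak) is returned.  Sign convention: a positive lag means the front
#' trace leads the back trace.
#'
#' For near-sinusoidal traces a positive peak at lag `l` is accompanied
#' by a trough of almost equal magnitude at `l - T/2`, making the bare
#' largest-magnitude rule sign-ambiguous.  Because the two traces are
#' same-sign contraction waveforms, extrema of positive correlation are
#' preferred among candidates within 80 percent of the largest magnitude;
#' remaining ties go to the smaller, then to the positive, lag.
#'
#' @param front,back `divergence_trace` objects on the same time base.
#' @param max_lag largest |lag| in samples (default half the length).
#' @return A `lag_estimate`: list with `found`, `lag` (min), `value` (the
#'   correlation at the peak) and the full `correlogram` data frame.
#' @export
cross_correlate <- function(front, back, max_lag = NULL) {
  f <- front$value - mean(front$value)
  b <- back$value - mean(back$value)
  n <- length(f)
  if (length(b) != n) stop("traces must have equal length")
  dt <- attr(front, "dt")
  if (is.null(max_lag)) max_lag <- min(n - 2L, floor(n / 2))
  denom <- sqrt(sum(f^2) * sum(b^2))
  if (denom < .Machine$double.eps) {
    return(structure(list(found = FALSE, lag = NA_real_, value = NA_real_,
                          correlogram = NULL),
                     class = "lag_estimate"))
  }
  lags <- -max_lag:max_lag
  val <- vapply(lags, function(k) {
    # c(k) = sum_t f(t) b(t + k) / denom ; positive k: front leads
    if (k >= 0) {
      sum(f[seq_len(n - k)] * b[seq_len(n - k) + k]) / denom
    } else {
      sum(f[seq_len(n + k) - k] * b[seq_len(n + k)]) / denom
    }
  }, numeric(1L))
  cg <- data.frame(lag = lags * dt, value = val)
  a <- abs(val)
  d2 <- diff(sign(diff(val)))
  extrema <- which(d2 != 0) + 1L            # strict local maxima and minima
  extrema <- extrema[extrema > 1L & extrema < length(val)]
  if (length(extrema) == 0L) {
    return(structure(list(found = FALSE, lag = NA_real_, value = NA_real_,
                          correlogram = cg),
                     class = "lag_estimate"))
  }
  M <- max(a[extrema])
  cand <- extrema[a[extrema] >= 0.8 * M]
  ord <- order(val[cand] <= 0,              # positive-correlation peaks first
               abs(cg$lag[cand]),           # then smaller |lag|
               cg$lag[cand] < 0)            # then positive lag
  best <- cand[ord][1L]
  structure(list(found = TRUE, lag = cg$lag[best], value = val[best],
                 correlogram = cg),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("lag %.3g min (peak correlation %.3f)\n", x$lag, x$value))
  } else {
    cat("no cross-correlation peak identified\n")
  }
  invisible(x)
}

#' Phase shift from a lag and a period
#'
#' `psi = 2 pi lag / period`, wrapped to `(-pi, pi]`.
#'
#' @param lag time lag (min).
#' @param period oscillation period (min).
#' @return Phase shift in radians.
#' @export
phase_shift <- function(lag, period) {
  if (period <= 0) stop("period must be positive")
  wrap_angle(2 * pi * lag / period)
}

#' Instantaneous and persistent speed of a tracked trajectory
#'
#' The trajectory is projected on the migration axis; the instantaneous
#' (signed) speed is the per-frame increment of the projection divided by
#' `dt`, and the persistent speed is the net axis displacement over the
#' whole window divided by its duration.  The period of the speed
#' oscillation is estimated from the increments with
#' [autocorrelate()]/[find_period()].
#'
#' @param positions data frame with columns `x`, `y` (um), one row per
#'   frame.
#' @param axis length-2 unit vector of the migration direction
#'   (normalised internally).
#' @param dt frame interval (min).
#' @return List with `instantaneous` (a trace, um/min), `persistent`
#'   (um/min), and `period` (a `period_estimate`).
#' @export
speed_series <- function(positions, axis, dt) {
  axis <- axis / sqrt(sum(axis^2))
  s <- positions$x * axis[1L] + positions$y * axis[2L]
  inc <- diff(s) / dt
  tr <- new_trace((seq_along(inc) - 1L) * dt, inc, dt = dt,
                  label = "axis speed")
  list(instantaneous = tr,
       persistent = (s[length(s)] - s[1L]) / ((length(s) - 1L) * dt),
       period = find_period(autocorrelate(tr)))
}
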