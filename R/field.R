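#' Per-frame displacement-rate vector field
#'
#' A `vector_field_series` holds scattered sample positions and matrix
#' displacement-rate vectors for a sequence of frames, in physical units
#' (positions in micrometres, rates in micrometres per minute).  It is the
#' common currency between the tracker, the divergence/kymograph stage and
#' the multipole stage.
#'
#' @param data data frame with columns `frame` (integer, 1-based), `x`, `y`
#'   (sample positions, um) and `u`, `v` (displacement-rate components,
#'   um/min).
#' @param dt frame interval in minutes.
#' @param pixel_size pixel size in um/px, `NA` if the field never lived on a
#'   pixel grid.
#' @param meta optional named list of provenance information carried along
#'   into files written by [write_field_tsv()].
#' @return An object of class `vector_field_series`: the data frame with
#'   attributes `dt`, `pixel_size` and `meta`.
#' @seealso [gen_dipole_field()], [track()], [divergence_field()]
#' @export
vector_field_series <- function(data, dt, pixel_size = NA_real_, meta = list()) {
  needed <- c("frame", "x", "y", "u", "v")
  if (!all(needed %in% names(data))) {
    stop("`data` must have columns ", paste(needed, collapse = ", "))
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (minutes)")
  }
  if (any(!is.finite(as.matrix(data[needed])))) {
    stop("non-finite values in vector field data")
  }
  data <- as.data.frame(data)[needed]
  data$frame <- as.integer(data$frame)
  structure(data,
            dt = dt, pixel_size = pixel_size, meta = meta,
            class = c("vector_field_series", "data.frame"))
}

#' @export
print.vector_field_series <- function(x, ...) {
  fr <- unique(x$frame)
  cat(sprintf("<vector_field_series> %d frames, %d samples/frame, dt = %g min\n",
              length(fr), sum(x$frame == fr[1L]), attr(x, "dt")))
  cat(sprintf("  |u| range: %.3g .. %.3g um/min\n",
              min(sqrt(x$u^2 + x$v^2)), max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' @export
plot.vector_field_series <- function(x, frame = 1L, scale = 1,
                                     length = 0.03, ...) {
  f <- x[x$frame == frame, ]
  if (nrow(f) == 0L) stop("no samples for frame ", frame)
  plot(f$x, f$y, pch = 16, cex = 0.3, asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  nz <- (f$u^2 + f$v^2) > 0
  if (any(nz)) {
    arrows(f$x[nz], f$y[nz],
           f$x[nz] + scale * f$u[nz], f$y[nz] + scale * f$v[nz],
           length = length, col = "darkgreen")
  }
  invisible(x)
}

#' Extract one frame of a field as a plain data frame
#'
#' @param field a [vector_field_series()].
#' @param frame frame index.
#' @return Data frame with columns `x`, `y`, `u`, `v`.
#' @export
field_frame <- function(field, frame) {
  f <- field[field$frame == frame, c("x", "y", "u", "v")]
  if (nrow(f) == 0L) stop("no samples for frame ", frame)
  as.data.frame(f)
}

#' Number of frames in a field series
#' @param field a [vector_field_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(field) length(unique(field$frame))

#' Per-frame cell geometry
#'
#' Stores, for every frame, the cell center, the unit polarization /
#' migration axis and the nucleus front and back positions.  The axis is
#' the projection line for kymographs and the contraction direction for the
#' multipole reduction; front/back positions center the divergence
#' averaging regions.
#'
#' @param data data frame with columns `frame`, `cx`, `cy` (cell center,
#'   um), `ax`, `ay` (axis direction, normalised internally), `front_x`,
#'   `front_y`, `back_x`, `back_y` (nucleus front/back, um).
#' @param dt frame interval in minutes.
#' @return Object of class `cell_geometry_series`.
#' @export
cell_geometry_series <- function(data, dt) {
  needed <- c("frame", "cx", "cy", "ax", "ay",
              "front_x", "front_y", "back_x", "back_y")
  if (!all(needed %in% names(data))) {
    stop("`data` must have columns ", paste(needed, collapse = ", "))
  }
  data <- as.data.frame(data)[needed]
  nrm <- sqrt(data$ax^2 + data$ay^2)
  if (any(nrm == 0)) stop("axis vector of length zero")
  data$ax <- data$ax / nrm
  data$ay <- data$ay / nrm
  data$frame <- as.integer(data$frame)
  structure(data, dt = dt,
            class = c("cell_geometry_series", "data.frame"))
}

#' @export
print.cell_geometry_series <- function(x, ...) {
  cat(sprintf("<cell_geometry_series> %d frames, dt = %g min\n",
              length(unique(x$frame)), attr(x, "dt")))
  invisible(x)
}

geometry_frame <- function(geometry, frame) {
  g <- geometry[geometry$frame == frame, ]
  if (nrow(g) == 0L) {
    # geometry held fixed: fall back to the last frame at hand
    g <- geometry[nrow(geometry), ]
  }
  g[1L, ]
}
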