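# Image helpers shared by the texture generator and the feature tracker.
# Images are numeric matrices [row, col]; row 1 is the top of the image.
# Physical coordinates are micrometres, y up, origin at the image center:
#   x =  (col - (ncol+1)/2) * pixel_size
#   y = -(row - (nrow+1)/2) * pixel_size

px_to_um <- function(row, col, dim, pixel_size) {
  list(x = (col - (dim[2L] + 1) / 2) * pixel_size,
       y = -(row - (dim[1L] + 1) / 2) * pixel_size)
}
um_to_px <- function(x, y, dim, pixel_size) {
  list(row = -y / pixel_size + (dim[1L] + 1) / 2,
       col = x / pixel_size + (dim[2L] + 1) / 2)
}

# bilinear interpolation of img at fractional (row, col); outside -> fill
bilinear_interp <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  out <- rep(fill, length(row))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- img[cbind(r0k, c0k)];     i01 <- img[cbind(r0k, c0k + 1L)]
    i10 <- img[cbind(r0k + 1L, c0k)]; i11 <- img[cbind(r0k + 1L, c0k + 1L)]
    out[ok] <- i00 * (1 - frk) * (1 - fck) + i01 * (1 - frk) * fck +
      i10 * frk * (1 - fck) + i11 * frk * fck
  }
  out
}

# separable binomial blur (approximates a small Gaussian)
blur3 <- function(img, passes = 1L) {
  k <- c(1, 2, 1) / 4
  for (p in seq_len(passes)) {
    pad <- rbind(img[1L, , drop = FALSE], img, img[nrow(img), , drop = FALSE])
    img <- k[1] * pad[seq_len(nrow(img)), ] + k[2] * pad[seq_len(nrow(img)) + 1L, ] +
      k[3] * pad[seq_len(nrow(img)) + 2L, ]
    pad <- cbind(img[, 1L, drop = FALSE], img, img[, ncol(img), drop = FALSE])
    img <- k[1] * pad[, seq_len(ncol(img))] + k[2] * pad[, seq_len(ncol(img)) + 1L] +
      k[3] * pad[, seq_len(ncol(img)) + 2L]
  }
  img
}

# downsample by 2 after blurring (image pyramid level)
pyr_down <- function(img) {
  img <- blur3(img, passes = 2L)
  img[seq(1L, nrow(img), by = 2L), seq(1L, ncol(img), by = 2L)]
}

#' Parameters of the synthetic fibrous texture
#'
#' Stand-in for the fluorescent fibronectin meshwork: bright fibers of
#' random position and orientation over a dim noisy background, giving the
#' high-contrast texture that feature tracking requires.
#'
#' @param size image size in pixels (square).
#' @param pixel_size um per pixel.
#' @param n_fibers number of fiber segments.
#' @param fiber_length mean fiber length (um).
#' @param fiber_intensity peak fiber brightness (image units).
#' @param background_sd background noise standard deviation.
#' @param seed integer seed.
#' @return Object of class `texture_params`.
#' @export
texture_params <- function(size = 192L, pixel_size = 0.4, n_fibers = 400L,
                           fiber_length = 8, fiber_intensity = 1,
                           background_sd = 0.02, seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_fibers = as.integer(n_fibers), fiber_length = fiber_length,
                 fiber_intensity = fiber_intensity,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "texture_params")
}

make_fiber_texture <- function(tex) {
  with_seed(tex$seed, {
    n <- tex$size
    img <- matrix(stats::rnorm(n * n, 0.1, tex$background_sd), n, n)
    len_px <- tex$fiber_length / tex$pixel_size
    for (f in seq_len(tex$n_fibers)) {
      r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
      th <- stats::runif(1, 0, pi)
      L <- stats::rexp(1, 1 / len_px)
      amp <- tex$fiber_intensity * stats::runif(1, 0.4, 1)
      steps <- seq(0, L, by = 0.5)
      rr <- round(r0 + steps * sin(th)); cc <- round(c0 + steps * cos(th))
      keep <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      img[cbind(rr[keep], cc[keep])] <- img[cbind(rr[keep], cc[keep])] + amp
    }
    img <- blur3(img, passes = 1L)
    img / max(img)
  })
}

#' Generate a textured image sequence warped by a displacement field
#'
#' Frame 1 is a random fiber texture; each later frame is the previous
#' frame warped by the incremental displacement of the field over one
#' frame interval (backward mapping with bilinear interpolation).  The
#' per-pixel ground-truth displacement between consecutive frames is
#' retained for tracker validation.
#'
#' @param field a [dipole_field_params()] object (evaluated analytically),
#'   or a function `f(x, y, t)` returning `list(u =, v =)` displacement
#'   rates (um/min) at physical positions.
#' @param tex a [texture_params()].
#' @param n_frames number of frames.
#' @param dt frame interval (min); taken from `field` when it is a
#'   parameter object.
#' @return List of image matrices with attributes `truth` (list of
#'   per-step data frames: `row`, `col`, `dx_px`, `dy_px` displacement of
#'   the scene between frame `k` and `k+1`, in pixels, image convention),
#'   `pixel_size` and `dt`.
#' @export
gen_texture_sequence <- function(field, tex, n_frames = 3L, dt = NULL) {
  if (inherits(field, "dipole_field_params")) {
    if (is.null(dt)) dt <- field$dt
    fun <- function(x, y, t) dipole_field_eval(field, x, y, t)
  } else if (is.function(field)) {
    if (is.null(dt)) stop("`dt` required when `field` is a function")
    fun <- field
  } else {
    stop("`field` must be dipole_field_params or a function(x, y, t)")
  }
  img <- make_fiber_texture(tex)
  n <- tex$size
  grid <- expand.grid(row = seq_len(n), col = seq_len(n))
  pos <- px_to_um(grid$row, grid$col, c(n, n), tex$pixel_size)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames - 1L)
  frames[[1L]] <- img
  for (k in seq_len(n_frames - 1L)) {
    t_k <- (k - 1L) * dt
    f <- fun(pos$x, pos$y, t_k)
    dx_um <- f$u * dt; dy_um <- f$v * dt
    # physical y up -> image row down
    dcol <- dx_um / tex$pixel_size
    drow <- -dy_um / tex$pixel_size
    maxd <- max(abs(c(dcol, drow)))
    if (maxd > n / 4) stop("displacement exceeds image margin")
    # backward warp: new(p) = old(p - d)
    frames[[k + 1L]] <- matrix(
      bilinear_interp(frames[[k]], grid$row - drow, grid$col - dcol,
                      fill = 0.1),
      n, n)
    truth[[k]] <- data.frame(row = grid$row, col = grid$col,
                             dx_px = dcol, dy_px = drow)
  }
  structure(frames, truth = truth, pixel_size = tex$pixel_size, dt = dt)
}
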