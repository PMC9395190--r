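#' Configuration of the pyramidal KLT feature tracker
#'
#' Defaults follow common practice for matrix-deformation tracking in
#' textured fluorescence/phase-contrast images: thousands of
#' minimum-eigenvalue corners spaced at least `min_distance` pixels apart,
#' tracked with an interrogation window of `window_size` pixels over a
#' two-level image pyramid, at most `max_iterations` refinement iterations
#' per level.  A separate, much sparser configuration estimates rigid
#' stage drift.
#'
#' @param n_features number of features requested per frame (5000-10000
#'   for full-size microscopy frames; scale down for small images).
#' @param min_distance minimum spacing between features (px).
#' @param window_size interrogation window size (px).
#' @param max_iterations iteration cap per pyramid level.
#' @param n_pyramids number of pyramid levels (1 = no pyramid).
#' @param fb_max_error forward-backward consistency threshold (px); tracks
#'   whose backward track misses the start by more are dropped.
#' @param drift list with the sparse drift-estimation settings.
#' @return Object of class `tracker_config`.
#' @export
tracker_config <- function(n_features = 8000L, min_distance = 10L,
                           window_size = 40L, max_iterations = 20L,
                           n_pyramids = 2L, fb_max_error = 1,
                           drift = list(n_features = 40L, min_distance = 8L,
                                        window_size = 20L, n_pyramids = 1L)) {
  if (window_size <= min_distance) {
    stop("window_size must exceed min_distance")
  }
  if (any(c(n_features, min_distance, window_size, max_iterations,
            n_pyramids) <= 0)) {
    stop("all tracker settings must be positive")
  }
  structure(list(n_features = as.integer(n_features),
                 min_distance = as.integer(min_distance),
                 window_size = as.integer(window_size),
                 max_iterations = as.integer(max_iterations),
                 n_pyramids = as.integer(n_pyramids),
                 fb_max_error = fb_max_error,
                 drift = drift),
            class = "tracker_config")
}

image_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gc <- matrix(0, nr, nc)  # d/dcol
  gc[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gr <- matrix(0, nr, nc)  # d/drow
  gr[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  list(gr = gr, gc = gc)
}

box_sum <- function(img, half) {
  # sum over (2*half+1)^2 neighbourhood via integral image
  nr <- nrow(img); nc <- ncol(img)
  ii <- rbind(0, cbind(0, t(apply(apply(img, 2L, cumsum), 1L, cumsum))))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- ii[cbind(r2 + 1L, c2[j] + 1L)] - ii[cbind(r1, c2[j] + 1L)] -
      ii[cbind(r2 + 1L, c1[j])] + ii[cbind(r1, c1[j])]
  }
  out
}

#' Detect trackable corner features
#'
#' Minimum-eigenvalue (Shi-Tomasi) scoring of the windowed structure
#' tensor with greedy non-maximal suppression at `min_distance`.
#'
#' @param img numeric image matrix.
#' @param config a [tracker_config()].
#' @param border margin to exclude (px); defaults to half the window.
#' @return Data frame with feature positions `row`, `col` (px, integer)
#'   and `score`.
#' @export
detect_features <- function(img, config, border = NULL) {
  g <- image_gradients(img)
  half <- max(2L, config$min_distance %/% 2L)
  a <- box_sum(g$gc * g$gc, half)
  b <- box_sum(g$gc * g$gr, half)
  c_ <- box_sum(g$gr * g$gr, half)
  lam <- ((a + c_) - sqrt((a - c_)^2 + 4 * b^2)) / 2
  if (is.null(border)) border <- config$window_size %/% 2L + 1L
  nr <- nrow(img); nc <- ncol(img)
  lam[c(seq_len(border), nr - seq_len(border) + 1L), ] <- -Inf
  lam[, c(seq_len(border), nc - seq_len(border) + 1L)] <- -Inf
  thr <- 1e-4 * max(lam)
  cand <- which(lam > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(row = integer(), col = integer(), score = numeric()))
  }
  sc <- lam[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]
  # greedy NMS on a coarse occupancy grid
  cell <- max(1L, config$min_distance)
  occ <- new.env(hash = TRUE)
  keep <- logical(nrow(cand))
  kept_r <- numeric(0); kept_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1L]; ci <- cand[i, 2L]
    gr_ <- ri %/% cell; gc_ <- ci %/% cell
    clash <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      key <- paste(gr_ + dr, gc_ + dc)
      pts <- occ[[key]]
      if (!is.null(pts) &&
          any((pts[, 1L] - ri)^2 + (pts[, 2L] - ci)^2 <
              config$min_distance^2)) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      keep[i] <- TRUE
      key <- paste(gr_, gc_)
      occ[[key]] <- rbind(occ[[key]], c(ri, ci))
      if (sum(keep) >= config$n_features) break
    }
  }
  data.frame(row = cand[keep, 1L], col = cand[keep, 2L], score = sc[keep])
}

build_pyramid <- function(img, n_levels) {
  pyr <- vector("list", n_levels)
  pyr[[1L]] <- img
  for (l in seq_len(n_levels - 1L)) pyr[[l + 1L]] <- pyr_down(pyr[[l]])
  pyr
}

# iterative LK at one pyramid level; pts and disp in this level's pixels
lk_level <- function(img1, grad1, img2, rows, cols, drow, dcol,
                     half, max_iter) {
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  n <- length(rows)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    wr <- rows[i] + offs$dr; wc <- cols[i] + offs$dc
    ix <- bilinear_interp(grad1$gc, wr, wc)
    iy <- bilinear_interp(grad1$gr, wr, wc)
    i1 <- bilinear_interp(img1, wr, wc)
    gxx <- sum(ix * ix); gxy <- sum(ix * iy); gyy <- sum(iy * iy)
    det <- gxx * gyy - gxy^2
    if (det < 1e-12) { ok[i] <- FALSE; next }
    for (it in seq_len(max_iter)) {
      i2 <- bilinear_interp(img2, wr + drow[i], wc + dcol[i])
      di <- i1 - i2
      bx <- sum(ix * di); by <- sum(iy * di)
      ddc <- (gyy * bx - gxy * by) / det
      ddr <- (gxx * by - gxy * bx) / det
      dcol[i] <- dcol[i] + ddc
      drow[i] <- drow[i] + ddr
      if (ddc^2 + ddr^2 < 1e-4) break
    }
    if (!is.finite(drow[i]) || !is.finite(dcol[i])) ok[i] <- FALSE
  }
  list(drow = drow, dcol = dcol, ok = ok)
}

# full pyramidal LK from img1 to img2 for features at integer (row, col)
lk_track <- function(img1, img2, feats, window_size, max_iter, n_pyr) {
  half <- window_size %/% 2L
  p1 <- build_pyramid(img1, n_pyr)
  p2 <- build_pyramid(img2, n_pyr)
  grads <- lapply(p1, image_gradients)
  n <- nrow(feats)
  drow <- rep(0, n); dcol <- rep(0, n); ok <- rep(TRUE, n)
  for (l in n_pyr:1) {
    sc <- 2^(l - 1L)
    res <- lk_level(p1[[l]], grads[[l]], p2[[l]],
                    (feats$row - 1) / sc + 1, (feats$col - 1) / sc + 1,
                    drow, dcol, half = max(2L, half %/% sc), max_iter)
    ok <- ok & res$ok
    drow <- res$drow; dcol <- res$dcol
    if (l > 1L) { drow <- drow * 2; dcol <- dcol * 2 }
  }
  data.frame(row = feats$row, col = feats$col,
             drow = drow, dcol = dcol, ok = ok)
}

#' Track matrix deformation through an image sequence
#'
#' For each consecutive frame pair, corner features detected on the
#' earlier frame are followed into the later frame with the pyramidal
#' Lucas-Kanade tracker; tracks failing the forward-backward consistency
#' check are dropped.  Pixel displacements are converted to physical
#' displacement rates (um/min).
#'
#' @param images list of image matrices (or a multi-page stack read by
#'   [read_image_stack()]).
#' @param config a [tracker_config()].
#' @param pixel_size um per pixel.
#' @param dt frame interval (min).
#' @return A [vector_field_series()] with one set of samples per frame
#'   pair (frame `k` holds the displacement rate between frames `k` and
#'   `k+1`).
#' @export
track <- function(images, config = tracker_config(), pixel_size, dt) {
  if (length(images) < 2L) stop("need at least two frames")
  dims <- dim(images[[1L]])
  frames <- vector("list", length(images) - 1L)
  for (k in seq_len(length(images) - 1L)) {
    feats <- detect_features(images[[k]], config)
    if (nrow(feats) == 0L) stop("no trackable features in frame ", k)
    fw <- lk_track(images[[k]], images[[k + 1L]], feats,
                   config$window_size, config$max_iterations,
                   config$n_pyramids)
    # forward-backward validation
    back_feats <- data.frame(row = fw$row + fw$drow, col = fw$col + fw$dcol)
    bw <- lk_track(images[[k + 1L]], images[[k]], back_feats,
                   config$window_size, config$max_iterations,
                   config$n_pyramids)
    fb_err <- sqrt((fw$drow + bw$drow)^2 + (fw$dcol + bw$dcol)^2)
    good <- fw$ok & bw$ok & fb_err < config$fb_max_error
    if (sum(good) < 0.1 * min(config$n_features, nrow(feats))) {
      stop(sprintf(
        "frame %d: only %d of %d tracks usable (<10%% of requested); %s",
        k, sum(good), nrow(feats),
        "check texture contrast and window size"))
    }
    pos <- px_to_um(fw$row[good], fw$col[good], dims, pixel_size)
    frames[[k]] <- data.frame(
      frame = k, x = pos$x, y = pos$y,
      u = fw$dcol[good] * pixel_size / dt,
      v = -fw$drow[good] * pixel_size / dt)
  }
  vector_field_series(do.call(rbind, frames), dt = dt,
                      pixel_size = pixel_size,
                      meta = list(tracker = "pyramidal KLT",
                                  window_px = config$window_size,
                                  n_pyramids = config$n_pyramids))
}

#' Estimate and subtract rigid stage drift
#'
#' Drift is estimated per frame pair from a small number of widely spaced
#' features tracked with a light single-level configuration, summarized by
#' the median displacement vector (robust to features on the cell), and
#' subtracted from every sample of the field.
#'
#' @param field a [vector_field_series()] from [track()].
#' @param images the image sequence the field was tracked on.
#' @param config a [tracker_config()]; its `drift` entry is used.
#' @return The drift-corrected [vector_field_series()]; the per-frame
#'   drift rates are attached as attribute `drift` (um/min).
#' @export
subtract_drift <- function(field, images, config = tracker_config()) {
  dcfg <- tracker_config(n_features = config$drift$n_features,
                         min_distance = config$drift$min_distance,
                         window_size = config$drift$window_size,
                         max_iterations = config$max_iterations,
                         n_pyramids = config$drift$n_pyramids)
  px <- attr(field, "pixel_size")
  dt <- attr(field, "dt")
  drift <- data.frame(frame = integer(), u = numeric(), v = numeric())
  for (k in seq_len(length(images) - 1L)) {
    feats <- detect_features(images[[k]], dcfg)
    tr <- lk_track(images[[k]], images[[k + 1L]], feats,
                   dcfg$window_size, dcfg$max_iterations, dcfg$n_pyramids)
    tr <- tr[tr$ok, ]
    du <- stats::median(tr$dcol) * px / dt
    dv <- -stats::median(tr$drow) * px / dt
    sel <- field$frame == k
    field$u[sel] <- field$u[sel] - du
    field$v[sel] <- field$v[sel] - dv
    drift <- rbind(drift, data.frame(frame = k, u = du, v = dv))
  }
  attr(field, "drift") <- drift
  field
}
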