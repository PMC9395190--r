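#' Write a vector field series as annotated tab-separated text
#'
#' The file starts with `# key: value` metadata lines (frame interval,
#' pixel size, plus anything in the field's `meta` attribute) followed by a
#' header line and one row per sample: `frame, x_um, y_um, u_um_per_min,
#' v_um_per_min`.
#'
#' @param field a [vector_field_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_tsv <- function(field, path) {
  meta <- c(list(dt_min = attr(field, "dt"),
                 pixel_size_um = attr(field, "pixel_size")),
            attr(field, "meta"))
  hdr <- vapply(names(meta),
                function(k) sprintf("# %s: %s", k, format(meta[[k]])),
                character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- data.frame(frame = field$frame,
                    x_um = field$x, y_um = field$y,
                    u_um_per_min = field$u, v_um_per_min = field$v)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(k)]] <- v
  }
  meta
}

#' Read a vector field series written by [write_field_tsv()]
#'
#' @param path file path.
#' @return A [vector_field_series()].
#' @export
read_field_tsv <- function(path) {
  meta <- read_tsv_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  names(df) <- c("frame", "x", "y", "u", "v")
  dt <- as.numeric(meta[["dt_min"]])
  px <- suppressWarnings(as.numeric(meta[["pixel_size_um"]]))
  meta[["dt_min"]] <- NULL
  meta[["pixel_size_um"]] <- NULL
  vector_field_series(df, dt = dt, pixel_size = px, meta = meta)
}

#' Write / read per-frame cell geometry as tab-separated text
#'
#' @param geometry a [cell_geometry_series()].
#' @param path file path.
#' @return `path` (write) or a [cell_geometry_series()] (read).
#' @export
write_geometry_tsv <- function(geometry, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_min: %s", format(attr(geometry, "dt"))), con)
  utils::write.table(as.data.frame(geometry), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry_tsv
#' @export
read_geometry_tsv <- function(path) {
  meta <- read_tsv_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  cell_geometry_series(df, dt = as.numeric(meta[["dt_min"]]))
}

#' Read or write a multi-page grayscale TIFF stack
#'
#' Thin wrappers around the `tiff` package returning a plain list of
#' numeric matrices in `[0, 1]`.  Frames are matrices indexed
#' `[row, column]`, i.e. image convention with y increasing downwards.
#'
#' @param path file path.
#' @param frames list of numeric matrices.
#' @return `read_image_stack()`: list of matrices; `write_image_stack()`:
#'   `path`, invisibly.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read TIFF stacks")
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(im) {
    if (length(dim(im)) == 3L) im <- im[, , 1L]  # first channel
    im
  })
}

#' @rdname read_image_stack
#' @export
write_image_stack <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write TIFF stacks")
  }
  frames <- lapply(frames, function(f) {
    f <- (f - min(f)) / max(max(f) - min(f), .Machine$double.eps)
    f
  })
  tiff::writeTIFF(frames, path)
  invisible(path)
}
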