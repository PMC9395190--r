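#' End-to-end gait analysis of a matrix displacement-rate field
#'
#' Runs the full analysis chain on one cell: grid divergence of the
#' field, kymograph along the cell axis, front/back contraction traces,
#' correlogram periods, front-back cross-correlation lag and phase
#' shift, dipole-quadrupole trajectory and cycle areas, and a
#' migrating / non-migrating classification.
#'
#' The classification rule is a repo convention, not biology: a cell is
#' called migrating when its normalized D-Q cycle area exceeds
#' `noise_floor` (e.g. from [dq_noise_floor()]) and the front-back lag
#' magnitude exceeds one frame interval.
#'
#' @param field a [vector_field_series()].
#' @param geometry a [cell_geometry_series()].
#' @param band_halfwidth kymograph band half-width (um).
#' @param trace_width front/back averaging window width (um, 2-5).
#' @param radii D-Q cutoff radius ensemble, see [dq_trajectory()].
#' @param noise_floor normalized-area noise floor (percent) for the
#'   classification; `NA` leaves the classification undecided.
#' @param mode eigenvalue convention, see [principal_components()].
#' @param output_dir when given, every intermediate (kymograph, front and
#'   back traces, correlograms, D-Q trajectory, cycle areas, summary) is
#'   written there as annotated tab-separated text.
#' @return An object of class `gait_analysis`; see [summary.gait_analysis()].
#' @examples
#' params <- dipole_field_params(psi = pi / 2, duration = 32, seed = 3)
#' ga <- gait_analysis(gen_dipole_field(params), dipole_field_geometry(params))
#' ga
#' @export
gait_analysis <- function(field, geometry, band_halfwidth = 5,
                          trace_width = 3, radii = c(0.6, 0.8, 1, 1.2),
                          noise_floor = NA_real_, mode = "magnitude",
                          output_dir = NULL) {
  divf <- divergence_field(field)
  kymo <- kymograph(divf, geometry, band_halfwidth)
  traces <- front_back_traces(kymo, geometry, trace_width)
  per_front <- find_period(autocorrelate(traces$front))
  per_back <- find_period(autocorrelate(traces$back))
  lag <- cross_correlate(traces$front, traces$back)
  periods <- c(per_front$period, per_back$period)
  period <- if (any(!is.na(periods))) mean(periods, na.rm = TRUE) else NA_real_
  psi <- if (lag$found && !is.na(period)) {
    phase_shift(lag$lag, period)
  } else {
    NA_real_
  }
  dq <- dq_trajectory(field, geometry, radii, mode = mode)
  areas <- if (!is.na(period)) dq_cycle_areas(dq, period) else NULL
  dt <- attr(field, "dt")
  classification <- NA_character_
  if (!is.na(noise_floor) && !is.null(areas) && lag$found) {
    norm_area <- attr(areas, "summary")[["normalized_mean"]]
    classification <- if (norm_area > noise_floor && abs(lag$lag) > dt) {
      "migrating"
    } else {
      "non-migrating"
    }
  }
  out <- structure(list(kymograph = kymo, traces = traces,
                        period_front = per_front, period_back = per_back,
                        lag = lag, psi = psi, dq = dq, areas = areas,
                        noise_floor = noise_floor,
                        classification = classification, dt = dt),
                   class = "gait_analysis")
  if (!is.null(output_dir)) write_gait_artifacts(out, output_dir)
  out
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, function(m) format(m), character(1L))),
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

write_gait_artifacts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- x$kymograph
  kdf <- data.frame(position_um = attr(k, "positions"),
                    unclass(k), check.names = FALSE)
  names(kdf)[-1L] <- sprintf("t_%g", attr(k, "times"))
  write_tsv_with_header(kdf, file.path(dir, "kymograph.tsv"),
                        list(dt_min = attr(k, "dt"),
                             band_halfwidth_um = attr(k, "band_halfwidth")))
  for (side in c("front", "back")) {
    tr <- x$traces[[side]]
    write_tsv_with_header(as.data.frame(tr),
                          file.path(dir, paste0("trace_", side, ".tsv")),
                          list(dt_min = attr(tr, "dt"),
                               label = attr(tr, "label")))
  }
  if (!is.null(x$lag$correlogram)) {
    write_tsv_with_header(x$lag$correlogram,
                          file.path(dir, "cross_correlogram.tsv"),
                          list(lag_min = x$lag$lag))
  }
  write_tsv_with_header(as.data.frame(x$dq), file.path(dir, "dq.tsv"),
                        list(dt_min = attr(x$dq, "dt")))
  if (!is.null(x$areas)) {
    write_tsv_with_header(as.data.frame(x$areas),
                          file.path(dir, "cycle_areas.tsv"),
                          as.list(attr(x$areas, "summary")))
  }
  write_tsv_with_header(summary(x), file.path(dir, "summary.tsv"),
                        list(noise_floor = x$noise_floor,
                             classification = x$classification))
  invisible(dir)
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("<gait_analysis>\n")
  cat(sprintf("  period front/back: %s / %s min\n",
              fmt_or_none(x$period_front$period),
              fmt_or_none(x$period_back$period)))
  cat(sprintf("  front-back lag: %s min; psi = %s rad\n",
              fmt_or_none(x$lag$lag), fmt_or_none(x$psi)))
  if (!is.null(x$areas)) {
    s <- attr(x$areas, "summary")
    cat(sprintf("  D-Q cycle area: %.4g um^5/min^2 (%.2f%% of bounding box)\n",
                s[["absolute_mean"]], s[["normalized_mean"]]))
  }
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

fmt_or_none <- function(v) if (is.na(v)) "none" else sprintf("%.3g", v)

#' @export
summary.gait_analysis <- function(object, ...) {
  s <- if (!is.null(object$areas)) attr(object$areas, "summary") else
    c(absolute_mean = NA_real_, absolute_sd = NA_real_,
      normalized_mean = NA_real_, normalized_sd = NA_real_)
  out <- data.frame(
    period_front = object$period_front$period,
    period_back = object$period_back$period,
    lag = object$lag$lag,
    psi = object$psi,
    area_abs = unname(s["absolute_mean"]),
    area_abs_sd = unname(s["absolute_sd"]),
    area_norm = unname(s["normalized_mean"]),
    area_norm_sd = unname(s["normalized_sd"]),
    classification = object$classification)
  class(out) <- c("summary.gait_analysis", "data.frame")
  out
}

#' @export
coef.gait_analysis <- function(object, ...) {
  s <- summary(object)
  stats::setNames(as.numeric(s[1L, 1:8]), names(s)[1:8])
}

#' @export
plot.gait_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$kymograph, main = "divergence kymograph")
  plot(x$traces$front, main = "front / back traces", col = 2)
  graphics::lines(x$traces$back$t, x$traces$back$value, col = 4)
  graphics::legend("topright", legend = c("front", "back"), col = c(2, 4),
                   lty = 1, bty = "n", cex = 0.8)
  if (!is.null(x$lag$correlogram)) {
    plot(x$lag$correlogram$lag, x$lag$correlogram$value, type = "l",
         xlab = "lag (min)", ylab = "cross-correlation",
         main = "front x back")
    graphics::abline(v = x$lag$lag, lty = 2, col = 2)
  }
  plot(x$dq, main = "D-Q trajectory")
  invisible(x)
}

#' Noise floor of the normalized D-Q cycle area
#'
#' Monte-Carlo reference distribution: fields containing measurement
#' noise only (`amplitude = 0`, same grid, duration and noise level as
#' `params`) are run through the D-Q cycle-area computation, and a high
#' quantile of their normalized areas is returned.  Normalized areas
#' above this floor cannot be explained by tracker jitter alone.
#'
#' @param params a [dipole_field_params()] describing the study
#'   conditions (its `amplitude` is ignored and set to zero).
#' @param n number of noise-only replicates.
#' @param probs quantile reported (default 0.95).
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @return The quantile of normalized areas (percent), with the full
#'   sample in attribute `samples`.
#' @export
dq_noise_floor <- function(params, n = 100L, probs = 0.95, seed = 100L) {
  vals <- vapply(seq_len(n), function(i) {
    p <- params
    p$amplitude <- 0
    p$seed <- as.integer(seed + i)
    field <- gen_dipole_field(p)
    geom <- dipole_field_geometry(p)
    dq <- dq_trajectory(field, geom, radii = 1)
    ca <- cycle_area(dq$D, dq$Q, params$T, params$dt)
    ca$normalized
  }, numeric(1L))
  structure(stats::quantile(vals, probs, names = FALSE), samples = vals)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y numeric vectors.
#' @return List with `r` and `p` (two-sided, from the t distribution).
#' @export
pearson_cor <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' @param values numeric vector of observations.
#' @param groups group labels (factor or vector).
#' @return List with the `H` statistic, degrees of freedom and `p` from
#'   the chi-square approximation (midrank tie handling).
#' @export
kruskal_wallis <- function(values, groups) {
  kt <- stats::kruskal.test(values, as.factor(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Power-law fit of persistent speed against oscillation period
#'
#' Least-squares fit of `log |V|` on `log T`, the readout discriminating
#' the swimmer-like `V ~ 1/T` and crawler-like `V ~ 1/T^2` behaviours.
#'
#' @param speed persistent speeds (um/min).
#' @param period oscillation periods (min).
#' @return List with `slope`, `se` and 95 percent `ci`
#'   (see [fit_power_law()]).
#' @export
speed_vs_period_fit <- function(speed, period) {
  fit_power_law(period, speed)
}
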