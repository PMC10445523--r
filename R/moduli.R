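# Dilatational moduli, amplitude sweeps, Lissajous analysis.

#' Dilatational elastic and viscous moduli from fitted cycles
#'
#' Given per-cycle sinusoid fits of interfacial tension and drop area, forms
#' the phase shift `delta = phase(gamma) - phase(area)` wrapped to (-pi, pi]
#' and the moduli
#' `Ed' = (dgamma / dA) * A0 * cos(delta)` and
#' `Ed'' = (dgamma / dA) * A0 * sin(delta)`,
#' where `dgamma` and `dA` are the fitted amplitudes.  For a physical
#' interface `delta` is expected in `[0, pi/2)`; values outside are flagged
#' (`physical = FALSE`) but not rejected.
#'
#' @param gamma_fit,area_fit [fit_sinusoid()] results for the tension and
#'   area signals of the same window.
#' @param A0 reference drop area in mm2.
#' @return An object of class `dilatational_moduli`: `elastic`, `viscous`
#'   (mN m-1), `phase` (radians), `amplitude_fraction` (dA/A0), `physical`.
#' @examples
#' t <- seq(0, 50, by = 1)
#' g <- fit_sinusoid(t, 20 + 2 * sin(2 * pi * 0.02 * t), 0.02)
#' a <- fit_sinusoid(t, 20 * (1 + 0.1 * sin(2 * pi * 0.02 * t)), 0.02)
#' dilatational_moduli(g, a, 20)   # purely elastic: Ed' = 20, Ed'' = 0
#' @export
dilatational_moduli <- function(gamma_fit, area_fit, A0) {
  stopifnot(inherits(gamma_fit, "cycle_fit"), inherits(area_fit, "cycle_fit"),
            A0 > 0)
  if (area_fit$amplitude <= 0) {
    stop("zero area amplitude: moduli undefined")
  }
  delta <- wrap_to_pi(gamma_fit$phase - area_fit$phase)
  ratio <- gamma_fit$amplitude / area_fit$amplitude * A0
  structure(list(elastic = ratio * cos(delta),
                 viscous = ratio * sin(delta),
                 phase = delta,
                 amplitude_fraction = area_fit$amplitude / A0,
                 physical = delta >= 0 && delta < pi / 2),
            class = "dilatational_moduli")
}

#' @export
print.dilatational_moduli <- function(x, ...) {
  cat(sprintf(
    "Ed' = %.4g, Ed'' = %.4g mN m-1 (delta = %.3g rad, dA/A0 = %.3g)%s\n",
    x$elastic, x$viscous, x$phase, x$amplitude_fraction,
    if (x$physical) "" else "  [phase outside [0, pi/2)]"))
  invisible(x)
}

#' Amplitude sweep: moduli per amplitude step
#'
#' Fits every complete active cycle of the record at the drive frequency and
#' averages the per-cycle moduli within each amplitude step; per-cycle
#' scatter is retained as standard deviations.  Steps without a single
#' complete cycle are omitted with a warning.
#'
#' @param series an [oscillation_series()] with a schedule.
#' @return A `data.frame` with one row per amplitude step: `step`,
#'   `amplitude` (target), `amplitude_fraction` (measured mean dA/A0),
#'   `elastic`, `viscous`, `phase`, their standard deviations `elastic_sd`,
#'   `viscous_sd`, and `n_cycles`.
#' @export
amplitude_sweep <- function(series) {
  cyc <- segment_cycles(series)
  if (is.null(cyc) || nrow(cyc) == 0L) stop("no complete active cycles")
  planned <- sum(series$schedule$active)
  steps <- split(cyc, cyc$step)
  if (length(steps) < planned) {
    warning(sprintf("%d amplitude step(s) without complete cycles omitted",
                    planned - length(steps)))
  }
  rows <- lapply(steps, function(sc) {
    mods <- lapply(seq_len(nrow(sc)), function(i) {
      idx <- sc$start[i]:sc$end[i]
      dilatational_moduli(
        fit_sinusoid(series$time[idx], series$gamma[idx], series$frequency),
        fit_sinusoid(series$time[idx], series$area[idx], series$frequency),
        series$reference_area)
    })
    el <- vapply(mods, `[[`, 0, "elastic")
    vi <- vapply(mods, `[[`, 0, "viscous")
    data.frame(step = sc$step[1], amplitude = sc$amplitude[1],
               amplitude_fraction =
                 mean(vapply(mods, `[[`, 0, "amplitude_fraction")),
               elastic = mean(el), viscous = mean(vi),
               phase = mean(vapply(mods, `[[`, 0, "phase")),
               elastic_sd = if (length(el) > 1L) stats::sd(el) else 0,
               viscous_sd = if (length(vi) > 1L) stats::sd(vi) else 0,
               n_cycles = nrow(sc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lissajous curve of one amplitude step
#'
#' Surface pressure `gamma - gamma0` against relative deformation
#' `(A - A0) / A0` over the middle 3 cycles of the step (cycles 2-4 of the
#' usual 5; all complete cycles if fewer than 5 are available).  The baseline
#' `gamma0` is the mean tension over the trailing half of the blank block
#' preceding the step; the first step falls back to the tail of the
#' pre-oscillation record, and failing that to the step's own mean.
#'
#' @param series an [oscillation_series()] with a schedule.
#' @param step active-step index (1-based, in schedule order).
#' @return A `data.frame` of class `lissajous_curve` with columns
#'   `deformation`, `pressure`, `cycle`, and attributes `gamma0`, `step`,
#'   `amplitude`.
#' @export
lissajous_curve <- function(series, step) {
  cyc <- segment_cycles(series)
  sc <- cyc[cyc$step == step, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no complete cycles in step ", step)
  pick <- if (nrow(sc) >= 5L) 2:4 else seq_len(nrow(sc))
  sc <- sc[pick, , drop = FALSE]
  step_start <- min(sc$start) - (min(sc$cycle) - 1L) * samples_per_cycle(series)
  gamma0 <- lissajous_baseline(series, step_start)
  idx <- unlist(lapply(seq_len(nrow(sc)),
                       function(i) sc$start[i]:sc$end[i]))
  out <- data.frame(
    deformation = (series$area[idx] - series$reference_area) /
      series$reference_area,
    pressure = series$gamma[idx] - gamma0,
    cycle = rep(sc$cycle, each = sc$end[1] - sc$start[1] + 1L))
  attr(out, "gamma0") <- gamma0
  attr(out, "step") <- step
  attr(out, "amplitude") <- sc$amplitude[1]
  class(out) <- c("lissajous_curve", "data.frame")
  out
}

# Mean gamma over the trailing half of the blank block preceding sample
# `step_start`; falls back to the pre-oscillation tail, then to NA.
lissajous_baseline <- function(series, step_start) {
  sch <- series$schedule
  prev <- sch[!sch$active & sch$end < step_start, , drop = FALSE]
  if (nrow(prev) > 0L) {
    b <- prev[nrow(prev), ]
    half <- b$start + floor((b$end - b$start) / 2)
    return(mean(series$gamma[half:b$end]))
  }
  if (step_start > 1L) {
    tail_idx <- max(1L, step_start - samples_per_cycle(series)):(step_start - 1L)
    return(mean(series$gamma[tail_idx]))
  }
  NA_real_
}

#' Enclosed area of a Lissajous curve
#'
#' Mean absolute shoelace area of the per-cycle polygons.  For a linear
#' viscoelastic response this equals `pi * dgamma * (dA/A0) * sin(delta)`, so
#' it vanishes for a purely elastic interface.
#'
#' @param curve a [lissajous_curve()].
#' @return Enclosed area in (mN m-1) x (relative deformation).
#' @export
lissajous_area <- function(curve) {
  stopifnot(inherits(curve, "lissajous_curve"))
  per_cycle <- vapply(split(seq_len(nrow(curve)), curve$cycle), function(i) {
    x <- curve$deformation[i]; y <- curve$pressure[i]
    j <- c(seq_along(i)[-1L], 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }, 0)
  mean(per_cycle)
}

#' Nonlinearity metrics of a Lissajous curve
#'
#' Quantifies strain softening/stiffening from the curve extremes: the
#' expansion (compression) secant modulus is the absolute surface pressure at
#' maximum expansion (compression) divided by the absolute deformation
#' there, and `asymmetry_ratio = (compression - expansion) / (compression +
#' expansion)` of the two secants, in `[-1, 1]`.  Positive values indicate
#' stiffening in compression and/or softening in expansion; a perfect
#' (linear) ellipse gives 0.
#'
#' @param curve a [lissajous_curve()].
#' @return A list with `expansion_secant_modulus`,
#'   `compression_secant_modulus` (mN m-1) and `asymmetry_ratio`.
#' @export
nonlinearity_metrics <- function(curve) {
  stopifnot(inherits(curve, "lissajous_curve"))
  x <- curve$deformation; y <- curve$pressure
  if (diff(range(x)) < 1e-12) stop("zero deformation range")
  ie <- which.max(x); ic <- which.min(x)
  sec_e <- abs(y[ie]) / abs(x[ie])
  sec_c <- abs(y[ic]) / abs(x[ic])
  list(expansion_secant_modulus = sec_e,
       compression_secant_modulus = sec_c,
       asymmetry_ratio = (sec_c - sec_e) / (sec_c + sec_e))
}
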