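# Oscillating-drop tensiometer records: containers, I/O and cycle handling.

#' Amplitude schedule of an oscillation run
#'
#' Describes the blocks of a drop-tensiometer protocol as sample-index
#' segments: each row is one block with its target relative area amplitude,
#' inclusive start/end sample indices, and whether the drop is actually
#' oscillated (`active`) or held (blank).  Segments must not overlap.
#'
#' @param amplitude target amplitude as a fraction of the reference area
#'   (0 for blank blocks).
#' @param start,end inclusive 1-based sample indices.
#' @param active logical, `TRUE` for oscillated blocks.
#' @return A `data.frame` of class `oscillation_schedule`.
#' @export
oscillation_schedule <- function(amplitude, start, end, active) {
  n <- length(amplitude)
  stopifnot(length(start) == n, length(end) == n, length(active) == n,
            all(start >= 1L), all(end >= start),
            all(amplitude >= 0), is.logical(active))
  o <- order(start)
  sch <- data.frame(amplitude = amplitude[o], start = as.integer(start[o]),
                    end = as.integer(end[o]), active = active[o])
  if (n > 1L && any(sch$start[-1L] <= sch$end[-n])) {
    stop("schedule segments overlap")
  }
  class(sch) <- c("oscillation_schedule", "data.frame")
  sch
}

#' Time-resolved interfacial tension and drop area record
#'
#' Couples uniformly sampled interfacial tension gamma(t) (mN m-1) and drop
#' surface area A(t) (mm2) with the drive frequency, the reference (resting)
#' drop area A0 and an amplitude schedule.  The tensiometer protocol mirrored
#' here oscillates the drop in blocks of cycles at one frequency, with blank
#' rest blocks in between.
#'
#' @param time sample times in seconds, strictly increasing, uniform.
#' @param gamma interfacial tension in mN m-1.
#' @param area drop surface area in mm2, positive.
#' @param frequency drive frequency in Hz.
#' @param reference_area resting drop area A0 in mm2 (default 20.0).
#' @param schedule an [oscillation_schedule()], or `NULL` if unknown.
#' @return An object of class `oscillation_series`.
#' @export
oscillation_series <- function(time, gamma, area, frequency,
                               reference_area = 20, schedule = NULL) {
  n <- length(time)
  stopifnot(n >= 2L, length(gamma) == n, length(area) == n,
            frequency > 0, reference_area > 0)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time must be uniformly sampled (within 1e-6 relative)")
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("area must be positive everywhere")
  }
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "oscillation_schedule"))
    if (max(schedule$end) > n) stop("schedule extends past the record")
  }
  structure(list(time = as.numeric(time), gamma = as.numeric(gamma),
                 area = as.numeric(area), frequency = frequency,
                 reference_area = reference_area, schedule = schedule),
            class = "oscillation_series")
}

#' @export
print.oscillation_series <- function(x, ...) {
  cat(sprintf(
    "oscillation_series: %d samples, %.3g s, f = %g Hz, A0 = %g mm2\n",
    length(x$time), diff(range(x$time)), x$frequency, x$reference_area))
  if (!is.null(x$schedule)) {
    act <- x$schedule[x$schedule$active, ]
    cat(sprintf("  schedule: %d active steps (amplitudes %s)\n", nrow(act),
                paste(signif(act$amplitude, 3), collapse = ", ")))
  }
  invisible(x)
}

samples_per_cycle <- function(series) {
  dt <- mean(diff(series$time))
  round(1 / (series$frequency * dt))
}

#' Split an oscillation record into complete active cycles
#'
#' Within each active schedule block, cycle boundaries are placed at integer
#' multiples of one period from the block start; trailing partial cycles are
#' dropped and blank blocks are excluded entirely.
#'
#' @param series an [oscillation_series()] with a schedule.
#' @return A `data.frame` with columns `step` (active-block index),
#'   `amplitude` (target), `cycle`, `start`, `end` (inclusive sample indices).
#' @export
segment_cycles <- function(series) {
  stopifnot(inherits(series, "oscillation_series"))
  if (is.null(series$schedule)) stop("series has no amplitude schedule")
  spc <- samples_per_cycle(series)
  if (spc < 8L) {
    stop("sampling rate below 8 points per period: cycles are unfittable")
  }
  act <- series$schedule[series$schedule$active, , drop = FALSE]
  out <- vector("list", nrow(act))
  for (s in seq_len(nrow(act))) {
    len <- act$end[s] - act$start[s] + 1L
    ncyc <- floor(len / spc)
    if (ncyc < 1L) next
    k <- seq_len(ncyc)
    out[[s]] <- data.frame(step = s, amplitude = act$amplitude[s],
                           cycle = k,
                           start = act$start[s] + (k - 1L) * spc,
                           end = act$start[s] + k * spc - 1L)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Fixed-frequency sinusoid fit
#'
#' Least-squares fit of `c + a sin(2 pi f t) + b cos(2 pi f t)` at the known
#' drive frequency over one window of samples.  The fit is exact for
#' noiseless sinusoids; for a constant (rank-degenerate) signal the amplitude
#' is zero and the phase is reported as 0 by convention.
#'
#' @param time,signal numeric vectors covering at least one period.
#' @param frequency drive frequency in Hz.
#' @return An object of class `cycle_fit`: `amplitude`, `phase` (radians in
#'   (-pi, pi], such that the fit is `offset + amplitude *
#'   sin(2 pi f t + phase)`), `offset`, `rms_residual`.
#' @export
fit_sinusoid <- function(time, signal, frequency) {
  stopifnot(length(time) == length(signal), frequency > 0)
  # a cycle of n samples spans (n-1)/n of a period (the next cycle owns the
  # endpoint), so accept windows down to 7/8 of a period
  if (diff(range(time)) < 0.875 / frequency - 1e-9 / frequency) {
    stop("window must cover at least one full period")
  }
  w <- 2 * pi * frequency
  X <- cbind(1, sin(w * time), cos(w * time))
  cf <- qr.coef(qr(X), signal)
  cf[is.na(cf)] <- 0
  res <- signal - X %*% cf
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  tol <- 1e-12 * max(1, max(abs(signal)))
  if (amp <= tol) amp <- 0   # rank-degenerate / constant signal
  structure(list(amplitude = amp,
                 phase = if (amp > 0) atan2(cf[3], cf[2]) else 0,
                 offset = cf[1],
                 rms_residual = sqrt(mean(res^2))),
            class = "cycle_fit")
}

#' Read / write oscillation records
#'
#' The record itself is a CSV with columns `time_s`, `gamma_mN_per_m`,
#' `area_mm2`.  The amplitude schedule, frequency and reference area travel
#' in a YAML sidecar; absent a sidecar, `read_oscillation_series` falls back
#' to best-effort auto-detection of the schedule from the area envelope
#' (see [detect_schedule()]).
#'
#' @param series an [oscillation_series()].
#' @param path CSV file path.
#' @param schedule_path YAML sidecar path (optional on read; written when
#'   given on write).
#' @param frequency,reference_area required on read only when no sidecar is
#'   available and auto-detection is used (`frequency` may still be `NULL`,
#'   in which case it is estimated from the dominant spectral line of the
#'   area signal).
#' @return `read_oscillation_series` returns an `oscillation_series`.
#' @export
write_oscillation_series <- function(series, path, schedule_path = NULL) {
  stopifnot(inherits(series, "oscillation_series"))
  utils::write.csv(data.frame(time_s = series$time,
                              gamma_mN_per_m = series$gamma,
                              area_mm2 = series$area),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(schedule_path)) {
    if (is.null(series$schedule)) stop("series has no schedule to write")
    yaml::write_yaml(list(frequency_hz = series$frequency,
                          reference_area_mm2 = series$reference_area,
                          steps = lapply(seq_len(nrow(series$schedule)),
                                         function(i) {
                            r <- series$schedule[i, ]
                            list(amplitude = r$amplitude, start = r$start,
                                 end = r$end, active = r$active)
                          })),
                     schedule_path)
  }
  invisible(path)
}

#' @rdname write_oscillation_series
#' @export
read_oscillation_series <- function(path, schedule_path = NULL,
                                    frequency = NULL, reference_area = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "gamma_mN_per_m", "area_mm2")
  if (!all(need %in% names(df))) {
    stop("oscillation CSV must have columns ", paste(need, collapse = ", "))
  }
  if (!is.null(schedule_path)) {
    y <- yaml::read_yaml(schedule_path)
    sch <- oscillation_schedule(
      amplitude = vapply(y$steps, function(s) as.numeric(s$amplitude), 0),
      start = vapply(y$steps, function(s) as.integer(s$start), 0L),
      end = vapply(y$steps, function(s) as.integer(s$end), 0L),
      active = vapply(y$steps, function(s) as.logical(s$active), NA))
    return(oscillation_series(df$time_s, df$gamma_mN_per_m, df$area_mm2,
                              frequency = y$frequency_hz,
                              reference_area = y$reference_area_mm2,
                              schedule = sch))
  }
  ser <- oscillation_series(df$time_s, df$gamma_mN_per_m, df$area_mm2,
                            frequency = frequency %||%
                              estimate_frequency(df$time_s, df$area_mm2),
                            reference_area = reference_area %||%
                              stats::median(df$area_mm2))
  ser$schedule <- detect_schedule(ser)
  ser
}

# Dominant non-zero spectral line of a detrended signal.
estimate_frequency <- function(time, signal) {
  n <- length(signal)
  dt <- mean(diff(time))
  sp <- Mod(stats::fft(signal - mean(signal)))[2:floor(n / 2)]
  (which.max(sp)) / (n * dt)
}

#' Auto-detect an amplitude schedule from the area envelope
#'
#' Best-effort recovery of the oscillation protocol when no sidecar is
#' available: the record is cut into consecutive one-period windows, each
#' window's relative area amplitude is fitted at the drive frequency, windows
#' above a 2% amplitude threshold are marked active, and consecutive active
#' windows with similar amplitude (within 25% relative) are merged into
#' steps.  Intended for well-separated stepwise protocols only.
#'
#' @param series an [oscillation_series()].
#' @param threshold minimum relative amplitude treated as active.
#' @return An [oscillation_schedule()].
#' @export
detect_schedule <- function(series, threshold = 0.02) {
  spc <- samples_per_cycle(series)
  n <- length(series$time)
  nwin <- floor(n / spc)
  if (nwin < 1L) stop("record shorter than one period")
  amp <- numeric(nwin)
  for (k in seq_len(nwin)) {
    idx <- ((k - 1L) * spc + 1L):(k * spc)
    amp[k] <- fit_sinusoid(series$time[idx], series$area[idx],
                           series$frequency)$amplitude /
      series$reference_area
  }
  active <- amp > threshold
  # merge consecutive windows of the same state (and similar active amplitude)
  grp <- cumsum(c(TRUE, abs(diff(active)) > 0 |
                    (active[-1L] & active[-nwin] &
                       abs(diff(amp)) > 0.25 * pmax(amp[-nwin], 1e-12))))
  segs <- split(seq_len(nwin), grp)
  oscillation_schedule(
    amplitude = vapply(segs, function(w) if (active[w[1]]) mean(amp[w]) else 0,
                       0),
    start = vapply(segs, function(w) (w[1] - 1L) * spc + 1L, 0),
    end = vapply(segs, function(w) w[length(w)] * spc, 0),
    active = vapply(segs, function(w) active[w[1]], NA))
}
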