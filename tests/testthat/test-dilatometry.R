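# Oscillatory dilatational rheology: segmentation, harmonic fits, moduli,
# Lissajous analysis.

test_that("cycle segmentation honours the active/blank schedule", {
  # 5 active cycles at 0.02 Hz sampled at 1 Hz: 5 ranges of 50 samples
  ser <- gen_oscillation_series(amplitudes = 0.1, samples_per_cycle = 50,
                                cycles_per_step = 5, blank_cycles = 5)
  cyc <- segment_cycles(ser)
  expect_equal(nrow(cyc), 5)
  expect_true(all(cyc$end - cyc$start + 1L == 50L))

  # active + blank + active: ranges never fall inside the blank block
  ser2 <- gen_oscillation_series(amplitudes = c(0.1, 0.2))
  cyc2 <- segment_cycles(ser2)
  expect_equal(nrow(cyc2), 10)
  blanks <- ser2$schedule[!ser2$schedule$active, ]
  for (i in seq_len(nrow(blanks))) {
    expect_false(any(cyc2$start <= blanks$end[i] & cyc2$end >= blanks$start[i]))
  }

  # 4.5 cycles of data: the trailing partial cycle is dropped
  ser3 <- gen_oscillation_series(amplitudes = 0.1, cycles_per_step = 5,
                                 blank_cycles = 0)
  keep <- 1:(4.5 * 50)
  sch <- oscillation_schedule(0.1, 1, length(keep), TRUE)
  ser3b <- oscillation_series(ser3$time[keep], ser3$gamma[keep],
                              ser3$area[keep], ser3$frequency,
                              ser3$reference_area, sch)
  expect_equal(nrow(segment_cycles(ser3b)), 4)

  # under 8 points per period is unfittable
  coarse <- gen_oscillation_series(amplitudes = 0.1, samples_per_cycle = 8)
  coarse$time <- coarse$time * 2          # halves the sampling density
  expect_error(segment_cycles(coarse), "unfittable")
})

test_that("fixed-frequency sinusoid fits are exact on noiseless signals", {
  f <- 0.02
  t <- seq(0, 49, by = 1)
  fit <- fit_sinusoid(t, 3 + 2 * sin(2 * pi * f * t), f)
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$phase, 0, tolerance = 1e-9)
  expect_equal(fit$offset, 3, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  fit2 <- fit_sinusoid(t, sin(2 * pi * f * t + pi / 4), f)
  expect_equal(fit2$phase, pi / 4, tolerance = 1e-9)

  # quadrature pair differs by exactly pi/2
  fs <- fit_sinusoid(t, sin(2 * pi * f * t), f)
  fc <- fit_sinusoid(t, cos(2 * pi * f * t), f)
  expect_equal(fc$phase - fs$phase, pi / 2, tolerance = 1e-9)

  # constant signal: zero amplitude, phase 0 by convention
  fit3 <- fit_sinusoid(t, rep(5, length(t)), f)
  expect_equal(fit3$amplitude, 0, tolerance = 1e-9)
  expect_equal(fit3$phase, 0)
})

test_that("moduli follow the amplitude-ratio and phase relations", {
  f <- 0.02
  t <- seq(0, 49, by = 1)
  afit <- fit_sinusoid(t, 20 * (1 + 0.1 * sin(2 * pi * f * t)), f)
  gfit0 <- fit_sinusoid(t, 20 + 2 * sin(2 * pi * f * t), f)
  m0 <- dilatational_moduli(gfit0, afit, 20)
  expect_equal(m0$elastic, 20, tolerance = 1e-9)
  expect_equal(m0$viscous, 0, tolerance = 1e-6)

  gfit1 <- fit_sinusoid(t, 20 + 2 * sin(2 * pi * f * t + pi / 6), f)
  m1 <- dilatational_moduli(gfit1, afit, 20)
  expect_equal(m1$elastic, 20 * cos(pi / 6), tolerance = 1e-9)  # 17.32
  expect_equal(m1$viscous, 20 * sin(pi / 6), tolerance = 1e-9)  # 10.00
  expect_equal(m1$viscous, m1$elastic * tan(m1$phase), tolerance = 1e-6)

  gfit2 <- fit_sinusoid(t, 20 + 2 * sin(2 * pi * f * t + pi / 2), f)
  m2 <- dilatational_moduli(gfit2, afit, 20)
  expect_equal(m2$elastic, 0, tolerance = 1e-9)

  # magnitude identity Ed'^2 + Ed''^2 = (dgamma A0 / dA)^2
  expect_equal(m1$elastic^2 + m1$viscous^2,
               (gfit1$amplitude / afit$amplitude * 20)^2, tolerance = 1e-9)

  const <- fit_sinusoid(t, rep(20, length(t)), f)
  expect_error(dilatational_moduli(gfit0, const, 20), "undefined")
})

test_that("amplitude sweeps invert the generator across moduli and noise", {
  # noiseless recovery over a grid of ground-truth moduli
  for (ed in list(c(0, 10), c(19, 3), c(50, 0), c(12, 12))) {
    ser <- gen_oscillation_series(elastic = ed[1], viscous = ed[2],
                                  amplitudes = c(0.1, 0.5))
    sw <- amplitude_sweep(ser)
    expect_equal(nrow(sw), 2)
    expect_equal(sw$elastic, rep(ed[1], 2), tolerance = 1e-6)
    expect_equal(sw$viscous, rep(ed[2], 2), tolerance = 1e-6)
  }

  # single-step schedule gives a length-1 sweep
  expect_equal(nrow(amplitude_sweep(gen_oscillation_series(amplitudes = 0.3))),
               1)

  # 1% multiplicative noise at 50 samples/cycle recovers within 5%
  ser <- gen_oscillation_series(19, 3, noise_sd = 0.01, seed = 42)
  sw <- amplitude_sweep(ser)
  expect_true(all(rel_err(sw$elastic, 19) < 0.05))
})

test_that("sweep results are invariant to time offset and subsampling", {
  ser <- gen_oscillation_series(19, 3, samples_per_cycle = 48, seed = 1)
  ref <- amplitude_sweep(ser)

  shifted <- oscillation_series(ser$time + 137.5, ser$gamma, ser$area,
                                ser$frequency, ser$reference_area,
                                ser$schedule)
  sw_shift <- amplitude_sweep(shifted)
  expect_equal(sw_shift$elastic, ref$elastic, tolerance = 1e-9)
  expect_equal(sw_shift$viscous, ref$viscous, tolerance = 1e-9)

  # every 3rd sample: 16 points per cycle, still within 1%
  keep <- seq(1, length(ser$time), by = 3)
  sch <- ser$schedule
  sch$start <- (sch$start - 1L) %/% 3L + 1L
  sch$end <- sch$end %/% 3L
  sub <- oscillation_series(ser$time[keep], ser$gamma[keep], ser$area[keep],
                            ser$frequency, ser$reference_area, sch)
  sw_sub <- amplitude_sweep(sub)
  expect_true(all(rel_err(sw_sub$elastic, ref$elastic) < 0.01))
  expect_true(all(rel_err(sw_sub$viscous, ref$viscous) < 0.01))
})

test_that("Lissajous curves have the analytic shape, area and baseline", {
  # purely elastic: the curve degenerates to a line segment
  ser0 <- gen_oscillation_series(19, 0)
  lc0 <- lissajous_curve(ser0, 2)
  expect_lt(lissajous_area(lc0), 1e-9)
  expect_equal(attr(lc0, "gamma0"), 20, tolerance = 1e-9)

  # viscoelastic ellipse: enclosed area pi * dgamma * (dA/A0) * sin(delta)
  ser <- gen_oscillation_series(19, 3)
  a <- 0.3
  lc <- lissajous_curve(ser, 3)
  expect_equal(attr(lc, "amplitude"), a)
  expect_equal(length(unique(lc$cycle)), 3)   # the middle 3 of 5 cycles
  expect_equal(sort(unique(lc$cycle)), 2:4)
  delta <- atan2(3, 19)
  analytic <- pi * (a * sqrt(19^2 + 3^2)) * a * sin(delta)
  expect_equal(lissajous_area(lc), analytic, tolerance = 0.01)

  # enclosed area vanishes as the phase angle does
  areas <- vapply(c(4, 2, 0.5), function(v) {
    lissajous_area(lissajous_curve(gen_oscillation_series(19, v), 3))
  }, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("nonlinearity metrics read softening/stiffening asymmetry", {
  # a linear response is symmetric
  nm0 <- nonlinearity_metrics(lissajous_curve(gen_oscillation_series(19, 3), 4))
  expect_equal(nm0$asymmetry_ratio, 0, tolerance = 1e-9)

  # compression-stiffening distortion: positive asymmetry
  hard <- gen_oscillation_series(19, 3, stiffening = 8)
  nm1 <- nonlinearity_metrics(lissajous_curve(hard, 5))
  expect_gt(nm1$asymmetry_ratio, 0.05)

  # flipping the distortion flips the sign
  soft <- gen_oscillation_series(19, 3, stiffening = -8)
  nm2 <- nonlinearity_metrics(lissajous_curve(soft, 5))
  expect_equal(nm2$asymmetry_ratio, -nm1$asymmetry_ratio, tolerance = 1e-6)

  # an odd third harmonic bends the shape (large residual from a straight
  # line) without breaking expansion/compression symmetry
  bent <- gen_oscillation_series(19, 0, harmonic3 = 4)
  lc <- lissajous_curve(bent, 5)
  lin <- stats::lm(pressure ~ deformation, data = lc)
  straight <- lissajous_curve(gen_oscillation_series(19, 0), 5)
  lin0 <- stats::lm(pressure ~ deformation, data = straight)
  expect_gt(max(abs(stats::resid(lin))), 0.5)
  expect_lt(max(abs(stats::resid(lin0))), 1e-9)
  nm3 <- nonlinearity_metrics(lc)
  expect_equal(nm3$asymmetry_ratio, 0, tolerance = 1e-6)
})

test_that("oscillation records round-trip through CSV + YAML sidecar", {
  ser <- gen_oscillation_series(19, 3, noise_sd = 0.005, seed = 9)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_oscillation_series(ser, csv, yml)
  back <- read_oscillation_series(csv, yml)
  expect_equal(back$gamma, ser$gamma, tolerance = 1e-6)
  expect_equal(back$frequency, ser$frequency)
  expect_equal(back$schedule$start, ser$schedule$start)
  sw <- amplitude_sweep(back)
  expect_true(all(rel_err(sw$elastic, 19) < 0.05))
})

test_that("schedule auto-detection recovers a stepwise protocol", {
  ser <- gen_oscillation_series(19, 3, amplitudes = c(0.1, 0.3, 0.5),
                                noise_sd = 0.002, seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_oscillation_series(ser, csv)
  back <- read_oscillation_series(csv, frequency = 0.02,
                                  reference_area = 20)
  act <- back$schedule[back$schedule$active, ]
  expect_equal(nrow(act), 3)
  expect_equal(act$amplitude, c(0.1, 0.3, 0.5), tolerance = 0.05)
  sw <- amplitude_sweep(back)
  expect_true(all(rel_err(sw$elastic, 19) < 0.02))
})
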