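# Seeded synthetic-data generators.
#
# These emulate the statistical structure of the pipeline's inputs -- a
# light-scattering size distribution, a drop-tensiometer oscillation record,
# a two-droplet bead trajectory, replicate fusion outcomes -- so every
# analyzer can be exercised and inverted without instruments or an MD
# engine.  Trajectory "dynamics" are scripted geometry plus Gaussian jitter,
# not physics.  Every generator embeds its ground truth in the output's
# `truth` attribute, and all randomness flows from the seed.

#' Synthetic log-normal droplet size distribution
#'
#' Discretizes a log-normal number-weighted diameter law (number median
#' `median`, geometric standard deviation `gsd`) over `n_bins` log-spaced
#' bins spanning +/- 4 log-sd, converts to volume weights (the form a
#' laser-diffraction instrument reports) and optionally roughens the weights
#' with multiplicative log-normal noise.  Under this convention the
#' continuous law has the closed form `d4,3 = median * exp(3.5 * log(gsd)^2)`,
#' which is stored in the `truth` attribute for recovery tests; by default
#' the median is chosen so that d4,3 equals `target_d43`.
#'
#' @param target_d43 target volume mean diameter in um (ignored when
#'   `median` is given).
#' @param gsd geometric standard deviation (>= 1; 1 gives a monodisperse
#'   single bin).
#' @param median number-median diameter in um (overrides `target_d43`).
#' @param n_bins number of diameter bins.
#' @param noise_sd standard deviation of the log-normal weight noise.
#' @param seed integer RNG seed.
#' @return A volume-weighted [size_distribution()] with attribute `truth`
#'   (list: `d43`, `median`, `gsd`, `seed`).
#' @examples
#' d <- gen_size_distribution(target_d43 = 1.7, gsd = 1.5, seed = 1)
#' d43(d)   # ~1.7
#' @export
gen_size_distribution <- function(target_d43 = 1.7, gsd = 1.5,
                                  median = NULL, n_bins = 80,
                                  noise_sd = 0.02, seed = 1) {
  if (gsd < 1) stop("geometric standard deviation must be >= 1")
  sig <- log(gsd)
  if (is.null(median)) median <- target_d43 / exp(3.5 * sig^2)
  stopifnot(median > 0, n_bins >= 1L)
  mu <- log(median)
  truth <- list(d43 = median * exp(3.5 * sig^2), median = median,
                gsd = gsd, seed = seed)
  if (sig == 0) {
    out <- size_distribution(median, 1, "volume")
    attr(out, "truth") <- truth
    return(out)
  }
  lg <- seq(mu - 4 * sig, mu + 4 * sig, length.out = n_bins)
  d <- exp(lg)
  w_num <- stats::dnorm(lg, mu, sig)          # number weight per log-bin
  w_vol <- w_num * d^3
  if (noise_sd > 0) {
    w_vol <- w_vol * with_seed(seed, exp(stats::rnorm(n_bins, 0, noise_sd)))
  }
  out <- size_distribution(d, w_vol, "volume")
  attr(out, "truth") <- truth
  out
}

#' Synthetic drop-tensiometer oscillation record
#'
#' Inverts the dilatational-moduli relations: per amplitude step `a` the
#' drop area is `A0 (1 + a sin(2 pi f t))` over `cycles_per_step` cycles
#' followed by `blank_cycles` resting cycles (plus a resting lead-in), and
#' the tension is
#' `gamma0 + a (Ed' sin + Ed'' cos) - stiffening x^2 + a harmonic3 sin(3 .)`
#' with `x` the instantaneous relative deformation, plus multiplicative
#' Gaussian noise.  Positive `stiffening` produces a compression-stiffening
#' (asymmetric) response; `harmonic3` adds an odd third-harmonic distortion
#' that bends the Lissajous shape without breaking expansion/compression
#' symmetry.
#'
#' @param elastic,viscous ground-truth moduli Ed' and Ed'' in mN m-1.
#' @param gamma0 resting interfacial tension, mN m-1.
#' @param reference_area resting drop area A0, mm2.
#' @param amplitudes relative amplitude per step (fractions of A0).
#' @param frequency drive frequency, Hz.
#' @param samples_per_cycle samples per oscillation period.
#' @param cycles_per_step,blank_cycles active and resting cycles per step.
#' @param noise_sd relative sd of the multiplicative tension noise.
#' @param stiffening even-order distortion coefficient, mN m-1 per squared
#'   relative deformation.
#' @param harmonic3 odd third-harmonic distortion amplitude, mN m-1 per unit
#'   relative deformation.
#' @param seed integer RNG seed.
#' @return An [oscillation_series()] with attribute `truth`.
#' @export
gen_oscillation_series <- function(elastic = 19, viscous = 3, gamma0 = 20,
                                   reference_area = 20,
                                   amplitudes = seq(0.1, 0.5, by = 0.1),
                                   frequency = 0.02,
                                   samples_per_cycle = 50,
                                   cycles_per_step = 5, blank_cycles = 5,
                                   noise_sd = 0, stiffening = 0,
                                   harmonic3 = 0, seed = 1) {
  stopifnot(elastic >= 0, viscous >= 0, length(amplitudes) >= 1L,
            all(amplitudes > 0), frequency > 0, samples_per_cycle >= 8L,
            cycles_per_step >= 1L, blank_cycles >= 0L)
  spc <- as.integer(samples_per_cycle)
  dt <- 1 / (frequency * spc)
  blocks <- list(list(amplitude = 0, cycles = max(blank_cycles, 1L),
                      active = FALSE))
  for (a in amplitudes) {
    blocks <- c(blocks, list(list(amplitude = a, cycles = cycles_per_step,
                                  active = TRUE)))
    if (blank_cycles > 0L) {
      blocks <- c(blocks, list(list(amplitude = 0, cycles = blank_cycles,
                                    active = FALSE)))
    }
  }
  ncyc <- vapply(blocks, `[[`, 0, "cycles")
  ends <- cumsum(ncyc * spc)
  starts <- c(1, ends[-length(ends)] + 1)
  n <- ends[length(ends)]
  time <- (seq_len(n) - 1) * dt
  area <- rep(reference_area, n)
  gamma <- rep(gamma0, n)
  for (b in seq_along(blocks)) {
    if (!blocks[[b]]$active) next
    idx <- starts[b]:ends[b]
    a <- blocks[[b]]$amplitude
    th <- 2 * pi * frequency * (time[idx] - time[idx[1]])
    x <- a * sin(th)
    area[idx] <- reference_area * (1 + x)
    gamma[idx] <- gamma0 + elastic * x + viscous * a * cos(th) -
      stiffening * x^2 + harmonic3 * a * sin(3 * th)
  }
  if (noise_sd > 0) {
    gamma <- gamma * (1 + with_seed(seed, stats::rnorm(n, 0, noise_sd)))
  }
  sch <- oscillation_schedule(
    amplitude = vapply(blocks, `[[`, 0, "amplitude"),
    start = starts, end = ends,
    active = vapply(blocks, `[[`, NA, "active"))
  out <- oscillation_series(time, gamma, area, frequency,
                            reference_area, sch)
  attr(out, "truth") <- list(elastic = elastic, viscous = viscous,
                             gamma0 = gamma0, amplitudes = amplitudes,
                             noise_sd = noise_sd, stiffening = stiffening,
                             harmonic3 = harmonic3, seed = seed)
  out
}

#' Droplet build specification
#'
#' Bundle of the parameters defining one droplet of a two-droplet system:
#' core molecule count and radius, shell molecule count and target surface
#' density (or explicit head-sphere radius).  When both a shell density and
#' radius are supplied they must agree through `n / (4 pi R^2)`.
#'
#' @param n_core core molecule count (> 0).
#' @param core_radius core radius, nm (`NULL`: derived from the template's
#'   molecule volume at build time).
#' @param n_shell shell molecule count (0 for a bare droplet).
#' @param shell_density target shell density, nm-2.
#' @param shell_radius explicit shell head-sphere radius, nm.
#' @return An object of class `droplet_spec`.
#' @export
droplet_spec <- function(n_core, core_radius = NULL, n_shell = 0,
                         shell_density = NULL, shell_radius = NULL) {
  stopifnot(n_core >= 1L, n_shell >= 0L)
  if (!is.null(core_radius)) stopifnot(core_radius > 0)
  if (!is.null(shell_density) && !is.null(shell_radius)) {
    implied <- n_shell / (4 * pi * shell_radius^2)
    if (abs(implied - shell_density) > 1e-6 * shell_density) {
      stop("shell_density and shell_radius are inconsistent")
    }
  }
  structure(list(n_core = as.integer(n_core), core_radius = core_radius,
                 n_shell = as.integer(n_shell),
                 shell_density = shell_density,
                 shell_radius = shell_radius),
            class = "droplet_spec")
}

#' Synthetic two-droplet bead trajectory
#'
#' Builds a phospholipid-coated droplet and a bare oil droplet, composes
#' them with a surface gap along x, and emits `n_frames` frames of the
#' static pair with independent Gaussian bead jitter.  When `fuse_at` is
#' set, a scripted fusion runs from that frame: the free droplet is first
#' translated into surface contact (so the first inter-droplet contact
#' occurs at `fuse_at` itself), then positions interpolate linearly over
#' `merge_frames` frames towards an endpoint in which both cores form a
#' single sphere of conserved total volume (radius `(Ra^3 + Rb^3)^(1/3)`)
#' and the shell is redistributed on a sphere scaled by the same ratio, so
#' first-contact, radius and shell-density recovery all have closed-form
#' truths.  Scripted geometry, not dynamics.
#'
#' @param spec_a [droplet_spec()] of the coated droplet.
#' @param spec_b [droplet_spec()] of the bare droplet.
#' @param n_frames number of frames.
#' @param jitter_sd per-bead Gaussian jitter sd, nm.
#' @param fuse_at 1-based frame at which the scripted fusion starts, or
#'   `NULL` for a non-fusing run.
#' @param gap initial surface-to-surface distance, nm (kept larger than the
#'   detection cutoff for non-fusing runs).
#' @param box periodic box, nm (`NULL`: fitted around the pair with a 3 nm
#'   margin).
#' @param merge_frames frames over which the fusion interpolates.
#' @param core_template,shell_template molecule templates.
#' @param dt_ps frame spacing in ps (metadata only).
#' @param seed integer RNG seed.
#' @return A [frame_set()] with attribute `truth` (list incl. `fuse_at`,
#'   `gap`, core radii and shell radii before/after).
#' @export
gen_two_droplet_trajectory <- function(spec_a, spec_b, n_frames = 40,
                                       jitter_sd = 0.02, fuse_at = NULL,
                                       gap = 2.0, box = NULL,
                                       merge_frames = 10L,
                                       core_template = template_triolein(),
                                       shell_template = template_dppc(),
                                       dt_ps = 10, seed = 1) {
  stopifnot(inherits(spec_a, "droplet_spec"), inherits(spec_b, "droplet_spec"),
            n_frames >= 1L, jitter_sd >= 0, gap >= 0, merge_frames >= 1L)
  a <- build_droplet(core_template, spec_a$n_core,
                     radius = spec_a$core_radius,
                     shell_template = shell_template,
                     n_shell = spec_a$n_shell,
                     shell_density = spec_a$shell_density,
                     shell_radius = spec_a$shell_radius,
                     seed = seed, core_component = "oleosome_core",
                     shell_component = "oleosome_shell")
  b <- build_droplet(core_template, spec_b$n_core,
                     radius = spec_b$core_radius,
                     seed = seed + 50L, core_component = "free_tag")
  if (is.null(box)) {
    ext <- function(s) apply(s$pos, 2L, function(v) diff(range(v)))
    margin <- 3
    box <- c(ext(a)[1] + ext(b)[1] + gap + 2 * margin,
             max(ext(a)[2], ext(b)[2]) + 2 * margin,
             max(ext(a)[3], ext(b)[3]) + 2 * margin)
  }
  base <- compose_two_droplet_box(a, b, gap = gap, box = box)
  ra <- attr(a, "core_radius"); rb <- attr(b, "core_radius")
  shell_r <- attr(a, "shell_radius")
  truth <- list(fuse_at = fuse_at, gap = gap, seed = seed,
                core_radius_a = ra, core_radius_b = rb,
                shell_radius_before = shell_r,
                shell_radius_after = NA_real_,
                merged_radius = NA_real_)
  final_pos <- NULL
  if (!is.null(fuse_at)) {
    rm_ <- (ra^3 + rb^3)^(1 / 3)
    centers <- attr(base, "centers")
    wa <- ra^3 / (ra^3 + rb^3)
    cm <- wa * centers[1, ] + (1 - wa) * centers[2, ]
    merged_core <- build_core(core_template, spec_a$n_core + spec_b$n_core,
                              radius = rm_, seed = seed + 101L,
                              component = "merged", center = cm)
  nbt <- length(core_template$beads)
    na_beads <- spec_a$n_core * nbt
    core_a_pos <- merged_core$pos[seq_len(na_beads), , drop = FALSE]
    core_b_pos <- merged_core$pos[-seq_len(na_beads), , drop = FALSE]
    shell_final <- NULL
    if (spec_a$n_shell > 0L) {
      shell_r_after <- shell_r * rm_ / ra
      shell_final <- build_shell(NULL, shell_template, spec_a$n_shell,
                                 radius = shell_r_after, seed = seed + 102L,
                                 center = cm)
      truth$shell_radius_after <- shell_r_after
    }
    truth$merged_radius <- rm_
    final_pos <- rbind(core_a_pos,
                       if (is.null(shell_final)) NULL else shell_final$pos,
                       core_b_pos)
    stopifnot(nrow(final_pos) == n_beads(base))
  }
  # bridge configuration: the free droplet translated into slight surface
  # overlap, so the first inter-droplet contact lands at fuse_at itself
  contact_pos <- base$pos
  if (!is.null(fuse_at)) {
    free_sel <- base$component == "free_tag"
    contact_pos[free_sel, 1] <- contact_pos[free_sel, 1] - (gap + 0.3)
  }
  frames <- with_seed(seed + 1L, lapply(seq_len(n_frames), function(f) {
    p <- if (is.null(fuse_at) || f < fuse_at) {
      base$pos
    } else {
      lam <- min(1, (f - fuse_at + 1) / merge_frames)
      (1 - lam) * contact_pos + lam * final_pos
    }
    if (jitter_sd > 0) {
      p <- p + matrix(stats::rnorm(length(p), 0, jitter_sd), ncol = 3L)
    }
    fr <- base
    fr$pos <- p
    wrap_system(fr)
  }))
  out <- frame_set(frames, times = (seq_len(n_frames) - 1) * dt_ps)
  attr(out, "truth") <- truth
  out
}

#' Synthetic replicate fusion outcomes
#'
#' Seeded Bernoulli(p) outcomes packaged as [fusion_record()]s (fused
#' records carry a nominal uniformly drawn first-contact frame).
#'
#' @param p fusion probability in `[0, 1]`.
#' @param n number of replicate runs.
#' @param seed integer RNG seed.
#' @return A list of `n` [fusion_record()] objects with attribute `truth`.
#' @export
gen_fusion_outcomes <- function(p, n, seed = 1) {
  stopifnot(p >= 0, p <= 1, n >= 1L)
  with_seed(seed, {
    fused <- stats::runif(n) < p
    fc <- sample.int(100L, n, replace = TRUE)
    out <- lapply(seq_len(n), function(i) {
      fusion_record(sprintf("run%03d", i), fused[i],
                    first_contact = if (fused[i]) fc[i] else NA_integer_)
    })
    attr(out, "truth") <- list(p = p, n = n, seed = seed)
    out
  })
}
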