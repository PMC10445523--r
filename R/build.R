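# Construction of coarse-grained droplet systems: packed oil cores,
# spherical phospholipid monolayer shells, two-droplet boxes, hydration.
#
# These are initial-configuration generators for an MD engine: geometry is
# seeded and reproducible, inter-molecular contacts are respected where
# physically required, and mild strain (to be relaxed by the engine's
# equilibration) is acceptable.

#' Pack an oil droplet core by seeded random sequential insertion
#'
#' Molecule anchor points are inserted uniformly in a sphere; each
#' molecule's beads are then grown from the anchor as a random walk at the
#' template bond length.  A bead placement is rejected when it falls within
#' the template contact distance of any previously placed molecule's beads
#' (cell-list lookup) or leaves the sphere by more than one bond length.
#' Identical template, counts, radius and seed give bitwise-identical
#' coordinates.
#'
#' @param template a [molecule_template()] with role `"core"`.
#' @param n_molecules number of molecules to pack.
#' @param radius sphere radius in nm; when `NULL`, derived from
#'   `n_molecules * molecule_volume`.
#' @param seed integer RNG seed.
#' @param component component tag for the packed beads.
#' @param center droplet centre, nm.
#' @param max_anchor_tries,max_regrow,max_bead_tries retry budgets; packing
#'   aborts with a diagnostic when exhausted.
#' @return A `bead_system` fragment (no box) with attributes `center` and
#'   `radius`.
#' @export
build_core <- function(template, n_molecules, radius = NULL, seed = 1,
                       component = "oleosome_core", center = c(0, 0, 0),
                       max_anchor_tries = 300L, max_regrow = 25L,
                       max_bead_tries = 40L) {
  stopifnot(inherits(template, "molecule_template"), n_molecules >= 1)
  if (is.null(radius)) {
    if (is.null(template$molecule_volume)) {
      stop("need an explicit radius or a template molecule_volume")
    }
    radius <- (3 * n_molecules * template$molecule_volume / (4 * pi))^(1 / 3)
  }
  stopifnot(radius > 0)
  nb <- length(template$beads)
  N <- as.integer(n_molecules) * nb
  contact <- template$contact_distance
  bond <- template$bond_length
  # hard-sphere packing-fraction bound: random insertion of spheres of
  # diameter `contact` jams well below ~0.38; refuse clearly hopeless specs
  phi <- N * (contact / 2)^3 / (radius + bond)^3
  if (phi > 0.40) {
    stop(sprintf(
      "requested packing fraction %.2f exceeds the random-insertion bound",
      phi))
  }
  h <- contact
  origin <- center - (radius + bond + h)
  P <- matrix(NA_real_, N, 3L)
  cells <- new.env(hash = TRUE, parent = emptyenv())
  offs <- as.matrix(expand.grid(-1L:1L, -1L:1L, -1L:1L))
  cell_of <- function(p) as.integer(floor((p - origin) / h))
  ok_bead <- function(p) {
    ci <- cell_of(p)
    for (o in seq_len(27L)) {
      key <- paste(ci[1] + offs[o, 1], ci[2] + offs[o, 2], ci[3] + offs[o, 3])
      idx <- cells[[key]]
      if (!is.null(idx)) {
        dx <- P[idx, , drop = FALSE] -
          matrix(p, length(idx), 3L, byrow = TRUE)
        if (min(rowSums(dx * dx)) < contact^2) return(FALSE)
      }
    }
    TRUE
  }
  add_bead <- function(p, row) {
    ci <- cell_of(p)
    key <- paste(ci[1], ci[2], ci[3])
    cells[[key]] <- c(cells[[key]], row)
  }
  r2max <- (radius + bond)^2
  with_seed(seed, {
    row <- 0L
    for (m in seq_len(n_molecules)) {
      placed <- FALSE
      for (a in seq_len(max_anchor_tries)) {
        u <- drop(random_unit_vectors(1L))
        anchor <- center + radius * stats::runif(1L)^(1 / 3) * u
        if (!ok_bead(anchor)) next
        for (g in seq_len(max_regrow)) {
          chain <- matrix(NA_real_, nb, 3L)
          chain[1L, ] <- anchor
          ok <- TRUE
          if (nb > 1L) for (k in 2L:nb) {
            found <- FALSE
            for (b in seq_len(max_bead_tries)) {
              p <- chain[k - 1L, ] + bond * drop(random_unit_vectors(1L))
              if (sum((p - center)^2) <= r2max && ok_bead(p)) {
                chain[k, ] <- p
                found <- TRUE
                break
              }
            }
            if (!found) { ok <- FALSE; break }
          }
          if (ok) {
            for (k in seq_len(nb)) {
              P[row + k, ] <- chain[k, ]
              add_bead(chain[k, ], row + k)
            }
            row <- row + nb
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) {
        stop(sprintf(
          paste0("core packing failed at molecule %d of %d ",
                 "(radius %.2f nm, packing fraction %.2f): ",
                 "increase the radius or reduce the count"),
          m, n_molecules, radius, phi))
      }
    }
  })
  sys <- bead_system(P,
                     molid = rep(seq_len(n_molecules), each = nb),
                     atom = rep(template$beads, n_molecules),
                     component = rep(component, N),
                     template = rep(template$name, N))
  attr(sys, "center") <- center
  attr(sys, "radius") <- radius
  sys
}

#' Dress a droplet core with a phospholipid monolayer shell
#'
#' Head groups are placed quasi-uniformly on a sphere by a Fibonacci lattice
#' given a seeded random rotation; each molecule's remaining beads run
#' radially inward at the template bond spacing, so every phospholipid has
#' its head group strictly outside its tails.  The head-group centroid of
#' each molecule sits exactly at `radius`, which makes the declared density
#' `n_shell / (4 pi radius^2)` agree with [measure_shell_density()].
#' The shell is deterministic given the seed; shell tails intentionally
#' reach into the core region (phospholipid fatty acids are solubilized in
#' the oil core).
#'
#' @param core a `bead_system` core fragment (supplies centre and default
#'   radius), or `NULL` with explicit `center`/`radius`.
#' @param template a [molecule_template()] with role `"shell"`.
#' @param n_shell number of shell molecules (0 gives an empty fragment).
#' @param radius head-group sphere radius, nm; default core radius plus one
#'   bond length.
#' @param seed integer RNG seed (rotation only).
#' @param component component tag for the shell beads.
#' @param center droplet centre; default taken from `core`.
#' @return A `bead_system` fragment, or `NULL` when `n_shell` is 0.
#' @export
build_shell <- function(core, template, n_shell, radius = NULL, seed = 1,
                        component = "oleosome_shell", center = NULL) {
  stopifnot(inherits(template, "molecule_template"),
            template$role == "shell", n_shell >= 0)
  if (n_shell == 0L) return(NULL)
  if (is.null(center)) {
    center <- attr(core, "center") %||% colMeans(core$pos)
  }
  if (is.null(radius)) {
    if (is.null(core)) stop("need a core or an explicit shell radius")
    radius <- (attr(core, "radius") %||%
                 max(sqrt(rowSums(sweep(core$pos, 2, center)^2)))) +
      template$bond_length
  }
  nb <- length(template$beads)
  bond <- template$bond_length
  hbar <- mean(template$head_beads)
  r_k <- radius + (hbar - seq_len(nb)) * bond
  if (min(r_k) <= 0.05) {
    stop("shell radius too small for the template chain length")
  }
  spacing <- sqrt(4 * pi * radius^2 / n_shell)
  if (spacing < template$contact_distance) {
    stop(sprintf(
      "shell density demands head spacing %.2f nm below contact %.2f nm",
      spacing, template$contact_distance))
  }
  i <- seq_len(n_shell) - 0.5
  z <- 1 - 2 * i / n_shell
  rho <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n_shell) - 1)
  U <- cbind(rho * cos(th), rho * sin(th), z)
  R <- with_seed(seed, random_rotation())
  U <- U %*% t(R)
  # beads: molecule m bead k at center + r_k[k] * U[m, ]
  pos <- matrix(NA_real_, n_shell * nb, 3L)
  for (k in seq_len(nb)) {
    pos[seq(k, by = nb, length.out = n_shell), ] <-
      sweep(U * r_k[k], 2L, center, "+")
  }
  sys <- bead_system(pos,
                     molid = rep(seq_len(n_shell), each = nb),
                     atom = rep(template$beads, n_shell),
                     component = rep(component, n_shell * nb),
                     template = rep(template$name, n_shell * nb))
  attr(sys, "center") <- center
  attr(sys, "radius") <- radius
  sys
}

#' Build a complete droplet (core plus optional monolayer shell)
#'
#' Convenience wrapper: packs the core, optionally derives the shell radius
#' from a target surface density (`radius = sqrt(n_shell / (4 pi rho))`),
#' and merges core and shell into one fragment.
#'
#' @param core_template,n_core core species and count.
#' @param radius core radius, nm (`NULL`: derived from molecule volume).
#' @param shell_template,n_shell shell species and count (0 for a bare
#'   droplet).
#' @param shell_density target shell surface density in nm-2 (used to derive
#'   the shell radius when given).
#' @param shell_radius explicit head-group sphere radius, nm.
#' @param seed integer seed; the shell uses a derived seed.
#' @param core_component,shell_component component tags.
#' @return A `bead_system` fragment with attributes `center`, `core_radius`,
#'   `shell_radius` and `declared_density`.
#' @examples
#' \donttest{
#' drop <- build_droplet(template_triolein(), n_core = 40, radius = 2.8,
#'                       shell_template = template_dppc(), n_shell = 30,
#'                       shell_density = 0.7, seed = 7)
#' measure_shell_density(drop)
#' }
#' @export
build_droplet <- function(core_template, n_core, radius = NULL,
                          shell_template = NULL, n_shell = 0,
                          shell_density = NULL, shell_radius = NULL,
                          seed = 1,
                          core_component = "oleosome_core",
                          shell_component = "oleosome_shell") {
  core <- build_core(core_template, n_core, radius = radius, seed = seed,
                     component = core_component)
  shell <- NULL
  if (n_shell > 0L) {
    if (is.null(shell_radius) && !is.null(shell_density)) {
      shell_radius <- sqrt(n_shell / (4 * pi * shell_density))
    }
    shell <- build_shell(core, shell_template, n_shell,
                         radius = shell_radius, seed = seed + 1L,
                         component = shell_component)
  }
  sys <- if (is.null(shell)) core else merge_systems(core, shell)
  attr(sys, "center") <- attr(core, "center")
  attr(sys, "core_radius") <- attr(core, "radius")
  attr(sys, "shell_radius") <- if (is.null(shell)) NA_real_
                               else attr(shell, "radius")
  attr(sys, "declared_density") <- if (is.null(shell)) NA_real_
    else n_shell / (4 * pi * attr(shell, "radius")^2)
  sys
}

#' Assemble the two-droplet periodic box
#'
#' Places two droplet fragments side by side along x with a prescribed
#' surface-to-surface gap (surfaces taken as the extreme bead coordinates of
#' each fragment along x), centres the pair in the box, and rejects
#' configurations that do not fit.
#'
#' @param a,b `bead_system` fragments (e.g. a coated and a bare droplet).
#' @param gap surface-to-surface distance along x, nm.
#' @param box periodic box lengths, nm.
#' @return A `bead_system` with the box set, component tags preserved and
#'   molecule ids renumbered; attribute `centers` holds the two droplet
#'   centres.
#' @export
compose_two_droplet_box <- function(a, b, gap = 0.47, box = c(52, 32, 32)) {
  stopifnot(inherits(a, "bead_system"), inherits(b, "bead_system"),
            gap >= 0, length(box) == 3L)
  ca <- colMeans(a$pos); cb <- colMeans(b$pos)
  ra <- sweep(a$pos, 2L, ca); rb <- sweep(b$pos, 2L, cb)
  shift_bx <- max(ra[, 1]) + gap - min(rb[, 1])   # b centre rel. to a centre
  span_x <- (max(rb[, 1]) + shift_bx) - min(ra[, 1])
  half_yz_a <- apply(abs(ra[, 2:3, drop = FALSE]), 2L, max)
  half_yz_b <- apply(abs(rb[, 2:3, drop = FALSE]), 2L, max)
  if (span_x >= box[1] || any(2 * pmax(half_yz_a, half_yz_b) >= box[2:3])) {
    stop("droplets overlap the box boundary")
  }
  a_cx <- (box[1] - span_x) / 2 - min(ra[, 1])
  ca_new <- c(a_cx, box[2] / 2, box[3] / 2)
  cb_new <- ca_new + c(shift_bx, 0, 0)
  a2 <- translate_system(a, ca_new - ca)
  b2 <- translate_system(b, cb_new - cb)
  sys <- merge_systems(a2, b2)
  sys$box <- as.numeric(box)
  attr(sys, "centers") <- rbind(ca_new, cb_new)
  attr(sys, "gap") <- gap
  sys
}

#' Hydrate a boxed system with coarse-grained solvent beads
#'
#' Solvent beads are placed on a jittered rectangular lattice at the target
#' bead density, excluding lattice points within an exclusion distance of
#' any solute bead.  The default density of 8.3 nm-3 is a calibration: with
#' this builder's exclusion geometry it reproduces a solvent count of about
#' 350,000 beads for the reference two-droplet 52 x 32 x 32 nm system (see
#' the package vignette).
#'
#' @param system a `bead_system` with a box.
#' @param template solvent [molecule_template()] (one bead per molecule).
#' @param density target solvent bead density, nm-3 (0 adds nothing).
#' @param exclusion minimum solvent-solute distance, nm.
#' @param jitter half-width of the uniform lattice jitter, nm (kept small so
#'   neighbouring solvent beads stay at least `exclusion` apart).
#' @param seed integer RNG seed for the jitter.
#' @param component component tag for the solvent.
#' @return The hydrated, wrapped `bead_system`; attribute `water_count`
#'   holds the number of solvent beads added.
#' @export
hydrate <- function(system, template = template_water(), density = 8.3,
                    exclusion = 0.40, jitter = 0.04, seed = 1,
                    component = "water") {
  stopifnot(inherits(system, "bead_system"), !is.null(system$box),
            density >= 0, exclusion >= 0, jitter >= 0)
  if (density == 0) {
    attr(system, "water_count") <- 0L
    return(system)
  }
  box <- system$box
  nvec <- pmax(1L, as.integer(round(box * density^(1 / 3))))
  s <- box / nvec
  if (min(s) - 2 * jitter < exclusion * 0.99) {
    warning("lattice spacing close to the exclusion distance; ",
            "solvent-solvent contacts may fall below it")
  }
  ncand <- prod(nvec)
  jit <- with_seed(seed,
                   matrix(stats::runif(3L * ncand, -jitter, jitter),
                          ncol = 3L))
  excluded <- logical(ncand)
  sol <- system$pos
  reach <- exclusion + jitter * sqrt(3)
  if (reach > min(s)) {
    stop("exclusion distance exceeds the lattice spacing stencil")
  }
  offs <- as.matrix(expand.grid(-1L:1L, -1L:1L, -1L:1L))
  k0 <- cbind(round(sol[, 1] / s[1] + 0.5),
              round(sol[, 2] / s[2] + 0.5),
              round(sol[, 3] / s[3] + 0.5))
  for (o in seq_len(nrow(offs))) {
    ki <- sweep(k0, 2L, as.numeric(offs[o, ]), "+")
    valid <- ki[, 1] >= 1 & ki[, 1] <= nvec[1] &
      ki[, 2] >= 1 & ki[, 2] <= nvec[2] &
      ki[, 3] >= 1 & ki[, 3] <= nvec[3]
    if (!any(valid)) next
    ki <- ki[valid, , drop = FALSE]
    lin <- as.integer((ki[, 3] - 1) * nvec[1] * nvec[2] +
                        (ki[, 2] - 1) * nvec[1] + ki[, 1])
    cx <- cbind((ki[, 1] - 0.5) * s[1], (ki[, 2] - 0.5) * s[2],
                (ki[, 3] - 0.5) * s[3]) + jit[lin, , drop = FALSE]
    d2 <- rowSums((cx - sol[valid, , drop = FALSE])^2)
    excluded[lin[d2 < exclusion^2]] <- TRUE
  }
  keep <- which(!excluded)
  nw <- length(keep)
  k1 <- (keep - 1L) %% nvec[1] + 1L
  k2 <- ((keep - 1L) %/% nvec[1]) %% nvec[2] + 1L
  k3 <- (keep - 1L) %/% (nvec[1] * nvec[2]) + 1L
  wpos <- cbind((k1 - 0.5) * s[1], (k2 - 0.5) * s[2], (k3 - 0.5) * s[3]) +
    jit[keep, , drop = FALSE]
  water <- bead_system(wpos, molid = seq_len(nw),
                       atom = rep(template$beads[1], nw),
                       component = rep(component, nw),
                       template = rep(template$name, nw))
  out <- wrap_system(merge_systems(system, water))
  for (at in c("centers", "gap", "center", "core_radius", "shell_radius",
               "declared_density")) {
    a <- attr(system, at)
    if (!is.null(a)) attr(out, at) <- a
  }
  attr(out, "water_count") <- nw
  out
}

#' Measured phospholipid surface density of a shell
#'
#' Divides the shell molecule count by the area of the sphere through the
#' mean head-bead radial distance from the droplet core centre.
#'
#' @param system a `bead_system` containing the shell (fragment or boxed).
#' @param shell_component component tag of the shell.
#' @param core_component component tag supplying the droplet centre; by
#'   default the shell tag with `"shell"` replaced by `"core"` when such
#'   beads exist, else the shell itself.
#' @param head_atoms bead labels treated as head-group beads.
#' @return Surface density in nm-2.
#' @export
measure_shell_density <- function(system, shell_component = "oleosome_shell",
                                  core_component = NULL,
                                  head_atoms = c("NC3", "PO4")) {
  stopifnot(inherits(system, "bead_system"))
  if (!any(system$component == shell_component)) {
    stop("no beads with component ", shell_component)
  }
  if (is.null(core_component)) {
    guess <- sub("shell", "core", shell_component, fixed = TRUE)
    core_component <- if (any(system$component == guess)) guess
                      else shell_component
  }
  center <- component_center(system, core_component)
  sel <- system$component == shell_component & system$atom %in% head_atoms
  if (!any(sel)) {
    stop("no head beads (", paste(head_atoms, collapse = ", "),
         ") in component ", shell_component)
  }
  dx <- min_image(sweep(system$pos[sel, , drop = FALSE], 2L, center),
                  system$box)
  r_hat <- mean(sqrt(rowSums(dx * dx)))
  n_shell <- length(unique(system$molid[system$component == shell_component]))
  n_shell / (4 * pi * r_hat^2)
}
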