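# Interfacial phospholipid bookkeeping for an oleosome-in-water dispersion.
#
# Unit conventions: masses g, densities g cm-3, diameters um internally
# converted to nm, areas nm2, volumes nm3.  1 cm3 = 1e21 nm3.

CM3_TO_NM3 <- 1e21
UM_TO_NM <- 1e3

#' Composition of an oleosome dispersion
#'
#' Parameter set for the interfacial density bookkeeping: a water dispersion
#' of oleosomes (default 70 g at 10 wt%, i.e. 7 g of oleosome lipid), oil
#' density 0.91 g cm-3, a phospholipid content of 0.6 wt% of the oleosome
#' mass with phosphatidylcholine molar mass 786.1 g mol-1, and optionally a
#' mass of free oil added to the dispersion.  Added oil is assumed to share
#' the oleosome oil density and carries no phospholipid.
#'
#' @param batch_mass total dispersion mass in g.
#' @param oleosome_mass_fraction oleosome mass fraction of the dispersion.
#' @param oil_density oil density in g cm-3.
#' @param pl_mass_fraction phospholipid mass fraction of the oleosome mass.
#' @param pl_molar_mass phospholipid molar mass in g mol-1.
#' @param added_oil_mass mass of free oil added, g (>= 0).
#' @param avogadro Avogadro's number, mol-1.
#' @return An object of class `dispersion_spec`.
#' @examples
#' spec <- dispersion_spec()
#' oleosome_mass(spec)          # 7 g
#' pl_count(spec)               # ~3.2e19 molecules
#' @export
dispersion_spec <- function(batch_mass = 70,
                            oleosome_mass_fraction = 0.10,
                            oil_density = 0.91,
                            pl_mass_fraction = 0.006,
                            pl_molar_mass = 786.1,
                            added_oil_mass = 0,
                            avogadro = 6.02214e23) {
  stopifnot(batch_mass >= 0, added_oil_mass >= 0,
            oleosome_mass_fraction >= 0, oleosome_mass_fraction <= 1,
            pl_mass_fraction >= 0, pl_mass_fraction <= 1,
            oil_density > 0, pl_molar_mass > 0, avogadro > 0)
  structure(list(batch_mass = batch_mass,
                 oleosome_mass_fraction = oleosome_mass_fraction,
                 oil_density = oil_density,
                 pl_mass_fraction = pl_mass_fraction,
                 pl_molar_mass = pl_molar_mass,
                 added_oil_mass = added_oil_mass,
                 avogadro = avogadro),
            class = "dispersion_spec")
}

#' @rdname dispersion_spec
#' @param spec a `dispersion_spec`.
#' @export
oleosome_mass <- function(spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  spec$batch_mass * spec$oleosome_mass_fraction
}

#' Total interfacial area of the dispersed oil
#'
#' Treats all oil (oleosome lipid plus any added free oil) as monodisperse
#' spheres of the representative diameter: the total area is the area of one
#' droplet times the droplet count, which collapses to `6 V / d` for total
#' oil volume `V`.
#'
#' @param spec a [dispersion_spec()].
#' @param diameter representative droplet diameter in micrometres (the
#'   pipeline default is the volume mean diameter d4,3).
#' @return Total interfacial area in nm2.
#' @examples
#' total_surface_area(dispersion_spec(), 1.7)   # ~2.7e19 nm2
#' @export
total_surface_area <- function(spec, diameter) {
  stopifnot(inherits(spec, "dispersion_spec"))
  if (!is.finite(diameter) || diameter <= 0) {
    stop("representative diameter must be positive")
  }
  oil_mass <- oleosome_mass(spec) + spec$added_oil_mass
  if (oil_mass <= 0) stop("no oil in the dispersion")
  V <- oil_mass / spec$oil_density * CM3_TO_NM3   # nm3
  6 * V / (diameter * UM_TO_NM)
}

#' Number of phospholipid molecules in the dispersion
#'
#' `N_PL = oleosome mass x PL mass fraction / molar mass x N_A`.  Added free
#' oil contributes no phospholipid.
#'
#' @inheritParams total_surface_area
#' @return Phospholipid count (dimensionless).
#' @export
pl_count <- function(spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  oleosome_mass(spec) * spec$pl_mass_fraction / spec$pl_molar_mass *
    spec$avogadro
}

#' Interfacial density report
#'
#' Assembles the full per-droplet and whole-dispersion bookkeeping: droplet
#' area and volume at the representative diameter, droplet count, total
#' interfacial area, phospholipid count, phospholipids per nm2 and its
#' inverse, the area available per phospholipid.  When the dispersion holds
#' no phospholipid the area per phospholipid is reported as `NA`.
#'
#' @inheritParams total_surface_area
#' @return An object of class `interface_density_report` (a named list).
#' @examples
#' rep <- density_report(dispersion_spec(), 1.7)
#' rep$pl_per_area              # ~1.19 nm^-2
#' ca_round(rep$pl_per_area)    # 1, the one-significant-figure value
#' @export
density_report <- function(spec, diameter) {
  a_t <- total_surface_area(spec, diameter)
  d_nm <- diameter * UM_TO_NM
  a_d <- pi * d_nm^2
  v_d <- pi * d_nm^3 / 6
  n_pl <- pl_count(spec)
  structure(list(representative_diameter = diameter,
                 droplet_area = a_d,
                 droplet_volume = v_d,
                 droplet_count = a_t / a_d,
                 total_area = a_t,
                 pl_count = n_pl,
                 pl_per_area = n_pl / a_t,
                 area_per_pl = if (n_pl > 0) a_t / n_pl else NA_real_),
            class = "interface_density_report")
}

#' @export
print.interface_density_report <- function(x, ...) {
  cat("interface density report\n")
  cat(sprintf("  representative diameter: %.3g um\n",
              x$representative_diameter))
  cat(sprintf("  droplets: %.3g, total area %.3g nm2\n",
              x$droplet_count, x$total_area))
  cat(sprintf("  phospholipids: %.3g (%.3g per nm2",
              x$pl_count, x$pl_per_area))
  if (is.finite(x$area_per_pl %||% NA_real_)) {
    cat(sprintf(", %.3g nm2 per PL)\n", x$area_per_pl))
  } else {
    cat(")\n")
  }
  invisible(x)
}

#' Round to a few significant figures, "circa" style
#'
#' The headline numbers of this kind of bookkeeping are order-of-magnitude
#' estimates; this helper rounds to one significant figure by default.
#'
#' @param x numeric.
#' @param digits significant digits (default 1).
#' @export
ca_round <- function(x, digits = 1) signif(x, digits)
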