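# Coarse-grained molecule templates (Martini-style bead resolution).

#' Coarse-grained molecule template
#'
#' Describes one molecule species at coarse-grained bead resolution: an
#' ordered set of bead labels, the bond length between consecutive beads,
#' the minimum contact distance this species demands from beads of other
#' molecules, and (for monolayer shell species) which beads form the polar
#' head group.  `molecule_volume` is the effective per-molecule volume used
#' to derive droplet radii from molecule counts.
#'
#' @param name residue name (<= 5 characters, GRO convention).
#' @param role `"core"`, `"shell"` or `"solvent"`.
#' @param beads character vector of ordered bead labels (>= 1).
#' @param bond_length distance between consecutive beads, nm.
#' @param contact_distance minimum inter-molecular bead distance, nm.
#' @param head_beads indices of head-group beads (required for shell role).
#' @param molecule_volume effective molecular volume, nm3 (optional).
#' @return An object of class `molecule_template`.
#' @export
molecule_template <- function(name, role = c("core", "shell", "solvent"),
                              beads, bond_length = 0.47,
                              contact_distance = 0.40,
                              head_beads = NULL, molecule_volume = NULL) {
  role <- match.arg(role)
  stopifnot(nchar(name) >= 1L, nchar(name) <= 5L, length(beads) >= 1L,
            bond_length > 0, contact_distance > 0)
  if (role == "shell") {
    if (is.null(head_beads) || length(head_beads) < 1L) {
      stop("shell templates must declare at least one head bead")
    }
    stopifnot(all(head_beads >= 1L), all(head_beads <= length(beads)))
  }
  structure(list(name = name, role = role, beads = as.character(beads),
                 bond_length = bond_length,
                 contact_distance = contact_distance,
                 head_beads = head_beads,
                 molecule_volume = molecule_volume),
            class = "molecule_template")
}

#' Built-in templates: triolein, DPPC, water
#'
#' Fifteen-bead triolein (three glycerol/ester beads plus three four-bead
#' oleoyl tails), twelve-bead DPPC (choline + phosphate head, two glycerol
#' beads, two four-bead palmitoyl tails; head beads are the first two) and
#' single-bead coarse-grained water.  Triolein's `molecule_volume` of
#' 2.178 nm3 is a calibration chosen so that 2560 molecules correspond to a
#' droplet radius of 11.0 nm.
#'
#' @return A [molecule_template()].
#' @export
template_triolein <- function() {
  molecule_template("TRIO", "core",
                    beads = c("GL1", "GL2", "GL3",
                              "C1A", "C2A", "C3A", "C4A",
                              "C1B", "C2B", "C3B", "C4B",
                              "C1C", "C2C", "C3C", "C4C"),
                    molecule_volume = 2.178)
}

#' @rdname template_triolein
#' @export
template_dppc <- function() {
  molecule_template("DPPC", "shell",
                    beads = c("NC3", "PO4", "GL1", "GL2",
                              "C1A", "C2A", "C3A", "C4A",
                              "C1B", "C2B", "C3B", "C4B"),
                    head_beads = c(1L, 2L))
}

#' @rdname template_triolein
#' @export
template_water <- function() {
  molecule_template("W", "solvent", beads = "W")
}
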