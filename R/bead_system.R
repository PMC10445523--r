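# Labelled bead configurations: container, contact validation.

#' Labelled bead configuration
#'
#' The builder's product and the analyzers' input: bead positions in nm with
#' per-bead molecule id, bead (atom) label, template (residue) name and a
#' component tag (e.g. `oleosome_core`, `oleosome_shell`, `free_tag`,
#' `water`), plus an optional orthorhombic periodic box.  Systems without a
#' box are fragments under construction, conventionally centred near the
#' origin.
#'
#' @param pos n x 3 numeric matrix of positions, nm.
#' @param molid integer molecule id per bead (contiguous within a system).
#' @param atom character bead label per bead.
#' @param component character component tag per bead.
#' @param template character residue/template name per bead.
#' @param box periodic box lengths `c(lx, ly, lz)` in nm, or `NULL`.
#' @return An object of class `bead_system`.
#' @export
bead_system <- function(pos, molid, atom, component, template, box = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3L, length(molid) == n, length(atom) == n,
            length(component) == n, length(template) == n)
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  structure(list(pos = unname(pos), molid = as.integer(molid),
                 atom = as.character(atom),
                 component = as.character(component),
                 template = as.character(template),
                 box = if (is.null(box)) NULL else as.numeric(box)),
            class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("bead_system: %d beads, %d molecules%s\n", n_beads(x),
              length(unique(x$molid)),
              if (is.null(x$box)) " (fragment, no box)"
              else sprintf(", box %s nm", paste(signif(x$box, 4),
                                                collapse = " x "))))
  tab <- table(x$component)
  for (nm in names(tab)) cat(sprintf("  %-15s %d beads\n", nm, tab[[nm]]))
  invisible(x)
}

#' @rdname bead_system
#' @param system a `bead_system`.
#' @export
n_beads <- function(system) nrow(system$pos)

#' Combine bead systems
#'
#' Concatenates two systems, renumbering the second system's molecule ids to
#' follow the first.  The box is taken from `a` unless `a` is a fragment.
#'
#' @param a,b `bead_system` objects.
#' @return A `bead_system`.
#' @export
merge_systems <- function(a, b) {
  stopifnot(inherits(a, "bead_system"), inherits(b, "bead_system"))
  off <- if (n_beads(a)) max(a$molid) else 0L
  bead_system(rbind(a$pos, b$pos),
              c(a$molid, b$molid - min(b$molid) + off + 1L),
              c(a$atom, b$atom), c(a$component, b$component),
              c(a$template, b$template), box = a$box %||% b$box)
}

#' Rigid translation of a bead system
#'
#' @param system a `bead_system`.
#' @param shift length-3 numeric displacement in nm.
#' @return The translated `bead_system`.
#' @export
translate_system <- function(system, shift) {
  stopifnot(inherits(system, "bead_system"), length(shift) == 3L)
  system$pos <- sweep(system$pos, 2L, as.numeric(shift), "+")
  system
}

#' Wrap positions into the periodic box
#'
#' @param system a `bead_system` with a box.
#' @return The wrapped `bead_system` with all coordinates in `[0, box)`.
#' @export
wrap_system <- function(system) {
  stopifnot(inherits(system, "bead_system"), !is.null(system$box))
  for (k in 1:3) system$pos[, k] <- system$pos[, k] %% system$box[k]
  system
}

#' Subset of a system by component
#'
#' @param system a `bead_system`.
#' @param component character vector of component tags to keep.
#' @return A `bead_system` restricted to the selected beads.
#' @export
component_subset <- function(system, component) {
  keep <- system$component %in% component
  if (!any(keep)) stop("no beads with component ",
                       paste(component, collapse = ", "))
  bead_system(system$pos[keep, , drop = FALSE], system$molid[keep],
              system$atom[keep], system$component[keep],
              system$template[keep], box = system$box)
}

#' Minimum inter-molecular bead distance
#'
#' Cell-list search for the smallest distance between beads of different
#' molecules, exact whenever that distance is below `cutoff`; returns `Inf`
#' if no inter-molecular pair is closer than `cutoff`.  `method = "brute"`
#' computes the exact minimum by an all-pairs scan (small systems only) and
#' serves as the independent cross-check of the cell-list path.
#'
#' @param system a `bead_system`.
#' @param cutoff search radius in nm (cell method).
#' @param method `"cell"` or `"brute"`.
#' @return Minimum inter-molecular distance in nm (possibly `Inf`).
#' @export
min_intermolecular_distance <- function(system, cutoff = 1.0,
                                        method = c("cell", "brute")) {
  method <- match.arg(method)
  if (method == "brute") {
    n <- n_beads(system)
    if (n > 20000L) stop("brute-force check is limited to small systems")
    best <- Inf
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      j <- j[system$molid[j] != system$molid[i]]
      if (!length(j)) next
      dx <- system$pos[j, , drop = FALSE] -
        matrix(system$pos[i, ], length(j), 3L, byrow = TRUE)
      dx <- min_image(dx, system$box)
      best <- min(best, sqrt(min(rowSums(dx * dx))))
    }
    return(best)
  }
  pr <- grid_join(system$pos, system$pos, cutoff, system$box)
  keep <- pr$i < pr$j & system$molid[pr$i] != system$molid[pr$j]
  if (!any(keep)) Inf else min(pr$d[keep])
}

#' Inter-molecular contact report
#'
#' Counts inter-molecular bead pairs closer than `min_dist`, optionally
#' exempting declared component pairs (the phospholipid shell is expected to
#' interdigitate with the oil core it coats, so `oleosome_shell` vs
#' `oleosome_core` is exempt by default when both tags are present).
#'
#' @param system a `bead_system`.
#' @param min_dist contact distance in nm.
#' @param exempt list of length-2 character vectors of component-tag pairs
#'   excluded from the check (unordered).
#' @return A list: `n_violations`, `min_distance` (among checked pairs below
#'   `min_dist`, `Inf` if none), `checked_pairs` (count of close pairs seen
#'   including exempt ones).
#' @export
contact_report <- function(system, min_dist = 0.40, exempt = list()) {
  pr <- grid_join(system$pos, system$pos, min_dist, system$box)
  keep <- pr$i < pr$j & system$molid[pr$i] != system$molid[pr$j]
  i <- pr$i[keep]; j <- pr$j[keep]; d <- pr$d[keep]
  # aliasing in tiny periodic boxes can report a pair twice; deduplicate
  key <- paste(i, j)
  dup <- duplicated(key)
  i <- i[!dup]; j <- j[!dup]; d <- d[!dup]
  total <- length(d)
  if (length(exempt) && total) {
    pair_tag <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ex <- vapply(exempt, function(p) pair_tag(p[1], p[2]), "")
    keep2 <- !(pair_tag(system$component[i], system$component[j]) %in% ex)
    i <- i[keep2]; j <- j[keep2]; d <- d[keep2]
  }
  list(n_violations = length(d),
       min_distance = if (length(d)) min(d) else Inf,
       checked_pairs = total)
}
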