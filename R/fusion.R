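# Droplet fusion detection and shell-density time series.

#' Fusion outcome record of one simulation run
#'
#' @param run_id identifier of the run.
#' @param fused logical outcome.
#' @param first_contact frame index of the first qualifying contact (`NA`
#'   iff not fused).
#' @param cutoff,persistence the criterion parameters used (nm, frames).
#' @return An object of class `fusion_record`.
#' @export
fusion_record <- function(run_id, fused, first_contact = NA_integer_,
                          cutoff = NA_real_, persistence = NA_integer_) {
  stopifnot(is.logical(fused), length(fused) == 1L)
  if (fused && is.na(first_contact)) {
    stop("fused records must carry a first-contact frame")
  }
  if (!fused && !is.na(first_contact)) {
    stop("unfused records must not carry a first-contact frame")
  }
  structure(list(run_id = run_id, fused = fused,
                 first_contact = as.integer(first_contact),
                 cutoff = cutoff, persistence = as.integer(persistence)),
            class = "fusion_record")
}

#' @export
print.fusion_record <- function(x, ...) {
  cat(sprintf("fusion_record %s: %s%s\n", x$run_id,
              if (x$fused) "fused" else "not fused",
              if (x$fused) sprintf(" (first contact frame %d)",
                                   x$first_contact) else ""))
  invisible(x)
}

#' Detect droplet fusion in a trajectory
#'
#' Two components are considered fused when at least one inter-component
#' bead pair lies within `cutoff` (minimum-image distance) in some frame and
#' in each of the following `persistence - 1` frames; the first such frame
#' is the first contact.  Fusion detection is monotone in the cutoff: a
#' contact at cutoff c persists at any larger cutoff.
#'
#' @param frames a [frame_set()].
#' @param component_a,component_b component tags of the two droplets.
#' @param cutoff contact distance in nm.
#' @param persistence number of consecutive contact frames required.
#' @param run_id identifier stored in the record.
#' @return A [fusion_record()].
#' @export
detect_fusion <- function(frames, component_a = "oleosome_core",
                          component_b = "free_tag", cutoff = 0.6,
                          persistence = 3L, run_id = "run") {
  stopifnot(inherits(frames, "frame_set"), cutoff > 0, persistence >= 1L)
  f1 <- frames$frames[[1]]
  if (!any(f1$component == component_a)) stop("missing ", component_a)
  if (!any(f1$component == component_b)) stop("missing ", component_b)
  nf <- n_frames(frames)
  contact <- logical(nf)
  for (f in seq_len(nf)) {
    fr <- frames$frames[[f]]
    a <- fr$pos[fr$component == component_a, , drop = FALSE]
    b <- fr$pos[fr$component == component_b, , drop = FALSE]
    pr <- grid_join(a, b, cutoff, fr$box)
    contact[f] <- length(pr$d) > 0L
  }
  runs <- rle(contact)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= persistence)
  if (length(hit)) {
    first <- ends[hit[1L]] - runs$lengths[hit[1L]] + 1L
    fusion_record(run_id, TRUE, first, cutoff, persistence)
  } else {
    fusion_record(run_id, FALSE, cutoff = cutoff, persistence = persistence)
  }
}

#' Shell surface density per frame
#'
#' Applies [measure_shell_density()] to every frame, gating each frame on a
#' successful core-radius estimate from that frame's single-frame radial
#' density profile; frames whose radius estimation fails are reported as
#' `NA` with a message.  After a fusion event the shell spreads over a
#' larger core, so the series decreases.
#'
#' @param frames a [frame_set()].
#' @param shell_component component tag of the shell.
#' @param core_component component tag of the core (centre and radius
#'   estimation); default derived as in [measure_shell_density()].
#' @param head_atoms head-group bead labels.
#' @param n_bins radial bins for the per-frame gating profile.
#' @return Numeric vector, one density (nm-2, possibly `NA`) per frame.
#' @export
shell_density_timeseries <- function(frames,
                                     shell_component = "oleosome_shell",
                                     core_component = NULL,
                                     head_atoms = c("NC3", "PO4"),
                                     n_bins = 100) {
  stopifnot(inherits(frames, "frame_set"))
  f1 <- frames$frames[[1]]
  if (!any(f1$component == shell_component)) {
    stop("missing shell component ", shell_component)
  }
  if (is.null(core_component)) {
    guess <- sub("shell", "core", shell_component, fixed = TRUE)
    core_component <- if (any(f1$component == guess)) guess
                      else shell_component
  }
  vapply(seq_len(n_frames(frames)), function(f) {
    fr <- frames$frames[[f]]
    ok <- tryCatch({
      prof <- radial_component_density(fr, core_component,
                                       groups = fr$component,
                                       n_bins = n_bins,
                                       r_max = if (is.null(fr$box)) {
                                         ctr <- component_center(fr, core_component)
                                         max(sqrt(rowSums(
                                           sweep(fr$pos, 2L, ctr)^2))) + 1
                                       } else NULL)
      estimate_core_radius(prof, core_component)
      TRUE
    }, error = function(e) {
      message(sprintf("frame %d omitted: %s", f, conditionMessage(e)))
      FALSE
    })
    if (!ok) return(NA_real_)
    measure_shell_density(fr, shell_component, core_component, head_atoms)
  }, 0)
}
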