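# Multi-frame trajectories and periodic-aware centres.

#' Ordered set of trajectory frames
#'
#' A list of `bead_system` frames sharing bead count and labels, with
#' non-decreasing time stamps in ps.
#'
#' @param frames list of `bead_system` objects.
#' @param times numeric time stamps in ps (default `0, 1, ...`).
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(frames, times = seq_along(frames) - 1) {
  stopifnot(length(frames) >= 1L, length(times) == length(frames))
  if (any(diff(times) < 0)) stop("time stamps must be non-decreasing")
  f1 <- frames[[1]]
  stopifnot(inherits(f1, "bead_system"))
  for (f in frames[-1L]) {
    stopifnot(inherits(f, "bead_system"))
    if (n_beads(f) != n_beads(f1) || !identical(f$atom, f1$atom) ||
        !identical(f$component, f1$component) ||
        !identical(f$molid, f1$molid)) {
      stop("all frames must share bead count and labels")
    }
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames x %d beads, t = %g..%g ps\n",
              length(x$frames), n_beads(x$frames[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname frame_set
#' @param x a `frame_set`.
#' @export
n_frames <- function(x) length(x$frames)

#' Centre of geometry of a component with periodic unwrapping
#'
#' Beads are shifted to the periodic image nearest a reference bead (the
#' component's first bead) before averaging, so a component straddling the
#' box boundary gets its physical centre rather than the wrapped average;
#' the centre is finally wrapped back into the box.
#'
#' @param frame a `bead_system`.
#' @param component component tag.
#' @return Length-3 position in nm.
#' @export
component_center <- function(frame, component) {
  stopifnot(inherits(frame, "bead_system"))
  sel <- frame$component == component
  if (!any(sel)) stop("empty component ", component)
  p <- frame$pos[sel, , drop = FALSE]
  if (is.null(frame$box)) return(colMeans(p))
  ref <- p[1L, ]
  dx <- min_image(sweep(p, 2L, ref), frame$box)
  (ref + colMeans(dx)) %% frame$box
}
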